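# Variant effect prediction: per-family gain/loss calls for SNPs, an
# in-silico control-mutation null, and the probability-shift filter.

#' Read a SNP table
#'
#' Tab-separated with columns CHROM, POS (1-based), REF, ALT and an
#' optional phenotype column; header optional. Only single-nucleotide
#' substitutions are kept.
#'
#' @param path Path to the TSV.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `phenotype`.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("chrom|CHROM", first)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "pos", "ref", "alt")
  if (ncol(df) < 5) df$phenotype <- "" else names(df)[5] <- "phenotype"
  keep <- nchar(df$ref) == 1 & nchar(df$alt) == 1
  if (any(!keep))
    warning(sum(!keep), " non-SNV record(s) dropped")
  df[keep, c("chrom", "pos", "ref", "alt", "phenotype"), drop = FALSE]
}

#' Extract reference and alternate windows around a variant
#'
#' A `window`-bp window centred on the variant (the variant sits at
#' 0-based offset `window/2` for interior positions; windows are shifted
#' inward at chromosome edges so that they always have full length). The
#' reference allele is checked against the genome.
#'
#' @param genome A `genome_sequence`.
#' @param variant One-row data.frame (or list) with `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param window Window length (bp).
#' @return List with `ref_seq`, `alt_seq`, `offset` (0-based variant
#'   position inside the window), `start` (0-based genomic window start).
#' @export
extract_variant_windows <- function(genome, variant, window = 250L) {
  chrom <- variant$chrom
  len <- genome$lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  pos0 <- variant$pos - 1L               # 0-based
  half <- window %/% 2L
  start <- min(max(pos0 - half, 0L), len - window)
  offset <- pos0 - start
  ref_seq <- get_sequence(genome, chrom, start, start + window)
  have <- substring(ref_seq, offset + 1L, offset + 1L)
  if (have != toupper(variant$ref))
    stop("reference allele mismatch at ", chrom, ":", variant$pos,
         " (genome has ", have, ", variant says ", variant$ref, ")")
  alt_seq <- ref_seq
  substring(alt_seq, offset + 1L, offset + 1L) <- toupper(variant$alt)
  list(ref_seq = ref_seq, alt_seq = alt_seq, offset = offset, start = start)
}

classify_shift <- function(p_ref, p_alt, threshold) {
  ifelse(p_ref < threshold & p_alt >= threshold, "gain",
    ifelse(p_alt < threshold & p_ref >= threshold, "loss",
      ifelse(p_ref >= threshold, "retained", "unbound")))
}

#' Predict the per-family effect of a variant
#'
#' Classifies each family as gain (`p_ref < theta <= p_alt`), loss
#' (`p_alt < theta <= p_ref`), retained (both above) or unbound (both
#' below), with the probability shift `delta = p_alt - p_ref`.
#'
#' @param model Trained `tf_classifier`.
#' @param ref_seq,alt_seq Window sequences from
#'   [extract_variant_windows()].
#' @param threshold Classification threshold (default 0.5).
#' @return data.frame with `family`, `p_ref`, `p_alt`, `delta`, `status`.
#' @export
predict_variant_effect <- function(model, ref_seq, alt_seq,
                                   threshold = 0.5) {
  p <- predict_probabilities(model, c(ref_seq, alt_seq),
                             threshold = threshold)$probabilities
  data.frame(family = model$families,
             p_ref = p[1, ], p_alt = p[2, ],
             delta = p[2, ] - p[1, ],
             status = classify_shift(p[1, ], p[2, ], threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict effects for a table of variants
#'
#' @param model Trained `tf_classifier`.
#' @param genome A `genome_sequence`.
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param threshold Classification threshold.
#' @param window Window length.
#' @return data.frame with one row per (variant, family):
#'   `variant_index`, `chrom`, `pos`, `family`, `p_ref`, `p_alt`, `delta`,
#'   `status`.
#' @export
predict_variant_effects <- function(model, genome, variants,
                                    threshold = 0.5, window = 250L) {
  wins <- lapply(seq_len(nrow(variants)), function(i)
    extract_variant_windows(genome, variants[i, ], window))
  seqs <- c(vapply(wins, `[[`, character(1), "ref_seq"),
            vapply(wins, `[[`, character(1), "alt_seq"))
  n <- nrow(variants)
  p <- predict_probabilities(model, seqs, threshold = threshold)$probabilities
  out <- lapply(seq_len(n), function(i) {
    pr <- p[i, ]; pa <- p[n + i, ]
    data.frame(variant_index = i, chrom = variants$chrom[i],
               pos = variants$pos[i], family = model$families,
               p_ref = pr, p_alt = pa, delta = pa - pr,
               status = classify_shift(pr, pa, threshold),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Control-mutation null for a variant
#'
#' Applies the variant's ref-to-alt substitution at `n` random positions
#' of the same window whose reference base equals the variant's reference
#' base (sampled without replacement, never the variant position itself),
#' re-predicts, and classifies every control against the real variant's
#' gain/loss family set: `expected` (identical gain/loss set), `de_novo`
#' (some other perturbation) or `none` (no gain/loss anywhere).
#'
#' @param model Trained `tf_classifier`.
#' @param genome A `genome_sequence`.
#' @param variant One-row variant data.frame.
#' @param n Number of control mutations (default 30).
#' @param seed Integer seed.
#' @param threshold Classification threshold.
#' @param window Window length.
#' @return A `control_null`: list with `controls` (data.frame: position,
#'   category), `fractions` (expected/de_novo/none), `n_requested`,
#'   `n_used`, `real_effect`.
#' @export
control_mutation_null <- function(model, genome, variant, n = 30L,
                                  seed = 1L, threshold = 0.5,
                                  window = 250L) {
  wv <- extract_variant_windows(genome, variant, window)
  real <- predict_variant_effect(model, wv$ref_seq, wv$alt_seq, threshold)
  real_set <- real$family[real$status %in% c("gain", "loss")]
  real_status <- real$status[match(real_set, real$family)]
  chars <- strsplit(wv$ref_seq, "", fixed = TRUE)[[1]]
  eligible <- setdiff(which(chars == toupper(variant$ref)), wv$offset + 1L)
  n_used <- min(n, length(eligible))
  if (n_used == 0)
    stop("no eligible control positions in the window")
  positions <- with_seed(seed, sample(eligible, n_used))
  mut_seqs <- vapply(positions, function(at) {
    s <- wv$ref_seq
    substring(s, at, at) <- toupper(variant$alt)
    s
  }, character(1))
  p <- predict_probabilities(model, c(wv$ref_seq, mut_seqs),
                             threshold = threshold)$probabilities
  categories <- vapply(seq_len(n_used), function(i) {
    st <- classify_shift(p[1, ], p[1 + i, ], threshold)
    set <- model$families[st %in% c("gain", "loss")]
    if (!length(set)) return("none")
    if (length(set) == length(real_set) && all(sort(set) == sort(real_set)) &&
        all(st[match(real_set, model$families)] == real_status))
      return("expected")
    "de_novo"
  }, character(1))
  fr <- c(expected = mean(categories == "expected"),
          de_novo = mean(categories == "de_novo"),
          none = mean(categories == "none"))
  structure(list(controls = data.frame(position = positions - 1L,
                                       category = categories,
                                       stringsAsFactors = FALSE),
                 fractions = fr, n_requested = n, n_used = n_used,
                 real_effect = real),
            class = "control_null")
}

#' Filter gain/loss events by probability shift
#'
#' Keeps gain/loss events whose absolute probability shift is strictly
#' larger than `min_shift` (default 0.2); a shift of exactly `min_shift`
#' is dropped.
#'
#' @param effects data.frame from [predict_variant_effects()].
#' @param min_shift Minimum |delta|.
#' @return The filtered gain/loss rows, with attribute
#'   `retained_fraction` = kept / all gain-loss events.
#' @export
filter_by_shift <- function(effects, min_shift = 0.2) {
  gl <- effects[effects$status %in% c("gain", "loss"), , drop = FALSE]
  keep <- gl[abs(gl$delta) > min_shift, , drop = FALSE]
  attr(keep, "retained_fraction") <-
    if (nrow(gl)) nrow(keep) / nrow(gl) else NA_real_
  keep
}

#' Summarise variant effects
#'
#' @param effects data.frame from [predict_variant_effects()].
#' @return List with `pct_variants_gain_loss` (percent of variants with at
#'   least one gain/loss family) and `pct_events_gain_loss` (percent of
#'   (variant, family) pairs that are gain/loss).
#' @export
summarize_variant_effects <- function(effects) {
  by_var <- tapply(effects$status %in% c("gain", "loss"),
                   effects$variant_index, any)
  list(pct_variants_gain_loss = 100 * mean(by_var),
       pct_events_gain_loss =
         100 * mean(effects$status %in% c("gain", "loss")))
}
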