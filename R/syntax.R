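# Regulatory-syntax statistics: offset independence, weighted co-occurrence,
# IPM context importance and predictability, co-enrichment networks,
# IPM-baseline FDR comparison and flanking-perturbation scans.

#' Maximum number of sliding windows containing a motif
#'
#' Enumerates the start positions of a sliding window (length `window`,
#' stride `step`) that fully contain a motif of length `motif_len`; the
#' count is the ceiling used to normalise offset-independence scores. For a
#' 250 bp window with 10 bp stride and motifs of 11-20 bp the ceiling is
#' 24 consecutive windows.
#'
#' @param window Window length (bp).
#' @param step Stride (bp).
#' @param motif_len Motif length (bp).
#' @return Integer count of window placements.
#' @export
max_consecutive_windows <- function(window = 250L, step = 10L,
                                    motif_len = 15L) {
  if (motif_len > window) return(0L)
  # window starts live on the stride grid {0, step, 2*step, ...}; a window
  # [s, s + window) contains a motif at [m, m + motif_len) iff
  # m + motif_len - window <= s <= m. Enumerate all motif placements m over
  # one stride period and count grid starts in that interval.
  max(vapply(0:(step - 1L), function(m) {
    lo <- m + motif_len - window
    hi <- m
    max(0, floor(hi / step) - ceiling(lo / step) + 1)
  }, numeric(1)))
}

#' Offset independence of family predictions
#'
#' Regions (e.g. 1.5 kb around a TSS) are scanned with a sliding window
#' (250 bp, 10 bp step). For each family, each maximal run of consecutive
#' positively called windows is scored as its length divided by the
#' ceiling (24 windows for the default geometry, the largest number of
#' placements that can contain one motif), capped at 1; the family score
#' is the mean over runs, or 0 if the family is never called.
#'
#' @param model Trained `tf_classifier`.
#' @param regions Character vector of region sequences (>= window bp).
#' @param window Window length (bp).
#' @param step Stride (bp).
#' @param threshold Call threshold.
#' @param ceiling_len Representative motif length used for the ceiling.
#' @return Named numeric vector of per-family scores in `[0, 1]`.
#' @export
offset_independence <- function(model, regions, window = 250L, step = 10L,
                                threshold = 0.5, ceiling_len = 15L) {
  ceiling_n <- max_consecutive_windows(window, step, ceiling_len)
  fam <- model$families
  run_scores <- stats::setNames(vector("list", length(fam)), fam)
  regions <- regions[nchar(regions) >= window]
  for (reg in regions) {
    starts <- seq.int(1L, nchar(reg) - window + 1L, by = step)
    seqs <- substring(reg, starts, starts + window - 1L)
    calls <- predict_probabilities(model, seqs,
                                   threshold = threshold)$calls
    for (f in seq_along(fam)) {
      v <- calls[, f]
      if (!any(v == 1)) next
      r <- rle(v)
      lens <- r$lengths[r$values == 1]
      run_scores[[f]] <- c(run_scores[[f]], pmin(lens / ceiling_n, 1))
    }
  }
  vapply(run_scores, function(s) if (length(s)) mean(s) else 0, numeric(1))
}

#' Weighted average co-occurrence per family
#'
#' For family f, over the windows where f is called, the count-weighted
#' mean number of other families called:
#' `sum_k k * n_k(f) / sum_k n_k(f)` where `n_k(f)` is the number of
#' windows with f called and exactly k other families called.
#'
#' @param calls Binary call matrix (windows x families) or
#'   `prediction_matrix`.
#' @return Named numeric vector; `NA` for families never called.
#' @export
weighted_cooccurrence <- function(calls) {
  if (inherits(calls, "prediction_matrix")) calls <- calls$calls
  tot <- rowSums(calls)
  vapply(seq_len(ncol(calls)), function(f) {
    sel <- calls[, f] == 1
    if (!any(sel)) return(NA_real_)
    mean(tot[sel] - 1)
  }, numeric(1)) -> out
  names(out) <- colnames(calls)
  out
}

#' IPM context importance value (IPMciv)
#'
#' Primary definition: the fraction of motif-containing windows that the
#' model does NOT call bound,
#' `civ = 1 - (#windows called and containing a hit) / (#windows containing
#' a hit)`; a high value means the motif alone rarely suffices and the
#' model relies on sequence context. The literal occurrence ratio
#' (called-and-containing windows divided by the total number of hits,
#' which can exceed the number of windows) is reported alongside for
#' transparency.
#'
#' @param calls Binary call vector for the family over `windows`, or a
#'   `prediction_matrix` (with `family`).
#' @param hits Motif hits from [scan_genome()].
#' @param windows A `window_set` (taken from `calls` when absent).
#' @param family Family name when `calls` is a `prediction_matrix`.
#' @return List with `civ`, `literal_ratio`, `n_hit_windows`,
#'   `n_called_hit_windows`, `n_hits`.
#' @export
ipm_context_importance <- function(calls, hits, windows = NULL,
                                   family = NULL) {
  if (inherits(calls, "prediction_matrix")) {
    windows <- calls$windows
    calls <- calls$calls[, family]
  }
  if (nrow(hits) == 0 || is.null(windows))
    return(list(civ = NA_real_, literal_ratio = NA_real_,
                n_hit_windows = 0L, n_called_hit_windows = 0L,
                n_hits = nrow(hits)))
  wgr <- as_granges0(windows)
  hgr <- as_granges0(hits)
  ov <- GenomicRanges::findOverlaps(wgr, hgr)
  hit_windows <- unique(S4Vectors::queryHits(ov))
  if (!length(hit_windows))
    return(list(civ = NA_real_, literal_ratio = NA_real_,
                n_hit_windows = 0L, n_called_hit_windows = 0L,
                n_hits = nrow(hits)))
  called_hit <- hit_windows[calls[hit_windows] == 1]
  list(civ = 1 - length(called_hit) / length(hit_windows),
       literal_ratio = length(called_hit) / nrow(hits),
       n_hit_windows = length(hit_windows),
       n_called_hit_windows = length(called_hit),
       n_hits = nrow(hits))
}

#' IPM predictability
#'
#' `1 / civ - 1`: high when motif presence alone predicts binding, low when
#' context dominates. `civ = 0` returns the configured cap.
#'
#' @param ipm_civ Context importance value in `[0, 1]`.
#' @param cap Value returned for `civ = 0`.
#' @return Non-negative scalar.
#' @export
ipm_predictability <- function(ipm_civ, cap = 1e6) {
  if (is.na(ipm_civ)) return(NA_real_)
  if (ipm_civ < 0 || ipm_civ > 1) stop("ipm_civ must be in [0, 1]")
  if (ipm_civ == 0) return(cap)
  1 / ipm_civ - 1
}

#' Co-enrichment Z-score network of family calls
#'
#' For each family pair (a, b) with call probabilities `p_a`, `p_b` over N
#' windows, the expected number of co-calls under independence is
#' `E = N p_a p_b` with standard deviation
#' `sqrt(N p_a p_b (1 - p_a p_b))`; `Z = (observed - E) / sd`. Edges are
#' pairs with `Z >= z_edge`; Fisher's exact p-value is attached per pair
#' and degree centrality per family.
#'
#' @param calls Binary call matrix or `prediction_matrix`.
#' @param sensitivities Optional named per-family sensitivities (attached
#'   to the nodes).
#' @param z_edge Edge threshold (default 1).
#' @return A `cooccurrence_network`: list with `Z` (symmetric matrix),
#'   `fisher_p`, `edges` (data.frame), `degree`, `sensitivity`.
#' @export
cooccurrence_network <- function(calls, sensitivities = NULL, z_edge = 1) {
  if (inherits(calls, "prediction_matrix")) calls <- calls$calls
  fam <- colnames(calls)
  N <- nrow(calls)
  p <- colMeans(calls)
  Fn <- length(fam)
  Z <- matrix(NA_real_, Fn, Fn, dimnames = list(fam, fam))
  FP <- matrix(NA_real_, Fn, Fn, dimnames = list(fam, fam))
  for (a in seq_len(Fn - 1)) for (b in (a + 1):Fn) {
    if (p[a] %in% c(0, 1) || p[b] %in% c(0, 1)) next
    obs <- sum(calls[, a] == 1 & calls[, b] == 1)
    pe <- p[a] * p[b]
    z <- (obs - N * pe) / sqrt(N * pe * (1 - pe))
    Z[a, b] <- Z[b, a] <- z
    tab <- matrix(c(obs, sum(calls[, a] == 1) - obs,
                    sum(calls[, b] == 1) - obs,
                    N - sum(calls[, a] == 1) - sum(calls[, b] == 1) + obs),
                  2, 2)
    FP[a, b] <- FP[b, a] <- stats::fisher.test(tab)$p.value
  }
  ed <- which(upper.tri(Z) & Z >= z_edge, arr.ind = TRUE)
  edges <- data.frame(family_a = fam[ed[, 1]], family_b = fam[ed[, 2]],
                      Z = Z[ed], fisher_p = FP[ed],
                      stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(Fn), fam)
  for (i in seq_len(nrow(edges))) {
    degree[edges$family_a[i]] <- degree[edges$family_a[i]] + 1L
    degree[edges$family_b[i]] <- degree[edges$family_b[i]] + 1L
  }
  structure(list(Z = Z, fisher_p = FP, edges = edges, degree = degree,
                 sensitivity = sensitivities, z_edge = z_edge),
            class = "cooccurrence_network")
}

#' Compare model calls with an IPM-occurrence-only baseline
#'
#' The baseline predictor calls a window bound when it contains at least
#' one motif hit; the model predictor uses its binary calls. Both are
#' scored against experimental labels: `FDR = FP / (FP + TP)` per family,
#' plus the precision fold-change of the model over the baseline.
#'
#' @param hits_list Named list (per family) of hit data.frames from
#'   [scan_genome()].
#' @param calls Binary call matrix or `prediction_matrix` (with windows).
#' @param labels Binary experimental label matrix or `label_matrix`.
#' @param windows `window_set`; taken from `calls` when absent.
#' @return A `baseline_comparison` data.frame with per-family
#'   `fdr_ipm_only`, `fdr_model`, `precision_fold_change`, and an
#'   `averages` attribute.
#' @export
ipm_vs_model_fdr <- function(hits_list, calls, labels, windows = NULL) {
  if (inherits(calls, "prediction_matrix")) {
    if (is.null(windows)) windows <- calls$windows
    calls <- calls$calls
  }
  if (inherits(labels, "label_matrix")) labels <- labels$values
  fam <- intersect(colnames(calls), names(hits_list))
  wgr <- as_granges0(windows)
  out <- lapply(fam, function(f) {
    hits <- hits_list[[f]]
    ipm_call <- integer(nrow(windows))
    if (nrow(hits)) {
      ov <- GenomicRanges::findOverlaps(wgr, as_granges0(hits))
      ipm_call[unique(S4Vectors::queryHits(ov))] <- 1L
    }
    y <- labels[, f]
    fdr <- function(pred) {
      tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
      if (tp + fp == 0) NA_real_ else fp / (fp + tp)
    }
    fi <- fdr(ipm_call); fm <- fdr(calls[, f])
    data.frame(family = f, fdr_ipm_only = fi, fdr_model = fm,
               precision_fold_change = (1 - fm) / (1 - fi),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "averages") <- c(fdr_ipm_only = mean(res$fdr_ipm_only, na.rm = TRUE),
                             fdr_model = mean(res$fdr_model, na.rm = TRUE))
  class(res) <- c("baseline_comparison", "data.frame")
  res
}

#' Perturbation scan of motif-flanking positions
#'
#' For sequences containing a core motif at known offsets, substitutes
#' each base at the requested positions relative to the core (negative =
#' upstream of the core start, `core_len + k` = downstream) and reports
#' the change in per-family call frequency against the unperturbed
#' sequences.
#'
#' @param model Trained `tf_classifier`.
#' @param seqs Sequences containing the core.
#' @param core_offsets 0-based offset of the core within each sequence.
#' @param core_len Core length (bp).
#' @param positions Positions relative to the core start to perturb
#'   (default the -1/+1 flanks).
#' @param threshold Call threshold.
#' @return data.frame with `position`, `base`, and per-family call
#'   frequency deltas; substituting a base by itself gives a zero delta.
#' @export
flank_perturbation_scan <- function(model, seqs, core_offsets, core_len = 6L,
                                    positions = c(-1L, core_len),
                                    threshold = 0.5) {
  stopifnot(length(core_offsets) == length(seqs))
  keep <- !is.na(core_offsets)
  n_skipped <- sum(!keep)
  seqs <- seqs[keep]; core_offsets <- core_offsets[keep]
  if (!length(seqs)) stop("no sequences contain the core motif")
  base_calls <- colMeans(predict_probabilities(model, seqs,
                                               threshold = threshold)$calls)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (pos in positions) {
    at <- core_offsets + pos + 1L          # 1-based string position
    ok <- at >= 1L & at <= nchar(seqs)
    for (b in bases) {
      mut <- seqs[ok]
      substring(mut, at[ok], at[ok]) <- b
      mc <- colMeans(predict_probabilities(model, mut,
                                           threshold = threshold)$calls)
      out[[length(out) + 1L]] <- data.frame(
        position = pos, base = b, t(mc - base_calls[names(mc)]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_skipped") <- n_skipped
  res
}
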