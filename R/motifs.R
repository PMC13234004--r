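# Interaction predictive motif (IPM) discovery: attribution of trained
# models, seqlet extraction, motif building, clustering and genome scanning.

#' Per-nucleotide attribution of a family's prediction
#'
#' `grad_input` computes the gradient of the family's output probability
#' with respect to the one-hot input, multiplied by the input
#' (gradient x input). `shap_sample` estimates sampled Shapley-style
#' contributions: positions are revealed one at a time in random order on
#' top of dinucleotide-shuffled reference sequences and the marginal
#' probability changes are attributed to the revealed position, averaged
#' over `n_refs` references; it is seeded and deterministic.
#'
#' @param model A trained `tf_classifier`.
#' @param seqs Character vector of input sequences.
#' @param family Family name (must be one of `model$families`).
#' @param method `"grad_input"` (default) or `"shap_sample"`.
#' @param n_refs Number of reference shuffles for `shap_sample`.
#' @param seed Seed for `shap_sample`.
#' @param chunk Batch size for `grad_input`.
#' @return List of 4 x L attribution matrices (rows A, C, G, T), one per
#'   sequence.
#' @export
attribute <- function(model, seqs, family,
                      method = c("grad_input", "shap_sample"),
                      n_refs = 10L, seed = 1L, chunk = 256L) {
  method <- match.arg(method)
  f <- match(family, model$families)
  if (is.na(f)) stop("unknown family: ", family)
  L <- model$config$input_len
  if (any(nchar(seqs) != L)) stop("sequences must have length ", L)
  if (method == "grad_input") {
    out <- vector("list", length(seqs))
    for (s in seq(1L, length(seqs), by = chunk)) {
      take <- s:min(s + chunk - 1L, length(seqs))
      B <- length(take)
      X <- encode_batch(seqs[take])
      fwd <- nn_forward(model$params, model$config, X, B, train = FALSE,
                        keep_cache = TRUE)
      dlog <- matrix(0, B, model$config$n_outputs)
      dlog[, f] <- fwd$probs[, f] * (1 - fwd$probs[, f])  # d p / d logit
      bwd <- nn_backward(model$params, model$config, fwd, dlog, B,
                         want_input_grad = TRUE)
      gx <- bwd$dX * X                      # gradient x input
      for (b in seq_len(B)) {
        rows <- ((b - 1L) * L + 1L):(b * L)
        m <- t(gx[rows, , drop = FALSE])
        rownames(m) <- c("A", "C", "G", "T")
        out[[take[b]]] <- m
      }
    }
    out
  } else {
    lapply(seq_along(seqs), function(i) {
      shap_sample_one(model, seqs[i], f, n_refs, seed + i)
    })
  }
}

shap_sample_one <- function(model, seq, f, n_refs, seed) {
  L <- model$config$input_len
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  scores <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  refs <- shuffle_sequences(rep(seq, n_refs), order = 2L, seed = seed)
  with_seed(seed, {
    for (r in seq_len(n_refs)) {
      ref_chars <- strsplit(refs[r], "", fixed = TRUE)[[1]]
      perm <- sample.int(L)
      # batch of L+1 sequences: positions revealed cumulatively
      cur <- ref_chars
      batch <- character(L + 1L)
      batch[1] <- paste(cur, collapse = "")
      for (k in seq_len(L)) {
        cur[perm[k]] <- chars[perm[k]]
        batch[k + 1L] <- paste(cur, collapse = "")
      }
      p <- predict_probabilities(model, batch)$probabilities[, f]
      delta <- diff(p)
      bi <- match(chars[perm], c("A", "C", "G", "T"))
      ok <- !is.na(bi)
      scores[cbind(bi[ok], perm[ok])] <-
        scores[cbind(bi[ok], perm[ok])] + delta[ok]
    }
  })
  scores / n_refs
}

#' Extract high-attribution seqlets
#'
#' Positions whose smoothed absolute attribution exceeds `z_threshold`
#' standard deviations above the per-window mean are merged into maximal
#' runs; runs are trimmed to `max_len` (centred on the attribution peak)
#' and padded to `min_len`.
#'
#' @param maps List of 4 x L attribution matrices from [attribute()].
#' @param seqs The matching sequences.
#' @param z_threshold Z-score threshold.
#' @param min_len,max_len Seqlet length bounds (bp).
#' @param smooth Moving-average window (positions).
#' @param max_gap Gap (bp) across which neighbouring runs are merged.
#' @return data.frame with `window` (index), `start`, `end` (window-local,
#'   0-based half-open), `score` (summed absolute attribution) and `seq`.
#' @export
extract_seqlets <- function(maps, seqs, z_threshold = 1.5, min_len = 4L,
                            max_len = 25L, smooth = 3L, max_gap = 2L) {
  out <- list()
  L <- ncol(maps[[1]])
  for (i in seq_along(maps)) {
    a <- abs(colSums(maps[[i]]))
    if (smooth > 1L) {
      a <- stats::filter(a, rep(1 / smooth, smooth), sides = 2)
      a[is.na(a)] <- 0
      a <- as.numeric(a)
    }
    s <- stats::sd(a)
    if (s == 0) next
    z <- (a - mean(a)) / s
    hot <- which(z > z_threshold)
    if (!length(hot)) next
    runs <- split(hot, cumsum(c(1, diff(hot) > max_gap + 1L)))
    for (r in runs) {
      lo <- min(r); hi <- max(r)
      if (hi - lo + 1L > max_len) {       # trim around the peak
        peak <- r[which.max(a[r])]
        lo <- max(1L, peak - max_len %/% 2L)
        hi <- min(L, lo + max_len - 1L)
        lo <- hi - max_len + 1L
      }
      while (hi - lo + 1L < min_len) {    # pad inside the window
        if (lo > 1L) lo <- lo - 1L
        if (hi - lo + 1L < min_len && hi < L) hi <- hi + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        window = i, start = lo - 1L, end = hi,
        score = sum(a[lo:hi]),
        seq = substring(seqs[i], lo, hi), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(window = integer(), start = integer(),
                      end = integer(), score = numeric(), seq = character()))
  do.call(rbind, out)
}

pwm_revcomp <- function(pwm) {
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- rownames(pwm)
  out
}

pwm_ic <- function(pwm, eps = 1e-9) {
  apply(pwm, 2, function(p) 2 + sum(p * log2(p + eps)))
}

#' Best-offset, strand-aware similarity of two motifs
#'
#' Maximum Pearson correlation of the flattened overlapping columns over
#' all ungapped offsets with at least `min_overlap` shared columns, taking
#' the better of the forward and reverse-complement orientation of the
#' second motif.
#'
#' @param m1,m2 4 x W numeric matrices (probabilities or one-hot averages).
#' @param min_overlap Minimum overlapping columns.
#' @return Similarity in `[-1, 1]`.
#' @export
motif_similarity <- function(m1, m2, min_overlap = 4L) {
  best <- -1
  best_ov <- 0L
  for (m2x in list(m2, pwm_revcomp(m2))) {
    w1 <- ncol(m1); w2 <- ncol(m2x)
    for (off in (-(w2 - min_overlap)):(w1 - min_overlap)) {
      i1 <- max(1L, off + 1L):min(w1, off + w2)
      i2 <- i1 - off
      if (length(i1) < min_overlap) next
      v1 <- as.vector(m1[, i1]); v2 <- as.vector(m2x[, i2])
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
      r <- stats::cor(v1, v2)
      # ties (e.g. periodic motifs) resolve to the larger overlap
      if (r > best + 1e-9 ||
          (abs(r - best) <= 1e-9 && length(i1) > best_ov)) {
        best <- r
        best_ov <- length(i1)
      }
    }
  }
  best
}

#' Build interaction predictive motifs from seqlets
#'
#' Seqlets are greedily clustered by best-offset, strand-aware Pearson
#' correlation of their one-hot matrices against the running cluster
#' average; clusters with at least `min_support` members become IPMs:
#' position-frequency matrices with pseudocount 1, normalised to
#' probabilities.
#'
#' @param seqlets data.frame from [extract_seqlets()].
#' @param family Family label attached to the IPMs.
#' @param min_support Minimum seqlets per IPM (default 10).
#' @param sim_threshold Similarity needed to join an existing cluster.
#' @param max_seqlets Use at most this many top-scoring seqlets.
#' @return List of `ipm` objects (sorted by support), possibly empty; each
#'   has `family`, `pwm` (4 x W, columns sum to 1), `support`, `ic`.
#' @export
build_ipms <- function(seqlets, family, min_support = 10L,
                       sim_threshold = 0.6, max_seqlets = 2000L) {
  seqlets <- seqlets[!grepl("N", seqlets$seq), , drop = FALSE]
  if (nrow(seqlets) < min_support) return(list())
  seqlets <- seqlets[order(-seqlets$score), , drop = FALSE]
  if (nrow(seqlets) > max_seqlets)
    seqlets <- seqlets[seq_len(max_seqlets), , drop = FALSE]
  clusters <- list()   # each: counts matrix (4 x W), n
  for (i in seq_len(nrow(seqlets))) {
    oh <- one_hot(seqlets$seq[i])
    placed <- FALSE
    if (length(clusters)) {
      sims <- vapply(clusters, function(cl)
        motif_similarity(cl$counts / cl$n, oh), numeric(1))
      j <- which.max(sims)
      if (sims[j] >= sim_threshold) {
        clusters[[j]] <- merge_into_cluster(clusters[[j]], oh)
        placed <- TRUE
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- list(counts = oh, n = 1L)
  }
  keep <- vapply(clusters, function(cl) cl$n >= min_support, logical(1))
  clusters <- clusters[keep]
  if (!length(clusters)) return(list())
  clusters <- clusters[order(-vapply(clusters, function(cl) cl$n, numeric(1)))]
  lapply(clusters, function(cl) {
    pfm <- cl$counts + 1                       # pseudocount
    pwm <- sweep(pfm, 2, colSums(pfm), "/")
    structure(list(family = family, pwm = pwm, support = cl$n,
                   ic = pwm_ic(pwm)), class = "ipm")
  })
}

# Align a one-hot seqlet onto the cluster average at its best offset/strand
# and add it to the running counts (overlapping columns only).
merge_into_cluster <- function(cl, oh) {
  avg <- cl$counts / cl$n
  best <- list(sim = -Inf, ov = 0L)
  for (strand in c("+", "-")) {
    m <- if (strand == "+") oh else pwm_revcomp(oh)
    w1 <- ncol(avg); w2 <- ncol(m)
    for (off in (-(w2 - 4L)):(w1 - 4L)) {
      i1 <- max(1L, off + 1L):min(w1, off + w2)
      i2 <- i1 - off
      if (length(i1) < 4L) next
      v1 <- as.vector(avg[, i1]); v2 <- as.vector(m[, i2])
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
      r <- stats::cor(v1, v2)
      if (r > best$sim + 1e-9 ||
          (abs(r - best$sim) <= 1e-9 && length(i1) > best$ov))
        best <- list(sim = r, ov = length(i1), off = off, m = m)
    }
  }
  if (!is.finite(best$sim)) return(cl)
  i1 <- max(1L, best$off + 1L):min(ncol(avg), best$off + ncol(best$m))
  i2 <- i1 - best$off
  cl$counts[, i1] <- cl$counts[, i1] + best$m[, i2]
  cl$n <- cl$n + 1L
  cl
}

#' @export
print.ipm <- function(x, ...) {
  cat("ipm [", x$family, "]: width ", ncol(x$pwm), ", support ", x$support,
      ", consensus ", paste(rownames(x$pwm)[apply(x$pwm, 2, which.max)],
                            collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Cluster IPMs into a motif tree
#'
#' Average-linkage hierarchy over pairwise best-offset, strand-aware
#' column-correlation similarities (distance = 1 - similarity). Pairwise
#' comparisons require an alignment of at least `min_overlap` columns
#' (default 8, about one core motif) — shorter alignments between sharp
#' matrices produce spuriously high correlations.
#'
#' @param ipms List of `ipm` objects (>= 2), ideally named.
#' @param min_overlap Minimum aligned columns for the pairwise
#'   similarities.
#' @return A `motif_tree`: list with `ipms`, `similarity` matrix, `hclust`.
#' @export
cluster_ipms <- function(ipms, min_overlap = 8L) {
  if (length(ipms) < 2) stop("need >= 2 IPMs to cluster")
  labels <- names(ipms)
  if (is.null(labels))
    labels <- make.unique(vapply(ipms, function(x) x$family, character(1)))
  n <- length(ipms)
  S <- diag(1, n)
  dimnames(S) <- list(labels, labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- motif_similarity(ipms[[i]]$pwm, ipms[[j]]$pwm,
                                           min_overlap = min_overlap)
  }
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  structure(list(ipms = ipms, similarity = S, hclust = hc),
            class = "motif_tree")
}

#' Cut a motif tree into flat clusters
#'
#' @param tree A `motif_tree`.
#' @param h Height (1 - similarity) at which to cut.
#' @return Named integer vector of cluster assignments.
#' @export
cut_motif_tree <- function(tree, h = 0.5) {
  stats::cutree(tree$hclust, h = h)
}

#' Scan sequences for motif matches
#'
#' Log-odds scoring against a uniform background (0.25 per base) at every
#' offset on both strands; positions with `N` contribute 0. A hit is
#' reported wherever the score reaches `min_fraction` of the motif's
#' maximum possible theoretical score; overlapping hits are all reported.
#'
#' @param x A `genome_sequence` or (named) character vector of sequences.
#' @param ipm An `ipm` object or a 4 x W probability matrix.
#' @param min_fraction Fraction of the maximum score required (default
#'   0.85).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `score`, `fraction_of_max`.
#' @export
scan_genome <- function(x, ipm, min_fraction = 0.85) {
  pwm <- if (inherits(ipm, "ipm")) ipm$pwm else ipm
  seqs <- if (inherits(x, "genome_sequence")) x$seqs else x
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lo <- log2(pmax(pwm, 1e-9) / 0.25)
  max_score <- sum(apply(lo, 2, max))
  if (max_score <= 0) stop("motif has non-positive maximum log-odds score")
  thr <- min_fraction * max_score
  w <- ncol(lo)
  out <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < w) next
    code <- match(chars, c("A", "C", "G", "T"))
    code[is.na(code)] <- 5L               # N row scores 0
    for (strand in c("+", "-")) {
      m <- if (strand == "+") lo else {
        tmp <- lo[4:1, rev(seq_len(w)), drop = FALSE]
        tmp
      }
      m5 <- rbind(m, 0)
      S <- numeric(n - w + 1L)
      for (j in seq_len(w)) {
        S <- S + m5[cbind(code[j:(n - w + j)], j)]
      }
      hit <- which(S >= thr)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = hit - 1L, end = hit - 1L + w,
          strand = strand, score = S[hit],
          fraction_of_max = S[hit] / max_score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), fraction_of_max = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of motif hits recovered by predicted binding
#'
#' The recovery rate of a motif is the fraction of its genomic hits that
#' fall entirely inside windows called bound for the family.
#'
#' @param pred A `prediction_matrix` carrying `windows`, or a binary call
#'   vector aligned with `windows`.
#' @param hits data.frame of motif hits from [scan_genome()].
#' @param family Family whose calls are used (when `pred` is a
#'   `prediction_matrix`).
#' @param windows Optional `window_set` when `pred` is a plain vector.
#' @return Fraction in `[0,1]`, or `NA` when there are no hits.
#' @export
recovery_rate <- function(pred, hits, family = NULL, windows = NULL) {
  if (inherits(pred, "prediction_matrix")) {
    windows <- pred$windows
    calls <- pred$calls[, family]
  } else calls <- pred
  if (nrow(hits) == 0) return(NA_real_)
  called <- windows[calls == 1, , drop = FALSE]
  if (nrow(called) == 0) return(0)
  hgr <- as_granges0(hits)
  wgr <- as_granges0(called)
  ov <- GenomicRanges::findOverlaps(hgr, wgr, type = "within")
  length(unique(S4Vectors::queryHits(ov))) / nrow(hits)
}

#' Write motifs in MEME minimal format
#'
#' @param ipms List of `ipm` objects (named or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(ipms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  nms <- names(ipms)
  if (is.null(nms))
    nms <- make.unique(vapply(ipms, function(x) x$family, character(1)))
  for (i in seq_along(ipms)) {
    pwm <- ipms[[i]]$pwm
    writeLines(sprintf("MOTIF %s", nms[i]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(pwm), ipms[[i]]$support), con)
    writeLines(apply(pwm, 2, function(p)
      paste(sprintf("%.6f", p), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path Path to a MEME-format motif file.
#' @return Named list of `ipm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    nm <- sub("^MOTIF\\s+(\\S+).*", "\\1", lines[s])
    hdr <- s + 1L
    while (hdr <= length(lines) && !grepl("letter-probability", lines[hdr]))
      hdr <- hdr + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    nsites <- suppressWarnings(
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- lines[(hdr + 1L):(hdr + w)]
    pwm <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    pwm <- t(pwm)  # back to 4 x W
    dim(pwm) <- c(4L, w)
    rownames(pwm) <- c("A", "C", "G", "T")
    out[[nm]] <- structure(list(family = nm, pwm = pwm,
                                support = if (is.na(nsites)) 0L else nsites,
                                ic = pwm_ic(pwm)), class = "ipm")
  }
  out
}

#' Discover IPMs for one family end to end
#'
#' Selects windows correctly predicted positive for the family, attributes
#' them, extracts seqlets and builds IPMs.
#'
#' @param model Trained `tf_classifier`.
#' @param seqs Window sequences.
#' @param labels Binary label matrix (windows x families).
#' @param family Family name.
#' @param max_windows Attribution is restricted to at most this many
#'   top-probability correctly predicted windows.
#' @param pred Optional precomputed `prediction_matrix` over `seqs`
#'   (avoids re-predicting when discovering motifs for many families).
#' @param ... Passed to [extract_seqlets()] and [build_ipms()].
#' @param min_support,z_threshold Tuning knobs forwarded to the steps.
#' @return List of `ipm` objects (possibly empty).
#' @export
discover_ipms <- function(model, seqs, labels, family, max_windows = 2000L,
                          z_threshold = 1.5, min_support = 10L,
                          pred = NULL, ...) {
  if (is.null(pred)) pred <- predict_probabilities(model, seqs)
  f <- match(family, model$families)
  ok <- which(pred$calls[, f] == 1 & labels[, f] == 1)
  if (!length(ok)) return(list())
  ok <- ok[order(-pred$probabilities[ok, f])]
  ok <- ok[seq_len(min(length(ok), max_windows))]
  maps <- attribute(model, seqs[ok], family)
  sl <- extract_seqlets(maps, seqs[ok], z_threshold = z_threshold)
  build_ipms(sl, family, min_support = min_support, ...)
}
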