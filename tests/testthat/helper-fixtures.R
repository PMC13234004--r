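# Shared small fixtures and slow-object caches for the test suite.

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A tiny deterministic genome useful across files.
toy_genome <- function() {
  genome_sequence(c(chrA = paste(rep("ACGT", 250), collapse = ""),
                    chrB = paste(rep("TTGC", 150), collapse = "")))
}

# Brute-force auPR by step-function integration over every threshold —
# the independent oracle for compute_pr_roc.
bruteforce_aupr <- function(scores, labels) {
  if (sum(labels) == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    prec[i] <- sum(labels[pred]) / sum(pred)
    rec[i] <- sum(labels[pred]) / sum(labels)
  }
  sum(diff(c(0, rec)) * prec)
}

# Literal per-window re-implementation of the multi-label confusion
# allocation, kept deliberately separate from compute_mlcm.
mlcm_oracle <- function(calls, labels) {
  fam <- colnames(labels)
  n <- length(fam) + 1L
  M <- matrix(0L, n, n)
  for (i in seq_len(nrow(labels))) {
    T_ <- which(labels[i, ] == 1); P_ <- which(calls[i, ] == 1)
    for (f in intersect(T_, P_)) M[f, f] <- M[f, f] + 1L
    miss <- setdiff(T_, P_); extra <- setdiff(P_, T_)
    if (length(miss) > 0 && length(extra) > 0) {
      for (a in miss) for (b in extra) M[a, b] <- M[a, b] + 1L
    } else if (length(miss) > 0) {
      for (a in miss) M[a, n] <- M[a, n] + 1L
    } else if (length(extra) > 0) {
      for (b in extra) M[n, b] <- M[n, b] + 1L
    } else if (length(T_) == 0 && length(P_) == 0) {
      M[n, n] <- M[n, n] + 1L
    }
  }
  M
}

count_kmers <- function(s, k) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  table(vapply(seq_len(n - k + 1L), function(i)
    paste(chars[i:(i + k - 1L)], collapse = ""), character(1)))
}

# Cache for the expensive end-to-end objects shared by the acceptance
# tests; built on first use only.
.accept_cache <- new.env(parent = emptyenv())

acceptance_bundle <- function() {
  if (is.null(.accept_cache$bundle)) {
    .accept_cache$bundle <- synthetic_bundle(seed = 7)
    w <- tile_windows(.accept_cache$bundle$genome, 250L, 250L)
    .accept_cache$windows <- w
    .accept_cache$labels <- assign_labels(w, .accept_cache$bundle$peak_sets)
    .accept_cache$seqs <- window_sequences(.accept_cache$bundle$genome, w)
  }
  list(bundle = .accept_cache$bundle, windows = .accept_cache$windows,
       labels = .accept_cache$labels, seqs = .accept_cache$seqs)
}

# Reference protocol at test scale: 75 bp offset training windows,
# unweighted, trimmed epoch cap (the vignette documents the problem
# sizes). The d-baseline shares each fold's prepared data.
acceptance_config <- function(seed, epochs = 15L) {
  model_config(n_outputs = 8L, max_epochs = epochs, seed = seed)
}

acceptance_folds <- function() {
  if (is.null(.accept_cache$folds)) {
    ab <- acceptance_bundle()
    chroms <- ab$bundle$genome$chrom_names[1:3]
    .accept_cache$folds <- lapply(chroms, function(ch)
      prepare_fold(ab$bundle$genome, ab$bundle$peak_sets, ch,
                   train_step = 75L))
  }
  .accept_cache$folds
}

fold_result <- function(model, fold) {
  pred <- predict_probabilities(model, fold$val$seqs)
  list(model = model, fold = fold, prediction = pred,
       metrics = compute_pr_roc(pred$probabilities,
                                fold$val$labels$values),
       scores = per_class_scores(pred$calls, fold$val$labels$values))
}

# Real reference models, one per fold.
acceptance_cv <- function() {
  if (is.null(.accept_cache$cv)) {
    .accept_cache$cv <- lapply(seq_along(acceptance_folds()), function(i) {
      fold <- acceptance_folds()[[i]]
      fold_result(train_fold(fold, acceptance_config(100L + i)), fold)
    })
  }
  .accept_cache$cv
}

# Matched dinucleotide-shuffle baselines (same folds; they plateau within
# a couple of epochs because only composition is learnable).
acceptance_cv_dbaseline <- function() {
  if (is.null(.accept_cache$cv_d)) {
    .accept_cache$cv_d <- lapply(seq_along(acceptance_folds()), function(i) {
      fold <- acceptance_folds()[[i]]
      fold_result(train_fold(fold, acceptance_config(200L + i, epochs = 3L),
                             shuffle_order = 2L, shuffle_seed = i),
                  fold)
    })
  }
  .accept_cache$cv_d
}

# Plain non-overlapping-window model on fold 1: the standard-protocol
# baseline that the imbalance-mitigation contrast is measured against.
acceptance_plain_fold1 <- function() {
  if (is.null(.accept_cache$plain1)) {
    ab <- acceptance_bundle()
    fold <- prepare_fold(ab$bundle$genome, ab$bundle$peak_sets, "chr1",
                         train_step = 250L)
    .accept_cache$plain1 <- list(
      model = train_fold(fold, acceptance_config(401L, epochs = 25L)),
      fold = fold)
  }
  .accept_cache$plain1
}

# Class-weighted + 75 bp offset model on fold 1 (the "optimised"
# protocol); the weighted loss converges more slowly, hence the longer
# epoch cap.
acceptance_optimised_fold1 <- function() {
  if (is.null(.accept_cache$opt1)) {
    fold <- acceptance_folds()[[1]]
    cfg <- acceptance_config(301L, epochs = 30L)
    cfg$use_class_weights <- TRUE
    .accept_cache$opt1 <- list(model = train_fold(fold, cfg), fold = fold)
  }
  .accept_cache$opt1
}
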