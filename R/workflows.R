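# Orchestration: fold preparation, chromosome-held-out cross-validation,
# shuffle baselines and the offset/weighted training variants.

#' Prepare training and validation data for one CV fold
#'
#' Training windows are tiled over the training chromosomes at
#' `train_step` (250 for the plain protocol; 75 or 125 for offset
#' augmentation); validation windows are always non-overlapping.
#'
#' @param genome A `genome_sequence`.
#' @param peak_sets List of `peak_set` objects.
#' @param val_chrom Held-out chromosome.
#' @param window_len Window length (bp).
#' @param train_step Step for the training windows.
#' @param min_peak_coverage Labelling coverage threshold.
#' @return List with `train` and `val`, each `list(windows, labels, seqs)`,
#'   plus `val_chrom`.
#' @export
prepare_fold <- function(genome, peak_sets, val_chrom, window_len = 250L,
                         train_step = window_len,
                         min_peak_coverage = 0.7) {
  if (!val_chrom %in% genome$chrom_names)
    stop("unknown validation chromosome: ", val_chrom)
  sub_genome <- function(chroms)
    genome_sequence(genome$seqs[chroms])
  g_tr <- sub_genome(setdiff(genome$chrom_names, val_chrom))
  g_va <- sub_genome(val_chrom)
  w_tr <- tile_windows(g_tr, window_len, train_step)
  w_va <- tile_windows(g_va, window_len, window_len)
  list(train = list(windows = w_tr,
                    labels = assign_labels(w_tr, peak_sets,
                                           min_peak_coverage),
                    seqs = window_sequences(genome, w_tr)),
       val = list(windows = w_va,
                  labels = assign_labels(w_va, peak_sets,
                                         min_peak_coverage),
                  seqs = window_sequences(genome, w_va)),
       val_chrom = val_chrom)
}

#' Train a classifier on one fold
#'
#' Optionally trains on shuffled sequences (`shuffle_order` 1 or 2) to
#' produce the s-/d-baseline models: training and early-stopping sequences
#' are shuffled, labels are kept, and evaluation is performed on the real
#' held-out sequences by the caller.
#'
#' @param fold A fold from [prepare_fold()].
#' @param config A `model_config` (its `n_outputs` must match the
#'   families).
#' @param shuffle_order `NULL` (real sequences), 1 (s-baseline) or 2
#'   (d-baseline).
#' @param shuffle_seed Seed for the baseline shuffles.
#' @param verbose Print training progress.
#' @return A trained `tf_classifier`.
#' @export
train_fold <- function(fold, config, shuffle_order = NULL,
                       shuffle_seed = 1L, verbose = FALSE) {
  fam <- fold$train$labels$families
  if (config$n_outputs != length(fam))
    stop("config$n_outputs must equal the number of families")
  tr_seqs <- fold$train$seqs
  va_seqs <- fold$val$seqs
  if (!is.null(shuffle_order)) {
    tr_seqs <- shuffle_sequences(tr_seqs, shuffle_order, shuffle_seed)
    va_seqs <- shuffle_sequences(va_seqs, shuffle_order, shuffle_seed + 1L)
  }
  model <- build_classifier(config, families = fam)
  train_classifier(model, tr_seqs, fold$train$labels$values,
                   va_seqs, fold$val$labels$values, verbose = verbose)
}

#' Chromosome-held-out cross-validation
#'
#' Trains one model per chromosome fold (plus, optionally, matched
#' shuffle-baseline models) and evaluates every model on its real held-out
#' windows.
#'
#' @param genome A `genome_sequence`.
#' @param peak_sets List of `peak_set` objects.
#' @param config_fn Function `fold_index -> model_config` (so that each
#'   fold can get its own seed), or a single `model_config`.
#' @param folds Fold indices to run (default all chromosomes).
#' @param train_step Training-window step.
#' @param shuffle_order Baseline shuffle order (`NULL` for the real model).
#' @param verbose Print progress.
#' @return List of per-fold results: `model`, `metrics`
#'   (`metrics_report`), `scores` (per-class data.frame), `val_chrom`.
#' @export
run_chromosome_cv <- function(genome, peak_sets, config_fn,
                              folds = NULL, train_step = 250L,
                              shuffle_order = NULL, verbose = FALSE) {
  splits <- chromosome_splits(genome)
  if (is.null(folds)) folds <- seq_along(splits)
  if (inherits(config_fn, "model_config")) {
    cfg <- config_fn
    config_fn <- function(i) { c2 <- cfg; c2$seed <- cfg$seed + i; c2 }
  }
  lapply(folds, function(i) {
    split <- splits[[i]]
    fold <- prepare_fold(genome, peak_sets, split$val_chrom,
                         train_step = train_step)
    model <- train_fold(fold, config_fn(i), shuffle_order = shuffle_order,
                        shuffle_seed = i, verbose = verbose)
    pred <- predict_probabilities(model, fold$val$seqs)
    list(model = model,
         fold = fold,
         prediction = pred,
         metrics = compute_pr_roc(pred$probabilities,
                                  fold$val$labels$values),
         scores = per_class_scores(pred$calls, fold$val$labels$values),
         val_chrom = split$val_chrom,
         fold_index = i)
  })
}
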