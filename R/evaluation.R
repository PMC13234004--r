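#' Area under the precision-recall curve (step-wise integration)
#'
#' Computed by a full threshold sweep with step-wise (non-interpolated)
#' integration of precision over recall. Ties in the scores are handled by
#' grouping: all observations with the same score enter the curve together.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return auPR in `[0, 1]`, or `NA` when there are no positives.
#' @export
auc_pr <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_last <- cumsum(rle(s)$lengths)       # last index of each tied block
  tp <- cumsum(y)[grp_last]
  n <- grp_last
  prec <- tp / n
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney U statistic (rank formulation); ties get
#' half credit.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return auROC in `[0, 1]`, or `NA` when one class is absent or the
#'   scores are constant.
#' @export
auc_roc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  if (length(unique(scores)) == 1L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Per-family and aggregate auPR/auROC metrics
#'
#' Computes per-family precision-recall and ROC areas by threshold sweep,
#' the macro (unweighted) means and the support-weighted means
#' (weights proportional to the number of positive windows in scope).
#' Families without positives in scope are reported as `NA` and excluded
#' from the aggregates. An optional `region_mask` restricts the evaluation
#' to a subset of windows (e.g. promoter-region bins).
#'
#' @param probabilities Matrix (windows x families) of predicted
#'   probabilities, or a `prediction_matrix`.
#' @param labels Binary matrix of the same shape, or a `label_matrix`.
#' @param region_mask Optional logical vector over windows.
#' @param region_scope Free-text scope tag stored in the report.
#' @return A `metrics_report`: data.frame `per_family` (auPR, auROC,
#'   support) plus `macro_aupr`, `macro_auroc`, `weighted_aupr`,
#'   `weighted_auroc`, `region_scope`.
#' @export
compute_pr_roc <- function(probabilities, labels, region_mask = NULL,
                           region_scope = "genome") {
  P <- if (inherits(probabilities, "prediction_matrix"))
    probabilities$probabilities else probabilities
  Y <- if (inherits(labels, "label_matrix")) labels$values else labels
  stopifnot(all(dim(P) == dim(Y)))
  if (!is.null(region_mask)) {
    P <- P[region_mask, , drop = FALSE]
    Y <- Y[region_mask, , drop = FALSE]
  }
  fam <- colnames(P)
  per <- data.frame(
    family = fam,
    support = colSums(Y),
    aupr = vapply(seq_along(fam), function(f) auc_pr(P[, f], Y[, f]),
                  numeric(1)),
    auroc = vapply(seq_along(fam), function(f) auc_roc(P[, f], Y[, f]),
                   numeric(1)),
    stringsAsFactors = FALSE)
  ok_pr <- !is.na(per$aupr)
  ok_roc <- !is.na(per$auroc)
  structure(list(
    per_family = per,
    macro_aupr = mean(per$aupr[ok_pr]),
    macro_auroc = mean(per$auroc[ok_roc]),
    weighted_aupr = sum((per$aupr * per$support)[ok_pr]) /
      sum(per$support[ok_pr]),
    weighted_auroc = sum((per$auroc * per$support)[ok_roc]) /
      sum(per$support[ok_roc]),
    region_scope = region_scope), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report [", x$region_scope, "]: macro auPR ",
      round(x$macro_aupr, 3), ", weighted auPR ", round(x$weighted_aupr, 3),
      ", macro auROC ", round(x$macro_auroc, 3), "\n", sep = "")
  invisible(x)
}

#' Multi-label confusion matrix with a no-label row/column
#'
#' Per window, the true and predicted family sets are aligned: matched
#' families increment the diagonal; unmatched true families distribute one
#' count to every falsely predicted family (or to the no-prediction column
#' when nothing false was predicted); unmatched predicted families
#' analogously go to cells of the no-true-label row; windows with neither
#' true nor predicted labels increment the (no-label, no-label) cell.
#'
#' @param calls Binary matrix (windows x families) of predicted calls.
#' @param labels Binary matrix of true labels, same shape.
#' @return A `mlcm` object: integer matrix of size (F+1) x (F+1) with
#'   `"none"` as the extra row/column; rows are true families, columns
#'   predicted.
#' @export
compute_mlcm <- function(calls, labels) {
  if (inherits(calls, "prediction_matrix")) calls <- calls$calls
  if (inherits(labels, "label_matrix")) labels <- labels$values
  stopifnot(all(dim(calls) == dim(labels)))
  fam <- colnames(labels)
  Fp1 <- length(fam) + 1L
  M <- matrix(0L, Fp1, Fp1, dimnames = list(true = c(fam, "none"),
                                            predicted = c(fam, "none")))
  for (i in seq_len(nrow(labels))) {
    t_set <- which(labels[i, ] == 1)
    p_set <- which(calls[i, ] == 1)
    both <- intersect(t_set, p_set)
    miss <- setdiff(t_set, p_set)      # true but not predicted
    extra <- setdiff(p_set, t_set)     # predicted but not true
    for (f in both) M[f, f] <- M[f, f] + 1L
    if (length(miss) && length(extra)) {
      M[miss, extra] <- M[miss, extra, drop = FALSE] + 1L
    } else if (length(miss)) {
      M[miss, Fp1] <- M[miss, Fp1] + 1L
    } else if (length(extra)) {
      M[Fp1, extra] <- M[Fp1, extra] + 1L
    } else if (!length(t_set) && !length(p_set)) {
      M[Fp1, Fp1] <- M[Fp1, Fp1] + 1L
    }
  }
  structure(M, class = c("mlcm", "matrix"))
}

#' Mask the diagonal of a multi-label confusion matrix
#'
#' Zeroes the diagonal so that off-diagonal confusion structure (shared
#' binding preferences between families) stands out.
#'
#' @param mlcm An `mlcm` matrix.
#' @return The matrix with a zero diagonal.
#' @export
mask_diagonal <- function(mlcm) {
  diag(mlcm) <- 0L
  mlcm
}

mcc_from_counts <- function(tp, fp, fn, tn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)            # constant predictor convention
  (tp * tn - fp * fn) / denom
}

#' Per-family MCC, F1 and balanced accuracy
#'
#' One-vs-rest binary scores per family. The MCC of a constant predictor is
#' defined as 0.
#'
#' @param calls Binary call matrix (windows x families) or
#'   `prediction_matrix`.
#' @param labels Binary label matrix or `label_matrix`.
#' @return data.frame with `family`, `support`, `tp`, `fp`, `fn`, `tn`,
#'   `mcc`, `f1`, `balanced_accuracy`, `sensitivity`.
#' @export
per_class_scores <- function(calls, labels) {
  if (inherits(calls, "prediction_matrix")) calls <- calls$calls
  if (inherits(labels, "label_matrix")) labels <- labels$values
  stopifnot(all(dim(calls) == dim(labels)))
  fam <- colnames(labels)
  out <- lapply(seq_along(fam), function(f) {
    y <- labels[, f]; p <- calls[, f]
    tp <- sum(y == 1 & p == 1); fp <- sum(y == 0 & p == 1)
    fn <- sum(y == 1 & p == 0); tn <- sum(y == 0 & p == 0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    data.frame(family = fam[f], support = sum(y), tp = tp, fp = fp, fn = fn,
               tn = tn, mcc = mcc_from_counts(tp, fp, fn, tn), f1 = f1,
               balanced_accuracy = mean(c(sens, spec)), sensitivity = sens,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bootstrap MCC by number of families called per window
#'
#' Windows are binned by the number of distinct families called (0 up to
#' `max_bin`, larger counts pooled into the last bin). Within each bin the
#' MCC over all (window, family) cells is computed exactly and over
#' `n_boot` bootstrap resamples of the bin's windows (with replacement,
#' same size). Empty bins are skipped with a note.
#'
#' @param calls Binary call matrix or `prediction_matrix`.
#' @param labels Binary label matrix or `label_matrix`.
#' @param n_boot Bootstrap replicates (default 100; 1000 reproduces the
#'   larger protocol).
#' @param max_bin Largest bin (counts >= `max_bin` pooled).
#' @param seed Integer seed.
#' @return A `binned_mcc` object: data.frame `bins` (bin, n_windows,
#'   exact_mcc, boot_mean, boot_sd) plus list `boot` of per-bin bootstrap
#'   draws.
#' @export
binned_bootstrap_mcc <- function(calls, labels, n_boot = 100L, max_bin = 11L,
                                 seed = 1L) {
  if (inherits(calls, "prediction_matrix")) calls <- calls$calls
  if (inherits(labels, "label_matrix")) labels <- labels$values
  k <- pmin(rowSums(calls), max_bin)
  flat_mcc <- function(rows) {
    p <- as.vector(calls[rows, , drop = FALSE])
    y <- as.vector(labels[rows, , drop = FALSE])
    mcc_from_counts(sum(y & p), sum(!y & p), sum(y & !p), sum(!y & !p))
  }
  bins <- sort(unique(k))
  boot <- list()
  rows_list <- split(seq_along(k), k)
  res <- with_seed(seed, {
    lapply(bins, function(b) {
      rows <- rows_list[[as.character(b)]]
      draws <- replicate(n_boot,
                         flat_mcc(rows[sample.int(length(rows),
                                                  replace = TRUE)]))
      boot[[as.character(b)]] <<- draws
      data.frame(bin = b, n_windows = length(rows),
                 exact_mcc = flat_mcc(rows),
                 boot_mean = mean(draws), boot_sd = stats::sd(draws))
    })
  })
  skipped <- setdiff(0:max_bin, bins)
  structure(list(bins = do.call(rbind, res), boot = boot, n_boot = n_boot,
                 skipped_bins = skipped),
            class = "binned_mcc")
}

#' Correlation between class abundance and class performance
#'
#' Pearson correlation (with a two-sided t-test) between per-family support
#' and a per-family performance metric such as MCC.
#'
#' @param support Numeric vector of per-family supports.
#' @param metric Numeric vector of per-family scores (NA allowed).
#' @return List with `r`, `p`, `n`; `r = NA` when fewer than 3 families
#'   have defined values or a vector is constant.
#' @export
abundance_correlation <- function(support, metric) {
  ok <- !is.na(support) & !is.na(metric)
  if (sum(ok) < 3 || stats::sd(support[ok]) == 0 || stats::sd(metric[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(support[ok], metric[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Write a metrics report to TSV
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.table(report$per_family, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
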