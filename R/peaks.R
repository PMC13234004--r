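# Annotation of untargeted footprint peaks (MOA-seq/ATAC-style) with TF
# families, agreement with experimental assignments, and condition-response
# classification with permutation importance.

#' Standardize peaks to a fixed length
#'
#' Each peak is replaced by a `length`-bp interval centred on its midpoint
#' (midpoint rounded down for odd-length peaks). Peaks whose standardized
#' interval would cross a chromosome edge are shifted inward and flagged.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), or a `peak_set`.
#' @param genome A `genome_sequence` (for edge clipping).
#' @param length Target length (default 250).
#' @return data.frame with the original columns plus `std_start`,
#'   `std_end`, `clipped`.
#' @export
standardize_peak_length <- function(peaks, genome, length = 250L) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$peaks
  half <- length %/% 2L
  mid <- (peaks$start + peaks$end) %/% 2L
  start <- mid - half
  end <- start + length
  lens <- genome$lengths[peaks$chrom]
  clipped <- start < 0L | end > lens
  start <- pmin(pmax(start, 0L), lens - length)
  peaks$std_start <- as.integer(start)
  peaks$std_end <- as.integer(start + length)
  peaks$clipped <- clipped
  peaks
}

#' Annotate peaks with predicted TF families
#'
#' Standardizes peaks to the model input length, predicts per-family
#' probabilities and calls.
#'
#' @param model Trained `tf_classifier`.
#' @param genome A `genome_sequence`.
#' @param peaks data.frame or `peak_set`.
#' @param threshold Call threshold (default 0.5).
#' @return An `annotated_peaks` object: list with `peaks` (standardized),
#'   `probabilities`, `calls`, `families`, `fraction_assigned` (share of
#'   peaks with at least one call).
#' @export
annotate_peaks <- function(model, genome, peaks, threshold = 0.5) {
  std <- standardize_peak_length(peaks, genome, model$config$input_len)
  seqs <- window_sequences(genome, data.frame(chrom = std$chrom,
                                              start = std$std_start,
                                              end = std$std_end))
  pred <- predict_probabilities(model, seqs, threshold = threshold)
  structure(list(peaks = std,
                 probabilities = pred$probabilities,
                 calls = pred$calls,
                 families = model$families,
                 fraction_assigned = mean(rowSums(pred$calls) > 0)),
            class = "annotated_peaks")
}

#' Attach experimental family assignments by peak overlap
#'
#' Assigns to each annotated peak the set of families whose experimental
#' peaks overlap it by at least `min_overlap` bp.
#'
#' @param annotated An `annotated_peaks` object.
#' @param peak_sets Named list of experimental `peak_set` objects.
#' @param min_overlap Minimum overlap (bp, default 1).
#' @return The `annotated_peaks` with an `experimental` binary matrix
#'   (peaks x families) attached.
#' @export
attach_experimental_families <- function(annotated, peak_sets,
                                         min_overlap = 1L) {
  std <- annotated$peaks
  wgr <- as_granges0(data.frame(chrom = std$chrom, start = std$std_start,
                                end = std$std_end))
  fam <- annotated$families
  M <- matrix(0L, nrow(std), length(fam), dimnames = list(NULL, fam))
  for (f in intersect(fam, names(peak_sets))) {
    pk <- peak_sets[[f]]$peaks
    if (!nrow(pk)) next
    ov <- GenomicRanges::findOverlaps(wgr, as_granges0(pk),
                                      minoverlap = min_overlap)
    M[unique(S4Vectors::queryHits(ov)), f] <- 1L
  }
  annotated$experimental <- M
  annotated
}

#' Agreement between predicted and experimental peak annotation
#'
#' Reports the share of peaks assigned to at least one family, and --
#' among peaks with a non-empty experimental family set -- the share whose
#' predicted calls intersect the experimental set, plus per-family
#' assigned/experimental counts.
#'
#' @param annotated An `annotated_peaks` with `experimental` attached
#'   ([attach_experimental_families()]).
#' @return List with `fraction_assigned`, `fraction_correct` (NA when no
#'   experimental sets exist), `n_with_experimental`, `per_family`
#'   (data.frame of assigned vs experimental counts).
#' @export
annotation_agreement <- function(annotated) {
  calls <- annotated$calls
  per_family <- data.frame(family = annotated$families,
                           n_assigned = colSums(calls),
                           stringsAsFactors = FALSE)
  if (is.null(annotated$experimental)) {
    return(list(fraction_assigned = annotated$fraction_assigned,
                fraction_correct = NA_real_, n_with_experimental = 0L,
                per_family = per_family))
  }
  ex <- annotated$experimental
  per_family$n_experimental <- colSums(ex)
  has_ex <- rowSums(ex) > 0
  correct <- rowSums(calls == 1 & ex == 1) > 0
  list(fraction_assigned = annotated$fraction_assigned,
       fraction_correct = if (any(has_ex)) mean(correct[has_ex]) else
         NA_real_,
       n_with_experimental = sum(has_ex),
       per_family = per_family)
}

#' Fit a condition-response classifier on peak binding profiles
#'
#' L2-regularised logistic regression (fixed strength, standardized
#' features) from per-family predicted probabilities to the fold-change
#' sign class, evaluated by stratified k-fold cross-validation. The
#' `subset` filters peaks by response strength: `mild` (|lfc| < 1),
#' `extreme` (|lfc| >= 1) or `all`.
#'
#' @param profiles Matrix (peaks x families) of predicted probabilities.
#' @param lfc Numeric log fold change per peak.
#' @param subset `"mild"`, `"extreme"` or `"all"`.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param lambda Ridge penalty (fixed).
#' @return A `response_classifier`: list with `coefficients`, `intercept`,
#'   `cv_accuracy` (per fold), `subset`, `n`.
#' @export
fit_response_classifier <- function(profiles, lfc,
                                    subset = c("all", "mild", "extreme"),
                                    n_folds = 5L, seed = 1L,
                                    lambda = 0.01) {
  subset <- match.arg(subset)
  keep <- switch(subset,
                 all = rep(TRUE, length(lfc)),
                 mild = abs(lfc) < 1,
                 extreme = abs(lfc) >= 1)
  X <- as.matrix(profiles)[keep, , drop = FALSE]
  y <- factor(ifelse(lfc[keep] < 0, "negative", "positive"),
              levels = c("negative", "positive"))
  if (length(unique(y)) < 2)
    stop("subset '", subset, "' contains a single class")
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  acc <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = TRUE)
    pred <- predict(fit, X[!tr, , drop = FALSE], type = "class")
    mean(pred == as.character(y[!tr]))
  }, numeric(1))
  fit_all <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = lambda, standardize = TRUE)
  co <- as.matrix(stats::coef(fit_all))
  structure(list(coefficients = stats::setNames(co[-1, 1],
                                                rownames(co)[-1]),
                 intercept = co[1, 1],
                 cv_accuracy = acc,
                 folds = folds,
                 subset = subset,
                 lambda = lambda,
                 n = nrow(X),
                 X = X, y = y),
            class = "response_classifier")
}

#' Permutation importance of family profiles
#'
#' For each family, the profile column is independently permuted `n_perm`
#' times and the drop in cross-validated accuracy of the *fitted*
#' classifiers (each fold's model evaluated on its held-out peaks with
#' the permuted column; no refitting) relative to the intact data is
#' averaged.
#'
#' @param classifier A `response_classifier` from
#'   [fit_response_classifier()].
#' @param n_perm Number of permutations per family (default 30).
#' @param seed Integer seed.
#' @return data.frame with `family`, `importance` (mean accuracy drop),
#'   `sd`, sorted by decreasing importance.
#' @export
permutation_importance <- function(classifier, n_perm = 30L, seed = 1L) {
  X <- classifier$X; y <- classifier$y
  folds <- classifier$folds
  n_folds <- max(folds)
  fits <- lapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                   alpha = 0, lambda = classifier$lambda,
                   standardize = TRUE)
  })
  cv_acc <- function(Xp) {
    mean(vapply(seq_len(n_folds), function(k) {
      te <- folds == k
      mean(predict(fits[[k]], Xp[te, , drop = FALSE], type = "class") ==
             as.character(y[te]))
    }, numeric(1)))
  }
  base <- cv_acc(X)
  res <- with_seed(seed, {
    out <- lapply(colnames(X), function(f) {
      drops <- vapply(seq_len(n_perm), function(i) {
        Xp <- X
        Xp[, f] <- Xp[sample.int(nrow(Xp)), f]
        base - cv_acc(Xp)
      }, numeric(1))
      data.frame(family = f, importance = mean(drops), sd = stats::sd(drops),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  res[order(-res$importance), ]
}
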