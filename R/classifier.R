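#' Reference model configuration
#'
#' Builds the configuration of the multi-label CNN: four convolutional
#' blocks (convolution, batch normalisation, ReLU, max-pooling), two dense
#' blocks (dense, batch normalisation, ReLU, dropout) and a sigmoid output
#' with one unit per TF family. Training uses Adam with learning rate 0.002
#' and early stopping once the validation loss has not improved for
#' `patience` epochs.
#'
#' @param n_outputs Number of TF families (output units).
#' @param input_len Input window length in bp.
#' @param conv_filters,conv_kernels,conv_pools Per-block filter counts,
#'   kernel widths (bp) and pooling factors; all length 4 in the reference
#'   configuration.
#' @param dense_units Units of the two dense blocks.
#' @param dropout Dropout fraction in the dense blocks.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience (epochs).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param use_class_weights Whether to weight the per-family loss terms.
#' @param augment_rc Reverse-complement augmentation: during training each
#'   window is presented in a random orientation per epoch (labels
#'   unchanged). Binding sites occur on both strands, so this halves the
#'   orientation burden on the filters; inference remains forward-strand.
#' @param seed Integer seed controlling initialisation, batch order,
#'   augmentation and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(n_outputs,
                         input_len = 250L,
                         conv_filters = c(64L, 64L, 64L, 64L),
                         conv_kernels = c(12L, 8L, 8L, 8L),
                         conv_pools = c(2L, 2L, 2L, 2L),
                         dense_units = c(128L, 64L),
                         dropout = 0.25,
                         learning_rate = 0.002,
                         patience = 5L,
                         max_epochs = 50L,
                         batch_size = 64L,
                         use_class_weights = FALSE,
                         augment_rc = TRUE,
                         seed = 1L) {
  stopifnot(length(conv_filters) == length(conv_kernels),
            length(conv_filters) == length(conv_pools),
            dropout >= 0, dropout < 1, learning_rate > 0,
            n_outputs >= 1, patience >= 1, batch_size >= 1)
  cfg <- structure(list(
    n_outputs = as.integer(n_outputs),
    input_len = as.integer(input_len),
    conv_blocks = lapply(seq_along(conv_filters), function(i)
      list(filters = as.integer(conv_filters[i]),
           kernel = as.integer(conv_kernels[i]),
           pool = as.integer(conv_pools[i]))),
    dense_units = as.integer(dense_units),
    dropout = dropout,
    learning_rate = learning_rate,
    patience = as.integer(patience),
    max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size),
    use_class_weights = isTRUE(use_class_weights),
    augment_rc = isTRUE(augment_rc),
    seed = as.integer(seed)), class = "model_config")
  nn_dims(cfg)  # validates that pooling keeps the length >= 1
  cfg
}

#' Build an (untrained) multi-label classifier
#'
#' Parameters are initialised deterministically from `config$seed`; two
#' builds with the same configuration produce identical initial predictions.
#'
#' @param config A `model_config`.
#' @param families Character vector of family labels, length
#'   `config$n_outputs`.
#' @return A `tf_classifier` object.
#' @export
build_classifier <- function(config, families = NULL) {
  if (is.null(families))
    families <- paste0("F", seq_len(config$n_outputs))
  if (length(families) != config$n_outputs)
    stop("length(families) must equal config$n_outputs")
  structure(list(config = config,
                 families = families,
                 params = nn_init(config),
                 history = NULL),
            class = "tf_classifier")
}

#' @export
print.tf_classifier <- function(x, ...) {
  cat("tf_classifier:", length(x$families), "families,",
      length(x$config$conv_blocks), "conv blocks, dense",
      paste(x$config$dense_units, collapse = "/"),
      if (is.null(x$history)) "(untrained)" else
        sprintf("(trained, best epoch %d)", x$history$best_epoch), "\n")
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' `w_f = N / (F * n_f)` with `N` the total number of positive labels,
#' `F` the number of families and `n_f` the family support, renormalised to
#' mean 1. Families without positives are capped at `max_weight` (with a
#' warning) before renormalisation. Weights are monotone non-increasing in
#' support.
#'
#' @param label_matrix A `label_matrix`, or a numeric vector of supports.
#' @param max_weight Cap applied to zero-support families.
#' @return Named numeric vector of per-family weights (mean 1).
#' @export
compute_class_weights <- function(label_matrix, max_weight = 50) {
  supports <- if (inherits(label_matrix, "label_matrix"))
    label_matrix$supports else label_matrix
  N <- sum(supports)
  F_ <- length(supports)
  w <- N / (F_ * supports)
  if (any(!is.finite(w))) {
    warning(sum(!is.finite(w)),
            " zero-support family(ies); weight capped at ", max_weight)
    w[!is.finite(w)] <- max_weight
  }
  w <- pmin(w, max_weight)
  w <- w / mean(w)
  names(w) <- names(supports)
  w
}

#' Train the multi-label classifier
#'
#' Minimises the (optionally class-weighted) binary cross-entropy summed
#' over families with Adam, evaluates the validation loss after every epoch
#' in inference mode, and restores the parameters of the best validation
#' epoch. Epoch 0 is the pre-training validation evaluation, which seeds the
#' early-stopping state.
#'
#' @param model A `tf_classifier` (untrained or to be re-trained).
#' @param train_seqs,train_labels Training sequences (character vector,
#'   all `input_len` bp) and binary label matrix (rows match sequences,
#'   columns match `model$families`).
#' @param val_seqs,val_labels Validation data in the same format.
#' @param class_weights Optional per-family weights; computed from the
#'   training labels when `model$config$use_class_weights` is set and
#'   `class_weights` is `NULL`.
#' @param verbose Print per-epoch losses.
#' @return The trained `tf_classifier` with a `history` entry
#'   (`train_loss`, `val_loss`, `stopped_epoch`, `best_epoch`).
#' @export
train_classifier <- function(model, train_seqs, train_labels,
                             val_seqs, val_labels,
                             class_weights = NULL, verbose = FALSE) {
  config <- model$config
  stopifnot(ncol(train_labels) == config$n_outputs,
            nrow(train_labels) == length(train_seqs),
            nrow(val_labels) == length(val_seqs))
  if (is.null(class_weights) && config$use_class_weights)
    class_weights <- compute_class_weights(colSums(train_labels))
  if (!is.null(class_weights)) class_weights <- unname(class_weights)
  L <- config$input_len
  N <- length(train_seqs)
  Xall <- encode_batch(train_seqs)
  Xrc <- if (isTRUE(config$augment_rc)) encode_batch(revcomp(train_seqs))
         else NULL
  Y <- as.matrix(train_labels)
  params <- model$params
  opt <- adam_init(params)
  es <- es_new(config$patience)
  val_losses <- numeric(0)
  train_losses <- numeric(0)

  # early stopping monitors the plain (unweighted) validation loss so that
  # weighted and unweighted protocols are stopped on a comparable signal
  eval_val <- function(p) {
    predict_loss(p, config, val_seqs, as.matrix(val_labels), NULL)
  }
  v0 <- eval_val(params)
  es <- es_update(es, 0L, v0)
  val_losses <- v0
  best_params <- params
  stopped <- 0L

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(N)
      flip <- if (is.null(Xrc)) logical(N) else stats::runif(N) < 0.5
      nb <- ceiling(N / config$batch_size)
      epoch_loss <- 0
      for (bi in seq_len(nb)) {
        take <- perm[((bi - 1L) * config$batch_size + 1L):
                       min(bi * config$batch_size, N)]
        B <- length(take)
        rows <- as.vector(outer(seq_len(L), (take - 1L) * L, "+"))
        Xb <- Xall[rows, , drop = FALSE]
        for (ii in which(flip[take])) {
          Xb[((ii - 1L) * L + 1L):(ii * L), ] <-
            Xrc[((take[ii] - 1L) * L + 1L):(take[ii] * L), ]
        }
        Yb <- Y[take, , drop = FALSE]
        fwd <- nn_forward(params, config, Xb, B, train = TRUE)
        if (!all(is.finite(fwd$logits)))
          stop("NaN/Inf loss during training (epoch ", epoch,
               "); reduce the learning rate")
        epoch_loss <- epoch_loss +
          bce_loss(fwd$probs, Yb, class_weights) * B
        # fold batch statistics into the running estimates
        for (nm in names(fwd$caches)) {
          cc <- fwd$caches[[nm]]$bn
          params[[paste0(nm, "_rmean")]] <-
            BN_MOMENTUM * params[[paste0(nm, "_rmean")]] +
            (1 - BN_MOMENTUM) * cc$mu
          params[[paste0(nm, "_rvar")]] <-
            BN_MOMENTUM * params[[paste0(nm, "_rvar")]] +
            (1 - BN_MOMENTUM) * cc$var
        }
        dlog <- bce_grad_logits(fwd$probs, Yb, class_weights)
        bwd <- nn_backward(params, config, fwd, dlog, B)
        upd <- adam_step(params, bwd$grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      train_losses[epoch] <- epoch_loss / N
      vl <- eval_val(params)
      val_losses[epoch + 1L] <- vl
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        train_losses[epoch], vl))
      es <- es_update(es, epoch, vl)
      if (es$wait == 0L) best_params <- params
      stopped <- epoch
      if (es$stop) break
    }
  })
  model$params <- best_params
  model$history <- list(train_loss = train_losses,
                        val_loss = val_losses,
                        initial_val_loss = v0,
                        stopped_epoch = stopped,
                        best_epoch = es$best_epoch,
                        class_weights = class_weights)
  model
}

predict_loss <- function(params, config, seqs, Y, weights,
                         chunk = 512L) {
  n <- length(seqs)
  total <- 0
  for (s in seq(1L, n, by = chunk)) {
    take <- s:min(s + chunk - 1L, n)
    X <- encode_batch(seqs[take])
    fwd <- nn_forward(params, config, X, length(take), train = FALSE,
                      keep_cache = FALSE)
    total <- total + bce_loss(fwd$probs, Y[take, , drop = FALSE],
                              weights) * length(take)
  }
  total / n
}

#' Predict per-family binding probabilities
#'
#' Inference is deterministic (dropout off, batch-norm statistics frozen)
#' and evaluated in chunks; chunking does not change the result beyond
#' floating-point tolerance.
#'
#' @param model A trained `tf_classifier`.
#' @param seqs Character vector of sequences of length
#'   `model$config$input_len`, or a `window_set` plus `genome`.
#' @param genome Optional `genome_sequence` when `seqs` is a `window_set`.
#' @param threshold Calling threshold (probability `>= threshold` is a
#'   positive call).
#' @param chunk Chunk size for batched inference.
#' @return A `prediction_matrix`: list with `probabilities`, `calls`,
#'   `families`, `threshold` (and `windows` when predicted from a
#'   `window_set`).
#' @export
predict_probabilities <- function(model, seqs, genome = NULL,
                                  threshold = 0.5, chunk = 512L) {
  windows <- NULL
  if (inherits(seqs, "window_set") || (is.data.frame(seqs) &&
                                       all(c("chrom", "start", "end") %in% names(seqs)))) {
    if (is.null(genome)) stop("genome required to extract window sequences")
    windows <- seqs
    seqs <- window_sequences(genome, seqs)
  }
  if (any(nchar(seqs) != model$config$input_len))
    stop("all sequences must have length ", model$config$input_len)
  n <- length(seqs)
  probs <- matrix(NA_real_, n, model$config$n_outputs,
                  dimnames = list(NULL, model$families))
  for (s in seq(1L, n, by = chunk)) {
    take <- s:min(s + chunk - 1L, n)
    X <- encode_batch(seqs[take])
    fwd <- nn_forward(model$params, model$config, X, length(take),
                      train = FALSE, keep_cache = FALSE)
    probs[take, ] <- fwd$probs
  }
  prediction_matrix(probs, threshold = threshold, windows = windows)
}

#' Construct a prediction matrix
#'
#' @param probabilities Numeric matrix (windows x families) in `[0,1]` with
#'   family column names.
#' @param threshold Calling threshold.
#' @param windows Optional `window_set` the rows refer to.
#' @return A `prediction_matrix` object (`calls = probabilities >= threshold`).
#' @export
prediction_matrix <- function(probabilities, threshold = 0.5, windows = NULL) {
  stopifnot(threshold > 0, threshold < 1, !is.null(colnames(probabilities)))
  structure(list(probabilities = probabilities,
                 calls = call_binding(probabilities, threshold),
                 families = colnames(probabilities),
                 threshold = threshold,
                 windows = windows),
            class = "prediction_matrix")
}

#' Threshold probabilities into binary binding calls
#'
#' The comparison is `>=`: a probability exactly at the threshold counts as
#' bound.
#'
#' @param probabilities Numeric matrix or vector of probabilities.
#' @param threshold Calling threshold in `(0,1)`.
#' @return Binary matrix/vector of the same shape.
#' @export
call_binding <- function(probabilities, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  (probabilities >= threshold) * 1L
}

#' Extract window sequences from a genome
#'
#' @param genome A `genome_sequence`.
#' @param windows A `window_set` or data.frame with `chrom`, `start`, `end`.
#' @return Character vector of sequences.
#' @export
window_sequences <- function(genome, windows) {
  out <- character(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    sel <- windows$chrom == chrom
    out[sel] <- substring(genome$seqs[[chrom]],
                          windows$start[sel] + 1L, windows$end[sel])
  }
  out
}

#' Rank families by training support and subset a label matrix
#'
#' Used to build top-k / bottom-k family-subset models: the label matrix is
#' column-subset before training, ranking families by training-set support.
#'
#' @param labels A `label_matrix`.
#' @param k Number of families to keep.
#' @param which `"top"` (most abundant) or `"bottom"` (least abundant).
#' @return A `label_matrix` restricted to the selected families.
#' @export
subset_families <- function(labels, k, which = c("top", "bottom")) {
  which <- match.arg(which)
  ord <- order(labels$supports, decreasing = (which == "top"))
  keep <- sort(ord[seq_len(min(k, length(ord)))])
  label_matrix(labels$windows, labels$values[, keep, drop = FALSE])
}

#' Save / load a trained classifier
#'
#' @param model A `tf_classifier`.
#' @param path File path (`.rds`).
#' @return `path` (save) or the restored `tf_classifier` (load).
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  readRDS(path)
}
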