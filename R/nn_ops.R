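# Internal neural-network engine.
#
# Layout convention: a batch of B one-hot sequences of length L with C
# channels is a (L*B) x C matrix whose row index is l + (b-1)*L. Convolutions
# are evaluated as im2col (C++) followed by a single BLAS GEMM; batch
# normalisation, ReLU, max-pooling, dense layers and Adam live in plain R.
# Gradients are exact (verified by finite differences in the test suite).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

nn_dims <- function(config) {
  # propagate sequence length through the conv stack
  L <- config$input_len
  C <- 4L
  dims <- list()
  for (i in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[i]]
    P <- L - blk$kernel + 1L
    if (P < 1L) stop("conv block ", i, ": kernel wider than input length")
    Q <- P %/% blk$pool
    if (Q < 1L) stop("conv block ", i, ": pooling reduces length below 1")
    dims[[i]] <- list(L_in = L, C_in = C, P = P, Q = Q,
                      kernel = blk$kernel, pool = blk$pool,
                      filters = blk$filters)
    L <- Q
    C <- blk$filters
  }
  list(conv = dims, flat = L * C, L_out = L, C_out = C)
}

nn_init <- function(config) {
  dims <- nn_dims(config)
  params <- list()
  with_seed(config$seed, {
    for (i in seq_along(dims$conv)) {
      d <- dims$conv[[i]]
      fan_in <- d$kernel * d$C_in
      params[[paste0("conv", i, "_W")]] <-
        matrix(stats::rnorm(fan_in * d$filters, sd = sqrt(2 / fan_in)),
               fan_in, d$filters)
      params[[paste0("conv", i, "_gamma")]] <- rep(1, d$filters)
      params[[paste0("conv", i, "_beta")]] <- rep(0, d$filters)
      params[[paste0("conv", i, "_rmean")]] <- rep(0, d$filters)
      params[[paste0("conv", i, "_rvar")]] <- rep(1, d$filters)
    }
    nin <- dims$flat
    for (j in seq_along(config$dense_units)) {
      u <- config$dense_units[j]
      params[[paste0("dense", j, "_W")]] <-
        matrix(stats::rnorm(nin * u, sd = sqrt(2 / nin)), nin, u)
      params[[paste0("dense", j, "_b")]] <- rep(0, u)
      params[[paste0("dense", j, "_gamma")]] <- rep(1, u)
      params[[paste0("dense", j, "_beta")]] <- rep(0, u)
      params[[paste0("dense", j, "_rmean")]] <- rep(0, u)
      params[[paste0("dense", j, "_rvar")]] <- rep(1, u)
      nin <- u
    }
    # small output init keeps initial logits near 0 (p ~ 0.5)
    params[["out_W"]] <- matrix(stats::rnorm(nin * config$n_outputs, sd = 0.01),
                                nin, config$n_outputs)
    params[["out_b"]] <- rep(0, config$n_outputs)
  })
  params
}

# Full forward pass. `train` toggles batch statistics + dropout; when
# `keep_cache` the intermediates needed for a backward pass are returned.
nn_forward <- function(params, config, X, B, train = FALSE,
                       keep_cache = train) {
  dims <- nn_dims(config)
  caches <- list()
  nc <- length(dims$conv)
  idx <- seq_len(nc)
  st <- cpp_conv_stack_fwd(
    X,
    lapply(idx, function(i) params[[paste0("conv", i, "_W")]]),
    lapply(idx, function(i) params[[paste0("conv", i, "_gamma")]]),
    lapply(idx, function(i) params[[paste0("conv", i, "_beta")]]),
    lapply(idx, function(i) params[[paste0("conv", i, "_rmean")]]),
    lapply(idx, function(i) params[[paste0("conv", i, "_rvar")]]),
    vapply(dims$conv, function(d) d$kernel, integer(1)),
    vapply(dims$conv, function(d) d$pool, integer(1)),
    B, train, keep_cache)
  A <- st$H
  if (keep_cache && train) {
    for (i in idx) {
      caches[[paste0("conv", i)]] <- list(bn = list(mu = st$mu[[i]],
                                                    var = st$var[[i]]))
    }
  }
  # flatten (Q*B) x F -> B x (Q*F)
  Q <- dims$L_out; F_ <- dims$C_out
  dim(A) <- c(Q, B, F_)
  H <- matrix(aperm(A, c(2, 1, 3)), B, Q * F_)
  for (j in seq_along(config$dense_units)) {
    Z <- H %*% params[[paste0("dense", j, "_W")]] +
      rep(params[[paste0("dense", j, "_b")]], each = B)
    gamma <- params[[paste0("dense", j, "_gamma")]]
    beta <- params[[paste0("dense", j, "_beta")]]
    if (train) {
      bn <- cpp_bnrelu_fwd(Z, gamma, beta)
    } else {
      rvar <- params[[paste0("dense", j, "_rvar")]]
      bn <- list(Y = cpp_bnrelu_infer(Z, gamma, beta,
                                      params[[paste0("dense", j, "_rmean")]],
                                      rvar),
                 scale = gamma / sqrt(rvar + BN_EPS))
    }
    R <- bn$Y
    if (train && config$dropout > 0) {
      keep <- 1 - config$dropout
      mask <- matrix((stats::runif(length(R)) < keep) / keep,
                     nrow(R), ncol(R))
      Rdrop <- R * mask
    } else {
      mask <- NULL
      Rdrop <- R
    }
    if (keep_cache) {
      caches[[paste0("dense", j)]] <- list(H_in = H, bn = bn,
                                           drop_mask = mask)
    }
    H <- Rdrop
  }
  logits <- H %*% params[["out_W"]] + rep(params[["out_b"]], each = B)
  probs <- stats::plogis(logits)
  list(probs = probs, logits = logits, H = H, caches = caches, dims = dims)
}

# Backward pass from dlogits. In training mode returns parameter gradients;
# in inference mode (caches built with running statistics) only the input
# gradient is available, which is what attribution needs.
nn_backward <- function(params, config, fwd, dlogits, B,
                        want_input_grad = FALSE) {
  grads <- list()
  train_mode <- !is.null(fwd$caches[["dense1"]]$bn$Zhat)
  grads[["out_W"]] <- crossprod(fwd$H, dlogits)
  grads[["out_b"]] <- colSums(dlogits)
  dH <- dlogits %*% t(params[["out_W"]])
  for (j in rev(seq_along(config$dense_units))) {
    cc <- fwd$caches[[paste0("dense", j)]]
    if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
    if (!is.null(cc$bn$Zhat)) {
      bb <- cpp_bnrelu_bwd(dH, cc$bn$Y, cc$bn$Zhat, cc$bn$invstd,
                           params[[paste0("dense", j, "_gamma")]])
      dZ <- bb$dZ
      grads[[paste0("dense", j, "_gamma")]] <- bb$dgamma
      grads[[paste0("dense", j, "_beta")]] <- bb$dbeta
    } else {
      dZ <- dH * (cc$bn$Y > 0) * rep(cc$bn$scale, each = nrow(dH))
    }
    if (train_mode) {
      grads[[paste0("dense", j, "_W")]] <- crossprod(cc$H_in, dZ)
      grads[[paste0("dense", j, "_b")]] <- colSums(dZ)
    }
    dH <- dZ %*% t(params[[paste0("dense", j, "_W")]])
  }
  # unflatten B x (Q*F) -> (Q*B) x F
  dims <- fwd$dims
  Q <- dims$L_out; F_ <- dims$C_out
  dA <- array(dH, c(B, Q, F_))
  dA <- matrix(aperm(dA, c(2, 1, 3)), Q * B, F_)
  nc <- length(dims$conv)
  idx <- seq_len(nc)
  g <- cpp_conv_stack_bwd(
    dA, lapply(idx, function(i) params[[paste0("conv", i, "_W")]]),
    lapply(idx, function(i) params[[paste0("conv", i, "_gamma")]]),
    B, want_input_grad)
  if (train_mode) {
    for (i in idx) {
      grads[[paste0("conv", i, "_W")]] <- g$dW[[i]]
      grads[[paste0("conv", i, "_gamma")]] <- g$dgamma[[i]]
      grads[[paste0("conv", i, "_beta")]] <- g$dbeta[[i]]
    }
  }
  list(grads = grads, dX = if (want_input_grad) g$dX else NULL)
}

adam_init <- function(params) {
  trainable <- grep("_(rmean|rvar)$", names(params), invert = TRUE,
                    value = TRUE)
  list(m = lapply(params[trainable], function(p) p * 0),
       v = lapply(params[trainable], function(p) p * 0),
       t = 0L, names = trainable)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in state$names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Weighted multi-label binary cross-entropy: mean over the batch of the sum
# over families, each family's term multiplied by its class weight.
bce_loss <- function(probs, Y, weights = NULL, eps = 1e-12) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  ll <- -(Y * log(p) + (1 - Y) * log(1 - p))
  if (!is.null(weights)) ll <- ll * rep(weights, each = nrow(ll))
  sum(ll) / nrow(ll)
}

bce_grad_logits <- function(probs, Y, weights = NULL) {
  d <- (probs - Y) / nrow(Y)
  if (!is.null(weights)) d <- d * rep(weights, each = nrow(d))
  d
}

# Early-stopping bookkeeping shared by the trainer and a testable wrapper.
# Epochs are counted from 0 (the pre-training validation evaluation).
es_new <- function(patience) {
  list(best = Inf, best_epoch = 0L, wait = 0L, patience = patience,
       stop = FALSE)
}

es_update <- function(state, epoch, val_loss, tol = 1e-8) {
  if (val_loss < state$best - tol) {
    state$best <- val_loss
    state$best_epoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

#' Replay an early-stopping schedule on a validation-loss trace
#'
#' Epoch 0 is the pre-training validation evaluation; training stops once
#' the validation loss has failed to improve for `patience` consecutive
#' epochs, and the best epoch is the last improvement.
#'
#' @param val_losses Numeric vector of validation losses for epochs
#'   `0, 1, 2, ...`.
#' @param patience Number of non-improving epochs tolerated.
#' @return List with `stopped_epoch` and `best_epoch`.
#' @export
early_stop_schedule <- function(val_losses, patience = 5L) {
  st <- es_new(patience)
  st <- es_update(st, 0L, val_losses[1])
  stopped <- length(val_losses) - 1L
  if (length(val_losses) > 1L) {
    for (e in seq_len(length(val_losses) - 1L)) {
      st <- es_update(st, e, val_losses[e + 1L])
      if (st$stop) { stopped <- e; break }
    }
  }
  list(stopped_epoch = stopped, best_epoch = st$best_epoch)
}
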