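small_config <- function(...) {
  model_config(n_outputs = 3, input_len = 20,
               conv_filters = c(4, 5), conv_kernels = c(3, 3),
               conv_pools = c(2, 2), dense_units = c(6, 4),
               dropout = 0, augment_rc = FALSE, seed = 3, ...)
}

random_onehot <- function(L, B, seed = 1) {
  set.seed(seed)
  X <- matrix(0, L * B, 4)
  X[cbind(seq_len(L * B), sample.int(4, L * B, TRUE))] <- 1
  X
}

test_that("network gradients agree with finite differences", {
  ns <- asNamespace("tfbinder")
  cfg <- small_config()
  params <- ns$nn_init(cfg)
  B <- 4
  X <- random_onehot(20, B, seed = 9)
  set.seed(10)
  Y <- matrix(rbinom(B * 3, 1, .5), B, 3)
  fwd <- ns$nn_forward(params, cfg, X, B, train = TRUE)
  bwd <- ns$nn_backward(params, cfg, fwd,
                        ns$bce_grad_logits(fwd$probs, Y), B,
                        want_input_grad = TRUE)
  # epsilon sized for the single-precision convolution arithmetic
  eps <- 1e-3
  for (nm in names(bwd$grads)) {
    g <- bwd$grads[[nm]]
    if (is.null(g)) next
    for (i in seq_len(min(4, length(g)))) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (ns$bce_loss(ns$nn_forward(up, cfg, X, B, TRUE)$probs, Y) -
                ns$bce_loss(ns$nn_forward(dn, cfg, X, B, TRUE)$probs, Y)) /
        (2 * eps)
      expect_equal(g[i], num, tolerance = 5e-3,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("architecture validation and output dimensionality follow the configuration", {
  cfg46 <- model_config(n_outputs = 46)
  m <- build_classifier(cfg46)
  p <- predict_probabilities(m, rep(strrep("ACGT", 63) |> substr(1, 250), 2))
  expect_equal(ncol(p$probabilities), 46L)
  expect_true(all(p$probabilities >= 0 & p$probabilities <= 1))
  m10 <- build_classifier(model_config(n_outputs = 10))
  expect_length(m10$families, 10L)
  # pooling below length 1 is a configuration error
  expect_error(model_config(n_outputs = 2, input_len = 20,
                            conv_filters = c(4, 4), conv_kernels = c(3, 3),
                            conv_pools = c(8, 8)), "kernel wider|below 1")
})

test_that("same seed gives identical builds and predictions; duplicates predict identically", {
  cfg <- small_config()
  seqs <- vapply(1:6, function(i) paste(sample(c("A", "C", "G", "T"), 20,
                                               TRUE), collapse = ""),
                 character(1))
  m1 <- build_classifier(cfg)
  m2 <- build_classifier(cfg)
  p1 <- predict_probabilities(m1, seqs)$probabilities
  p2 <- predict_probabilities(m2, seqs)$probabilities
  expect_identical(p1, p2)
  # duplicated rows give identical outputs, chunking does not matter
  p3 <- predict_probabilities(m1, c(seqs, seqs[1]), chunk = 2)$probabilities
  expect_equal(p3[7, ], p3[1, ], tolerance = 1e-10)
  expect_equal(p3[1:6, ], p1, tolerance = 1e-5)
  # reverse-complement input generally changes the prediction
  p_rc <- predict_probabilities(m1, revcomp(seqs))$probabilities
  expect_false(isTRUE(all.equal(p_rc, p1)))
})

test_that("class weights follow inverse-frequency with mean 1 and support monotonicity", {
  expect_equal(unname(compute_class_weights(c(10, 10, 10))), rep(1, 3))
  w <- compute_class_weights(c(900, 100))
  expect_gt(w[2], w[1])
  expect_equal(mean(w), 1)
  # hand-computed example: supports (50, 25, 25) -> (0.6, 1.2, 1.2)
  expect_equal(unname(compute_class_weights(c(50, 25, 25))),
               c(0.6, 1.2, 1.2), tolerance = 1e-12)
  expect_warning(wz <- compute_class_weights(c(100, 0)), "zero-support")
  expect_true(all(is.finite(wz)))
})

test_that("early stopping stops after `patience` non-improving epochs and restores the best epoch", {
  # constructed trace: epoch 0 = 1.0, epoch 1 = 0.9, then five
  # non-improvements -> stop after epoch 6, best epoch 1
  es <- early_stop_schedule(c(1.0, 0.9, 0.91, 0.92, 0.93, 0.94, 0.95),
                            patience = 5)
  expect_equal(es$stopped_epoch, 6L)
  expect_equal(es$best_epoch, 1L)
  # monotone improvement never stops early
  es2 <- early_stop_schedule(seq(1, 0.1, length.out = 8), patience = 5)
  expect_equal(es2$stopped_epoch, 7L)
  expect_equal(es2$best_epoch, 7L)
})

test_that("training reduces validation loss on a planted-motif fixture and starts near F*ln2", {
  set.seed(77)
  motif <- "TTACGCAT"
  mk <- function(n, plant) vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    if (plant[i]) {
      at <- sample(1:(60 - 8), 1)
      substring(s, at, at + 7) <- motif
    }
    s
  }, character(1))
  plant_tr <- rbinom(300, 1, .5); plant_va <- rbinom(120, 1, .5)
  tr <- mk(300, plant_tr); va <- mk(120, plant_va)
  ytr <- matrix(plant_tr, ncol = 1, dimnames = list(NULL, "m"))
  yva <- matrix(plant_va, ncol = 1, dimnames = list(NULL, "m"))
  cfg <- model_config(n_outputs = 1, input_len = 60,
                      conv_filters = c(16, 16), conv_kernels = c(8, 8),
                      conv_pools = c(2, 2), dense_units = c(16, 8),
                      dropout = 0.1, max_epochs = 30, batch_size = 8,
                      seed = 5)
  m <- build_classifier(cfg, "m")
  m <- train_classifier(m, tr, ytr, va, yva)
  # analytic initial loss: balanced labels, sigmoid starts near 0.5
  expect_equal(m$history$initial_val_loss, log(2), tolerance = 0.05 * log(2))
  expect_lt(min(m$history$val_loss), m$history$initial_val_loss)
  # the planted motif is actually detected on held-out data
  p <- predict_probabilities(m, va)$probabilities[, 1]
  expect_gt(auc_roc(p, plant_va), 0.75)
  # deterministic retraining
  m2 <- train_classifier(build_classifier(cfg, "m"), tr, ytr, va, yva)
  expect_equal(m$history$val_loss, m2$history$val_loss, tolerance = 1e-10)
})

test_that("binding calls use >= at the threshold and are monotone in it", {
  p <- matrix(c(0.5, 0.49, 0.9, 0.1), 2, 2)
  expect_equal(unname(call_binding(p, 0.5)),
               matrix(c(1L, 0L, 1L, 0L), 2, 2))
  c9 <- call_binding(p, 0.9)
  expect_true(all(c9 <= call_binding(p, 0.5)))
  expect_error(call_binding(p, 0), "0,1")
})

test_that("family subsetting ranks by support", {
  g <- genome_sequence(c(chr1 = strrep("ACGT", 300)))
  w <- tile_windows(g, 250, 250)
  v <- cbind(a = c(1L, 1L, 1L, 0L), b = c(1L, 0L, 0L, 0L),
             c = c(1L, 1L, 0L, 0L))
  lab <- label_matrix(w, v)
  top2 <- subset_families(lab, 2, "top")
  expect_setequal(top2$families, c("a", "c"))
  bot1 <- subset_families(lab, 1, "bottom")
  expect_equal(bot1$families, "b")
})
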