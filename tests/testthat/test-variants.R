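# A deterministic hand-made "classifier" is impractical for the status
# arithmetic, so those parts use classify_shift via predict-style inputs;
# the model-dependent behaviour is exercised on a small trained network.

test_that("variant windows are centred, ref-checked and alt differs at exactly one base", {
  g <- genome_sequence(c(c1 = strrep("ACGT", 1000)))
  v <- list(chrom = "c1", pos = 2001L, ref = "A", alt = "T")
  wv <- extract_variant_windows(g, v, window = 250L)
  expect_equal(wv$offset, 125L)
  expect_equal(nchar(wv$ref_seq), 250L)
  expect_equal(substring(wv$ref_seq, 126, 126), "A")
  expect_equal(substring(wv$alt_seq, 126, 126), "T")
  d <- mapply(function(a, b) a != b,
              strsplit(wv$ref_seq, "")[[1]], strsplit(wv$alt_seq, "")[[1]])
  expect_equal(sum(d), 1L)
  # ref == alt gives identical windows
  wv2 <- extract_variant_windows(g, list(chrom = "c1", pos = 2001L,
                                         ref = "A", alt = "A"))
  expect_identical(wv2$ref_seq, wv2$alt_seq)
  # reference mismatch errors with the position named
  expect_error(extract_variant_windows(g, list(chrom = "c1", pos = 2001L,
                                               ref = "G", alt = "T")),
               "2001")
})

test_that("gain/loss/retained/unbound partition all probability pairs", {
  cs <- tfbinder:::classify_shift
  expect_equal(cs(0.3, 0.7, 0.5), "gain")
  expect_equal(cs(0.7, 0.3, 0.5), "loss")
  expect_equal(cs(0.6, 0.9, 0.5), "retained")
  expect_equal(cs(0.1, 0.4, 0.5), "unbound")
  # boundary: theta counts as bound
  expect_equal(cs(0.5, 0.5, 0.5), "retained")
  expect_equal(cs(0.49, 0.5, 0.5), "gain")
  set.seed(2)
  pr <- runif(500); pa <- runif(500)
  st <- cs(pr, pa, 0.5)
  expect_true(all(st %in% c("gain", "loss", "retained", "unbound")))
})

test_that("the probability-shift filter is strict at the boundary", {
  eff <- data.frame(variant_index = 1:4, chrom = "c", pos = 1:4,
                    family = "f",
                    p_ref = c(.3, .3, .3, .6), p_alt = c(.51, .5, .9, .2),
                    delta = c(.21, .2, .6, -.4),
                    status = c("gain", "gain", "gain", "loss"),
                    stringsAsFactors = FALSE)
  kept <- filter_by_shift(eff, 0.2)
  expect_equal(kept$delta, c(.21, .6, -.4))   # exactly 0.2 dropped
  expect_equal(attr(kept, "retained_fraction"), 3 / 4)
})

test_that("variant effect summary counts variants and events", {
  eff <- data.frame(variant_index = rep(1:2, each = 3),
                    status = c("gain", "unbound", "retained",
                               "unbound", "unbound", "unbound"))
  s <- summarize_variant_effects(eff)
  expect_equal(s$pct_variants_gain_loss, 50)
  expect_equal(s$pct_events_gain_loss, 100 / 6)
})

test_that("control mutations never sample the variant position and are seed-deterministic", {
  set.seed(19)
  # small trained model on 60 bp windows with a planted motif
  motif <- "GATTACAG"
  mk <- function(n, plant) vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    if (plant[i]) substring(s, 26, 33) <- motif
    s
  }, character(1))
  plant <- rep(c(1, 0), 150)
  seqs <- mk(300, plant)
  y <- matrix(plant, ncol = 1, dimnames = list(NULL, "m"))
  cfg <- model_config(n_outputs = 1, input_len = 60,
                      conv_filters = c(16, 16), conv_kernels = c(8, 8),
                      conv_pools = c(2, 2), dense_units = c(16, 8),
                      dropout = 0.1, max_epochs = 20, batch_size = 32,
                      seed = 21)
  m <- train_classifier(build_classifier(cfg, "m"),
                        seqs[1:240], y[1:240, , drop = FALSE],
                        seqs[241:300], y[241:300, , drop = FALSE])
  # genome containing one planted window; SNP destroys a high-IC position
  gseq <- mk(1, 1)
  g <- genome_sequence(c(c1 = gseq))
  ref <- substring(gseq, 30, 30)
  alt <- setdiff(c("A", "C", "G", "T"),
                 c(ref, substring(motif, 5, 5)))[1]
  v <- list(chrom = "c1", pos = 30L, ref = ref, alt = alt)
  cn <- control_mutation_null(m, g, v, n = 10, seed = 4, window = 60L)
  expect_s3_class(cn, "control_null")
  expect_false((v$pos - 1L) %in% cn$controls$position)
  expect_equal(sum(cn$fractions), 1)
  expect_true(all(cn$controls$category %in%
                    c("expected", "de_novo", "none")))
  cn2 <- control_mutation_null(m, g, v, n = 10, seed = 4, window = 60L)
  expect_identical(cn$controls, cn2$controls)
  # a different seed moves the control positions, not the real effect
  cn3 <- control_mutation_null(m, g, v, n = 10, seed = 5, window = 60L)
  expect_identical(cn$real_effect, cn3$real_effect)
  # controls only ever substitute at positions carrying the ref base
  chars <- strsplit(gseq, "")[[1]]
  expect_true(all(chars[cn$controls$position + 1L] == ref))
})

test_that("motif-disrupting SNPs are called as losses on the planted family", {
  set.seed(23)
  motif <- "GATTACAG"
  mk <- function(n, plant) vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    if (plant[i]) substring(s, 26, 33) <- motif
    s
  }, character(1))
  plant <- rep(c(1, 0), 200)
  seqs <- mk(400, plant)
  y <- matrix(plant, ncol = 1, dimnames = list(NULL, "m"))
  cfg <- model_config(n_outputs = 1, input_len = 60,
                      conv_filters = c(16, 16), conv_kernels = c(8, 8),
                      conv_pools = c(2, 2), dense_units = c(16, 8),
                      dropout = 0.1, max_epochs = 20, batch_size = 32,
                      seed = 31)
  m <- train_classifier(build_classifier(cfg, "m"),
                        seqs[1:320], y[1:320, , drop = FALSE],
                        seqs[321:400], y[321:400, , drop = FALSE])
  # destroy the motif core in predicted-positive planted windows
  idx <- which(plant == 1)
  p0 <- predict_probabilities(m, seqs[idx])$probabilities[, 1]
  idx <- idx[p0 >= 0.5][1:20]
  lost <- vapply(idx, function(i) {
    s <- seqs[i]
    alt <- s
    substring(alt, 29, 29) <- "C"   # GATT[A]CAG -> GATT[C]CAG
    eff <- predict_variant_effect(m, s, alt)
    eff$status[1] == "loss"
  }, logical(1))
  expect_gt(mean(lost), 0.5)
})

test_that("SNP tables round-trip through read_variants", {
  f <- tmp_file(c("chrom\tpos\tref\talt\tphenotype",
                  "c1\t100\tA\tT\tflowering",
                  "c1\t200\tAC\tT\tbad",
                  "c2\t300\tG\tC\tdefense"))
  expect_warning(v <- read_variants(f), "non-SNV")
  expect_equal(nrow(v), 2L)
  expect_equal(v$pos, c(100L, 300L))
  expect_equal(v$phenotype, c("flowering", "defense"))
})
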