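cacgtg_pwm <- function(flank = 3L) {
  core <- c("C", "A", "C", "G", "T", "G")
  bases <- c("A", "C", "G", "T")
  cols <- c(sample(bases, flank, TRUE), core, sample(bases, flank, TRUE))
  pwm <- vapply(cols, function(b) {
    p <- rep(0.02, 4); p[match(b, bases)] <- 0.94; p
  }, numeric(4))
  rownames(pwm) <- bases
  pwm
}

test_that("motif similarity is 1 for duplicates and reverse complements, and orders shared cores first", {
  set.seed(2)
  p1 <- cacgtg_pwm()
  expect_equal(motif_similarity(p1, p1), 1, tolerance = 1e-12)
  expect_equal(motif_similarity(p1, tfbinder:::pwm_revcomp(p1)), 1,
               tolerance = 1e-12)
  p2 <- cacgtg_pwm()        # same core, different flanks
  out <- one_hot("GGGGGGGGGGGG") + 0.02
  out <- sweep(out, 2, colSums(out), "/")
  expect_gt(motif_similarity(p1, p2), motif_similarity(p1, out))
})

test_that("IPM building recovers identical k-mers as near-deterministic columns and separates disjoint populations", {
  sl <- data.frame(window = 1:24, start = 0L, end = 8L, score = 1,
                   seq = c(rep("ACGTACGT", 12), rep("GGGTTTCC", 12)),
                   stringsAsFactors = FALSE)
  ipms <- build_ipms(sl, "fam", min_support = 10)
  expect_length(ipms, 2L)
  expect_s3_class(ipms[[1]], "ipm")
  for (ip in ipms) {
    expect_equal(colSums(ip$pwm), rep(1, ncol(ip$pwm)), tolerance = 1e-9)
    expect_true(all(ip$ic >= 0 & ip$ic <= 2 + 1e-9))
  }
  # 12 identical 8-mers with pseudocount 1: dominant probability 13/16
  expect_true(all(apply(ipms[[1]]$pwm, 2, max) >= 13 / 16 - 1e-9))
  # fewer than min_support seqlets -> empty list
  expect_length(build_ipms(sl[1:5, ], "fam", min_support = 10), 0L)
})

test_that("attribution localises planted motifs and recovers them as IPMs", {
  set.seed(31)
  motif <- "CCGGAATT"
  mk <- function(n, plant) vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    if (plant[i]) {
      at <- sample(10:40, 1)
      substring(s, at, at + 7) <- motif
    }
    s
  }, character(1))
  plant <- rep(c(1, 0), 150)
  seqs <- mk(300, plant)
  y <- matrix(plant, ncol = 1, dimnames = list(NULL, "m"))
  cfg <- model_config(n_outputs = 1, input_len = 60,
                      conv_filters = c(16, 16), conv_kernels = c(8, 8),
                      conv_pools = c(2, 2), dense_units = c(16, 8),
                      dropout = 0.1, max_epochs = 40, batch_size = 8,
                      learning_rate = 0.004, seed = 8)
  m <- train_classifier(build_classifier(cfg, "m"),
                        seqs[1:240], y[1:240, , drop = FALSE],
                        seqs[241:300], y[241:300, , drop = FALSE])
  pos_idx <- which(plant[1:240] == 1)[1:30]
  maps <- attribute(m, seqs[pos_idx], "m")
  expect_length(maps, 30L)
  expect_equal(dim(maps[[1]]), c(4L, 60L))
  maps2 <- attribute(m, seqs[pos_idx], "m")
  expect_identical(maps, maps2)
  # attribution mass concentrates on the planted site
  ratios <- vapply(seq_along(pos_idx), function(i) {
    at <- regexpr(motif, seqs[pos_idx[i]], fixed = TRUE)[1]
    v <- abs(colSums(maps[[i]]))
    inside <- at:(at + 7)
    mean(v[inside]) / mean(v[-inside])
  }, numeric(1))
  expect_gt(mean(ratios), 1.5)
  expect_gt(mean(ratios > 1), 0.9)
  # seqlets preferentially land on the planted site
  sl <- extract_seqlets(maps, seqs[pos_idx])
  expect_gt(nrow(sl), 10)
  hit <- mapply(function(wi, s0, e0) {
    at <- regexpr(motif, seqs[pos_idx[wi]], fixed = TRUE)[1] - 1L
    s0 < at + 8 & e0 > at
  }, sl$window, sl$start, sl$end)
  expect_gt(mean(hit), 0.4)
  # and the end-to-end IPM reconstructs the planted motif
  ipms <- build_ipms(sl, "m", min_support = 10)
  expect_gt(length(ipms), 0)
  best <- max(vapply(ipms, function(ip)
    motif_similarity(ip$pwm, one_hot(motif)), numeric(1)))
  expect_gte(best, 0.8)
  # an all-N window has zero gradient x input attribution
  mN <- attribute(m, strrep("N", 60), "m")
  expect_equal(sum(abs(mN[[1]])), 0)
})

test_that("flat attribution maps yield no seqlets", {
  flat <- matrix(0.1, 4, 50, dimnames = list(c("A", "C", "G", "T"), NULL))
  sl <- extract_seqlets(list(flat), strrep("A", 50))
  expect_equal(nrow(sl), 0L)
})

test_that("genome scanning equals a naive rescoring oracle and finds palindromic sites on both strands", {
  set.seed(13)
  g <- genome_sequence(c(s1 = paste(sample(c("A", "C", "G", "T"), 3000,
                                           TRUE), collapse = "")))
  pwm <- cacgtg_pwm(flank = 0)     # pure palindromic core
  hits <- scan_genome(g, pwm, min_fraction = 0.85)
  # palindrome: every site is reported on both strands at the same start
  if (nrow(hits)) {
    tab <- table(paste(hits$chrom, hits$start))
    expect_true(all(tab == 2))
  }
  # consensus sequence scores fraction 1
  h1 <- scan_genome(c(x = "CACGTG"), pwm, min_fraction = 0.99)
  expect_true(any(abs(h1$fraction_of_max - 1) < 1e-12))
  # naive per-offset oracle
  lo <- log2(pmax(pwm, 1e-9) / 0.25)
  rc <- tfbinder:::pwm_revcomp(lo)
  chars <- strsplit(g$seqs[[1]], "")[[1]]
  naive <- list()
  maxs <- sum(apply(lo, 2, max))
  for (i in 1:(3000 - 6 + 1)) {
    for (sm in list(list(m = lo, st = "+"), list(m = rc, st = "-"))) {
      sc <- sum(vapply(1:6, function(j)
        sm$m[match(chars[i + j - 1], c("A", "C", "G", "T")), j],
        numeric(1)))
      if (sc >= 0.85 * maxs)
        naive[[length(naive) + 1L]] <- data.frame(start = i - 1L,
                                                  strand = sm$st, score = sc)
    }
  }
  naive <- do.call(rbind, naive)
  expect_equal(nrow(hits), nrow(naive))
  expect_setequal(paste(hits$start, hits$strand),
                  paste(naive$start, naive$strand))
})

test_that("recovery rate counts hits inside called windows via containment", {
  g <- genome_sequence(c(c1 = strrep("A", 1000)))
  w <- tile_windows(g, 250, 250)
  calls <- c(1L, 0L, 1L, 0L)
  hits <- data.frame(chrom = "c1",
                     start = c(10L, 300L, 600L, 240L),
                     end = c(20L, 310L, 610L, 260L))
  # hit 1 inside called win1; hit 2 inside uncalled win2; hit 3 inside
  # called win3; hit 4 straddles windows 1|2 -> not contained
  r <- recovery_rate(calls, hits, windows = w)
  expect_equal(r, 2 / 4)
  expect_equal(recovery_rate(c(0L, 0L, 0L, 0L), hits, windows = w), 0)
  expect_true(is.na(recovery_rate(calls, hits[0, ], windows = w)))
})

test_that("motif trees merge duplicates first and group shared-core families before outgroups", {
  set.seed(4)
  a <- cacgtg_pwm(); b <- cacgtg_pwm()
  out <- vapply(1:12, function(j) {
    p <- rep(0.02, 4); p[sample(c(1, 4), 1)] <- 0.94; p
  }, numeric(4))
  rownames(out) <- c("A", "C", "G", "T")
  mk <- function(pwm, fam) structure(list(family = fam, pwm = pwm,
                                          support = 20,
                                          ic = tfbinder:::pwm_ic(pwm)),
                                     class = "ipm")
  tree <- cluster_ipms(list(coreA = mk(a, "A"), coreB = mk(b, "B"),
                            atrich = mk(out, "C")))
  expect_s3_class(tree, "motif_tree")
  expect_equal(tree$similarity["coreA", "coreB"],
               max(tree$similarity[upper.tri(tree$similarity)]))
  cut2 <- cut_motif_tree(tree, h = 1 - tree$similarity["coreA", "atrich"] - 0.01)
  expect_equal(cut2[["coreA"]], cut2[["coreB"]])
  expect_false(cut2[["coreA"]] == cut2[["atrich"]])
  # a duplicated IPM has similarity 1 and merges first
  tree2 <- cluster_ipms(list(x = mk(a, "A"), x2 = mk(a, "A"),
                             y = mk(out, "C")))
  expect_equal(tree2$similarity["x", "x2"], 1, tolerance = 1e-12)
  expect_equal(tree2$hclust$height[1], 0, tolerance = 1e-9)
})

test_that("MEME round trip preserves motif matrices", {
  set.seed(6)
  p1 <- cacgtg_pwm()
  ip <- structure(list(family = "fam1", pwm = p1, support = 42,
                       ic = tfbinder:::pwm_ic(p1)), class = "ipm")
  f <- tempfile(fileext = ".meme")
  write_meme(list(fam1 = ip), f)
  back <- read_meme(f)
  expect_equal(back$fam1$pwm, p1, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(back$fam1$support, 42L)
})
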