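test_that("gene flanking regions are strand-aware and truncated at edges", {
  g <- genome_sequence(c(c1 = strrep("A", 10000)))
  genes <- data.frame(gene_id = c("gp", "gm", "edge"),
                      chrom = "c1",
                      start = c(4000L, 4000L, 200L),
                      end = c(6000L, 6000L, 900L),
                      strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  r <- gene_flanking_regions(genes, g)
  pp <- r[r$gene_id == "gp" & r$region == "promoter", ]
  expect_equal(c(pp$start, pp$end), c(3000L, 4500L))  # 1 kb up + 0.5 kb down
  pm <- r[r$gene_id == "gm" & r$region == "promoter", ]
  # minus strand: promoter lies at higher coordinates than the TSS
  expect_equal(c(pm$start, pm$end), c(5500L, 7000L))
  pe <- r[r$gene_id == "edge" & r$region == "promoter", ]
  expect_true(pe$truncated)
  expect_equal(pe$start, 0L)
})

test_that("dbscan separates blobs, marks uniform noise and is order-stable", {
  set.seed(41)
  blob <- rbind(matrix(rnorm(120, 0, .04), ncol = 2),
                matrix(rnorm(120, 3, .04), ncol = 2))
  lab <- dbscan_cluster(blob / sd(blob[, 1]), eps = 0.25, min_pts = 5)
  expect_equal(length(unique(lab[lab > 0])), 2L)
  expect_equal(sum(lab == 0), 0L)
  # both blobs intact (no misassignment): each half has one label
  expect_equal(length(unique(lab[1:60])), 1L)
  expect_equal(length(unique(lab[61:120])), 1L)
  # sparse uniform points are mostly noise at the default radius
  unif <- matrix(runif(200, 0, 10), ncol = 2)
  lab_u <- dbscan_cluster(unif / sd(unif[, 1]), eps = 0.25, min_pts = 5)
  expect_gte(mean(lab_u == 0), 0.8)
})

test_that("profile clustering recovers planted archetypes and is seed-deterministic", {
  set.seed(55)
  K <- 4
  arche <- matrix(rpois(K * 8, 6) * matrix(rbinom(K * 8, 1, .4), K, 8),
                  K, 8)
  gene_arch <- rep(seq_len(K), each = 40)
  prof <- arche[gene_arch, ] + matrix(rpois(160 * 8, .3), 160, 8)
  rownames(prof) <- paste0("g", seq_len(160))
  colnames(prof) <- paste0("f", 1:8)
  ca <- cluster_profiles(prof, seed = 2)
  expect_s3_class(ca, "cluster_assignment")
  keep <- ca$cluster > 0
  expect_gt(mean(keep), 0.6)
  # adjusted Rand between recovered clusters and archetypes
  ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); n <- choose(sum(tab), 2)
    (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
  }
  expect_gte(ari(ca$cluster[keep], gene_arch[keep]), 0.7)
  expect_gte(ca$n_clusters, K - 1)
  # identical seed -> identical assignment; gene order permutation too
  ca2 <- cluster_profiles(prof, seed = 2)
  expect_identical(ca$cluster, ca2$cluster)
  perm <- sample(160)
  ca3 <- cluster_profiles(prof[perm, ], seed = 2)
  expect_gte(ari(ca3$cluster[ca3$cluster > 0 & ca$cluster[perm] > 0],
                 ca$cluster[perm][ca3$cluster > 0 & ca$cluster[perm] > 0]),
             0.95)
})

test_that("degenerate all-identical profiles collapse to a single cluster", {
  prof <- matrix(5, 60, 4, dimnames = list(paste0("g", 1:60),
                                           paste0("f", 1:4)))
  prof[, 1] <- prof[, 1] + rep(c(0, 1e-9), 30)
  ca <- cluster_profiles(prof + matrix(rnorm(240, 0, 1e-6), 60, 4), seed = 1)
  expect_lte(ca$n_clusters, 1L)
})

test_that("functional enrichment matches the exact hypergeometric computation", {
  cl <- c(rep(1L, 10), rep(2L, 90))
  names(cl) <- paste0("g", 1:100)
  assignment <- structure(list(cluster = cl, n_clusters = 2,
                               embedding = NULL),
                          class = "cluster_assignment")
  cats <- data.frame(gene_id = paste0("g", 1:100),
                     category = c(rep("catA", 8), rep("catB", 2),
                                  rep("catA", 10), rep("catB", 80)),
                     stringsAsFactors = FALSE)
  er <- functional_enrichment(assignment, cats)
  row <- er[er$cluster == 1 & er$category == "catA", ]
  expect_equal(c(row$in_in, row$in_out, row$out_in, row$out_out),
               c(8, 2, 10, 80))
  expect_equal(row$p,
               stats::fisher.test(matrix(c(8, 2, 10, 80), 2, 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_true(all(er$q >= er$p - 1e-12))
})

test_that("cluster equal to category gives minimal Fisher p", {
  cl <- c(rep(1L, 10), rep(2L, 40))
  names(cl) <- paste0("g", 1:50)
  assignment <- structure(list(cluster = cl, n_clusters = 2,
                               embedding = NULL),
                          class = "cluster_assignment")
  cats <- data.frame(gene_id = paste0("g", 1:50),
                     category = c(rep("hit", 10), rep("other", 40)))
  er <- functional_enrichment(assignment, cats)
  row <- er[er$cluster == 1 & er$category == "hit", ]
  expect_lt(row$p, 1e-10)
  expect_true(is.infinite(row$odds_ratio) || row$odds_ratio > 100)
})

test_that("co-expression permutation test hits the extreme-case floor and stays calibrated under the null", {
  set.seed(61)
  n <- 60
  ids <- paste0("g", seq_len(n))
  cl <- c(rep(1L, 10), rep(2L, 50))
  names(cl) <- ids
  assignment <- structure(list(cluster = cl, n_clusters = 2,
                               embedding = NULL),
                          class = "cluster_assignment")
  cx <- matrix(rnorm(n * n), n, n, dimnames = list(ids, ids))
  cx <- (cx + t(cx)) / 2
  # perfectly co-expressed cluster in random background -> minimal p
  cx[1:10, 1:10] <- 10
  diag(cx) <- NA
  ct <- coexpression_permutation_test(assignment, cx, n_perm = 400,
                                      seed = 9)
  expect_equal(ct$p[ct$cluster == 1], 1 / 401)
  # null calibration: random clusters give roughly uniform p
  ps <- replicate(60, {
    cl2 <- sample(cl)
    names(cl2) <- ids
    a2 <- structure(list(cluster = cl2, n_clusters = 2, embedding = NULL),
                    class = "cluster_assignment")
    cx2 <- matrix(rnorm(n * n), n, n, dimnames = list(ids, ids))
    cx2 <- (cx2 + t(cx2)) / 2; diag(cx2) <- NA
    coexpression_permutation_test(a2, cx2, n_perm = 99, seed = 1)$p[1]
  })
  expect_lt(mean(ps <= 0.05), 0.15)
  expect_gt(mean(ps), 0.3)
})

test_that("standardised logit transform centres and scales the upper triangle", {
  set.seed(3)
  raw <- matrix(runif(100, .1, .9), 10, 10)
  raw <- (raw + t(raw)) / 2
  z <- standardize_logit(raw)
  v <- z[upper.tri(z)]
  expect_equal(mean(v), 0, tolerance = 1e-9)
  expect_equal(sd(v), 1, tolerance = 1e-9)
})
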