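# Gene regulatory profiles: predicted binding over promoter/terminator
# regions, low-dimensional embedding, density-based clustering, functional
# enrichment and co-expression permutation tests.

#' Strand-aware promoter and terminator regions of genes
#'
#' The promoter is 1 kb upstream plus 0.5 kb downstream of the TSS; the
#' terminator is 0.5 kb upstream plus 1 kb downstream of the TTS (both
#' 1.5 kb total, on the gene strand). Regions are truncated at chromosome
#' edges and flagged.
#'
#' @param genes data.frame from [read_gff_genes()] (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param genome A `genome_sequence` (for edge truncation).
#' @param upstream,downstream Promoter geometry around the TSS (bp).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `region`
#'   (`promoter`/`terminator`), `truncated`.
#' @export
gene_flanking_regions <- function(genes, genome, upstream = 1000L,
                                  downstream = 500L) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    plus <- g$strand != "-"
    tss <- if (plus) g$start else g$end
    tts <- if (plus) g$end else g$start
    pro <- if (plus) c(tss - upstream, tss + downstream)
           else c(tss - downstream, tss + upstream)
    ter <- if (plus) c(tts - downstream, tts + upstream)
           else c(tts - upstream, tts + downstream)
    len <- genome$lengths[[g$chrom]]
    for (r in list(list(iv = pro, tag = "promoter"),
                   list(iv = ter, tag = "terminator"))) {
      s <- max(0L, r$iv[1]); e <- min(len, r$iv[2])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom, start = s, end = e,
        region = r$tag, truncated = (s != r$iv[1] || e != r$iv[2]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-gene predicted binding profiles
#'
#' Tiles windows at `step` bp across each gene's promoter and terminator
#' region, predicts family binding, and counts positive calls per family
#' over both regions.
#'
#' @param model Trained `tf_classifier`.
#' @param genome A `genome_sequence`.
#' @param genes data.frame of gene records ([read_gff_genes()]).
#' @param step Window step across the regions (default 250 =
#'   non-overlapping).
#' @param threshold Call threshold.
#' @param upstream,downstream Promoter geometry (bp).
#' @return Matrix (genes x families) of positive-call counts, with gene
#'   ids as row names.
#' @export
build_gene_profiles <- function(model, genome, genes, step = 250L,
                                threshold = 0.5, upstream = 1000L,
                                downstream = 500L) {
  regions <- gene_flanking_regions(genes, genome, upstream, downstream)
  wlen <- model$config$input_len
  wins <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$end - r$start < wlen) next
    starts <- seq.int(r$start, r$end - wlen, by = step)
    wins[[length(wins) + 1L]] <- data.frame(
      gene_id = r$gene_id, chrom = r$chrom, start = starts,
      end = starts + wlen, stringsAsFactors = FALSE)
  }
  wins <- do.call(rbind, wins)
  pred <- predict_probabilities(model, window_sequences(genome, wins),
                                threshold = threshold)
  prof <- rowsum(pred$calls, group = wins$gene_id)
  prof <- prof[match(unique(genes$gene_id), rownames(prof)), , drop = FALSE]
  prof[is.na(prof)] <- 0
  rownames(prof) <- unique(genes$gene_id)
  colnames(prof) <- model$families
  prof
}

#' Principal-component embedding of gene profiles
#'
#' Default embedder: log1p-transformed, column-scaled profiles projected
#' onto the first two principal components, globally rescaled by the
#' standard deviation of the leading component.
#'
#' @param profiles Matrix (genes x families).
#' @param dims Number of components (default 2).
#' @return Matrix (genes x dims).
#' @export
embed_profiles_pca <- function(profiles, dims = 2L) {
  x <- log1p(as.matrix(profiles))
  keep <- apply(x, 2, stats::sd) > 0
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  emb <- pc$x[, seq_len(min(dims, ncol(pc$x))), drop = FALSE]
  emb / stats::sd(emb[, 1])
}

#' Density-based clustering with a noise class
#'
#' A direct DBSCAN implementation: core points have at least `min_pts`
#' neighbours within `eps`; clusters are the connected components of core
#' points plus their border points; everything else is noise (cluster 0).
#'
#' @param x Numeric matrix of coordinates.
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbours (including the point itself).
#' @return Integer vector of cluster labels (0 = noise).
#' @export
dbscan_cluster <- function(x, eps = 0.25, min_pts = 5L) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Cluster gene regulatory profiles
#'
#' Pluggable two-stage procedure: a 2-D embedding (default
#' [embed_profiles_pca()]) followed by density-based clustering with a
#' noise class (default [dbscan_cluster()]). Deterministic given `seed`;
#' cluster labels are stable under gene-order permutation.
#'
#' @param profiles Matrix (genes x families) from [build_gene_profiles()].
#' @param embedder Function `profiles -> 2-column matrix`.
#' @param clusterer Function `embedding -> integer labels (0 = noise)`.
#' @param seed Integer seed (embedders/clusterers that use randomness draw
#'   from it).
#' @return A `cluster_assignment`: list with `cluster` (named integer
#'   vector, 0 = NOISE), `n_clusters`, `embedding`.
#' @export
cluster_profiles <- function(profiles, embedder = embed_profiles_pca,
                             clusterer = dbscan_cluster, seed = 1L) {
  if (nrow(profiles) < 50)
    warning("fewer than 50 genes; clustering may be unstable")
  emb <- with_seed(seed, embedder(profiles))
  labels <- with_seed(seed + 1L, clusterer(emb))
  # canonical order: clusters numbered by decreasing size
  sizes <- sort(table(labels[labels != 0]), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  labels2 <- ifelse(labels == 0, 0L, remap[as.character(labels)])
  names(labels2) <- rownames(profiles)
  structure(list(cluster = labels2,
                 n_clusters = length(sizes),
                 embedding = emb), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", x$n_clusters, "clusters,",
      sum(x$cluster == 0), "noise genes of", length(x$cluster), "\n")
  invisible(x)
}

#' Functional-category enrichment of regulatory clusters
#'
#' Per (cluster, category) a 2x2 contingency table over the clustered
#' (non-noise) gene universe is tested with a two-sided Fisher's exact
#' test; Benjamini-Hochberg correction is applied across the whole
#' cluster x category grid.
#'
#' @param assignment A `cluster_assignment`.
#' @param gene_categories data.frame with `gene_id`, `category` (a gene
#'   may appear with several categories).
#' @return data.frame with `cluster`, `category`, the table cells
#'   (`in_in`, `in_out`, `out_in`, `out_out`), `odds_ratio`, `p`, `q`.
#' @export
functional_enrichment <- function(assignment, gene_categories) {
  cl <- assignment$cluster
  cl <- cl[cl != 0]                     # noise genes excluded
  genes <- names(cl)
  gene_categories <- gene_categories[gene_categories$gene_id %in% genes, ]
  cats <- unique(gene_categories$category)
  out <- list()
  for (k in sort(unique(cl))) {
    in_cluster <- names(cl)[cl == k]
    for (cat in cats) {
      cat_genes <- gene_categories$gene_id[gene_categories$category == cat]
      a <- sum(in_cluster %in% cat_genes)
      b <- length(in_cluster) - a
      c_ <- sum(!(cat_genes %in% in_cluster))
      d <- length(genes) - a - b - c_
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2,
                                      byrow = TRUE))
      out[[length(out) + 1L]] <- data.frame(
        cluster = k, category = cat, in_in = a, in_out = b, out_in = c_,
        out_out = d, odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Co-expression permutation test for regulatory clusters
#'
#' For each cluster, the observed statistic is the mean standardised
#' logit co-expression over all within-cluster gene pairs. The null is
#' built by drawing, `n_perm` times, the same number of random gene pairs
#' from the clustered (non-noise) genes; the empirical p-value is
#' `(# null means >= observed + 1) / (n_perm + 1)`, followed by BH
#' correction across clusters.
#'
#' @param assignment A `cluster_assignment`.
#' @param coexpr Symmetric numeric matrix of pairwise co-expression scores
#'   (standardised logit scale), gene ids as dimnames.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return data.frame with `cluster`, `n_genes`, `n_pairs`, `observed`,
#'   `null_mean`, `p`, `q`; clusters of size < 2 are skipped.
#' @export
coexpression_permutation_test <- function(assignment, coexpr,
                                          n_perm = 1000L, seed = 1L) {
  cl <- assignment$cluster
  cl <- cl[cl != 0 & names(cl) %in% rownames(coexpr)]
  pool <- names(cl)
  np <- length(pool)
  pair_mean <- function(g) {
    m <- coexpr[g, g, drop = FALSE]
    mean(m[upper.tri(m)], na.rm = TRUE)
  }
  res <- with_seed(seed, {
    out <- list()
    for (k in sort(unique(cl))) {
      members <- names(cl)[cl == k]
      if (length(members) < 2) next
      obs <- pair_mean(members)
      n_pairs <- choose(length(members), 2)
      null <- vapply(seq_len(n_perm), function(i) {
        ii <- sample.int(np, n_pairs, replace = TRUE)
        jj <- sample.int(np - 1L, n_pairs, replace = TRUE)
        jj <- jj + (jj >= ii)           # distinct partner per pair
        mean(coexpr[cbind(pool[ii], pool[jj])], na.rm = TRUE)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        cluster = k, n_genes = length(members), n_pairs = n_pairs,
        observed = obs, null_mean = mean(null),
        p = (sum(null >= obs) + 1) / (n_perm + 1),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  if (is.null(res)) return(res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Standardised logit transform of co-expression scores
#'
#' Maps raw scores in (0, 1) to logits and standardises them to zero mean
#' and unit variance (over the upper triangle).
#'
#' @param scores Symmetric matrix of co-expression values in (0, 1).
#' @param eps Clamping bound away from 0/1.
#' @return Standardised logit matrix.
#' @export
standardize_logit <- function(scores, eps = 1e-6) {
  p <- pmin(pmax(scores, eps), 1 - eps)
  l <- log(p / (1 - p))
  v <- l[upper.tri(l)]
  (l - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
}
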