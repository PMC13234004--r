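test_that("motif libraries respect widths, shared cores and information content", {
  lib <- make_motif_library(5, widths = c(12, 13, 12, 11, 14),
                            shared_core = list(core = "CACGTG",
                                               members = 1:3),
                            seed = 2)
  expect_length(lib, 5L)
  expect_equal(vapply(lib, function(x) ncol(x$pwm), integer(1)),
               c(fam01 = 12L, fam02 = 13L, fam03 = 12L, fam04 = 11L,
                 fam05 = 14L))
  # shared-core members carry the exact core columns
  for (i in 1:3) {
    core <- lib[[i]]$pwm[, lib[[i]]$core_cols]
    expect_equal(rownames(core)[apply(core, 2, which.max)],
                 c("C", "A", "C", "G", "T", "G"))
  }
  # information-rich columns
  for (x in lib) expect_gt(mean(tfbinder:::pwm_ic(x$pwm)), 1)
  # core members are more similar to each other than to outgroups
  s_core <- motif_similarity(lib[[1]]$pwm, lib[[2]]$pwm)
  s_out <- motif_similarity(lib[[1]]$pwm, lib[[4]]$pwm)
  expect_gt(s_core, s_out)
  expect_error(make_motif_library(3, widths = 5,
                                  shared_core = list(core = "CACGTG",
                                                     members = 1:2)),
               "width")
})

test_that("synthetic genomes hit the requested GC and are byte-deterministic", {
  g <- synthesize_genome(2, 100000, gc = 0.5, seed = 9)
  chars <- strsplit(g$seqs[[1]], "")[[1]]
  expect_lt(abs(mean(chars %in% c("G", "C")) - 0.5), 0.01)
  g2 <- synthesize_genome(2, 100000, gc = 0.5, seed = 9)
  expect_identical(g$seqs, g2$seqs)
  expect_equal(g$chrom_names, c("chr1", "chr2"))
})

test_that("site planting matches requested abundances, avoids overlaps and respects co-occurrence rules", {
  lib <- make_motif_library(3, widths = 10, seed = 5)
  g <- synthesize_genome(2, 150000, seed = 6)
  pl <- plant_sites(g, lib, abundance = c(300, 100, 10),
                    cooccurrence_rules = list(list(a = "fam01",
                                                   b = "fam02",
                                                   prob = 0.8)),
                    seed = 11)
  reg <- pl$truth$registry
  counts <- table(reg$family)
  expect_equal(unname(counts[["fam01"]]), 300L)
  expect_equal(unname(counts[["fam03"]]), 10L)
  expect_gt(counts[["fam02"]], 100L)    # rule-planted extras
  # BED line counts match the registry
  expect_equal(nrow(pl$peak_sets$fam01$peaks), 300L)
  # no overlapping sites
  for (ch in unique(reg$chrom)) {
    r <- reg[reg$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1)
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }
  # co-occurrence: >= 70% of fam01 sites have a fam02 site within 250 bp
  a <- reg[reg$family == "fam01", ]
  b <- reg[reg$family == "fam02", ]
  near <- vapply(seq_len(nrow(a)), function(i)
    any(b$chrom == a$chrom[i] & abs(b$start - a$start[i]) <= 260),
    logical(1))
  expect_gte(mean(near), 0.7)
  # planted genome differs from background only where sites are
  expect_equal(g$lengths, pl$genome$lengths)
  # labelling the synthetic peaks recovers the registry geometry
  w <- tile_windows(pl$genome, 250, 250)
  lab <- assign_labels(w, pl$peak_sets)
  expect_gt(lab$supports[["fam01"]], 200)
})

test_that("synthetic SNPs hit planted sites or stay 10 bp away from them", {
  lib <- make_motif_library(2, widths = 10, seed = 3)
  g <- synthesize_genome(1, 100000, seed = 4)
  pl <- plant_sites(g, lib, abundance = c(150, 50), seed = 5)
  v <- make_variants(pl$truth, pl$genome, n_hit = 40, n_background = 40,
                     seed = 6)
  expect_equal(nrow(v), 80L)
  expect_true(all(v$ref != v$alt))
  reg <- pl$truth$registry
  hits <- v[v$truth == "hit", ]
  inside <- vapply(seq_len(nrow(hits)), function(i)
    any(reg$chrom == hits$chrom[i] & hits$pos[i] > reg$start &
          hits$pos[i] <= reg$end), logical(1))
  expect_true(all(inside))
  bg <- v[v$truth == "background", ]
  far <- vapply(seq_len(nrow(bg)), function(i)
    all(reg$chrom != bg$chrom[i] | bg$pos[i] <= reg$start - 9 |
          bg$pos[i] > reg$end + 10), logical(1))
  expect_true(all(far))
  # ref matches the genome
  for (i in sample(nrow(v), 10))
    expect_equal(substring(pl$genome$seqs[[v$chrom[i]]], v$pos[i], v$pos[i]),
                 v$ref[i])
})

test_that("condition datasets split mild/extreme at |lfc| = 1 with family-driven signs", {
  lib <- make_motif_library(3, widths = 10, seed = 7)
  g <- synthesize_genome(1, 120000, seed = 8)
  pl <- plant_sites(g, lib, abundance = c(200, 200, 50), seed = 9)
  cd <- make_condition_dataset(pl$truth, pl$peak_sets,
                               c("fam01", "fam02"), effect = 3,
                               noise = 0.5, seed = 10)
  expect_setequal(unique(cd$response_class), c("mild", "extreme"))
  expect_true(all((abs(cd$lfc) < 1) == (cd$response_class == "mild")))
  expect_true(all((cd$lfc < 0) == (cd$sign_class == "negative")))
  # Bayes sign accuracy from the family identity exceeds 0.95
  bayes <- mean((cd$family == "fam01") == (cd$sign_class == "positive"))
  expect_gt(bayes, 0.95)
  # effect 0 gives coin-flip signs
  cd0 <- make_condition_dataset(pl$truth, pl$peak_sets,
                                c("fam01", "fam02"), effect = 0,
                                noise = 0.5, seed = 11)
  expect_lt(abs(mean(cd0$sign_class == "positive") - 0.5), 0.1)
})

test_that("bundle regeneration is deterministic and writes the expected files", {
  b1 <- synthetic_bundle(seed = 3, n_chroms = 2, chrom_len = 50000,
                         abundance_range = c(150, 20), with_genes = TRUE)
  b2 <- synthetic_bundle(seed = 3, n_chroms = 2, chrom_len = 50000,
                         abundance_range = c(150, 20), with_genes = TRUE)
  expect_identical(b1$genome$seqs, b2$genome$seqs)
  expect_identical(b1$truth$registry, b2$truth$registry)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$condition_peaks$lfc, b2$condition_peaks$lfc)
  d <- file.path(tempdir(), "bundle_out")
  write_bundle(b1, d)
  expect_true(file.exists(file.path(d, "genome.fa")))
  expect_true(file.exists(file.path(d, "genes.gff3")))
  expect_true(file.exists(file.path(d, "snps.tsv")))
  # the FASTA round-trips to the same genome
  g <- read_fasta(file.path(d, "genome.fa"))
  expect_identical(g$seqs, b1$genome$seqs)
  # GFF3 gene records round-trip
  gg <- read_gff_genes(file.path(d, "genes.gff3"))
  expect_equal(nrow(gg), nrow(b1$genes))
  expect_equal(gg$start, b1$genes$start)
})
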