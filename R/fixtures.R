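# Synthetic genomes with planted motifs: the ground-truth test bed for the
# whole pipeline. Every generator is deterministic given its seed.

#' Generate a library of family position weight matrices
#'
#' Each family gets an information-rich PWM (dominant base probability drawn
#' in `[0.92, 0.99]` per column, emulating the sharp consensus of
#' high-affinity family motifs; mean information content >= 1.4 bit). An
#' optional subset of families shares a fixed core (e.g. the palindromic
#' G-box `CACGTG`) at the centre of their PWMs, with distinct flanks, which
#' emulates TF families with overlapping binding preferences.
#'
#' @param n_families Number of families (>= 2).
#' @param widths Integer vector of motif widths (recycled to `n_families`).
#' @param shared_core Optional list with `core` (consensus string) and
#'   `members` (indices of families sharing it).
#' @param families Optional family names.
#' @param seed Integer seed.
#' @return A `motif_library`: named list of `list(pwm, width, core_cols)`.
#' @export
make_motif_library <- function(n_families, widths = 12L, shared_core = NULL,
                               families = NULL, seed = 1L) {
  if (n_families < 2) stop("n_families must be >= 2")
  widths <- rep_len(as.integer(widths), n_families)
  if (is.null(families)) families <- sprintf("fam%02d", seq_len(n_families))
  core_chars <- NULL
  if (!is.null(shared_core)) {
    core_chars <- strsplit(toupper(shared_core$core), "", fixed = TRUE)[[1]]
    if (any(widths[shared_core$members] < length(core_chars)))
      stop("motif width smaller than shared core length")
  }
  bases <- c("A", "C", "G", "T")
  draw_pwm <- function(w, is_core_member) {
    # members of the shared-core group get moderately informative flanks
    # (sharp core, softer flanks, as in real family motifs) so that their
    # similarity is carried by the core they share
    pwm <- vapply(seq_len(w), function(j) {
      a <- if (is_core_member) stats::runif(1, 0.75, 0.90)
           else stats::runif(1, 0.92, 0.99)
      p <- rep((1 - a) / 3, 4)
      p[sample.int(4, 1)] <- a
      p
    }, numeric(4))
    rownames(pwm) <- bases
    pwm
  }
  with_seed(seed, {
    lib <- lapply(seq_len(n_families), function(i) {
      w <- widths[i]
      is_core_member <- !is.null(core_chars) && i %in% shared_core$members
      pwm <- draw_pwm(w, is_core_member)
      core_cols <- integer(0)
      if (is_core_member) {
        off <- (w - length(core_chars)) %/% 2
        core_cols <- off + seq_along(core_chars)
        for (j in seq_along(core_chars)) {
          p <- rep(0.01, 4)
          p[match(core_chars[j], bases)] <- 0.97
          pwm[, core_cols[j]] <- p
        }
      }
      list(pwm = pwm, width = w, core_cols = core_cols)
    })
    # the shared-core group is defined by mutual similarity; redraw any
    # outgroup motif that collides with it by chance so the library
    # actually encodes the designed structure
    if (!is.null(core_chars)) {
      members <- shared_core$members
      for (i in setdiff(seq_len(n_families), members)) {
        for (try in seq_len(200)) {
          s <- max(vapply(members, function(m)
            motif_similarity(lib[[i]]$pwm, lib[[m]]$pwm,
                             min_overlap = 8L), numeric(1)))
          if (s <= 0.45) break
          lib[[i]]$pwm <- draw_pwm(widths[i], FALSE)
        }
      }
    }
    names(lib) <- families
    structure(lib, class = "motif_library")
  })
}

#' Synthesize an i.i.d. background genome
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp); recycled.
#' @param gc GC fraction of the background.
#' @param seed Integer seed.
#' @return A `genome_sequence` with chromosomes `chr1`, `chr2`, ...
#' @export
synthesize_genome <- function(n_chroms = 5L, chrom_len = 200000L, gc = 0.36,
                              seed = 1L) {
  stopifnot(n_chroms >= 1, all(chrom_len >= 1), gc > 0, gc < 1)
  chrom_len <- rep_len(as.integer(chrom_len), n_chroms)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(names(probs), chrom_len[i], replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chroms))
    genome_sequence(seqs)
  })
}

sample_pwm_sequence <- function(pwm) {
  paste(apply(pwm, 2, function(p) sample(rownames(pwm), 1, prob = p)),
        collapse = "")
}

#' Plant motif instances into a genome
#'
#' Sites are sampled from each family's PWM, placed on a random strand at
#' non-overlapping positions, and recorded in a ground-truth registry.
#' Co-occurrence rules (a, b, prob) additionally place a site of family
#' `b` within `neighbourhood` bp of each site of family `a` with the stated
#' probability. Each planted site yields a peak: the site midpoint extended
#' to `peak_len` bp.
#'
#' @param genome A `genome_sequence` (background).
#' @param library A `motif_library`.
#' @param abundance Named (or positional) integer vector of per-family site
#'   counts.
#' @param cooccurrence_rules Optional list of `list(a=, b=, prob=)`.
#' @param seed Integer seed.
#' @param peak_len Total peak length (default 100 bp, so that a 250 bp
#'   window can cover >= 70% of a peak).
#' @param max_retries Placement retries before giving up.
#' @return List with `genome` (sites written in), `truth`
#'   (`synthetic_truth`: library, registry, abundance, rules, seed) and
#'   `peak_sets` (list of `peak_set`, one per family).
#' @export
plant_sites <- function(genome, library, abundance,
                        cooccurrence_rules = NULL, seed = 1L,
                        peak_len = 100L, max_retries = 200L) {
  families <- names(library)
  abundance <- rep_len(as.integer(abundance), length(families))
  names(abundance) <- families
  chroms <- genome$chrom_names
  lens <- genome$lengths
  chars <- lapply(genome$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  occupied <- lapply(lens, function(l) logical(l))
  flank <- as.integer(ceiling(peak_len / 2))
  registry <- list()

  place_one <- function(family, near = NULL) {
    pwm <- library[[family]]$pwm
    w <- library[[family]]$width
    for (try in seq_len(max_retries)) {
      if (is.null(near)) {
        chrom <- sample(chroms, 1, prob = lens)
        start <- sample.int(lens[[chrom]] - w - 2L * flank, 1) + flank  # 0-based
      } else {
        chrom <- near$chrom
        offset <- sample.int(2L * near$dist + 1L, 1) - near$dist - 1L
        start <- near$start + offset
        if (start < flank || start + w + flank > lens[[chrom]]) next
      }
      span <- (start + 1L):(start + w)
      if (any(occupied[[chrom]][span])) next
      strand <- sample(c("+", "-"), 1)
      s <- sample_pwm_sequence(pwm)
      if (strand == "-") s <- revcomp(s)
      chars[[chrom]][span] <<- strsplit(s, "", fixed = TRUE)[[1]]
      occupied[[chrom]][span] <<- TRUE
      registry[[length(registry) + 1L]] <<-
        data.frame(family = family, chrom = chrom, start = start,
                   end = start + w, strand = strand,
                   stringsAsFactors = FALSE)
      return(list(chrom = chrom, start = start))
    }
    stop("site placement failed after ", max_retries, " retries (",
         "occupied fraction: ",
         round(mean(unlist(lapply(occupied, mean))), 3), ")")
  }

  rule_for <- function(family) {
    if (is.null(cooccurrence_rules)) return(NULL)
    for (r in cooccurrence_rules) if (r$a == family) return(r)
    NULL
  }

  with_seed(seed, {
    for (family in families) {
      rule <- rule_for(family)
      for (i in seq_len(abundance[[family]])) {
        at <- place_one(family)
        if (!is.null(rule) && stats::runif(1) < rule$prob) {
          place_one(rule$b, near = list(chrom = at$chrom, start = at$start,
                                        dist = 250L))
        }
      }
    }
  })
  registry <- do.call(rbind, registry)
  rownames(registry) <- NULL
  genome2 <- genome_sequence(
    stats::setNames(vapply(chroms, function(ch)
      paste(chars[[ch]], collapse = ""), character(1)), chroms))
  peak_sets <- lapply(families, function(f) {
    sites <- registry[registry$family == f, , drop = FALSE]
    mid <- (sites$start + sites$end) %/% 2L
    peak_set(data.frame(chrom = sites$chrom,
                        start = pmax(mid - flank, 0L),
                        end = pmin(mid + flank, lens[sites$chrom]),
                        stringsAsFactors = FALSE),
             family = f, source = "synthetic planted sites")
  })
  names(peak_sets) <- families
  truth <- structure(list(library = library, registry = registry,
                          abundance = abundance,
                          cooccurrence_rules = cooccurrence_rules,
                          peak_len = peak_len, seed = seed),
                     class = "synthetic_truth")
  list(genome = genome2, truth = truth, peak_sets = peak_sets)
}

#' Generate SNPs that hit or miss planted motifs
#'
#' Hit SNPs are placed at the highest-information position of a planted
#' site, replacing the reference base with the least probable base of that
#' PWM column (strand-aware). Background SNPs fall at least `min_gap` bp
#' from every planted site and substitute a random different base.
#'
#' @param truth A `synthetic_truth` from [plant_sites()].
#' @param genome The matching planted `genome_sequence`.
#' @param n_hit,n_background Numbers of motif-hitting and background SNPs.
#' @param seed Integer seed.
#' @param min_gap Minimum distance of background SNPs from any site.
#' @return data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `phenotype`, `truth` (`"hit"`/`"background"`), `family`.
#' @export
make_variants <- function(truth, genome, n_hit, n_background, seed = 1L,
                          min_gap = 10L) {
  reg <- truth$registry
  if (nrow(reg) == 0) stop("empty site registry")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    hit_rows <- sample.int(nrow(reg), n_hit, replace = n_hit > nrow(reg))
    hits <- lapply(hit_rows, function(i) {
      site <- reg[i, ]
      pwm <- truth$library[[site$family]]$pwm
      ic <- apply(pwm, 2, function(p) 2 + sum(p * log2(p)))
      j <- which.max(ic)                      # motif column, + orientation
      pos0 <- if (site$strand == "+") site$start + j - 1L
              else site$end - j               # 0-based genome position
      ref <- substring(genome$seqs[[site$chrom]], pos0 + 1L, pos0 + 1L)
      worst <- bases[which.min(pwm[, j])]
      alt <- if (site$strand == "+") worst else chartr("ACGT", "TGCA", worst)
      if (alt == ref) {                       # ref may already be non-consensus
        alt <- sample(setdiff(bases, ref), 1)
      }
      data.frame(chrom = site$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
                 phenotype = "synthetic_trait", truth = "hit",
                 family = site$family, stringsAsFactors = FALSE)
    })
    # background: positions >= min_gap away from every planted site
    bg <- vector("list", n_background)
    k <- 0L
    while (k < n_background) {
      chrom <- sample(genome$chrom_names, 1, prob = genome$lengths)
      pos0 <- sample.int(genome$lengths[[chrom]] - 1L, 1)
      near <- reg$chrom == chrom &
        pos0 >= (reg$start - min_gap) & pos0 < (reg$end + min_gap)
      if (any(near)) next
      ref <- substring(genome$seqs[[chrom]], pos0 + 1L, pos0 + 1L)
      if (!ref %in% bases) next
      k <- k + 1L
      bg[[k]] <- data.frame(chrom = chrom, pos = pos0 + 1L, ref = ref,
                            alt = sample(setdiff(bases, ref), 1),
                            phenotype = "synthetic_trait",
                            truth = "background", family = NA_character_,
                            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(hits, bg))
    rownames(out) <- NULL
    out
  })
}

#' Generate a condition-response peak table
#'
#' Builds a differential-binding dataset from the peaks of two designated
#' responsive families: peaks of the first get positive, peaks of the
#' second negative log fold changes. Per-peak response strength is bimodal
#' (strong responders at the full `effect`, weak responders at
#' `weak_scale * effect`) so that both mild (`|lfc| < 1`) and extreme
#' (`|lfc| >= 1`) response classes are populated while the fold-change sign
#' stays family-driven.
#'
#' @param truth A `synthetic_truth`.
#' @param peak_sets Peak sets from [plant_sites()].
#' @param responsive_families Character vector of exactly two family names;
#'   the first responds positively, the second negatively.
#' @param effect Fold-change magnitude for strong responders.
#' @param noise Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param weak_fraction Fraction of weak-responder peaks.
#' @param weak_scale Effect multiplier for weak responders.
#' @return data.frame with `chrom`, `start`, `end`, `family`, `lfc`,
#'   `response_class` (`mild`/`extreme`), `sign_class`
#'   (`negative`/`positive`).
#' @export
make_condition_dataset <- function(truth, peak_sets, responsive_families,
                                   effect = 3, noise = 0.5, seed = 1L,
                                   weak_fraction = 0.5, weak_scale = 0.25) {
  if (length(responsive_families) != 2 ||
      !all(responsive_families %in% names(truth$library)))
    stop("responsive_families must name two families of the library")
  peaks <- do.call(rbind, lapply(responsive_families, function(f) {
    df <- peak_sets[[f]]$peaks
    df$family <- f
    df
  }))
  s <- ifelse(peaks$family == responsive_families[1], 1, -1)
  with_seed(seed, {
    g <- ifelse(stats::runif(nrow(peaks)) < weak_fraction, weak_scale, 1)
    peaks$lfc <- effect * g * s + stats::rnorm(nrow(peaks), sd = noise)
  })
  peaks$response_class <- ifelse(abs(peaks$lfc) < 1, "mild", "extreme")
  peaks$sign_class <- ifelse(peaks$lfc < 0, "negative", "positive")
  rownames(peaks) <- NULL
  peaks
}

#' Generate synthetic gene models and archetype annotations
#'
#' Lays non-overlapping gene bodies on the genome, assigns each gene a
#' regulatory archetype, plants the archetype's family sites into the gene
#' promoter, and derives a functional-category table plus a pairwise
#' co-expression matrix (standardised logit scores) in which genes of the
#' same archetype co-express.
#'
#' @param bundle A list with `genome`, `truth`, `peak_sets` (modified in
#'   place and returned).
#' @param n_genes_per_chrom Genes per chromosome.
#' @param n_archetypes Number of regulatory archetypes.
#' @param sites_per_gene Sites planted per archetype family in a promoter.
#' @param seed Integer seed.
#' @return The bundle extended with `genes`, `gene_categories`, `coexpr`
#'   (matrix) and updated `genome`/`truth`/`peak_sets`.
#' @export
add_synthetic_genes <- function(bundle, n_genes_per_chrom = 30L,
                                n_archetypes = 4L, sites_per_gene = 3L,
                                seed = 1L) {
  genome <- bundle$genome
  lib <- bundle$truth$library
  families <- names(lib)
  arch_fams <- with_seed(seed + 1L, lapply(seq_len(n_archetypes), function(k)
    sample(families, 2)))
  genes <- list()
  with_seed(seed, {
    for (chrom in genome$chrom_names) {
      len <- genome$lengths[[chrom]]
      slots <- floor(len / (n_genes_per_chrom + 1))
      for (g in seq_len(n_genes_per_chrom)) {
        body_start <- (g - 1L) * slots + 2000L
        body_end <- body_start + 1500L
        if (body_end + 1500L > len) next
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = sprintf("g%s_%02d", sub("chr", "", chrom), g),
          chrom = chrom, start = body_start, end = body_end,
          strand = sample(c("+", "-"), 1),
          archetype = sample.int(n_archetypes, 1),
          stringsAsFactors = FALSE)
      }
    }
  })
  genes <- do.call(rbind, genes)
  # plant archetype family sites into promoters (strand-aware upstream)
  chars <- lapply(genome$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  reg_extra <- list()
  with_seed(seed + 2L, {
    for (i in seq_len(nrow(genes))) {
      gfams <- arch_fams[[genes$archetype[i]]]
      tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i]
      lo <- if (genes$strand[i] == "+") tss - 1000L else tss - 500L
      hi <- if (genes$strand[i] == "+") tss + 500L else tss + 1000L
      for (f in gfams) {
        w <- lib[[f]]$width
        for (k in seq_len(sites_per_gene)) {
          start <- sample(seq.int(lo, hi - w), 1)
          s <- sample_pwm_sequence(lib[[f]]$pwm)
          chars[[genes$chrom[i]]][(start + 1L):(start + w)] <-
            strsplit(s, "", fixed = TRUE)[[1]]
          reg_extra[[length(reg_extra) + 1L]] <- data.frame(
            family = f, chrom = genes$chrom[i], start = start,
            end = start + w, strand = "+", stringsAsFactors = FALSE)
        }
      }
    }
  })
  genome2 <- genome_sequence(stats::setNames(
    vapply(genome$chrom_names, function(ch) paste(chars[[ch]], collapse = ""),
           character(1)), genome$chrom_names))
  registry <- rbind(bundle$truth$registry, do.call(rbind, reg_extra))
  bundle$truth$registry <- registry
  flank <- as.integer(ceiling(bundle$truth$peak_len / 2))
  bundle$peak_sets <- lapply(names(bundle$peak_sets), function(f) {
    sites <- registry[registry$family == f, , drop = FALSE]
    mid <- (sites$start + sites$end) %/% 2L
    peak_set(data.frame(chrom = sites$chrom,
                        start = pmax(mid - flank, 0L),
                        end = pmin(mid + flank, genome2$lengths[sites$chrom]),
                        stringsAsFactors = FALSE),
             family = f, source = "synthetic planted sites")
  })
  names(bundle$peak_sets) <- names(lib)
  bundle$genome <- genome2
  bundle$genes <- genes
  bundle$gene_archetype_families <- arch_fams
  bundle$gene_categories <- data.frame(
    gene_id = genes$gene_id,
    category = paste0("cat", genes$archetype),
    stringsAsFactors = FALSE)
  # co-expression: same-archetype pairs score high on the logit scale
  n <- nrow(genes)
  with_seed(seed + 3L, {
    same <- outer(genes$archetype, genes$archetype, "==")
    cx <- matrix(stats::rnorm(n * n, mean = 0, sd = 1), n, n)
    cx <- (cx + t(cx)) / sqrt(2)
    cx[same] <- cx[same] + 2
    diag(cx) <- NA
    dimnames(cx) <- list(genes$gene_id, genes$gene_id)
    bundle$coexpr <- cx
  })
  bundle
}

#' Assemble the default synthetic dataset bundle
#'
#' Five chromosomes of 200 kb, eight families of which three share a
#' `CACGTG` core, per-family site counts log-spaced from 1500 down to 30
#' (long-tailed imbalance), 100 bp peaks, one co-occurrence rule, gene
#' models with archetype-driven promoters, SNPs and a condition peak table.
#' Regeneration with the same seed is deterministic; when `out_dir` is
#' given, FASTA/BED/GFF3/TSV files are written there.
#'
#' @param seed Integer master seed (default 7).
#' @param n_chroms,chrom_len Genome shape.
#' @param n_families Number of TF families.
#' @param abundance_range Site counts of the most/least abundant family.
#' @param with_genes Also lay down synthetic gene models and the derived
#'   category/co-expression tables.
#' @param out_dir Optional directory to write the files to.
#' @return A list: `genome`, `truth`, `peak_sets`, `families`, and (with
#'   genes) `genes`, `gene_categories`, `coexpr`, plus `variants` and
#'   `condition_peaks`.
#' @export
synthetic_bundle <- function(seed = 7L, n_chroms = 5L, chrom_len = 200000L,
                             n_families = 8L,
                             abundance_range = c(1500L, 30L),
                             with_genes = TRUE, out_dir = NULL) {
  families <- c("GboxA", "GboxB", "GboxC", "WRKYlike", "AP2like",
                "MYBlike", "HSFlike", "TCPlike")[seq_len(n_families)]
  lib <- make_motif_library(
    n_families,
    widths = c(12L, 13L, 12L, 11L, 12L, 13L, 12L, 11L)[seq_len(n_families)],
    shared_core = list(core = "CACGTG", members = 1:3),
    families = families, seed = seed)
  genome <- synthesize_genome(n_chroms, chrom_len, gc = 0.36, seed = seed + 1L)
  abundance <- round(exp(seq(log(abundance_range[1]), log(abundance_range[2]),
                             length.out = n_families)))
  rules <- list(list(a = families[4], b = families[5], prob = 0.6))
  planted <- plant_sites(genome, lib, abundance, cooccurrence_rules = rules,
                         seed = seed + 2L)
  bundle <- list(genome = planted$genome, truth = planted$truth,
                 peak_sets = planted$peak_sets, families = families,
                 seed = seed)
  if (with_genes) bundle <- add_synthetic_genes(bundle, seed = seed + 3L)
  bundle$variants <- make_variants(bundle$truth, bundle$genome,
                                   n_hit = 60L, n_background = 60L,
                                   seed = seed + 4L)
  bundle$condition_peaks <- make_condition_dataset(
    bundle$truth, bundle$peak_sets,
    responsive_families = c(families[4], families[6]),
    effect = 3, noise = 0.5, seed = seed + 5L)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a synthetic bundle to plain-text files
#'
#' @param bundle A bundle from [synthetic_bundle()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genome, file.path(out_dir, "genome.fa"))
  for (f in names(bundle$peak_sets)) {
    write_bed(bundle$peak_sets[[f]]$peaks,
              file.path(out_dir, paste0("peaks_", f, ".bed")))
  }
  utils::write.table(bundle$truth$registry,
                     file.path(out_dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$genes)) {
    gff <- with(bundle$genes, paste(chrom, "tfbinder", "gene", start + 1L,
                                    end, ".", strand, ".",
                                    paste0("ID=", gene_id), sep = "\t"))
    writeLines(c("##gff-version 3", gff), file.path(out_dir, "genes.gff3"))
    utils::write.table(bundle$gene_categories,
                       file.path(out_dir, "gene_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$variants))
    utils::write.table(bundle$variants, file.path(out_dir, "snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$condition_peaks))
    utils::write.table(bundle$condition_peaks,
                       file.path(out_dir, "condition_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
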