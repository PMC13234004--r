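#' Tile fixed-length windows across a genome
#'
#' Windows start at position 0 of each chromosome and advance by `step` bp;
#' a trailing fragment shorter than `window_len` is dropped so that every
#' window has exactly `window_len` bp. With `step == window_len` the windows
#' are non-overlapping and tile each chromosome left to right; smaller steps
#' (e.g. 75 or 125 bp) produce the overlapping windows used for
#' offset-augmented training.
#'
#' @param genome A `genome_sequence`.
#' @param window_len Window length in bp (default 250).
#' @param step Step between window starts, `1 <= step <= window_len`.
#' @return A `window_set`: data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and attributes `window_len`, `step`.
#' @export
tile_windows <- function(genome, window_len = 250L, step = window_len) {
  window_len <- as.integer(window_len)
  step <- as.integer(step)
  if (window_len < 1L) stop("window_len must be >= 1")
  if (step < 1L || step > window_len) stop("step must be in [1, window_len]")
  pieces <- lapply(genome$chrom_names, function(chrom) {
    len <- genome$lengths[[chrom]]
    if (len < window_len) return(NULL)
    starts <- seq.int(0L, len - window_len, by = step)
    data.frame(chrom = chrom, start = starts, end = starts + window_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer())
  rownames(out) <- NULL
  structure(out, window_len = window_len, step = step,
            class = c("window_set", "data.frame"))
}

#' Label windows by peak coverage
#'
#' A window is labelled positive for a family if it covers at least
#' `min_peak_coverage` of the length of some peak of that family (default
#' 70%). Families are reported in the order given; a family with an empty
#' peak set yields an all-zero column with a warning.
#'
#' @param windows A `window_set` (or data.frame with `chrom`, `start`, `end`).
#' @param peak_sets List of `peak_set` objects (one per family).
#' @param min_peak_coverage Fraction of the peak that must be covered.
#' @return A `label_matrix`: list with `windows`, `families`, `values`
#'   (binary matrix windows x families) and `supports` (column sums).
#' @export
assign_labels <- function(windows, peak_sets, min_peak_coverage = 0.7) {
  if (inherits(peak_sets, "peak_set")) peak_sets <- list(peak_sets)
  families <- vapply(peak_sets, function(p) p$family, character(1))
  if (anyDuplicated(families)) stop("duplicate family labels in peak_sets")
  wgr <- as_granges0(windows)
  values <- matrix(0L, nrow = nrow(windows), ncol = length(families),
                   dimnames = list(NULL, families))
  for (i in seq_along(peak_sets)) {
    pk <- peak_sets[[i]]$peaks
    if (nrow(pk) == 0L) {
      warning("family '", families[i], "' has no peaks; all-zero column")
      next
    }
    pgr <- as_granges0(pk)
    hits <- GenomicRanges::findOverlaps(wgr, pgr)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(wgr)[qi], IRanges::ranges(pgr)[si]))
    need <- min_peak_coverage * (pk$end[si] - pk$start[si])
    pos <- unique(qi[ov >= need])
    values[pos, i] <- 1L
  }
  label_matrix(windows, values)
}

#' Construct a label matrix
#'
#' @param windows A `window_set` (or compatible data.frame).
#' @param values Binary matrix (windows x families) with family column names.
#' @return A `label_matrix` object.
#' @export
label_matrix <- function(windows, values) {
  stopifnot(nrow(values) == nrow(windows), !is.null(colnames(values)))
  if (!all(values %in% c(0L, 1L))) stop("label values must be 0/1")
  structure(list(windows = windows,
                 families = colnames(values),
                 values = values,
                 supports = colSums(values)),
            class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("label_matrix:", nrow(x$values), "windows x", length(x$families),
      "families; positives per family:\n")
  print(x$supports)
  invisible(x)
}

#' One-hot encode a nucleotide sequence
#'
#' @param sequence String over `{A,C,G,T,N}`.
#' @return 4 x L matrix with rows `A`, `C`, `G`, `T`; `N` gives an all-zero
#'   column.
#' @export
one_hot <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(idx) & chars != "N"))
    stop("sequence contains characters outside {A,C,G,T,N}")
  m <- matrix(0, nrow = 4, ncol = length(chars),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  ok <- !is.na(idx)
  m[cbind(idx[ok], which(ok))] <- 1
  m
}

# Internal: encode a character vector of equal-length sequences into the
# (L*B) x 4 layout consumed by the network (row index l + (b-1)*L).
encode_batch <- function(seqs) {
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("sequences must all have the same length")
  B <- length(seqs)
  chars <- unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE)
  idx <- match(chars, c("A", "C", "G", "T"))
  X <- matrix(0, nrow = L * B, ncol = 4)
  ok <- !is.na(idx)
  X[cbind(which(ok), idx[ok])] <- 1
  attr(X, "L") <- L
  attr(X, "B") <- B
  X
}

#' Chromosome-held-out cross-validation splits
#'
#' One split per chromosome: that chromosome is the validation set, the rest
#' are the training set. With five chromosomes this is the 5-fold
#' chromosome-level cross-validation protocol.
#'
#' @param genome A `genome_sequence`.
#' @return List of splits, each a list with `train_chroms`, `val_chrom`,
#'   `fold_index`.
#' @export
chromosome_splits <- function(genome) {
  chroms <- genome$chrom_names
  if (length(chroms) < 2L)
    stop("need >= 2 chromosomes for chromosome-held-out splits; ",
         "use a synthetic multi-chromosome fixture for testing")
  lapply(seq_along(chroms), function(i) {
    list(train_chroms = chroms[-i], val_chrom = chroms[i], fold_index = i)
  })
}

#' Shuffle sequences preserving mono- or dinucleotide composition
#'
#' Order 1 permutes the bases of each sequence (exact mononucleotide counts
#' preserved). Order 2 performs an Euler-path dinucleotide shuffle: the
#' shuffled sequence starts and ends on the same bases and has exactly the
#' same dinucleotide counts as the input. Both are deterministic given
#' `seed`. These shuffles provide the s-/d-baseline training sequences; the
#' label matrix is never altered by shuffling.
#'
#' @param sequences Character vector of sequences over `{A,C,G,T,N}`.
#' @param order 1 (mononucleotide) or 2 (dinucleotide-preserving).
#' @param seed Integer seed.
#' @return Character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(sequences, order = 1L, seed = 1L) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  with_seed(seed, {
    vapply(sequences, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      if (order == 1L) {
        paste(chars[sample.int(length(chars))], collapse = "")
      } else {
        dinucleotide_shuffle(chars)
      }
    }, character(1), USE.NAMES = FALSE)
  })
}

# Altschul-Erickson Euler-path dinucleotide shuffle on a character vector.
# Vertices are the distinct bases; edges are consecutive pairs. A random
# "last edge" is chosen for every vertex except the final base; if those last
# edges form a tree pointing to the final vertex, the remaining edges are
# permuted and the Euler path is walked. Retries until a valid tree is drawn.
dinucleotide_shuffle <- function(chars) {
  n <- length(chars)
  if (n <= 2L) return(paste(chars, collapse = ""))
  verts <- unique(chars)
  if (length(verts) == 1L) return(paste(chars, collapse = ""))
  vi <- match(chars, verts)
  from <- vi[-n]
  to <- vi[-1]
  last <- vi[n]
  edges <- split(to, from)           # adjacency (edge multiset) per vertex
  nonfinal <- setdiff(seq_along(verts), last)
  repeat {
    last_edge <- vapply(seq_along(verts), function(v) {
      e <- edges[[as.character(v)]]
      if (is.null(e) || v == last) return(NA_integer_)
      e[sample.int(length(e), 1L)]
    }, integer(1))
    # check the chosen last edges form a tree with all paths reaching `last`
    ok <- TRUE
    for (v in nonfinal) {
      cur <- v
      steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[cur]
        steps <- steps + 1L
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # permute non-last edges, append the chosen last edge per vertex
  adj <- lapply(seq_along(verts), function(v) {
    e <- edges[[as.character(v)]]
    if (is.null(e)) return(integer(0))
    if (!is.na(last_edge[v])) {
      drop <- match(last_edge[v], e)
      e <- e[-drop]
    }
    e <- if (length(e) > 1L) e[sample.int(length(e))] else e
    c(e, if (!is.na(last_edge[v])) last_edge[v])
  })
  ptr <- rep(1L, length(verts))
  out <- integer(n)
  out[1] <- vi[1]
  cur <- vi[1]
  for (i in 2:n) {
    nxt <- adj[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(verts[out], collapse = "")
}

# Internal: run code with a temporary RNG state so package functions do not
# disturb the caller's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Write a label matrix to TSV
#'
#' Tab-separated export with window coordinates and one 0/1 column per
#' family (header row of family names).
#'
#' @param labels A `label_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_matrix <- function(labels, path) {
  df <- cbind(labels$windows[, c("chrom", "start", "end")],
              as.data.frame(labels$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
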