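#' Read a genome from a FASTA file
#'
#' Reads every record of a FASTA file into an in-memory genome object.
#' Sequences are uppercased and any character outside the `{A,C,G,T,N}`
#' alphabet (IUPAC ambiguity codes, gaps, ...) is replaced by `N`, so that
#' downstream one-hot encoding is well defined. Record order in the file is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_sequence`: a list with `chrom_names`,
#'   `seqs` (named character vector of nucleotide strings) and `lengths`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  # first token of the header line is the chromosome name
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(seqs, sanitize_sequence, character(1))
  genome_sequence(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of nucleotide strings.
#' @return A `genome_sequence` object.
#' @export
genome_sequence <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  seqs <- vapply(seqs, sanitize_sequence, character(1))
  structure(
    list(chrom_names = names(seqs), seqs = seqs, lengths = nchar(seqs)),
    class = "genome_sequence"
  )
}

sanitize_sequence <- function(s) {
  s <- toupper(s)
  chartr_bad <- gsub("[ACGTN]", "", s)
  if (nzchar(chartr_bad)) {
    for (ch in unique(strsplit(chartr_bad, "")[[1]])) {
      s <- gsub(ch, "N", s, fixed = TRUE)
    }
  }
  s
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Write a genome object to FASTA
#'
#' @param genome A `genome_sequence`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in genome$chrom_names) {
    writeLines(paste0(">", chrom), con)
    s <- genome$seqs[[chrom]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a peak file (BED3+ or narrowPeak)
#'
#' Intervals are interpreted as 0-based half-open (BED convention); columns
#' beyond the first three are ignored. Records with `start >= end` are
#' rejected with a warning reporting how many were dropped. Output is sorted
#' by (chrom, start).
#'
#' @param path Path to a BED3+/narrowPeak file.
#' @param family Family label to attach to the peak set.
#' @return An object of class `peak_set`: list with `family`, `peaks`
#'   (data.frame `chrom`, `start`, `end`) and `source`.
#' @export
read_peak_bed <- function(path, family) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (!nzchar(family)) stop("family label must be non-empty")
  df <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("peak file has fewer than 3 tab-separated columns: ",
                         path)
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-integer coordinates in peak file: ", path)
  peak_set(df, family = family, source = path)
}

#' Construct a peak set from an interval data frame
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param family Family label.
#' @param source Free-text provenance string.
#' @return A `peak_set` object, sorted by (chrom, start).
#' @export
peak_set <- function(peaks, family, source = "") {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (!nzchar(family)) stop("family label must be non-empty")
  bad <- peaks$start >= peaks$end
  if (any(bad)) {
    warning(sum(bad), " record(s) with start >= end rejected for family ",
            family)
    peaks <- peaks[!bad, , drop = FALSE]
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(family = family,
                 peaks = peaks[, c("chrom", "start", "end")],
                 source = source),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set '", x$family, "': ", nrow(x$peaks), " peak(s)\n", sep = "")
  invisible(x)
}

#' Write intervals to a BED file
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally further
#'   BED columns (name, score, strand).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Extracts `gene`-typed records and converts them to 0-based half-open
#' coordinates. The gene identifier is taken from the `ID=` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) == 9L
  if (!all(ok)) stop("malformed GFF3 record at line(s): ",
                     paste(utils::head(which(!ok), 5), collapse = ", "))
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  id <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  data.frame(gene_id = id,
             chrom = m[, 1],
             start = as.integer(m[, 4]) - 1L,  # GFF3 is 1-based inclusive
             end = as.integer(m[, 5]),
             strand = m[, 7],
             stringsAsFactors = FALSE)
}

# Internal: intervals data.frame -> GRanges (keeps 0-based half-open inputs,
# shifts to 1-based for IRanges arithmetic).
as_granges0 <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand
  )
}

#' Extract a sequence for a 0-based half-open interval
#'
#' @param genome A `genome_sequence`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @return Nucleotide string.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  len <- genome$lengths[[chrom]]
  if (any(start < 0) || any(end > len) || any(start >= end))
    stop("interval out of bounds for ", chrom)
  substring(genome$seqs[[chrom]], start + 1L, end)
}

#' Reverse-complement nucleotide strings
#'
#' @param s Character vector of sequences over `{A,C,G,T,N}`.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(comp, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}
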