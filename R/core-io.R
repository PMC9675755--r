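# Readers and writers for the standard formats the pipeline touches:
# FASTA genomes, BED intervals, TSV tables and JASPAR position matrices.
# All genomic coordinates are 0-based half-open (BED convention) throughout
# the package; 1-based inputs must be converted at the boundary.

#' Construct a genome object
#'
#' A genome is a named set of uppercase DNA sequences over `{A,C,G,T,N}`
#' together with their lengths.
#'
#' @param sequences named character vector of DNA sequences.
#' @return an object of class `genome` with elements `seq` (named character
#'   vector, uppercased) and `lengths` (named integer vector).
#' @export
genome <- function(sequences) {
  if (length(sequences) == 0L) stop_format("genome has no sequences")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop_format("all sequences must be named")
  if (anyDuplicated(nm)) stop_format("duplicate sequence names: ",
                                     paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(sequences)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop_format("non-IUPAC (non-ACGTN) characters in: ",
                            paste(nm[bad], collapse = ", "))
  structure(list(seq = seqs, lengths = vapply(seqs, nchar, 1L)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d sequence(s), %s bp total\n",
              length(x$seq), format(sum(as.numeric(x$lengths)), big.mark = ",")))
  invisible(x)
}

genome_length <- function(g) sum(as.numeric(g$lengths))

# Extract genome subsequence on [start, end), 0-based half-open, clipped.
genome_subseq <- function(g, chrom, start, end) {
  if (!chrom %in% names(g$seq)) stop_arg("unknown chromosome: ", chrom)
  L <- g$lengths[[chrom]]
  s <- max(0L, as.integer(start))
  e <- min(L, as.integer(end))
  if (e <= s) return("")
  substr(g$seq[[chrom]], s + 1L, e)
}

#' Read a genome from a FASTA file
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return a [genome] object; sequences are uppercased and unwrapped.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_format("FASTA parse error: ", conditionMessage(e)))
  if (length(ss) == 0L) stop_format("empty FASTA file: ", path)
  # FASTA headers: identifier is the first whitespace-delimited token
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop_format("duplicate FASTA headers in ", path)
  seqs <- as.character(ss)
  names(seqs) <- nm
  genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param g a [genome].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(g$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Validate a 0-based half-open interval table
#'
#' @param x data.frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @param genome optional [genome]; if given, intervals must fit chromosomes.
#' @return `x`, invisibly, or an error.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) stop_format("interval table needs columns chrom/start/end")
  if (nrow(x)) {
    if (any(!nzchar(x$chrom))) stop_format("empty chromosome name")
    if (any(x$start < 0)) stop_format("negative start coordinate")
    if (any(x$end <= x$start)) stop_format("interval with end <= start")
    if (!is.null(genome)) {
      if (!all(x$chrom %in% names(genome$seq)))
        stop_format("interval chromosome absent from genome")
      if (any(x$end > genome$lengths[x$chrom]))
        stop_format("interval extends past chromosome end")
    }
  }
  invisible(x)
}

sort_intervals <- function(x) x[order(x$chrom, x$start, x$end), , drop = FALSE]

#' Read intervals from a BED3+ file
#'
#' @param path BED file path (tab-separated, no header).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`; coordinates are 0-based half-open.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      colClasses = "character", quote = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop_format("BED parse error: ", conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0L) return(empty_intervals())
  if (ncol(raw) < 3L) stop_format("BED needs >= 3 tab-separated columns")
  out <- data.frame(chrom = raw[[1L]],
                    start = suppressWarnings(as.integer(raw[[2L]])),
                    end = suppressWarnings(as.integer(raw[[3L]])),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) stop_format("non-integer BED coordinate")
  if (ncol(raw) >= 4L) out$name <- raw[[4L]]
  if (ncol(raw) >= 5L) out$score <- suppressWarnings(as.numeric(raw[[5L]]))
  if (ncol(raw) >= 6L) {
    if (!all(raw[[6L]] %in% c("+", "-", "."))) stop_format("invalid strand field")
    out$strand <- raw[[6L]]
  }
  validate_intervals(out)
  out
}

#' Write intervals to BED
#'
#' Output is sorted by (chrom, start); `read_bed(write_bed(x))` is the
#' identity on valid sorted interval tables.
#'
#' @param x interval data.frame (see [validate_intervals]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- sort_intervals(x)
  cols <- c("chrom", "start", "end")
  for (opt in c("name", "score", "strand")) {
    if (opt %in% names(x)) cols <- c(cols, opt) else break
  }
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV table with a header row
#'
#' @param path TSV path.
#' @return data.frame; numeric columns are typed.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop_format("empty table file: ", path)
  out <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE, fill = FALSE),
    error = function(e) stop_format("TSV parse error: ", conditionMessage(e)))
  out
}

#' Write a TSV table with a header row
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
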