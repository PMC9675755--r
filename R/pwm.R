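# Position weight matrices: construction, JASPAR input, log-odds transform.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Columns of `counts` are normalized to probabilities after adding
#' `pseudocount * columnSum * background[b]` to each cell, so a pseudocount
#' of 0.125 adds 12.5% of the column total, split by the background, before
#' normalization. This guarantees finite log-odds for any observed counts.
#'
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param name motif identifier.
#' @param background length-4 base composition (default uniform).
#' @param pseudocount fraction of the column total added as pseudo-counts.
#' @return an object of class `pwm` with elements `name`, `probs` (4 x L,
#'   each column summing to 1), `background`, `pseudocount`.
#' @export
pwm <- function(counts, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.125) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_format("PWM needs exactly 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop_format("negative PWM count")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop_arg("background must be 4 positive values summing to 1")
  if (!is_count1(pseudocount)) stop_arg("pseudocount must be a single value >= 0")
  tot <- colSums(counts)
  if (any(tot <= 0) && pseudocount == 0)
    stop_format("all-zero PWM column with zero pseudocount")
  # all-zero columns with a pseudocount fall back to the background
  tot[tot <= 0] <- 1
  probs <- sweep(counts, 2, tot, "/")
  probs <- probs + pseudocount * background
  probs <- sweep(probs, 2, colSums(probs), "/")
  dimnames(probs) <- list(DNA_BASES, NULL)
  names(background) <- DNA_BASES
  structure(list(name = name, probs = probs, background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, consensus %s\n",
              x$name, ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

pwm_width <- function(p) ncol(p$probs)

#' Consensus sequence of a PWM (highest-probability base per column,
#' ties broken in A<C<G<T order).
#' @param p a [pwm].
#' @return a character string of length `ncol(p$probs)`.
#' @export
pwm_consensus <- function(p) {
  paste0(DNA_BASES[apply(p$probs, 2, which.max)], collapse = "")
}

#' Read a JASPAR-format position matrix
#'
#' Accepts the JASPAR 2016+ text format: a `>` header line followed by four
#' labeled rows, e.g. `A [ 4 19 0 ... ]`. Bare 4-row count matrices without
#' brackets are accepted too.
#'
#' @param path file path.
#' @param pseudocount passed to [pwm()].
#' @param background passed to [pwm()].
#' @return a [pwm] built from the counts.
#' @export
read_jaspar_pwm <- function(path, pseudocount = 0.125,
                            background = rep(0.25, 4)) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format("empty PWM file: ", path)
  name <- "motif"
  if (startsWith(lines[[1L]], ">")) {
    name <- trimws(sub("^>", "", lines[[1L]]))
    if (!nzchar(name)) name <- "motif"
    name <- strsplit(name, "\\s+")[[1L]][1L]
    lines <- lines[-1L]
  }
  if (length(lines) != 4L)
    stop_format("JASPAR matrix must have exactly 4 data rows, found ", length(lines))
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("[\\[\\]]", "", l, perl = TRUE)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(vals)) stop_format("non-numeric PWM entry in ", path)
    vals
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) stop_format("unequal PWM row lengths in ", path)
  counts <- do.call(rbind, rows)
  pwm(counts, name = name, background = background, pseudocount = pseudocount)
}

#' Write a PWM's probabilities in JASPAR-like text format
#'
#' @param p a [pwm]; probabilities are written scaled by `scale`.
#' @param path output path.
#' @param scale multiplier turning probabilities into pseudo-counts.
#' @return `path`, invisibly.
#' @export
write_jaspar_pwm <- function(p, path, scale = 100) {
  vals <- round(p$probs * scale, 4)
  lines <- c(paste0(">", p$name),
             vapply(seq_len(4L), function(i) {
               sprintf("%s  [ %s ]", DNA_BASES[i],
                       paste(format(vals[i, ], trim = TRUE), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Log-odds matrix of a PWM
#'
#' Entry `(b, i)` is `ln(probs[b, i] / background[b])`. Natural log is used
#' throughout (HOMER's motif-score convention), so score thresholds such as
#' -2 and binned scores 7-12+ are on that scale, not log2.
#'
#' @param p a [pwm].
#' @return 4 x L numeric matrix, rows A, C, G, T.
#' @export
pwm_logodds <- function(p) {
  if (any(p$probs == 0))
    stop_arg("PWM contains zero probabilities; use a positive pseudocount")
  log(sweep(p$probs, 1, p$background, "/"))
}
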