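# PWM log-odds scanning around peak centers and DR1 segment dissection.
# Segment coordinates (1-based in the motif model): 5' extension = bases
# 1-4, PPARg half-site = bases 5-10, spacer = base 11, RXR half-site =
# bases 12-17; scores are natural-log odds, so the per-segment scores plus
# the spacer add up exactly to the full hit score.

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                   collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# per-position log-odds of `seq` aligned at each offset; NA where the
# placement covers an N. Returns numeric vector of scores per 0-based offset.
scan_scores <- function(seq_int, lo) {
  L <- ncol(lo)
  n <- length(seq_int)
  if (n < L) return(numeric())
  n_off <- n - L + 1L
  sc <- numeric(n_off)
  for (i in seq_len(L)) {
    b <- seq_int[i:(i + n_off - 1L)]
    v <- rep(NA_real_, n_off)
    ok <- !is.na(b)
    v[ok] <- lo[cbind(b[ok], i)]
    sc <- sc + v
  }
  sc
}

seq_to_int <- function(s) {
  m <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]],
             DNA_BASES)
  m
}

#' Best PWM hit in a sequence window
#'
#' Scores every placement of the motif on both strands (the minus strand is
#' scanned on the reverse complement) and returns the maximal-score hit.
#' Ties are broken by lower offset on the plus-strand window, then plus
#' strand. Placements covering `N` are skipped. Returns `NULL` iff the
#' window is shorter than the motif.
#'
#' @param window character DNA sequence (typically peak center +/- `flank`).
#' @param p a [pwm].
#' @return `NULL`, or a list with `offset` (0-based start of the occupied
#'   bases in `window`), `strand`, `score`, and `match` — the occupied
#'   subsequence oriented to the plus strand of the motif model.
#' @export
scan_best <- function(window, p) {
  stopifnot(is.character(window), length(window) == 1L, inherits(p, "pwm"))
  lo <- pwm_logodds(p)
  L <- ncol(lo)
  window <- toupper(window)
  n <- nchar(window)
  if (n < L) return(NULL)
  fwd <- scan_scores(seq_to_int(window), lo)
  rcw <- revcomp(window)
  rev_sc <- scan_scores(seq_to_int(rcw), lo)
  # offset of a minus-strand placement in plus-strand window coordinates
  rev_offsets <- n - L - (seq_along(rev_sc) - 1L)
  cand <- data.frame(offset = c(seq_along(fwd) - 1L, rev_offsets),
                     strand = rep(c("+", "-"), c(length(fwd), length(rev_sc))),
                     score = c(fwd, rev_sc), stringsAsFactors = FALSE)
  cand <- cand[!is.na(cand$score), , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  # scores within 1e-12 are ties (strand sums differ only in float
  # rounding); ties break to the lower offset, then the plus strand
  top <- cand[cand$score >= max(cand$score) - 1e-12, , drop = FALSE]
  o <- order(top$offset, top$strand == "-")
  best <- top[o[1L], ]
  match <- substr(window, best$offset + 1L, best$offset + L)
  if (best$strand == "-") match <- revcomp(match)
  list(offset = best$offset, strand = best$strand, score = best$score,
       match = match)
}

#' Dissect a motif hit into DR1 segments
#'
#' Computes per-segment log-odds sums over the motif model's plus-strand
#' coordinates: 5' extension (bases 1-4), PPARg half-site (bases 5-10),
#' spacer (base 11) and RXR half-site (bases 12-17). For motifs shorter
#' than 17 columns the segments are clipped, with a warning. The hit is
#' `called` iff the full score is at or above `call_threshold` (inclusive).
#'
#' @param hit result of [scan_best()].
#' @param p the [pwm] used for scanning.
#' @param call_threshold motif-calling threshold on the full score
#'   (natural-log odds); default -2.
#' @return list with `ext5`, `ppar_hs`, `spacer`, `rxr_hs`, `score`,
#'   `called`. `ext5 + ppar_hs + spacer + rxr_hs == score` when no segment
#'   is clipped.
#' @export
segment_scores <- function(hit, p, call_threshold = -2) {
  if (is.null(hit)) stop_arg("no motif hit to dissect")
  lo <- pwm_logodds(p)
  L <- ncol(lo)
  if (L < 17L) warning("PWM has ", L, " < 17 columns; segments clipped")
  b <- seq_to_int(hit$match)
  per_pos <- lo[cbind(b, seq_len(L))]
  seg <- function(from, to) {
    idx <- seq(from, min(to, L))
    if (from > L) 0 else sum(per_pos[idx])
  }
  list(ext5 = seg(1L, 4L), ppar_hs = seg(5L, 10L), spacer = seg(11L, 11L),
       rxr_hs = seg(12L, 17L), score = hit$score,
       called = hit$score >= call_threshold)
}

#' Scan peaks for the best response-element hit
#'
#' Extracts `center +/- flank` from the genome for each peak, finds the
#' best PWM placement on either strand and dissects it into DR1 segments.
#'
#' @param peaks finalized peak data.frame (with `chrom`, `center`, `id`).
#' @param g a [genome].
#' @param p a [pwm].
#' @param flank half-width of the scanned window (bp); default 100, i.e. a
#'   200-bp region around the peak center.
#' @param call_threshold passed to [segment_scores()].
#' @return data.frame, one row per peak: `id`, `offset` (0-based within
#'   the window), `genomic_start`, `strand`, `score`, `ext5`, `ppar_hs`,
#'   `spacer`, `rxr_hs`, `called`. Peaks with no scannable placement get NA
#'   scores and `called = FALSE`.
#' @export
scan_peaks_motif <- function(peaks, g, p, flank = 100L, call_threshold = -2) {
  stopifnot(is.data.frame(peaks), inherits(g, "genome"), inherits(p, "pwm"))
  n <- nrow(peaks)
  out <- data.frame(id = if (n) peaks$id else character(),
                    offset = rep(NA_integer_, n),
                    genomic_start = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    score = rep(NA_real_, n), ext5 = rep(NA_real_, n),
                    ppar_hs = rep(NA_real_, n), spacer = rep(NA_real_, n),
                    rxr_hs = rep(NA_real_, n), called = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    lo0 <- max(0L, peaks$center[i] - flank)
    win <- genome_subseq(g, peaks$chrom[i], lo0, peaks$center[i] + flank)
    hit <- scan_best(win, p)
    if (is.null(hit)) next
    ss <- segment_scores(hit, p, call_threshold)
    out$offset[i] <- hit$offset
    out$genomic_start[i] <- lo0 + hit$offset
    out$strand[i] <- hit$strand
    out$score[i] <- hit$score
    out$ext5[i] <- ss$ext5
    out$ppar_hs[i] <- ss$ppar_hs
    out$spacer[i] <- ss$spacer
    out$rxr_hs[i] <- ss$rxr_hs
    out$called[i] <- ss$called
  }
  out
}
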