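# HOMER-style peak calling with a local Poisson background.
#
# Candidate peaks are fixed-width windows; selection is greedy over window
# tag counts at 1-bp resolution (highest count first, leftmost on ties,
# overlapping windows discarded), which is exactly equivalent to exhaustive
# enumeration of every window position. Each selected window is then tested
# against (i) its local background (tags within +/- local_size/2 of the
# center, the window itself excluded) and (ii) a library-size-scaled control
# track. Strand is ignored: tags are collapsed to 5' positions.

# counts of sorted positions in [a, b) (vectors a, b allowed)
count_in <- function(pos, a, b) {
  findInterval(b - 1L, pos) - findInterval(a - 1L, pos)
}

# window counts w[s] for s = 0 .. L - width (returned 1-indexed)
window_counts <- function(pos, L, width) {
  if (L < width) return(numeric())
  cnt <- tabulate(pos + 1L, nbins = L)
  cs <- c(0, cumsum(cnt))
  cs[(width + 1L):(L + 1L)] - cs[1L:(L - width + 1L)]
}

#' Call peaks against local background and a control track
#'
#' Implements transcription-factor-style peak calling: greedy selection of
#' non-overlapping `peak_width` windows in decreasing tag order, Poisson
#' enrichment over the local background, and fold enrichment over a
#' depth-normalized control. A peak is retained iff
#' `fold_local >= fold_min`, `p_local < p_max` and `fold_control >= fold_min`.
#'
#' The expected local count is
#' `local tags (window excluded) * peak_width / (local_size - peak_width)`,
#' floored at the genome-wide expectation `peak_width * N / genome_length`
#' to avoid degenerate empty neighborhoods; the same floored expectation is
#' the Poisson rate for the p-value, computed as the exact upper tail
#' `P(X >= tags)`.
#'
#' @param target pooled [tag_track] to call peaks on.
#' @param control [tag_track] of the reference condition.
#' @param local_size span (bp) of the local background window; default 20000.
#' @param fold_min minimum fold enrichment over local background and control;
#'   default 4.
#' @param p_max maximum local Poisson p-value; default 1e-4.
#' @param peak_width candidate window width (bp); default 500.
#' @return data.frame of retained peaks, sorted by (chrom, start), with
#'   columns `chrom`, `start`, `end`, `center`, `tags`, `fold_local`,
#'   `p_local`, `fold_control`, `p_control`; `seqlengths` kept as an
#'   attribute. Pre-finalization peaks are pairwise non-overlapping.
#' @export
call_peaks <- function(target, control, local_size = 20000L, fold_min = 4,
                       p_max = 1e-4, peak_width = 500L) {
  stopifnot(inherits(target, "tag_track"), inherits(control, "tag_track"))
  if (local_size <= peak_width) stop_arg("local_size must exceed peak_width")
  if (fold_min <= 0 || p_max <= 0 || peak_width < 1)
    stop_arg("params must be positive")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      center = integer(), tags = integer(),
                      fold_local = numeric(), p_local = numeric(),
                      fold_control = numeric(), p_control = numeric(),
                      stringsAsFactors = FALSE)
  attr(empty, "seqlengths") <- target$seqlengths
  if (target$n == 0L) {
    warning("empty target track: no peaks called")
    return(empty)
  }
  if (control$n == 0L) stop_arg("control track is empty")
  glen <- sum(as.numeric(target$seqlengths))
  floor_exp <- peak_width * target$n / glen
  scale <- target$n / control$n
  half_local <- local_size / 2
  res <- list()
  for (ch in names(target$seqlengths)) {
    pos <- track_positions(target, ch)
    if (length(pos) == 0L) next
    L <- target$seqlengths[[ch]]
    w <- window_counts(pos, L, peak_width)
    starts <- greedy_select_windows(w, as.integer(peak_width))
    if (length(starts) == 0L) next
    tags <- w[starts + 1L]
    center <- starts + peak_width %/% 2L
    lo <- pmax(0, center - half_local)
    hi <- pmin(L, center + half_local)
    local_all <- count_in(pos, lo, hi)
    local_excl <- local_all - tags
    expected_local <- pmax(local_excl * peak_width / (local_size - peak_width),
                           floor_exp)
    fold_local <- tags / expected_local
    p_local <- stats::ppois(tags - 1L, expected_local, lower.tail = FALSE)
    cpos <- track_positions(control, ch)
    ctrl_tags <- count_in(cpos, starts, starts + peak_width)
    expected_ctrl <- pmax(ctrl_tags * scale, floor_exp)
    fold_control <- tags / expected_ctrl
    p_control <- stats::ppois(tags - 1L, expected_ctrl, lower.tail = FALSE)
    keep <- fold_local >= fold_min & p_local < p_max & fold_control >= fold_min
    if (!any(keep)) next
    res[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = starts[keep] + as.integer(peak_width),
                            center = center[keep], tags = as.integer(tags[keep]),
                            fold_local = fold_local[keep],
                            p_local = p_local[keep],
                            fold_control = fold_control[keep],
                            p_control = p_control[keep],
                            stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else empty
  rownames(out) <- NULL
  out <- sort_intervals(out)
  attr(out, "seqlengths") <- target$seqlengths
  out
}

# rows of x overlapping any interval in `other` by >= 1 bp
overlaps_any <- function(x, other) {
  if (nrow(x) == 0L || is.null(other) || nrow(other) == 0L)
    return(rep(FALSE, nrow(x)))
  hit <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(other))) {
    hit <- hit | (x$chrom == other$chrom[i] &
                    x$start < other$end[i] & x$end > other$start[i])
  }
  hit
}

#' Finalize called peaks: recenter, blacklist, tag floor
#'
#' Each peak becomes `[center - width/2, center + width/2)` clipped to its
#' chromosome (clipped peaks are logged); peaks overlapping a blacklist
#' interval by >= 1 bp are removed, then peaks with fewer than `min_tags`
#' tags are removed.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param width finalized width (bp); default 500.
#' @param blacklist interval data.frame of artifact regions, or `NULL`.
#' @param min_tags minimum tag count to retain a peak; default 35.
#' @param seqlengths named chromosome lengths; defaults to the attribute
#'   stored by [call_peaks()].
#' @return finalized, sorted peak data.frame with an added `id` column.
#' @export
finalize_peaks <- function(peaks, width = 500L, blacklist = NULL,
                           min_tags = 35L,
                           seqlengths = attr(peaks, "seqlengths")) {
  stopifnot(is.data.frame(peaks), "center" %in% names(peaks))
  if (is.null(seqlengths)) stop_arg("seqlengths required to clip peaks")
  if (nrow(peaks)) {
    half <- width %/% 2L
    start <- peaks$center - half
    end <- peaks$center + (width - half)
    clipped <- start < 0 | end > seqlengths[peaks$chrom]
    if (any(clipped))
      log_msg("info", sum(clipped), " peak(s) clipped at chromosome ends")
    peaks$start <- pmax(0L, start)
    peaks$end <- as.integer(pmin(seqlengths[peaks$chrom], end))
    if (!is.null(blacklist)) {
      validate_intervals(blacklist)
      peaks <- peaks[!overlaps_any(peaks, blacklist), , drop = FALSE]
    }
    peaks <- peaks[peaks$tags >= min_tags, , drop = FALSE]
  }
  peaks <- sort_intervals(peaks)
  rownames(peaks) <- NULL
  if (nrow(peaks))
    peaks$id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  else peaks$id <- character()
  attr(peaks, "seqlengths") <- seqlengths
  peaks
}
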