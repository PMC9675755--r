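# Closed-form biophysics utilities: helix content from far-UV CD and
# Calpha secondary chemical shifts with transient-helix calling.

#' Helix content from a far-UV CD spectrum
#'
#' Uses the linear single-wavelength estimate
#' `%H = ([theta]222 - 3000) / (-36000 - 3000) * 100`, where `[theta]222`
#' is the mean residue ellipticity at 222 nm (deg cm^2 dmol^-1). If 222 nm
#' was not measured but is bracketed, `[theta]222` is linearly
#' interpolated. The raw value is reported alongside a `[0, 100]`-clipped
#' one, since the formula can leave that range for extreme spectra.
#'
#' @param spectrum data.frame with columns `wavelength` (nm, strictly
#'   increasing) and `ellipticity`.
#' @return list with `theta222`, `percent_helix` (clipped) and
#'   `percent_helix_raw`.
#' @export
helicity_from_cd <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength", "ellipticity") %in% names(spectrum)))
  w <- spectrum$wavelength
  if (is.unsorted(w, strictly = TRUE))
    stop_arg("wavelengths must be strictly increasing")
  if (222 < min(w) || 222 > max(w))
    stop_arg("222 nm outside the measured range [", min(w), ", ", max(w), "]")
  theta222 <- stats::approx(w, spectrum$ellipticity, xout = 222)$y
  raw <- (theta222 - 3000) / (-36000 - 3000) * 100
  list(theta222 = theta222,
       percent_helix = min(100, max(0, raw)),
       percent_helix_raw = raw)
}

#' Calpha secondary chemical shifts
#'
#' `SCS_i = observed_i - random_coil_i` per residue. Residues without a
#' random-coil reference are excluded (logged).
#'
#' @param shifts data.frame with columns `residue` (contiguous integer
#'   index), `aa`, `observed`, `random_coil` (ppm).
#' @return data.frame `residue`, `aa`, `scs`, ordered by residue.
#' @export
secondary_shifts <- function(shifts) {
  stopifnot(is.data.frame(shifts),
            all(c("residue", "observed", "random_coil") %in% names(shifts)))
  miss <- is.na(shifts$random_coil) | is.na(shifts$observed)
  if (any(miss))
    log_msg("info", sum(miss), " residue(s) without reference excluded")
  x <- shifts[!miss, , drop = FALSE]
  x <- x[order(x$residue), , drop = FALSE]
  data.frame(residue = x$residue,
             aa = if (is.null(x$aa)) NA_character_ else x$aa,
             scs = x$observed - x$random_coil,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call transient helices from secondary chemical shifts
#'
#' A transient helix is any maximal run of at least `min_run` consecutive
#' residues with positive Calpha SCS (consecutive in residue numbering).
#'
#' @param scs data.frame from [secondary_shifts()].
#' @param min_run minimum run length; default 4.
#' @return data.frame `from`, `to`, `length` (residue indices), possibly
#'   empty.
#' @export
call_transient_helix <- function(scs, min_run = 4L) {
  stopifnot(is.data.frame(scs), all(c("residue", "scs") %in% names(scs)))
  empty <- data.frame(from = integer(), to = integer(), length = integer())
  if (nrow(scs) == 0L) return(empty)
  o <- order(scs$residue)
  res <- scs$residue[o]
  pos <- scs$scs[o] > 0
  # break runs at gaps in residue numbering
  grp <- cumsum(c(TRUE, diff(res) != 1L | diff(pos) != 0))
  runs <- lapply(split(seq_along(res), grp), function(ix) {
    if (pos[ix[1L]] && length(ix) >= min_run)
      data.frame(from = res[ix[1L]], to = res[ix[length(ix)]],
                 length = length(ix))
  })
  runs <- runs[!vapply(runs, is.null, TRUE)]
  if (length(runs) == 0L) return(empty)
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}
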