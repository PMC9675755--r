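# Tag tracks: deduplicated per-position read starts (HOMER tag-directory
# semantics), the unit of all window counting in the pipeline.

#' Construct a tag track
#'
#' @param positions data.frame with columns `chrom`, `pos` (0-based) and
#'   optionally `strand` (defaults to `"+"`).
#' @param seqlengths named integer vector of chromosome lengths.
#' @param assay,condition,replicate sample label.
#' @return an object of class `tag_track`: per-chromosome position/strand
#'   arrays sorted by position, a total tag count `n`, the sample label and
#'   `seqlengths`.
#' @export
tag_track <- function(positions, seqlengths, assay = NA_character_,
                      condition = NA_character_, replicate = NA_integer_) {
  stopifnot(is.data.frame(positions), all(c("chrom", "pos") %in% names(positions)))
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stop_arg("seqlengths must be named")
  if (is.null(positions$strand)) positions$strand <- "+"
  if (nrow(positions)) {
    if (!all(positions$chrom %in% names(seqlengths)))
      stop_arg("tag on chromosome absent from seqlengths")
    if (any(positions$pos < 0) ||
        any(positions$pos >= seqlengths[positions$chrom]))
      stop_arg("tag position outside chromosome bounds")
  }
  tags <- lapply(split(positions[c("pos", "strand")], positions$chrom),
                 function(d) {
                   o <- order(d$pos, d$strand)
                   list(pos = as.integer(d$pos[o]), strand = d$strand[o])
                 })
  structure(list(tags = tags,
                 n = nrow(positions),
                 label = list(assay = assay, condition = condition,
                              replicate = replicate),
                 seqlengths = seqlengths),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("tag_track [%s/%s/rep%s]: %s tags on %d chromosome(s)\n",
              x$label$assay, x$label$condition, x$label$replicate,
              format(x$n, big.mark = ","), length(x$tags)))
  invisible(x)
}

track_positions <- function(track, chrom) {
  t <- track$tags[[chrom]]
  if (is.null(t)) integer() else t$pos
}

# Flatten a track back to a positions data.frame.
track_df <- function(track) {
  if (length(track$tags) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(names(track$tags), function(ch) {
    t <- track$tags[[ch]]
    data.frame(chrom = ch, pos = t$pos, strand = t$strand,
               stringsAsFactors = FALSE)
  }))
}

#' Enforce a per-position tag cap (tag-directory construction)
#'
#' Keeps at most `tbp` tags per (chromosome, position, strand), mirroring
#' `makeTagDirectory -tbp`.
#'
#' @param track a [tag_track] (or positions data.frame plus `seqlengths`).
#' @param tbp maximum tags kept per position/strand; default 1.
#' @return a deduplicated [tag_track] with updated total `n`.
#' @export
make_tag_directory <- function(track, tbp = 1L) {
  stopifnot(inherits(track, "tag_track"))
  if (!is_count1(tbp) || tbp < 1) stop_arg("tbp must be >= 1")
  df <- track_df(track)
  n <- nrow(df)
  if (n) {
    o <- order(df$chrom, df$pos, df$strand)
    df <- df[o, , drop = FALSE]
    new_run <- c(TRUE, df$chrom[-1L] != df$chrom[-n] |
                   df$pos[-1L] != df$pos[-n] |
                   df$strand[-1L] != df$strand[-n])
    run_start <- which(new_run)
    within <- seq_len(n) - rep(run_start, diff(c(run_start, n + 1L))) + 1L
    df <- df[within <= tbp, , drop = FALSE]
  }
  tag_track(df, track$seqlengths, track$label$assay, track$label$condition,
            track$label$replicate)
}

#' Down-sample a tag track to a fixed depth
#'
#' Uniform random subset without replacement of exactly `target` tags,
#' deterministic for a fixed seed.
#'
#' @param track a [tag_track].
#' @param target number of tags to keep; must be `<= track$n`.
#' @param seed RNG seed.
#' @return a [tag_track] with `n == target`.
#' @export
downsample_tags <- function(track, target, seed = 1L) {
  stopifnot(inherits(track, "tag_track"))
  if (!is_count1(target)) stop_arg("target must be a single count")
  if (target > track$n) stop_arg("target (", target, ") exceeds track size (",
                                 track$n, ")")
  df <- track_df(track)
  keep <- with_seed(seed, sort(sample.int(nrow(df), target)))
  tag_track(df[keep, , drop = FALSE], track$seqlengths, track$label$assay,
            track$label$condition, track$label$replicate)
}

#' Pool several tag tracks into one
#'
#' @param tracks list of [tag_track]s sharing `seqlengths`.
#' @param assay,condition label of the pooled track.
#' @return a pooled [tag_track].
#' @export
pool_tracks <- function(tracks, assay = NA_character_,
                        condition = NA_character_) {
  stopifnot(length(tracks) >= 1L)
  sl <- tracks[[1L]]$seqlengths
  for (t in tracks) {
    stopifnot(inherits(t, "tag_track"))
    if (!identical(t$seqlengths, sl)) stop_arg("tracks disagree on seqlengths")
  }
  df <- do.call(rbind, lapply(tracks, track_df))
  tag_track(df, sl, assay, condition, NA_integer_)
}

#' Write a tag track as BED (one 1-bp interval per tag)
#' @param track a [tag_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tags_bed <- function(track, path) {
  df <- track_df(track)
  iv <- data.frame(chrom = df$chrom, start = df$pos, end = df$pos + 1L,
                   name = ".", score = 0, strand = df$strand,
                   stringsAsFactors = FALSE)
  write_bed(iv, path)
}

#' Read a tag track from BED
#' @param path BED path (tag = interval start, strand column honored).
#' @param seqlengths named chromosome lengths.
#' @param assay,condition,replicate sample label.
#' @return a [tag_track].
#' @export
read_tags_bed <- function(path, seqlengths, assay = NA_character_,
                          condition = NA_character_, replicate = NA_integer_) {
  iv <- read_bed(path)
  strand <- if ("strand" %in% names(iv)) iv$strand else "+"
  tag_track(data.frame(chrom = iv$chrom, pos = iv$start, strand = strand,
                       stringsAsFactors = FALSE),
            seqlengths, assay, condition, replicate)
}
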