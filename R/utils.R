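# Internal helpers: seeded evaluation, logging, validation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  force(seed)  # before saving state: the seed may itself be a random draw
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable per-stage seed: polynomial hash of the stage name folded into the
# global seed, kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(stage))) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"
.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Set the package log verbosity
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- .log_env$level
  .log_env$level <- level
  invisible(old)
}

log_msg <- function(level, ...) {
  if (.log_levels[[level]] >= .log_levels[[.log_env$level]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("enhancersens_format_error", "error")))
}

stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("enhancersens_argument_error", "error")))
}

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

geomean <- function(x) exp(mean(log(x)))
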