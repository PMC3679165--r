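# Internal helpers: logging, seeded evaluation, numeric formatting.

.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set or query the package log level
#'
#' Messages below the current level are suppressed. Threshold decisions taken
#' by the detection pipeline (early exit, pool threshold, GA restart) are
#' logged at \code{"info"}.
#'
#' @param level One of \code{"debug"}, \code{"info"}, \code{"warn"},
#'   \code{"quiet"}.
#' @return The previous level, invisibly.
#' @export
psLogLevel <- function(level) {
  old <- getOption("propellerscan.loglevel", "warn")
  if (!missing(level)) {
    level <- match.arg(level, names(.LOG_LEVELS))
    options(propellerscan.loglevel = level)
  }
  invisible(old)
}

psLog <- function(level, fmt, ...) {
  cur <- getOption("propellerscan.loglevel", "warn")
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[cur]] && cur != "quiet") {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Full-precision decimal rendering so that files round-trip bit-exactly.
num17 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
}

# 4-decimal rendering for human-facing tables.
num4 <- function(x) formatC(x, format = "f", digits = 4)

`%||%` <- function(a, b) if (is.null(a)) b else a
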