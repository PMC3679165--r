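# Versioned, human-readable key-value serialization of RepeatProfile.
# Numerals are written at full precision so files round-trip bit-exactly.

#' Write / read a repeat profile
#'
#' The profile file is a versioned plain-text format with blocks for the
#' background, per-position frequencies and counts, weights, the four
#' loop-length score tables (with their fit parameters), the tetrad
#' probabilities and the two regulator tables. Reading a written file
#' reproduces the profile bit-exactly (tetrad bonuses are re-derived from
#' the stored probabilities and background).
#'
#' @param profile A [RepeatProfile].
#' @param path File to write or read.
#' @return \code{readRepeatProfile}: the reconstructed [RepeatProfile].
#' @export
writeRepeatProfile <- function(profile, path) {
  ln <- c("# propellerscan repeat profile",
          paste0("format: ", .PROFILE_FORMAT),
          paste0("provenance: ", profile@meta$provenance %||% ""),
          paste0("weight_mode: ", profile@meta$weight_mode %||% "content"),
          paste0("n_repeats: ", profile@nRepeats),
          paste0("regulator_use: ", profile@regulator$use))
  ln <- c(ln, ">background",
          paste(AA20, num17(profile@background[AA20])))
  ln <- c(ln, ">frequencies",
          vapply(scoredPositions(), function(k)
            paste(c(k, num17(profile@frequencies[k, AA20])),
                  collapse = " "), character(1)))
  ln <- c(ln, ">counts",
          vapply(scoredPositions(), function(k)
            paste(c(k, num17(profile@counts[k, AA20])),
                  collapse = " "), character(1)))
  ln <- c(ln, ">weights",
          paste(scoredPositions(), num17(profile@weights[scoredPositions()])))
  for (loop in c("l_da", "l_ab", "l_bc", "l_cd")) {
    fitp <- profile@loopScores[[loop]]
    ln <- c(ln, sprintf(">loop %s t %s t0 %s l0 %d", loop, num17(fitp$t),
                        num17(fitp$t0), as.integer(fitp$l0)),
            paste(fitp$table$l, num17(fitp$table$score)))
  }
  ln <- c(ln, ">tetrad",
          paste("pPentad", num17(profile@tetrad$pPentad)),
          paste("pTetrad", num17(profile@tetrad$pTetrad)),
          paste("pTriad", num17(profile@tetrad$pTriad)))
  for (which in c("initial", "modified")) {
    ln <- c(ln, paste0(">regulator ", which),
            paste(1:40, num17(profile@regulator[[which]])))
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname writeRepeatProfile
#' @export
readRepeatProfile <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  hdr <- function(key) {
    hit <- grep(paste0("^", key, ": "), ln, value = TRUE)
    if (!length(hit)) stop("profile file missing header: ", key)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  fmt <- hdr("format")
  if (!identical(fmt, .PROFILE_FORMAT))
    stop("unsupported profile format version: ", fmt)

  secStarts <- grep("^>", ln)
  secs <- list()
  for (i in seq_along(secStarts)) {
    a <- secStarts[i] + 1L
    b <- if (i < length(secStarts)) secStarts[i + 1L] - 1L else length(ln)
    secs[[sub("^>", "", ln[secStarts[i]])]] <-
      if (b >= a) ln[a:b] else character(0)
  }
  kv <- function(lines) {
    tk <- strsplit(lines, " +")
    setNames(vapply(tk, function(x) as.numeric(x[2]), numeric(1)),
             vapply(tk, `[`, character(1), 1))
  }
  rowBlock <- function(lines) {
    tk <- strsplit(lines, " +")
    m <- t(vapply(tk, function(x) as.numeric(x[-1]), numeric(20)))
    rownames(m) <- vapply(tk, `[`, character(1), 1)
    colnames(m) <- AA20
    m[scoredPositions(), , drop = FALSE]
  }

  bg <- kv(secs[["background"]])[AA20]
  freq <- rowBlock(secs[["frequencies"]])
  counts <- rowBlock(secs[["counts"]])
  w <- kv(secs[["weights"]])[scoredPositions()]

  loopScores <- list()
  for (nm in names(secs)[startsWith(names(secs), "loop ")]) {
    head_tk <- strsplit(nm, " +")[[1]]
    loop <- head_tk[2]
    pars <- setNames(as.numeric(head_tk[c(4, 6, 8)]), c("t", "t0", "l0"))
    tab <- kv(secs[[nm]])
    loopScores[[loop]] <- list(
      table = data.frame(l = as.integer(names(tab)),
                         score = unname(tab)),
      t = pars[["t"]], t0 = pars[["t0"]], l0 = as.integer(pars[["l0"]]))
  }

  tt <- kv(secs[["tetrad"]])
  reg <- list(
    initial = unname(kv(secs[["regulator initial"]])[as.character(1:40)]),
    modified = unname(kv(secs[["regulator modified"]])[as.character(1:40)]),
    use = hdr("regulator_use"))

  new("RepeatProfile",
      frequencies = freq, counts = counts,
      nRepeats = as.integer(hdr("n_repeats")),
      weights = w, background = bg,
      loopScores = loopScores,
      tetrad = tetradProbabilities(tt[["pPentad"]], tt[["pTetrad"]],
                                   tt[["pTriad"]], bg),
      regulator = reg,
      meta = list(format = fmt, provenance = hdr("provenance"),
                  weight_mode = hdr("weight_mode")))
}

.profileCache <- new.env(parent = emptyenv())

#' The packaged default repeat profile
#'
#' Reads (and caches) the profile shipped with the package in
#' \code{inst/extdata/wd40_profile_default_synthetic.txt}. See
#' [makeDefaultProfile()] for how it is constructed and what parts of it are
#' synthetic.
#'
#' @return A [RepeatProfile].
#' @export
defaultProfile <- function() {
  if (is.null(.profileCache$default)) {
    path <- defaultProfilePath()
    .profileCache$default <- readRepeatProfile(path)
  }
  .profileCache$default
}

#' @rdname defaultProfile
#' @export
defaultProfilePath <- function() {
  system.file("extdata", "wd40_profile_default_synthetic.txt",
              package = "propellerscan", mustWork = TRUE)
}
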