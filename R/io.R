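# Readers and writers for the pipeline's external formats:
# FASTA (in), PSIPRED .ss2 (in), annotated repeat tables (in/out),
# repeat table TSV, secondary-structure FASTA/annotated blocks and the
# versioned classification report (out). All writers are deterministic:
# stable field order, full-precision ("%.17g") numerals in machine formats,
# 4 decimals in human-facing tables.

.REPORT_FORMAT <- "wd40-report/1"
.PROFILE_FORMAT <- "wd40-profile/1"

#' Read protein sequences from FASTA
#'
#' Order-preserving multi-record reader (via Biostrings). Lower-case
#' residues are upcased with a warning; letters outside the 20-residue
#' alphabet plus X/B/Z/U are rejected, and non-canonical letters are flagged.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{id} (first header token),
#'   \code{description} (remainder), \code{residues}.
#' @export
readFastaProtein <- function(path) {
  # BStringSet keeps case and letters verbatim; validation is ours
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    psLog("warn", "lower-case residues upcased")
    seqs <- toupper(seqs)
  }
  bad <- gsub(paste0("[", paste(c(AA20, "X", "B", "Z", "U"), collapse = ""),
                     "]"), "", seqs)
  if (any(nchar(bad) > 0))
    stop("invalid residue letters: ", paste(unique(strsplit(
      paste(bad, collapse = ""), "")[[1]]), collapse = ", "))
  if (any(grepl("[XBZU]", seqs)))
    psLog("warn", "non-canonical residues (X/B/Z/U) present; scored at background")
  data.frame(id = ids, description = desc, residues = unname(seqs))
}

#' Read an external secondary-structure prediction (.ss2)
#'
#' Accepts the PSIPRED vertical format (optional \code{# PSIPRED VFORMAT}
#' header; columns index, residue, state, then the coil/helix/strand
#' confidence columns, from which the integer confidence is
#' \code{round(9 * max)}), or a simplified two-column dialect
#' (state, integer confidence).
#'
#' @param path File to read.
#' @param sequence Optional residue string; the file's residue column is
#'   cross-checked against it and the lengths must agree.
#' @return An [SSPrediction].
#' @export
readSS2 <- function(path, sequence = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty secondary-structure file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  states <- character(length(toks)); conf <- integer(length(toks))
  resid <- rep(NA_character_, length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (nf[i] >= 6L) {
      states[i] <- tk[3]
      v <- suppressWarnings(as.numeric(tk[4:6]))
      if (anyNA(v)) stop(sprintf("malformed row at line %d of %s", i, path))
      conf[i] <- as.integer(round(9 * max(v)))
      resid[i] <- tk[2]
    } else if (nf[i] == 2L) {
      states[i] <- tk[1]
      v <- suppressWarnings(as.integer(tk[2]))
      if (is.na(v)) stop(sprintf("malformed row at line %d of %s", i, path))
      conf[i] <- v
    } else {
      stop(sprintf("malformed row at line %d of %s", i, path))
    }
  }
  if (!all(states %in% c("H", "E", "C")))
    stop("states must be H, E or C in ", path)
  if (!is.null(sequence)) {
    if (length(states) != nchar(sequence))
      stop(sprintf("prediction length %d != sequence length %d",
                   length(states), nchar(sequence)))
    sres <- strsplit(toupper(sequence), "")[[1]]
    chk <- !is.na(resid) & resid != sres
    if (any(chk))
      stop("residue mismatch with sequence at positions ",
           paste(head(which(chk), 5), collapse = ", "))
  }
  new("SSPrediction", states = states, conf = pmin(9L, pmax(0L, conf)))
}

#' Read / write annotated repeat tables
#'
#' Tab-separated, one repeat per row: \code{source_id}, \code{sequence},
#' then the 1-based inclusive start of each six-residue strand
#' (\code{Sd_start}, \code{Sa_start}, \code{Sb_start}, \code{Sc_start}).
#' Internally coordinates are 0-based.
#'
#' @param path File to read or write.
#' @return \code{readAnnotatedRepeats}: data.frame with 0-based
#'   \code{sd_start} .. \code{sc_start} columns.
#' @export
readAnnotatedRepeats <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("source_id", "sequence", "Sd_start", "Sa_start", "Sb_start",
            "Sc_start")
  if (!all(need %in% names(df)))
    stop("annotated repeat file must have columns ",
         paste(need, collapse = ", "))
  data.frame(source_id = as.character(df$source_id),
             sequence = toupper(df$sequence),
             sd_start = as.integer(df$Sd_start) - 1L,
             sa_start = as.integer(df$Sa_start) - 1L,
             sb_start = as.integer(df$Sb_start) - 1L,
             sc_start = as.integer(df$Sc_start) - 1L)
}

#' @rdname readAnnotatedRepeats
#' @param repeats Internal annotated repeat data.frame (0-based starts).
#' @export
writeAnnotatedRepeats <- function(repeats, path) {
  out <- data.frame(source_id = repeats$source_id,
                    sequence = repeats$sequence,
                    Sd_start = repeats$sd_start + 1L,
                    Sa_start = repeats$sa_start + 1L,
                    Sb_start = repeats$sb_start + 1L,
                    Sc_start = repeats$sc_start + 1L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- classification report ------------------------------------------------

# One typed "key: t values" line. Types: i(nteger), d(ouble), l(ogical),
# c(haracter).
.fieldLine <- function(key, value) {
  if (is.integer(value)) t <- "i"
  else if (is.double(value)) t <- "d"
  else if (is.logical(value)) t <- "l"
  else t <- "c"
  val <- switch(t, d = num17(value), c = as.character(value),
                as.character(value))
  sprintf("%s: %s %s", key, t, paste(val, collapse = " "))
}

.parseField <- function(rest) {
  tk <- strsplit(rest, " ")[[1]]
  t <- tk[1]; v <- tk[-1]
  switch(t, i = as.integer(v), d = as.numeric(v), l = as.logical(v), v)
}

.repeatCols <- c("start", "lda", "lab", "lbc", "end", "S_aa", "S_loop",
                 "S_corr", "S_ss", "S_repeat")

.reportLines <- function(report) {
  ln <- c("# propellerscan classification report",
          paste0("format: ", .REPORT_FORMAT),
          .fieldLine("sequence_id", report@sequenceId),
          .fieldLine("sequence_length", report@sequenceLength),
          .fieldLine("verdict", report@verdict),
          .fieldLine("early_exit", report@earlyExit),
          .fieldLine("seed", report@seed),
          .fieldLine("engine", report@engine),
          .fieldLine("profile_checksum",
                     if (nzchar(report@profileChecksum))
                       report@profileChecksum else "-"),
          .fieldLine("n_domains", report@nDomains),
          .fieldLine("tetrad_found", report@tetradFound))
  for (nm in names(report@thresholds))
    ln <- c(ln, .fieldLine(paste0("threshold ", nm),
                           report@thresholds[[nm]]))
  for (nm in names(report@poolInfo))
    ln <- c(ln, .fieldLine(paste0("pool ", nm), report@poolInfo[[nm]]))
  if (length(report@asr)) ln <- c(ln, .fieldLine("asr", report@asr))
  if (length(report@domains)) {
    sc <- vapply(report@domains, function(d) d@score, numeric(1))
    scr <- vapply(report@domains, function(d) d@scoreRegulated, numeric(1))
    ln <- c(ln, .fieldLine("domain_scores", sc),
            .fieldLine("domain_scores_regulated", scr))
  }
  ln <- c(ln, "begin repeats",
          paste(c("domain", .repeatCols), collapse = "\t"))
  for (d in seq_along(report@domains)) {
    df <- report@domains[[d]]@repeats
    for (i in seq_len(nrow(df))) {
      vals <- vapply(.repeatCols, function(cl) {
        v <- df[[cl]][i]
        if (is.double(v)) num17(v) else as.character(v)
      }, character(1))
      ln <- c(ln, paste(c(d, vals), collapse = "\t"))
    }
  }
  ln <- c(ln, "end repeats", "begin ss")
  ssv <- report@ss
  if (nchar(ssv)) {
    starts <- seq(1, nchar(ssv), by = 60)
    ln <- c(ln, substring(ssv, starts, pmin(starts + 59, nchar(ssv))))
  }
  c(ln, "end ss")
}

.md5OfLines <- function(lines) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf)
  unname(tools::md5sum(tf))
}

#' Write / read a classification report
#'
#' Versioned structured-text serialization of a [ClassificationReport],
#' including the seed, thresholds, pipeline diagnostics and the profile
#' checksum, protected by an md5 integrity checksum. Writing then reading
#' reproduces the object bit-exactly.
#'
#' @param report A [ClassificationReport].
#' @param path File to write or read.
#' @return \code{readReport}: the reconstructed [ClassificationReport].
#' @export
writeReport <- function(report, path) {
  ln <- .reportLines(report)
  ln <- c(ln, paste0("checksum: ", .md5OfLines(ln)))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  ln <- readLines(path)
  ci <- grep("^checksum: ", ln)
  if (length(ci) != 1L) stop("report has no checksum line: ", path)
  stored <- sub("^checksum: ", "", ln[ci])
  if (!identical(stored, unname(.md5OfLines(ln[seq_len(ci - 1L)]))))
    stop("report integrity error: checksum mismatch in ", path)
  fmt <- sub("^format: ", "", grep("^format: ", ln, value = TRUE)[1])
  if (!identical(fmt, .REPORT_FORMAT))
    stop("unsupported report format version: ", fmt)

  fields <- list(); thresholds <- list(); poolInfo <- list()
  body <- ln[seq_len(ci - 1L)]
  inRep <- FALSE; inSS <- FALSE
  repLines <- character(0); ssLines <- character(0)
  for (l in body) {
    if (identical(l, "begin repeats")) { inRep <- TRUE; next }
    if (identical(l, "end repeats"))   { inRep <- FALSE; next }
    if (identical(l, "begin ss"))      { inSS <- TRUE; next }
    if (identical(l, "end ss"))        { inSS <- FALSE; next }
    if (inRep) { repLines <- c(repLines, l); next }
    if (inSS)  { ssLines <- c(ssLines, l); next }
    if (grepl("^#", l) || grepl("^format: ", l) || !nzchar(l)) next
    key <- sub(":.*$", "", l)
    rest <- sub("^[^:]+: ", "", l)
    if (startsWith(key, "threshold ")) {
      thresholds[[sub("^threshold ", "", key)]] <- .parseField(rest)
    } else if (startsWith(key, "pool ")) {
      poolInfo[[sub("^pool ", "", key)]] <- .parseField(rest)
    } else {
      fields[[key]] <- .parseField(rest)
    }
  }

  hdr <- strsplit(repLines[1], "\t")[[1]]
  repDf <- if (length(repLines) > 1L) {
    m <- do.call(rbind, strsplit(repLines[-1L], "\t"))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- hdr
    for (cl in c("domain", "start", "lda", "lab", "lbc", "end"))
      df[[cl]] <- as.integer(df[[cl]])
    for (cl in c("S_aa", "S_loop", "S_corr", "S_ss", "S_repeat"))
      df[[cl]] <- as.numeric(df[[cl]])
    df
  } else {
    data.frame(domain = integer(0))
  }

  sc <- fields[["domain_scores"]] %||% numeric(0)
  scr <- fields[["domain_scores_regulated"]] %||% numeric(0)
  doms <- list()
  if (nrow(repDf) > 0L) {
    for (d in sort(unique(repDf$domain))) {
      sub <- repDf[repDf$domain == d, .repeatCols, drop = FALSE]
      rownames(sub) <- NULL
      dm <- domainModel(sub, fields[["sequence_id"]])
      dm@score <- sc[d]
      dm@scoreRegulated <- scr[d]
      doms[[d]] <- dm
    }
  }

  chk <- fields[["profile_checksum"]]
  new("ClassificationReport",
      sequenceId = fields[["sequence_id"]],
      sequenceLength = fields[["sequence_length"]],
      verdict = fields[["verdict"]],
      domains = doms, nDomains = fields[["n_domains"]],
      asr = fields[["asr"]] %||% numeric(0),
      tetradFound = fields[["tetrad_found"]],
      ss = paste(ssLines, collapse = ""),
      earlyExit = fields[["early_exit"]], seed = fields[["seed"]],
      engine = fields[["engine"]], thresholds = thresholds,
      profileChecksum = if (identical(chk, "-")) "" else chk,
      poolInfo = poolInfo)
}

#' Write the repeat table (TSV)
#'
#' One row per detected repeat with 1-based inclusive coordinates for the
#' repeat and each strand, plus the score breakdown at 4 decimals.
#'
#' @param report A [ClassificationReport].
#' @param path Output file.
#' @export
writeRepeatTable <- function(report, path) {
  rows <- list(); k <- 0L
  repIdx <- 0L
  for (d in seq_along(report@domains)) {
    df <- report@domains[[d]]@repeats
    for (i in seq_len(nrow(df))) {
      repIdx <- repIdx + 1L
      so <- strandOffsets(c(l_da = df$lda[i], l_ab = df$lab[i],
                            l_bc = df$lbc[i]))
      k <- k + 1L
      rows[[k]] <- data.frame(
        sequence_id = report@sequenceId, domain_index = d,
        repeat_index = repIdx, start = df$start[i] + 1L, end = df$end[i],
        Sd_start = df$start[i] + so[["Sd"]] + 1L,
        Sa_start = df$start[i] + so[["Sa"]] + 1L,
        Sb_start = df$start[i] + so[["Sb"]] + 1L,
        Sc_start = df$start[i] + so[["Sc"]] + 1L,
        S_aa = num4(df$S_aa[i]), S_loop_len = num4(df$S_loop[i]),
        S_corr = num4(df$S_corr[i]), S_psipred = num4(df$S_ss[i]),
        S_repeat = num4(df$S_repeat[i]))
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(sequence_id = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write predicted secondary structure
#'
#' \code{writeSSFasta} writes the two-line FASTA-like form (header +
#' E/C string); \code{writeSSBlocks} writes horizontal annotated blocks:
#' residue numbers, sequence, SS string and strand identifiers, 60 columns
#' per block.
#'
#' @param report A [ClassificationReport].
#' @param path Output file.
#' @param sequence Residue string (blocks form only).
#' @export
writeSSFasta <- function(report, path) {
  writeLines(c(paste0(">", report@sequenceId, " propellerscan secondary structure"),
               report@ss), path)
  invisible(path)
}

#' @rdname writeSSFasta
#' @export
writeSSBlocks <- function(report, sequence, path) {
  n <- report@sequenceLength
  seg <- emitSecondaryStructure(report@domains, n)$segments
  strandLab <- rep(" ", n)
  for (i in seq_len(nrow(seg))) {
    lab <- paste0(seg$strand[i], seg$repeat_index[i])
    at <- seg$start[i]:seg$end[i]
    strandLab[at] <- ""
    strandLab[at[seq_len(min(nchar(lab), length(at)))]] <-
      strsplit(lab, "")[[1]][seq_len(min(nchar(lab), length(at)))]
    strandLab[at][strandLab[at] == ""] <- "-"
  }
  ln <- character(0)
  for (s in seq(1, n, by = 60)) {
    e <- min(s + 59, n)
    ln <- c(ln,
            sprintf("%6d %s %d", s, substr(sequence, s, e), e),
            sprintf("       %s", substr(report@ss, s, e)),
            sprintf("       %s", paste(strandLab[s:e], collapse = "")),
            "")
  }
  writeLines(ln, path)
  invisible(path)
}
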