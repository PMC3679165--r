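# S4 classes shared across the package.

#' RepeatProfile: the trained WD40 repeat model
#'
#' Holds everything needed to score repeats and domains: per-position residue
#' frequencies and raw counts at the 31 scored template positions, per-position
#' information weights, background amino-acid frequencies, loop-length score
#' tables for the four loop classes, the tetrad (DHSW) statistics and the
#' repeat-count regulator used during domain assembly.
#'
#' @slot frequencies 31 x 20 matrix of per-position residue frequencies
#'   (rows = scored positions, columns = amino acids); each row sums to 1.
#' @slot counts 31 x 20 matrix of raw residue counts behind the frequencies
#'   (all zero for profiles not estimated from data).
#' @slot nRepeats Number of repeats the profile was trained on.
#' @slot weights Named numeric, per-position weight \code{w_k} (information
#'   content in bits by default).
#' @slot background Named numeric over the 20 amino acids, summing to 1.
#' @slot loopScores Named list (\code{l_da}, \code{l_ab}, \code{l_bc},
#'   \code{l_cd}); each entry a list with a \code{table} (data.frame
#'   \code{l}, \code{score}), the penalty slope \code{t}, transition width
#'   \code{t0} and intercept \code{l0}.
#' @slot tetrad List with motif probabilities \code{pPentad}, \code{pTetrad},
#'   \code{pTriad} and the derived log-odds bonuses.
#' @slot regulator List with numeric vectors \code{initial} and
#'   \code{modified} (R(N) for N = 1..40) and \code{use} naming the active one.
#' @slot meta List of free-form metadata (\code{provenance},
#'   \code{weight_mode}, \code{format}).
#' @export
setClass("RepeatProfile",
  representation(
    frequencies = "matrix",
    counts      = "matrix",
    nRepeats    = "integer",
    weights     = "numeric",
    background  = "numeric",
    loopScores  = "list",
    tetrad      = "list",
    regulator   = "list",
    meta        = "list"
  )
)

setValidity("RepeatProfile", function(object) {
  msg <- character()
  sp <- scoredPositions()
  fr <- object@frequencies
  if (!identical(rownames(fr), sp))
    msg <- c(msg, "frequencies must have the 31 scored positions as rownames")
  if (!identical(colnames(fr), AA20))
    msg <- c(msg, "frequencies must have the 20 amino acids as colnames")
  if (length(msg) == 0L) {
    if (any(fr <= 0))
      msg <- c(msg, "frequencies must be strictly positive (pseudo-counts)")
    if (any(abs(rowSums(fr) - 1) > 1e-9))
      msg <- c(msg, "each frequency row must sum to 1")
    if (!identical(names(object@weights), sp) || any(object@weights < 0))
      msg <- c(msg, "weights must be non-negative and named by scored position")
    bg <- object@background
    if (!identical(names(bg), AA20) || abs(sum(bg) - 1) > 1e-9 || any(bg <= 0))
      msg <- c(msg, "background must be positive over AA20 and sum to 1")
    if (!all(c("l_da", "l_ab", "l_bc", "l_cd") %in% names(object@loopScores)))
      msg <- c(msg, "loopScores must cover l_da, l_ab, l_bc, l_cd")
    tt <- object@tetrad
    if (!all(c("pPentad", "pTetrad", "pTriad") %in% names(tt))) {
      msg <- c(msg, "tetrad must hold pPentad, pTetrad, pTriad")
    } else if (!(tt$pTriad >= tt$pTetrad && tt$pTetrad >= tt$pPentad &&
                 tt$pPentad > 0)) {
      msg <- c(msg, "tetrad probabilities must nest: pTriad >= pTetrad >= pPentad > 0")
    }
    rg <- object@regulator
    for (nm in c("initial", "modified")) {
      r <- rg[[nm]]
      if (is.null(r) || length(r) != 40L) {
        msg <- c(msg, sprintf("regulator$%s must have 40 entries", nm))
      } else {
        for (p in c(7L, 14L, 21L, 28L, 35L)) {
          if (!(r[p] > r[p - 1L] && r[p] > r[p + 1L]))
            msg <- c(msg, sprintf("regulator$%s must peak at N = %d", nm, p))
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SSPrediction: external per-residue secondary-structure prediction
#'
#' @slot states Character vector of per-residue states in \code{H}, \code{E},
#'   \code{C}.
#' @slot conf Integer vector of per-residue confidences in 0..9.
#' @export
setClass("SSPrediction",
  representation(states = "character", conf = "integer"))

setValidity("SSPrediction", function(object) {
  msg <- character()
  if (length(object@states) != length(object@conf))
    msg <- c(msg, "states and conf must have equal length")
  if (!all(object@states %in% c("H", "E", "C")))
    msg <- c(msg, "states must be H, E or C")
  if (length(object@conf) && (any(object@conf < 0L) || any(object@conf > 9L)))
    msg <- c(msg, "conf must be integers in 0..9")
  if (length(msg)) msg else TRUE
})

#' RepeatCandidate: one placement of the repeat template on a sequence
#'
#' @slot sequenceId Identifier of the parent sequence.
#' @slot sequence The full parent residue string (kept so that tetrad slots
#'   outside the repeat span can be inspected).
#' @slot start 0-based index of the Sd1 residue.
#' @slot loopLengths Named integer vector \code{l_da}, \code{l_ab},
#'   \code{l_bc}.
#' @slot scoreTerms Named numeric: \code{S_aa}, \code{S_loop_len},
#'   \code{S_corr}, \code{S_psipred} (NA before scoring).
#' @export
setClass("RepeatCandidate",
  representation(
    sequenceId  = "character",
    sequence    = "character",
    start       = "integer",
    loopLengths = "integer",
    scoreTerms  = "numeric"
  )
)

setValidity("RepeatCandidate", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L) msg <- c(msg, "sequence must be a single string")
  ll <- object@loopLengths
  if (!all(c("l_da", "l_ab", "l_bc") %in% names(ll)))
    msg <- c(msg, "loopLengths must name l_da, l_ab, l_bc")
  else {
    sp <- candidateSpan(object@start, ll)
    if (sp[2] > nchar(object@sequence))
      msg <- c(msg, "candidate extends past the end of the sequence")
  }
  st <- object@scoreTerms
  if (!identical(names(st), c("S_aa", "S_loop_len", "S_corr", "S_psipred")))
    msg <- c(msg, "scoreTerms must name S_aa, S_loop_len, S_corr, S_psipred")
  if (length(msg)) msg else TRUE
})

#' CandidatePool: scored repeat candidates on one sequence
#'
#' The candidate table has one row per candidate with columns \code{start},
#' \code{lda}, \code{lab}, \code{lbc}, \code{end} (0-based half-open),
#' \code{S_aa}, \code{S_loop}, \code{S_corr}, \code{S_ss}, \code{S_repeat}.
#'
#' @slot candidates data.frame as described above, sorted by \code{start}.
#' @slot sequenceId Identifier of the scanned sequence.
#' @slot threshold Current pool threshold T (NA before thresholding).
#' @export
setClass("CandidatePool",
  representation(candidates = "data.frame", sequenceId = "character",
                 threshold = "numeric"))

.POOL_COLS <- c("start", "lda", "lab", "lbc", "end",
                "S_aa", "S_loop", "S_corr", "S_ss", "S_repeat")

setValidity("CandidatePool", function(object) {
  df <- object@candidates
  if (!all(.POOL_COLS %in% names(df)))
    return("candidate table missing required columns")
  if (nrow(df) > 1L && is.unsorted(df$start))
    return("candidates must be sorted by start")
  if (nrow(df) && any(df$end - df$start != 24L + df$lda + df$lab + df$lbc))
    return("end - start must equal 24 + l_da + l_ab + l_bc")
  TRUE
})

#' DomainModel: an ordered, non-overlapping set of repeats
#'
#' @slot repeats data.frame with the same columns as a [CandidatePool] table,
#'   in ascending sequence order, non-overlapping.
#' @slot lcdLengths Integer vector of the Lcd loop lengths between
#'   consecutive repeats (length \code{nrow(repeats) - 1}).
#' @slot sequenceId Identifier of the parent sequence.
#' @slot score Domain score without the repeat-count regulator.
#' @slot scoreRegulated Domain score with the regulator (as used during
#'   assembly; NA if not computed).
#' @export
setClass("DomainModel",
  representation(repeats = "data.frame", lcdLengths = "integer",
                 sequenceId = "character", score = "numeric",
                 scoreRegulated = "numeric"))

setValidity("DomainModel", function(object) {
  df <- object@repeats
  n <- nrow(df)
  if (n == 0L) {
    if (length(object@lcdLengths) != 0L)
      return("empty domain cannot have lcd lengths")
    return(TRUE)
  }
  if (length(object@lcdLengths) != n - 1L)
    return("need exactly nRepeats - 1 lcd lengths")
  if (n > 1L) {
    if (is.unsorted(df$start, strictly = TRUE))
      return("repeats must be in ascending sequence order")
    gaps <- df$start[-1L] - df$end[-n]
    if (any(gaps < 0L)) return("repeats must not overlap")
    if (!all(gaps == object@lcdLengths))
      return("lcd lengths must equal the inter-repeat gaps")
  }
  TRUE
})

#' ClassificationReport: the final verdict for one sequence
#'
#' @slot sequenceId,sequenceLength Scanned sequence and its length.
#' @slot verdict \code{"WD40"} or \code{"not-WD40"}.
#' @slot domains List of [DomainModel]; for a WD40 verdict every reported
#'   domain has at least the minimum repeat count and passes the score or
#'   tetrad criterion.
#' @slot nDomains Domain count from the total-repeat counting rule.
#' @slot asr Average repeat score (tetrad term excluded) per reported domain.
#' @slot tetradFound TRUE if any repeat in a reported domain carries a full
#'   DHSW tetrad.
#' @slot ss Per-residue secondary-structure string over \code{E}/\code{C}.
#' @slot earlyExit TRUE if the scan stopped because no candidate reached the
#'   early-exit score.
#' @slot seed,engine Assembly seed and engine (\code{"ga"} or \code{"dp"}).
#' @slot thresholds Named list of the thresholds in force.
#' @slot profileChecksum md5 of the profile file used (or \code{""}).
#' @slot poolInfo Named list of pipeline diagnostics (pool sizes, T, restarts).
#' @export
setClass("ClassificationReport",
  representation(
    sequenceId = "character", sequenceLength = "integer",
    verdict = "character", domains = "list", nDomains = "integer",
    asr = "numeric", tetradFound = "logical", ss = "character",
    earlyExit = "logical", seed = "integer", engine = "character",
    thresholds = "list", profileChecksum = "character", poolInfo = "list"
  )
)

setValidity("ClassificationReport", function(object) {
  msg <- character()
  if (!object@verdict %in% c("WD40", "not-WD40"))
    msg <- c(msg, "verdict must be WD40 or not-WD40")
  if (nchar(object@ss) != object@sequenceLength)
    msg <- c(msg, "ss string must cover the whole sequence")
  if (object@verdict == "WD40") {
    minRep <- object@thresholds$min_repeats %||% 6L
    ok <- vapply(object@domains, function(d) nrow(d@repeats) >= minRep,
                 logical(1))
    if (length(ok) == 0L || !all(ok))
      msg <- c(msg, "WD40 verdict requires every reported domain to reach the minimum repeat count")
  }
  if (length(msg)) msg else TRUE
})
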