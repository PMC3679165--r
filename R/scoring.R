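# Scoring of repeat candidates and assembled domains.
#
# S_repeat = S_aa + S_loop_len + S_corr + S_psipred:
#   S_aa       weighted log-odds of the residues at the 31 scored positions,
#   S_loop_len loop-length preference scores for l_da, l_ab, l_bc,
#   S_corr     bonus for a pentad / DHSW tetrad / DHS triad,
#   S_psipred  confidence-weighted term from an external SS prediction,
#              evaluated over the 24 strand positions only.
# Natural logarithms throughout; the published threshold constants
# (10/35/45/48) are calibrated against the packaged default profile and are
# configurable in the detection pipeline.

#' Construct a repeat candidate
#'
#' @param sequence Full parent residue string.
#' @param start 0-based index of the Sd1 residue.
#' @param loopLengths Named vector with \code{l_da}, \code{l_ab},
#'   \code{l_bc}.
#' @param sequenceId Identifier (default \code{"seq"}).
#' @return An unscored [RepeatCandidate].
#' @export
repeatCandidate <- function(sequence, start, loopLengths,
                            sequenceId = "seq") {
  ll <- .checkLoops(loopLengths)
  new("RepeatCandidate", sequenceId = sequenceId,
      sequence = toupper(as.character(sequence)[1]),
      start = as.integer(start), loopLengths = ll,
      scoreTerms = setNames(rep(NA_real_, 4),
                            c("S_aa", "S_loop_len", "S_corr", "S_psipred")))
}

# Log-odds lookup matrix: w_k * log(P_k(i) / P_all(i)), 31 x 20.
logOddsMatrix <- function(profile) {
  lo <- log(sweep(profile@frequencies, 2, profile@background, "/"))
  lo * profile@weights
}

#' Residue propensity score S_aa
#'
#' Weighted sum of the log-odds \eqn{w_k \log(P_k(i)/P_{all}(i))} over the 31
#' scored template positions. A scored loop position that the candidate's
#' loop is too short to hold, and any residue letter outside the 20-letter
#' alphabet, contributes background (zero log-odds); non-standard letters are
#' warned about.
#'
#' @param candidate A [RepeatCandidate].
#' @param profile A [RepeatProfile].
#' @return Numeric score.
#' @export
scoreAA <- function(candidate, profile) {
  off <- scoredOffsets(candidate@loopLengths)
  res <- strsplit(candidate@sequence, "")[[1]]
  lo <- logOddsMatrix(profile)
  total <- 0
  for (k in names(off)) {
    if (is.na(off[[k]])) next
    aa <- res[candidate@start + off[[k]] + 1L]
    if (!aa %in% AA20) {
      psLog("warn", "non-standard residue '%s' scored at background", aa)
      next
    }
    total <- total + lo[k, aa]
  }
  total
}

#' Loop-length score S_loop_len
#'
#' Sum of the loop-length scores for the three within-repeat loops. Lengths
#' outside a table's domain are scored by linear-penalty extrapolation with a
#' warning.
#'
#' @param l_da,l_ab,l_bc Loop lengths.
#' @param profile A [RepeatProfile] (its fitted loop tables are used).
#' @return Numeric score.
#' @export
scoreLoopLengths <- function(l_da, l_ab, l_bc, profile) {
  loopScore(l_da, profile@loopScores$l_da) +
    loopScore(l_ab, profile@loopScores$l_ab) +
    loopScore(l_bc, profile@loopScores$l_bc)
}

# Residues at the five pentad slots of a candidate. prevEnd (0-based
# exclusive end of the preceding repeat) gives the true Lcd context; without
# it the modal-loop fallback position start - 3 is used, and NA if that falls
# off the sequence (the pentad then degrades to the slots that exist).
tetradSlotResidues <- function(candidate, prevEnd = NA_integer_) {
  res <- strsplit(candidate@sequence, "")[[1]]
  ll <- candidate@loopLengths
  s <- candidate@start
  at <- function(pos0) {
    if (is.na(pos0) || pos0 < 0L || pos0 >= length(res)) NA_character_
    else res[pos0 + 1L]
  }
  scStart <- s + 18L + ll[["l_da"]] + ll[["l_ab"]] + ll[["l_bc"]]
  lcd2 <- if (!is.na(prevEnd)) prevEnd + 1L else s - 3L
  c(Sc1  = at(scStart),
    Lcd2 = at(lcd2),
    Lda3 = if (ll[["l_da"]] >= 3L) at(s + 8L) else NA_character_,
    Sb4  = at(s + 12L + ll[["l_da"]] + ll[["l_ab"]] + 3L),
    Sc5  = at(scStart + 4L))
}

# Which motif (if any) the slot residues form.
tetradMotifOf <- function(slots) {
  ok <- mapply(function(aa, cls) !is.na(aa) && aa %in% cls,
               slots, .TETRAD_SLOTS)
  if (ok[["Lcd2"]] && ok[["Lda3"]] && ok[["Sb4"]]) {
    if (ok[["Sc5"]]) {
      if (ok[["Sc1"]]) "pentad" else "tetrad"
    } else "triad"
  } else "none"
}

#' Tetrad cooperativity score S_corr
#'
#' Returns the pentad bonus if Ser/Thr, Asp, His, Ser/Thr, Trp occupy the
#' five slots Sc1, Lcd2, Lda3, Sb4, Sc5; otherwise the DHSW tetrad bonus if
#' the last four match; otherwise the DHS triad bonus if Asp-His-Ser/Thr
#' match; otherwise 0. Bonuses are log-odds of the motif probability in the
#' profile against its probability under the background composition.
#'
#' The Lcd2 slot lies in the loop before the repeat: \code{prevEnd} supplies
#' the true context inside an assembled domain; without it the modal-loop
#' fallback position is used, and at the very start of a sequence the pentad
#' degrades to the remaining slots.
#'
#' @inheritParams scoreAA
#' @param prevEnd 0-based exclusive end of the preceding repeat, or NA.
#' @return Numeric bonus (0 if no motif).
#' @export
scoreCorr <- function(candidate, profile, prevEnd = NA_integer_) {
  motif <- tetradMotifOf(tetradSlotResidues(candidate, prevEnd))
  switch(motif,
         pentad = profile@tetrad$bonusPentad,
         tetrad = profile@tetrad$bonusTetrad,
         triad  = profile@tetrad$bonusTriad,
         none   = 0)
}

.SS_COEF <- c(E = 0.1, C = -0.025, H = -0.1)

#' External secondary-structure score S_psipred
#'
#' Sum, over the 24 strand positions of the candidate, of the per-residue
#' prediction confidence times a state coefficient (E: +0.1, C: -0.025,
#' H: -0.1). Loop positions contribute nothing. With no prediction available
#' the term is 0 (degraded mode; strand-d placement accuracy drops).
#'
#' @inheritParams scoreAA
#' @param ss An [SSPrediction] covering the candidate's sequence, or NULL.
#' @param coefficients Named numeric over E, C, H.
#' @return Numeric score (0 if \code{ss} is NULL).
#' @export
scoreSSTerm <- function(candidate, ss = NULL, coefficients = .SS_COEF) {
  if (is.null(ss)) return(0)
  n <- nchar(candidate@sequence)
  if (length(ss@states) < n)
    stop("secondary-structure prediction shorter than the sequence")
  contrib <- ss@conf * coefficients[ss@states]
  so <- strandOffsets(candidate@loopLengths)
  idx <- as.vector(outer(0:5, candidate@start + so, "+")) + 1L
  sum(contrib[idx])
}

#' Score a repeat candidate
#'
#' Computes all four score terms and stores them in the candidate. The total
#' \code{S_repeat} is their sum; the classification statistic ASr later
#' excludes the \code{S_corr} term.
#'
#' @inheritParams scoreCorr
#' @param ss Optional [SSPrediction].
#' @return The candidate with \code{scoreTerms} filled (see
#'   [scoreBreakdown()]).
#' @export
scoreRepeat <- function(candidate, profile, ss = NULL,
                        prevEnd = NA_integer_) {
  ll <- candidate@loopLengths
  candidate@scoreTerms <- c(
    S_aa = scoreAA(candidate, profile),
    S_loop_len = scoreLoopLengths(ll[["l_da"]], ll[["l_ab"]], ll[["l_bc"]],
                                  profile),
    S_corr = scoreCorr(candidate, profile, prevEnd),
    S_psipred = scoreSSTerm(candidate, ss)
  )
  candidate
}

#' Repeat-count regulator R(N)
#'
#' Looks up the regulator value for a domain of \code{nRep} repeats. The
#' regulator rewards domains whose repeat count is a multiple of seven
#' during assembly and is removed from final reported scores.
#'
#' @param nRep Repeat count (>= 1); values beyond the table are clamped with
#'   a warning.
#' @param profile A [RepeatProfile].
#' @return Numeric R(N).
#' @export
regulator <- function(nRep, profile) {
  tab <- regulatorTable(profile)
  nRep <- as.integer(nRep)
  if (any(nRep < 1L)) stop("nRep must be >= 1")
  if (any(nRep > length(tab))) {
    psLog("warn", "repeat count beyond regulator table; clamping")
    nRep <- pmin(nRep, length(tab))
  }
  tab[nRep]
}

#' Build a domain model from repeats
#'
#' @param repeats data.frame of repeat rows (candidate-pool columns), in any
#'   order; they are sorted by start and must not overlap.
#' @param sequenceId Parent sequence identifier.
#' @return A [DomainModel] with scores unset (see [scoreDomain()]).
#' @export
domainModel <- function(repeats, sequenceId = "seq") {
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  n <- nrow(repeats)
  lcd <- if (n > 1L) as.integer(repeats$start[-1L] - repeats$end[-n])
    else integer(0)
  if (any(lcd < 0L)) stop("overlapping repeats cannot form a domain")
  new("DomainModel", repeats = repeats, lcdLengths = lcd,
      sequenceId = sequenceId, score = NA_real_,
      scoreRegulated = NA_real_)
}

#' Domain score S_domain
#'
#' Sum of the repeat scores of all member repeats plus the loop-length scores
#' of the inter-repeat Lcd loops, plus (during assembly) the repeat-count
#' regulator.
#'
#' @param domain A [DomainModel].
#' @param profile A [RepeatProfile].
#' @param useRegulator Include R(N)? (TRUE during assembly, FALSE for
#'   reported scores.)
#' @return The domain with its \code{score} / \code{scoreRegulated} slots
#'   filled; use \code{@score} or [scoreBreakdown()] accessors to read.
#' @export
scoreDomain <- function(domain, profile, useRegulator = FALSE) {
  n <- nrow(domain@repeats)
  base <- sum(domain@repeats$S_repeat) +
    sum(loopScore(domain@lcdLengths, profile@loopScores$l_cd,
                  warn = FALSE))
  domain@score <- base
  domain@scoreRegulated <- if (n >= 1L) base + regulator(n, profile)
    else base
  domain
}

#' Average repeat score ASr
#'
#' Mean over the domain's repeats of \code{S_repeat - S_corr}: the
#' cooperativity bonus is excluded so that the statistic measures per-repeat
#' profile agreement only. This is the quantity thresholded (default 48) in
#' classification.
#'
#' @param domain A [DomainModel] with at least one repeat.
#' @return Numeric ASr.
#' @export
averageRepeatScore <- function(domain) {
  if (nrow(domain@repeats) == 0L) stop("empty domain has no ASr")
  mean(domain@repeats$S_repeat - domain@repeats$S_corr)
}
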