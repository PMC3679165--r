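# Generics and accessor/show methods.

#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))
#' @export
setGeneric("tetradFound", function(x) standardGeneric("tetradFound"))
#' @export
setGeneric("ssString", function(x) standardGeneric("ssString"))
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @export
setGeneric("poolThresholdValue", function(x) standardGeneric("poolThresholdValue"))
#' @export
setGeneric("repeatTable", function(x) standardGeneric("repeatTable"))
#' @export
setGeneric("nRepeats", function(x) standardGeneric("nRepeats"))
#' @export
setGeneric("profileFrequencies", function(x) standardGeneric("profileFrequencies"))
#' @export
setGeneric("profileWeights", function(x) standardGeneric("profileWeights"))
#' @export
setGeneric("profileBackground", function(x) standardGeneric("profileBackground"))
#' @export
setGeneric("loopScoreTable", function(x, loop) standardGeneric("loopScoreTable"))
#' @export
setGeneric("regulatorTable",
           function(x, which = "active") standardGeneric("regulatorTable"))
#' @export
setGeneric("scoreBreakdown", function(x) standardGeneric("scoreBreakdown"))
#' @export
setGeneric("asrScores", function(x) standardGeneric("asrScores"))

#' @describeIn RepeatProfile Per-position residue frequency matrix.
#' @param x Object.
#' @export
setMethod("profileFrequencies", "RepeatProfile", function(x) x@frequencies)

#' @describeIn RepeatProfile Per-position information weights.
#' @export
setMethod("profileWeights", "RepeatProfile", function(x) x@weights)

#' @describeIn RepeatProfile Background amino-acid frequencies.
#' @export
setMethod("profileBackground", "RepeatProfile", function(x) x@background)

#' @describeIn RepeatProfile Loop-length score table for one loop class.
#' @param loop One of \code{"l_da"}, \code{"l_ab"}, \code{"l_bc"},
#'   \code{"l_cd"}.
#' @export
setMethod("loopScoreTable", "RepeatProfile", function(x, loop) {
  loop <- match.arg(loop, c("l_da", "l_ab", "l_bc", "l_cd"))
  x@loopScores[[loop]]$table
})

#' @describeIn RepeatProfile Repeat-count regulator R(N) for N = 1..40.
#' @param which \code{"active"} (default), \code{"initial"} or
#'   \code{"modified"}.
#' @export
setMethod("regulatorTable", "RepeatProfile", function(x, which = "active") {
  which <- match.arg(which, c("active", "initial", "modified"))
  if (which == "active") which <- x@regulator$use
  x@regulator[[which]]
})

#' @describeIn RepeatCandidate Score terms and their sum.
#' @param x Object.
#' @export
setMethod("scoreBreakdown", "RepeatCandidate", function(x) {
  c(x@scoreTerms, S_repeat = unname(sum(x@scoreTerms)))
})

#' @describeIn CandidatePool Candidate table.
#' @param x Object.
#' @export
setMethod("candidates", "CandidatePool", function(x) x@candidates)

#' @describeIn CandidatePool Current pool threshold T.
#' @export
setMethod("poolThresholdValue", "CandidatePool", function(x) x@threshold)

#' @describeIn DomainModel Repeat table of the domain.
#' @param x Object.
#' @export
setMethod("repeatTable", "DomainModel", function(x) x@repeats)

#' @describeIn DomainModel Number of repeats.
#' @export
setMethod("nRepeats", "DomainModel", function(x) nrow(x@repeats))

#' @describeIn ClassificationReport Verdict string.
#' @param x Object.
#' @export
setMethod("verdict", "ClassificationReport", function(x) x@verdict)

#' @describeIn ClassificationReport Reported domains.
#' @export
setMethod("domains", "ClassificationReport", function(x) x@domains)

#' @describeIn ClassificationReport Domain count from the counting rule.
#' @export
setMethod("nDomains", "ClassificationReport", function(x) x@nDomains)

#' @describeIn ClassificationReport Whether a full DHSW tetrad was found.
#' @export
setMethod("tetradFound", "ClassificationReport", function(x) x@tetradFound)

#' @describeIn ClassificationReport Per-residue secondary-structure string.
#' @export
setMethod("ssString", "ClassificationReport", function(x) x@ss)

#' @describeIn ClassificationReport Average repeat score per reported domain.
#' @export
setMethod("asrScores", "ClassificationReport", function(x) x@asr)

setMethod("show", "RepeatProfile", function(object) {
  cat("RepeatProfile:", object@nRepeats, "training repeats;",
      length(object@weights), "scored positions\n")
  cat("  weight mode:", object@meta$weight_mode %||% "content",
      "| regulator:", object@regulator$use, "\n")
  cat("  provenance:", object@meta$provenance %||% "(none)", "\n")
})

setMethod("show", "RepeatCandidate", function(object) {
  sp <- candidateSpan(object@start, object@loopLengths)
  cat(sprintf("RepeatCandidate %s [%d, %d] (1-based %d-%d) loops (%d,%d,%d)\n",
              object@sequenceId, sp[1], sp[2], sp[1] + 1L, sp[2],
              object@loopLengths[["l_da"]], object@loopLengths[["l_ab"]],
              object@loopLengths[["l_bc"]]))
  if (!anyNA(object@scoreTerms))
    cat("  S_repeat =", num4(sum(object@scoreTerms)), " (",
        paste(names(object@scoreTerms), num4(object@scoreTerms),
              sep = "=", collapse = ", "), ")\n")
})

setMethod("show", "CandidatePool", function(object) {
  df <- object@candidates
  cat(sprintf("CandidatePool on %s: %d candidates", object@sequenceId,
              nrow(df)))
  if (nrow(df)) cat(sprintf(", S_max = %s", num4(max(df$S_repeat))))
  if (!is.na(object@threshold))
    cat(sprintf(", T = %s", num4(object@threshold)))
  cat("\n")
})

setMethod("show", "DomainModel", function(object) {
  cat(sprintf("DomainModel on %s: %d repeats, S_domain = %s\n",
              object@sequenceId, nrow(object@repeats), num4(object@score)))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport %s (%d aa): %s\n", object@sequenceId,
              object@sequenceLength, object@verdict))
  cat(sprintf("  domains: %d reported (counting rule: %d); tetrad: %s%s\n",
              length(object@domains), object@nDomains,
              if (object@tetradFound) "yes" else "no",
              if (object@earlyExit) "; early exit" else ""))
  if (length(object@asr))
    cat("  ASr:", paste(num4(object@asr), collapse = ", "), "\n")
})
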