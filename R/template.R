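# Canonical WD40 repeat geometry.
#
# A sequence repeat is Sd-Lda-Sa-Lab-Sb-Lbc-Sc: four six-residue beta-strands
# separated by three variable loops. The loop Lcd between consecutive repeats
# belongs to the domain, not to either repeat. 31 positions are scored by the
# residue profile: all 24 strand positions plus the conserved loop positions
# Lda2, Lda3, Lab1-Lab4 and Lbc3 (numbered within each loop from its N-end).

#' @rdname template
#' @export
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

STRAND_LENGTH <- 6L
TEMPLATE_ELEMENTS <- c("Sd", "Lda", "Sa", "Lab", "Sb", "Lbc", "Sc")
STRAND_ELEMENTS <- c("Sd", "Sa", "Sb", "Sc")

# Modal template used when loop positions must be guessed without an
# assembled repeat (e.g. the Lcd2 tetrad slot of a standalone candidate).
MODAL_LOOPS <- c(l_da = 6L, l_ab = 4L, l_bc = 4L, l_cd = 4L)

#' Scored positions of the WD40 repeat template
#'
#' Returns the 31 position identifiers scored by the residue profile, in
#' template order: the 24 strand positions (strand length is fixed at six
#' residues) and the seven conserved loop positions.
#'
#' @return Character vector of 31 position identifiers such as \code{"Sd1"},
#'   \code{"Lda2"}, \code{"Lab4"}.
#' @examples
#' length(scoredPositions())  # 31
#' @rdname template
#' @export
scoredPositions <- function() {
  c(paste0("Sd", 1:6), paste0("Lda", 2:3), paste0("Sa", 1:6),
    paste0("Lab", 1:4), paste0("Sb", 1:6), "Lbc3", paste0("Sc", 1:6))
}

#' Default loop-length enumeration bounds
#'
#' Candidate enumeration considers loop lengths within these bounds. The
#' within-repeat loops are capped at 15 residues (the training procedure
#' discards longer loops as statistically unreliable); the inter-repeat Lcd
#' loop may be longer but is increasingly penalised.
#'
#' @return Named list of \code{c(min, max)} integer pairs for \code{l_da},
#'   \code{l_ab}, \code{l_bc} and \code{l_cd}.
#' @export
defaultLoopBounds <- function() {
  list(l_da = c(1L, 15L), l_ab = c(1L, 15L), l_bc = c(1L, 15L),
       l_cd = c(0L, 25L))
}

.checkLoops <- function(loopLengths) {
  need <- c("l_da", "l_ab", "l_bc")
  if (!all(need %in% names(loopLengths)))
    stop("loopLengths must name l_da, l_ab and l_bc")
  ll <- vapply(loopLengths[need], as.integer, integer(1))
  if (any(ll < 0L)) stop("loop lengths must be non-negative")
  ll
}

# Element lengths, in template order, for given loop lengths.
.elementLengths <- function(loopLengths) {
  ll <- .checkLoops(loopLengths)
  c(Sd = STRAND_LENGTH, Lda = ll[["l_da"]], Sa = STRAND_LENGTH,
    Lab = ll[["l_ab"]], Sb = STRAND_LENGTH, Lbc = ll[["l_bc"]],
    Sc = STRAND_LENGTH)
}

#' Map a within-repeat offset to its template position
#'
#' @param repeatOffset 0-based residue offset from the first residue of Sd.
#' @param loopLengths Named vector/list with \code{l_da}, \code{l_ab},
#'   \code{l_bc}.
#' @return A list with \code{element} (one of Sd, Lda, Sa, Lab, Sb, Lbc, Sc)
#'   and 1-based \code{index} within that element.
#' @examples
#' templatePositionOf(0, c(l_da = 6, l_ab = 4, l_bc = 4))  # Sd, 1
#' @export
templatePositionOf <- function(repeatOffset, loopLengths) {
  lens <- .elementLengths(loopLengths)
  total <- sum(lens)
  repeatOffset <- as.integer(repeatOffset)
  if (repeatOffset < 0L || repeatOffset >= total)
    stop(sprintf("offset %d outside repeat of length %d", repeatOffset, total))
  ends <- cumsum(lens)
  el <- which(repeatOffset < ends)[1]
  start <- c(0L, unname(ends))[el]
  list(element = names(lens)[el],
       index = as.integer(repeatOffset - start + 1L))
}

#' Inverse of \code{templatePositionOf}
#'
#' @param element Template element name.
#' @param index 1-based position within the element.
#' @inheritParams templatePositionOf
#' @return 0-based offset from the repeat start.
#' @export
templateOffsetOf <- function(element, index, loopLengths) {
  lens <- .elementLengths(loopLengths)
  if (!element %in% names(lens)) stop("unknown template element: ", element)
  index <- as.integer(index)
  if (index < 1L || index > lens[[element]])
    stop(sprintf("index %d outside element %s (length %d)",
                 index, element, lens[[element]]))
  starts <- c(0L, cumsum(lens))[seq_along(lens)]
  names(starts) <- names(lens)
  starts[[element]] + index - 1L
}

#' Residue span of a repeat candidate
#'
#' @param start 0-based index of the first residue (Sd1).
#' @inheritParams templatePositionOf
#' @return \code{c(start, end)}, a 0-based half-open interval; \code{end -
#'   start} is \code{24 + l_da + l_ab + l_bc}.
#' @examples
#' candidateSpan(0, c(l_da = 6, l_ab = 4, l_bc = 4))  # c(0, 38)
#' @export
candidateSpan <- function(start, loopLengths) {
  start <- as.integer(start)
  if (start < 0L) stop("negative start")
  ll <- .checkLoops(loopLengths)
  c(start, start + 4L * STRAND_LENGTH + sum(ll))
}

# 0-based offsets (from the candidate start) of the 31 scored positions for
# given loop lengths. A scored loop position that the loop is too short to
# hold is NA: it contributes background (zero log-odds) to the score.
# Loop positions are N-anchored: loop index i sits i-1 residues after the
# loop start, for every loop length.
scoredOffsets <- function(loopLengths) {
  ll <- .checkLoops(loopLengths)
  lda <- ll[["l_da"]]; lab <- ll[["l_ab"]]; lbc <- ll[["l_bc"]]
  off <- c(
    setNames(0:5, paste0("Sd", 1:6)),
    Lda2 = if (lda >= 2L) 7L else NA_integer_,
    Lda3 = if (lda >= 3L) 8L else NA_integer_,
    setNames(6L + lda + 0:5, paste0("Sa", 1:6)),
    setNames(ifelse(lab >= 1:4, 12L + lda + 0:3, NA_integer_),
             paste0("Lab", 1:4)),
    setNames(12L + lda + lab + 0:5, paste0("Sb", 1:6)),
    Lbc3 = if (lbc >= 3L) 18L + lda + lab + 2L else NA_integer_,
    setNames(18L + lda + lab + lbc + 0:5, paste0("Sc", 1:6))
  )
  off[scoredPositions()]
}

# 0-based start offsets of the four strands, from the candidate start.
strandOffsets <- function(loopLengths) {
  ll <- .checkLoops(loopLengths)
  c(Sd = 0L,
    Sa = 6L + ll[["l_da"]],
    Sb = 12L + ll[["l_da"]] + ll[["l_ab"]],
    Sc = 18L + ll[["l_da"]] + ll[["l_ab"]] + ll[["l_bc"]])
}
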