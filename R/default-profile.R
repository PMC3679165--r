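# Construction of the packaged default profile.
#
# The profile encodes the conserved-position preferences of the WD40 repeat
# family. Positions whose marginal residue frequencies have been published
# from structure-anchored alignments carry those values exactly (Sa1, Sa4
# and Sa6; Sc2 and Sc4; the Pro preference at Lab2 and at Lda6-equivalents;
# the Ser/Thr tetrad slots at Sb4/Sc1; the Trp-Asp dipeptide closing Sc; the
# Gly-His region of Lda; the beta-bulge X slot at Sb5). All remaining
# entries are in-house consensus choices: each position lists its dominant
# residues, the residual mass goes to a restricted set of chemically
# compatible residues (proportionally to background), and every other
# residue keeps a small floor. The profile is therefore a synthetic
# reconstruction, not a transcription of a published table, and is labelled
# as such in its provenance and file name. The overall conservation level
# was calibrated once so that repeats sampled from the profile score in the
# published S_repeat range (30-150, about 100 on average, natural-log
# scale), to which the pipeline's threshold constants (10/35/45/48) are
# calibrated.

# Per scored position: `top` = dominant residue frequencies; `rest` =
# residues sharing the residual mass proportionally to background.
.DEFAULT_POSITION_SPECS <- list(
  Sd1 = list(top = c(K = .22, E = .19, T = .16, S = .14, Q = .10, N = .08),
             rest = c("R", "D", "A")),
  Sd2 = list(top = c(L = .34, I = .27, V = .22, F = .08),
             rest = c("M", "A")),
  Sd3 = list(top = c(L = .34, I = .26, V = .20, F = .11),
             rest = c("M", "W", "Y")),
  Sd4 = list(top = c(L = .32, V = .26, I = .22, T = .08),
             rest = c("M", "F", "A")),
  Sd5 = list(top = c(R = .18, K = .16, T = .14, S = .13, E = .12, Q = .10),
             rest = c("N", "D", "A")),
  Sd6 = list(top = c(L = .33, I = .26, V = .21, F = .09),
             rest = c("M", "A", "C")),
  Lda2 = list(top = c(G = .70, A = .10, S = .07, D = .05),
              rest = c("N", "E", "T")),
  Lda3 = list(top = c(H = .62, G = .10, S = .08, N = .07),
              rest = c("Q", "T", "A")),
  Sa1 = list(top = c(V = .492, I = .290, L = .063, M = .06, T = .05),
             rest = c("A", "F", "C")),
  Sa2 = list(top = c(K = .19, R = .16, T = .14, S = .13, E = .11, Q = .09),
             rest = c("N", "D", "A")),
  Sa3 = list(top = c(T = .24, S = .20, V = .17, I = .13, A = .11),
             rest = c("C", "L", "N")),
  Sa4 = list(top = c(V = .356, L = .238, I = .142, M = .08, F = .07),
             rest = c("A", "T", "C")),
  Sa5 = list(top = c(S = .26, T = .21, A = .16, N = .12, D = .10),
             rest = c("G", "C", "E")),
  Sa6 = list(top = c(F = .301, W = .276, Y = .084, L = .10, I = .08),
             rest = c("V", "M", "C")),
  Lab1 = list(top = c(S = .24, D = .20, N = .16, G = .14, T = .11),
              rest = c("E", "A", "Q")),
  Lab2 = list(top = c(P = .396, A = .14, S = .11, G = .09),
              rest = c("T", "D", "N")),
  Lab3 = list(top = c(D = .25, N = .18, S = .15, G = .13, E = .10),
              rest = c("T", "A", "Q")),
  Lab4 = list(top = c(G = .28, A = .19, S = .16, T = .12, D = .09),
              rest = c("N", "E", "P")),
  Sb1 = list(top = c(K = .18, R = .15, E = .13, T = .12, S = .11, V = .09),
             rest = c("Q", "N", "I")),
  Sb2 = list(top = c(L = .33, I = .26, V = .21, A = .08),
             rest = c("M", "F", "C")),
  Sb3 = list(top = c(A = .25, V = .21, I = .17, L = .14, C = .09),
             rest = c("T", "S", "M")),
  Sb4 = list(top = c(S = .44, T = .36, A = .08, C = .04),
             rest = c("G", "N", "V")),
  Sb5 = list(top = c(G = .48, A = .24, S = .15, C = .07),
             rest = c("T", "N", "D")),
  Sb6 = list(top = c(S = .28, G = .24, T = .20, D = .16),
             rest = c("N", "A", "E")),
  Lbc3 = list(top = c(D = .25, G = .20, N = .16, S = .14, T = .10),
              rest = c("E", "A", "K")),
  Sc1 = list(top = c(S = .42, T = .33, A = .09, C = .05),
             rest = c("G", "N", "V")),
  Sc2 = list(top = c(I = .339, V = .293, L = .184, M = .07, F = .06),
             rest = c("A", "T", "C")),
  Sc3 = list(top = c(A = .24, S = .20, T = .16, G = .14, C = .09),
             rest = c("V", "N", "D")),
  Sc4 = list(top = c(V = .297, I = .268, L = .238, M = .07, F = .06),
             rest = c("A", "C", "T")),
  Sc5 = list(top = c(W = .72, F = .12, Y = .08),
             rest = c("L", "C", "H")),
  Sc6 = list(top = c(D = .56, N = .15, E = .11, S = .07),
             rest = c("G", "T", "Q"))
)

# Floor frequency kept by residues outside a position's top + rest sets.
.DEFAULT_FLOOR <- 0.001

# Loop-length pseudo-counts the default loop score tables are fitted from:
# unimodal distributions with modes at the modal template lengths
# (l_da = 6, l_ab = l_bc = 4, l_cd = 4) and tails thinning towards the caps.
.DEFAULT_LOOP_COUNTS <- list(
  l_da = setNames(c(2, 4, 10, 30, 60, 90, 60, 30, 14, 6, 3, 2, 1, 1, 1),
                  1:15),
  l_ab = setNames(c(5, 25, 70, 100, 45, 18, 7, 3, 2, 1, 1, 1, 1, 1, 1),
                  1:15),
  l_bc = setNames(c(4, 20, 60, 100, 50, 20, 8, 4, 2, 1, 1, 1, 1, 1, 1),
                  1:15),
  l_cd = setNames(c(2, 5, 15, 40, 80, 60, 35, 20, 12, 8, 6, 4, 3, 2, 2, 1,
                    1, 1, 1, 1, 1, 1, 1, 1, 1, 1), 0:25)
)

#' Build the default profile from its in-code specification
#'
#' Constructs the packaged profile deterministically: per-position dominant
#' residue frequencies (published marginals where available, consensus
#' choices elsewhere), with the residual mass restricted to chemically
#' compatible residues and a small floor everywhere else;
#' information-content weights; loop-length score tables fitted from the
#' modal loop-length distributions (penalty slope 2 for the within-repeat
#' loops and 0.8 for the more tolerant inter-repeat Lcd linker); tetrad
#' motif probabilities of 0.40 / 0.55 / 0.70 for pentad / tetrad / triad;
#' and the two regulator tables. The packaged file is this object
#' serialized; [defaultProfile()] reads that file.
#'
#' @param background Background amino-acid frequencies.
#' @return A [RepeatProfile].
#' @export
makeDefaultProfile <- function(background = defaultBackground()) {
  sp <- scoredPositions()
  P <- matrix(0, length(sp), 20, dimnames = list(sp, AA20))
  for (k in sp) {
    spec <- .DEFAULT_POSITION_SPECS[[k]]
    others <- setdiff(AA20, c(names(spec$top), spec$rest))
    rem <- 1 - sum(spec$top) - .DEFAULT_FLOOR * length(others)
    stopifnot(rem > 0)
    P[k, names(spec$top)] <- spec$top
    P[k, spec$rest] <- background[spec$rest] / sum(background[spec$rest]) *
      rem
    P[k, others] <- .DEFAULT_FLOOR
  }
  w <- vapply(sp, function(k) positionWeight(P[k, ]), numeric(1))

  bounds <- defaultLoopBounds()
  slopes <- c(l_da = 2, l_ab = 2, l_bc = 2, l_cd = 0.8)
  loopScores <- lapply(names(.DEFAULT_LOOP_COUNTS), function(nm)
    fitLoopScores(.DEFAULT_LOOP_COUNTS[[nm]], bounds[[nm]],
                  t = slopes[[nm]]))
  names(loopScores) <- names(.DEFAULT_LOOP_COUNTS)

  new("RepeatProfile",
      frequencies = P,
      counts = matrix(0, length(sp), 20, dimnames = list(sp, AA20)),
      nRepeats = 0L,
      weights = w,
      background = background[AA20] / sum(background[AA20]),
      loopScores = loopScores,
      tetrad = tetradProbabilities(0.40, 0.55, 0.70, background),
      regulator = makeRegulator(),
      meta = list(format = .PROFILE_FORMAT,
                  provenance = paste(
                    "synthetic default profile: published marginal",
                    "frequencies at documented positions, consensus",
                    "elsewhere; background-filled; see makeDefaultProfile()"),
                  weight_mode = "content"))
}
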