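# Profile training from annotated repeat alignments.
#
# Training consumes repeats whose four six-residue strands have been assigned
# from structural landmarks (the beta-bulge R1/R2 residues and the DHSW
# tetrad members). Strand columns are aligned exactly; loop residues are
# assigned to loop positions N-anchored (loop index i = i-th residue after
# the loop start), which makes loop column assignment deterministic, so no
# substitution-matrix alignment step is required. Loops longer than 15
# residues are excluded from loop column statistics.

# Swiss-Prot-style amino-acid composition for eukaryotic proteins, used as
# the default background P_all (overridable everywhere it is consumed).
.BG_EUK <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0228, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292
)
.BG_EUK <- .BG_EUK[AA20] / sum(.BG_EUK)

#' Default background amino-acid frequencies
#'
#' Amino-acid composition of eukaryotic proteins (Swiss-Prot release
#' statistics, renormalised over the 20 standard residues). Used as
#' \code{P_all} in the log-odds score wherever no custom background is given.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
defaultBackground <- function() .BG_EUK

# Tetrad slot definitions: residue classes required at the five pentad
# positions Sc1, Lcd2, Lda3, Sb4, Sc5 (S stands for Ser/Thr).
.TETRAD_SLOTS <- list(
  Sc1  = c("S", "T"),
  Lcd2 = "D",
  Lda3 = "H",
  Sb4  = c("S", "T"),
  Sc5  = "W"
)

#' Validate and align annotated WD40 repeats
#'
#' Takes a table of annotated repeats (one row per repeat: \code{source_id},
#' \code{sequence}, and 0-based strand starts \code{sd_start},
#' \code{sa_start}, \code{sb_start}, \code{sc_start}) and produces the
#' position-keyed alignment used for frequency estimation, together with the
#' observed loop lengths and tetrad-slot residues.
#'
#' Strand columns contain exactly the annotated strand residues. Loop
#' residues are assigned to loop positions N-anchored; loops longer than
#' \code{maxLoop} residues are excluded from loop column statistics. Lcd loop
#' lengths are collected from gaps between consecutive repeats of the same
#' source sequence. The Lcd2 tetrad slot of a repeat is read from its actual
#' preceding-repeat context when available and from the modal-loop fallback
#' position (3 residues before Sd1) otherwise.
#'
#' @param repeats data.frame of annotated repeats as above (see
#'   [readAnnotatedRepeats()] for the on-disk format).
#' @param maxLoop Loops longer than this are dropped from loop columns
#'   (default 15).
#' @return A list with \code{columns} (named list, scored position ->
#'   residue vector), \code{loops} (data.frame \code{l_da}, \code{l_ab},
#'   \code{l_bc}), \code{lcd} (observed Lcd lengths), \code{tetradSlots}
#'   (data.frame of slot residues per repeat) and \code{n}.
#' @export
alignAnnotatedRepeats <- function(repeats, maxLoop = 15L) {
  need <- c("source_id", "sequence", "sd_start", "sa_start", "sb_start",
            "sc_start")
  if (!is.data.frame(repeats) || !all(need %in% names(repeats)))
    stop("repeats must be a data.frame with columns ",
         paste(need, collapse = ", "))
  n <- nrow(repeats)
  if (n < 2L) stop("need at least 2 annotated repeats")

  res <- strsplit(toupper(repeats$sequence), "")
  starts <- as.matrix(repeats[, c("sd_start", "sa_start", "sb_start",
                                  "sc_start")])
  storage.mode(starts) <- "integer"

  for (i in seq_len(n)) {
    s <- starts[i, ]
    bad <- anyNA(s) || any(s < 0L) ||
      any(diff(s) < STRAND_LENGTH) ||
      s[4] + STRAND_LENGTH > length(res[[i]])
    if (bad)
      stop(sprintf("repeat %d (%s): malformed strand annotation", i,
                   repeats$source_id[i]))
  }

  loops <- data.frame(
    l_da = starts[, 2] - (starts[, 1] + STRAND_LENGTH),
    l_ab = starts[, 3] - (starts[, 2] + STRAND_LENGTH),
    l_bc = starts[, 4] - (starts[, 3] + STRAND_LENGTH)
  )

  cols <- setNames(vector("list", length(scoredPositions())),
                   scoredPositions())
  for (k in scoredPositions()) cols[[k]] <- character(0)

  loopStart <- function(i, loop) {
    switch(loop,
           Lda = starts[i, 1] + STRAND_LENGTH,
           Lab = starts[i, 2] + STRAND_LENGTH,
           Lbc = starts[i, 3] + STRAND_LENGTH)
  }
  loopLen <- function(i, loop) {
    switch(loop, Lda = loops$l_da[i], Lab = loops$l_ab[i],
           Lbc = loops$l_bc[i])
  }

  for (i in seq_len(n)) {
    r <- res[[i]]
    for (s in seq_along(STRAND_ELEMENTS)) {
      el <- STRAND_ELEMENTS[s]
      for (j in seq_len(STRAND_LENGTH)) {
        key <- paste0(el, j)
        cols[[key]] <- c(cols[[key]], r[starts[i, s] + j])
      }
    }
    for (spec in list(c("Lda", 2L), c("Lda", 3L), c("Lab", 1L),
                      c("Lab", 2L), c("Lab", 3L), c("Lab", 4L),
                      c("Lbc", 3L))) {
      loop <- spec[1]; idx <- as.integer(spec[2])
      len <- loopLen(i, loop)
      if (len > maxLoop || len < idx) next
      key <- paste0(loop, idx)
      cols[[key]] <- c(cols[[key]], r[loopStart(i, loop) + idx])
    }
  }

  # Lcd lengths and tetrad slots, using same-source adjacency.
  lcd <- integer(0)
  slotMat <- matrix(NA_character_, n, 5,
                    dimnames = list(NULL, names(.TETRAD_SLOTS)))
  ord <- order(repeats$source_id, starts[, 1])
  prevEnd <- rep(NA_integer_, n)
  for (j in seq_along(ord)[-1]) {
    i <- ord[j]; p <- ord[j - 1L]
    if (repeats$source_id[i] == repeats$source_id[p] &&
        identical(repeats$sequence[i], repeats$sequence[p])) {
      gap <- unname(starts[i, 1] - (starts[p, 4] + STRAND_LENGTH))
      if (gap >= 0L) {
        lcd <- c(lcd, gap)
        prevEnd[i] <- starts[p, 4] + STRAND_LENGTH
      }
    }
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    at <- function(pos0) if (pos0 >= 0L && pos0 < length(r)) r[pos0 + 1L]
      else NA_character_
    lcd2 <- if (!is.na(prevEnd[i])) at(prevEnd[i] + 1L)
      else at(starts[i, 1] - 3L)
    slotMat[i, ] <- c(at(starts[i, 4]),                 # Sc1
                      lcd2,                             # Lcd2
                      at(starts[i, 1] + STRAND_LENGTH + 2L),  # Lda3
                      at(starts[i, 3] + 3L),            # Sb4
                      at(starts[i, 4] + 4L))            # Sc5
  }

  list(columns = cols, loops = loops, lcd = lcd,
       tetradSlots = as.data.frame(slotMat), n = n)
}

#' Estimate per-position residue frequencies
#'
#' Turns alignment columns into a frequency matrix with a pseudo-count added
#' to every residue count. A scored loop column with no observations (every
#' loop shorter than the position) is set to the background distribution so
#' that it contributes zero log-odds.
#'
#' @param alignment Result of [alignAnnotatedRepeats()].
#' @param pseudoCount Pseudo-count added to every residue frequency
#'   (default 0.0001).
#' @param background Background distribution for empty columns (default
#'   [defaultBackground()]).
#' @return List with \code{P} (31 x 20 frequency matrix), \code{counts} and
#'   \code{nRepeats}.
#' @export
estimateFrequencies <- function(alignment, pseudoCount = 1e-4,
                                background = defaultBackground()) {
  cols <- alignment$columns
  if (is.null(cols) || length(cols) == 0L) stop("empty alignment")
  sp <- scoredPositions()
  counts <- matrix(0, length(sp), 20, dimnames = list(sp, AA20))
  P <- counts
  for (k in sp) {
    obs <- cols[[k]]
    obs <- obs[obs %in% AA20]
    if (length(obs) == 0L) {
      P[k, ] <- background
      next
    }
    cnt <- table(factor(obs, levels = AA20))
    counts[k, ] <- as.numeric(cnt)
    P[k, ] <- (counts[k, ] + pseudoCount) /
      (sum(counts[k, ]) + 20 * pseudoCount)
  }
  list(P = P, counts = counts, nRepeats = alignment$n)
}

#' Per-position conservation weight
#'
#' The weight of a scored position is, by default, its information content
#' \eqn{w_k = \log_2 20 - H_k} with \eqn{H_k = -\sum_i P_k(i) \log_2 P_k(i)},
#' so fully conserved positions get the maximal weight
#' \eqn{\log_2 20 \approx 4.32} and uniform positions get 0. A raw-entropy
#' mode (\eqn{w_k = H_k}) is available for comparison.
#'
#' @param p Numeric probability vector over residues (normalised).
#' @param mode \code{"content"} (default) or \code{"entropy"}.
#' @return Non-negative weight in bits.
#' @export
positionWeight <- function(p, mode = c("content", "entropy")) {
  mode <- match.arg(mode)
  p <- p[p > 0]
  H <- -sum(p * log2(p))
  if (mode == "content") max(0, log2(20) - H) else H
}

#' Fit a loop-length score table
#'
#' Builds the score \eqn{S(l)} over a bounded loop-length range from observed
#' loop lengths. The documented procedure is:
#' \enumerate{
#'   \item add a pseudo-count (default 0.01) to the count of every length in
#'     the range and normalise to probabilities \eqn{P(l)};
#'   \item smooth \eqn{P(l)} with a centred 3-point moving average;
#'   \item least-squares fit a quadratic in \eqn{l} to \eqn{\log P_s(l)},
#'     weighting each length by \eqn{P_s(l)} so the fit tracks the
#'     well-populated lengths rather than the sparse tail;
#'   \item set the fitted score \eqn{S^*(l)} to the fitted curve plus
#'     \eqn{\log K} (log-odds against the uniform length distribution over
#'     the \eqn{K} lengths in range);
#'   \item \eqn{l_0} is the first length beyond the mode where
#'     \eqn{S^*(l) < 1}; for \eqn{l \le l_0}, \eqn{S(l) = S^*(l)};
#'   \item beyond \eqn{l_0} a linear penalty \eqn{S(l) = 1 - t (l - l_0)}
#'     takes over, blended with the fitted curve over a window of width
#'     \eqn{t_0}; a monotonicity guard keeps \eqn{S} strictly decreasing
#'     past \eqn{l_0}.
#' }
#'
#' @param lengths Integer vector of observed loop lengths (observations
#'   outside \code{bounds} are ignored), or a named numeric vector of counts
#'   (names = lengths).
#' @param bounds \code{c(min, max)} lengths the table must cover.
#' @param pseudoCount Pseudo-count added to every length frequency
#'   (default 0.01).
#' @param t Slope of the long-loop linear penalty (score units per residue).
#' @param t0 Width of the transition window between fitted curve and linear
#'   penalty.
#' @return List with \code{table} (data.frame \code{l}, \code{score}),
#'   \code{t}, \code{t0}, \code{l0}.
#' @export
fitLoopScores <- function(lengths, bounds, pseudoCount = 0.01, t = 2,
                          t0 = 1) {
  ls <- seq.int(bounds[1], bounds[2])
  K <- length(ls)
  if (!is.null(names(lengths))) {
    cnt <- setNames(rep(0, K), ls)
    keep <- names(lengths)[as.integer(names(lengths)) %in% ls]
    cnt[keep] <- as.numeric(lengths[keep])
  } else {
    lengths <- lengths[lengths >= bounds[1] & lengths <= bounds[2]]
    cnt <- as.numeric(table(factor(lengths, levels = ls)))
  }
  if (sum(cnt) == 0) stop("no loop-length observations within bounds")

  p <- (cnt + pseudoCount) / sum(cnt + pseudoCount)
  ps <- vapply(seq_len(K), function(i) {
    w <- max(1, i - 1):min(K, i + 1)
    mean(p[w])
  }, numeric(1))
  g <- log(ps)
  fit <- lm(g ~ ls + I(ls^2), weights = ps)
  sFit <- as.numeric(predict(fit)) + log(K)

  mode <- ls[which.max(sFit)]
  beyond <- ls > mode & sFit < 1
  l0 <- if (any(beyond)) ls[which(beyond)[1]] else max(ls)

  score <- sFit
  over <- ls > l0
  if (any(over)) {
    w <- pmin(1, (ls[over] - l0) / max(t0, 1e-9))
    lin <- 1 - t * (ls[over] - l0)
    score[over] <- (1 - w) * sFit[over] + w * lin
    # guard: strictly decreasing past l0
    idx <- which(over)
    for (i in idx) {
      if (score[i] >= score[i - 1L]) score[i] <- score[i - 1L] - 1e-6
    }
  }
  list(table = data.frame(l = ls, score = score), t = t, t0 = t0, l0 = l0)
}

# Score of one loop length under a fitted table, with linear-penalty
# extrapolation outside the table domain.
loopScore <- function(len, loopFit, warn = TRUE) {
  tab <- loopFit$table
  hit <- match(len, tab$l)
  out <- !is.na(len) & is.na(hit)
  sc <- tab$score[hit]
  if (any(out)) {
    if (warn) psLog("warn", "loop length outside score table; extrapolating")
    below <- out & len < tab$l[1]
    above <- out & len > tab$l[nrow(tab)]
    sc[below] <- tab$score[1] - loopFit$t * (tab$l[1] - len[below])
    sc[above] <- tab$score[nrow(tab)] -
      loopFit$t * (len[above] - tab$l[nrow(tab)])
  }
  sc
}

#' Estimate the tetrad model
#'
#' Counts, over the aligned repeats, how often the pentad (Ser/Thr, Asp, His,
#' Ser/Thr, Trp at positions Sc1, Lcd2, Lda3, Sb4, Sc5), the DHSW tetrad
#' (the last four) and the DHS triad (Asp, His, Ser/Thr) occur, and converts
#' the pseudo-counted probabilities into log-odds bonuses against the
#' probability of the motif arising independently under the background
#' composition.
#'
#' @param alignment Result of [alignAnnotatedRepeats()].
#' @param background Background residue frequencies.
#' @param pseudoCount Pseudo-count on motif counts (default 0.01).
#' @return List with probabilities \code{pPentad}, \code{pTetrad},
#'   \code{pTriad} and bonuses \code{bonusPentad}, \code{bonusTetrad},
#'   \code{bonusTriad}.
#' @export
estimateTetradModel <- function(alignment, background = defaultBackground(),
                                pseudoCount = 0.01) {
  slots <- alignment$tetradSlots
  n <- nrow(slots)
  inClass <- function(col, cls) !is.na(slots[[col]]) & slots[[col]] %in% cls
  m <- mapply(inClass, names(.TETRAD_SLOTS), .TETRAD_SLOTS)
  triad  <- m[, "Lcd2"] & m[, "Lda3"] & m[, "Sb4"]
  tetrad <- triad & m[, "Sc5"]
  pentad <- tetrad & m[, "Sc1"]
  pr <- function(k) (sum(k) + pseudoCount) / (n + 2 * pseudoCount)
  tetradProbabilities(pPentad = pr(pentad), pTetrad = pr(tetrad),
                      pTriad = pr(triad), background = background)
}

# Assemble the tetrad list (probabilities + derived bonuses) from given
# motif probabilities.
tetradProbabilities <- function(pPentad, pTetrad, pTriad,
                                background = defaultBackground()) {
  q <- function(slots) prod(vapply(slots, function(cls)
    sum(background[cls]), numeric(1)))
  qPentad <- q(.TETRAD_SLOTS)
  qTetrad <- q(.TETRAD_SLOTS[-1])
  qTriad  <- q(.TETRAD_SLOTS[2:4])
  list(pPentad = pPentad, pTetrad = pTetrad, pTriad = pTriad,
       bonusPentad = max(0, log(pPentad / qPentad)),
       bonusTetrad = max(0, log(pTetrad / qTetrad)),
       bonusTriad  = max(0, log(pTriad / qTriad)))
}

#' Cosine similarity between two frequency matrices
#'
#' Flattens the position-by-residue entries of both inputs and returns their
#' cosine, \eqn{S_{XY} = \sum_i x_i y_i / (\|X\| \|Y\|)}. For non-negative
#' frequencies the value lies in \eqn{[0, 1]}, and equals 1 exactly when the
#' two distributions are proportional.
#'
#' @param X,Y Numeric matrices or vectors of identical shape, or objects with
#'   a \code{$P} frequency matrix, or [RepeatProfile] objects.
#' @return Cosine similarity in \eqn{[-1, 1]}.
#' @export
similarityCoefficient <- function(X, Y) {
  grab <- function(z) {
    if (is(z, "RepeatProfile")) return(as.numeric(z@frequencies))
    if (is.list(z) && !is.null(z$P)) return(as.numeric(z$P))
    as.numeric(z)
  }
  x <- grab(X); y <- grab(Y)
  if (length(x) != length(y)) stop("inputs must have the same shape")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm input")
  sum(x * y) / (nx * ny)
}

#' Split-half stability of the frequency profile
#'
#' Randomly divides the annotated repeats into two halves, estimates a
#' frequency matrix from each, and records the cosine similarity of the two
#' matrices; repeated \code{nTrials} times with independent random divisions.
#' High values indicate the profile is stable against sampling noise.
#'
#' @param repeats Annotated repeat data.frame (see
#'   [alignAnnotatedRepeats()]).
#' @param nTrials Number of random divisions (default 10).
#' @param seed RNG seed making the divisions reproducible.
#' @param pseudoCount,background Passed to [estimateFrequencies()].
#' @return List with \code{values} (per-trial similarity) and \code{mean}.
#' @export
splitHalfStability <- function(repeats, nTrials = 10L, seed = 1L,
                               pseudoCount = 1e-4,
                               background = defaultBackground()) {
  n <- nrow(repeats)
  if (n < 4L) stop("need at least 4 repeats for a split-half test")
  withSeed(seed, {
    vals <- vapply(seq_len(nTrials), function(trial) {
      idx <- sample.int(n)
      half <- idx[seq_len(floor(n / 2))]
      A <- estimateFrequencies(alignAnnotatedRepeats(repeats[half, ]),
                               pseudoCount, background)
      B <- estimateFrequencies(alignAnnotatedRepeats(repeats[-half, ]),
                               pseudoCount, background)
      similarityCoefficient(A, B)
    }, numeric(1))
    list(values = vals, mean = mean(vals))
  })
}

#' Train a repeat profile from annotated repeats
#'
#' Runs the full training stack: alignment, frequency and weight estimation,
#' loop-length score fitting for the three within-repeat loops and the
#' inter-repeat Lcd loop, tetrad statistics, and regulator construction.
#'
#' @param repeats Annotated repeat data.frame (see
#'   [alignAnnotatedRepeats()]).
#' @param background Background residue frequencies.
#' @param pseudoCount Residue pseudo-count (default 0.0001).
#' @param loopPseudoCount Loop-length pseudo-count (default 0.01).
#' @param t,t0 Long-loop penalty slope and transition width per loop class
#'   (scalars, recycled).
#' @param weightMode \code{"content"} or \code{"entropy"}; see
#'   [positionWeight()].
#' @param bounds Loop-length bounds, as [defaultLoopBounds()].
#' @param provenance Free-text provenance recorded in the profile.
#' @return A [RepeatProfile].
#' @export
trainProfile <- function(repeats, background = defaultBackground(),
                         pseudoCount = 1e-4, loopPseudoCount = 0.01,
                         t = 2, t0 = 1,
                         weightMode = c("content", "entropy"),
                         bounds = defaultLoopBounds(),
                         provenance = "trained from annotated repeats") {
  weightMode <- match.arg(weightMode)
  aln <- alignAnnotatedRepeats(repeats)
  fr <- estimateFrequencies(aln, pseudoCount, background)
  w <- vapply(scoredPositions(), function(k)
    positionWeight(fr$P[k, ], weightMode), numeric(1))
  obs <- list(l_da = aln$loops$l_da, l_ab = aln$loops$l_ab,
              l_bc = aln$loops$l_bc, l_cd = aln$lcd)
  loopScores <- lapply(names(obs), function(nm)
    fitLoopScores(obs[[nm]], bounds[[nm]], loopPseudoCount, t, t0))
  names(loopScores) <- names(obs)
  tet <- estimateTetradModel(aln, background)
  new("RepeatProfile",
      frequencies = fr$P, counts = fr$counts,
      nRepeats = as.integer(fr$nRepeats),
      weights = w, background = background[AA20] / sum(background[AA20]),
      loopScores = loopScores, tetrad = tet,
      regulator = makeRegulator(),
      meta = list(format = "wd40-profile/1", provenance = provenance,
                  weight_mode = weightMode))
}

#' Repeat-count regulator tables
#'
#' Builds both regulator tables: the initial one, a sum of five Gaussians of
#' equal amplitude centred at 7, 14, 21, 28 and 35 repeats, and the modified
#' one, with wider Gaussians and amplitudes decaying with domain count so
#' that near-complete 6/7/8-repeat propellers remain competitive during
#' assembly while the 7-fold peaks stay dominant.
#'
#' @param amplitude Amplitude of the initial Gaussians (default 20).
#' @param sigma Width of the initial Gaussians (default 1).
#' @param use Which table detection uses: \code{"modified"} (default) or
#'   \code{"initial"}.
#' @return List with \code{initial}, \code{modified} (numeric, N = 1..40)
#'   and \code{use}.
#' @export
makeRegulator <- function(amplitude = 20, sigma = 1, use = "modified") {
  N <- 1:40
  centers <- seq(7, 35, by = 7)
  gsum <- function(A, s) {
    rowSums(vapply(seq_along(centers), function(k)
      A[k] * exp(-(N - centers[k])^2 / (2 * s^2)), numeric(length(N))))
  }
  list(initial = gsum(rep(amplitude, 5), sigma),
       modified = gsum(c(20, 18, 16, 14, 12), 1.5),
       use = match.arg(use, c("modified", "initial")))
}
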