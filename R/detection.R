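# Detection pipeline: terminal trimming -> exhaustive candidate enumeration
# -> overlap filter -> early exit -> pool threshold -> domain assembly
# (genetic algorithm, with an exact dynamic-programming oracle) -> restart
# rule -> classification -> secondary-structure emission.

#' Trim helix-rich termini before scanning
#'
#' With an external secondary-structure prediction available, terminal
#' stretches whose 30-residue windows are majority-helix are excluded from
#' the scan (beta-propellers contain no long helices). Interior residues are
#' never removed; without a prediction the full sequence is scanned.
#'
#' @param sequence Residue string.
#' @param ss An [SSPrediction] or NULL.
#' @param windowSize Window length (default 30).
#' @param helixFrac Helix fraction above which a window is trimmed
#'   (default 0.5, strict).
#' @return 0-based half-open interval \code{c(from, to)} to scan.
#' @export
trimTermini <- function(sequence, ss = NULL, windowSize = 30L,
                        helixFrac = 0.5) {
  n <- nchar(sequence)
  if (is.null(ss) || n < windowSize) return(c(0L, n))
  isH <- as.integer(ss@states == "H")
  cs <- c(0L, cumsum(isH))
  winFrac <- function(s) (cs[s + windowSize] - cs[s]) / windowSize
  from <- 0L
  while (from + windowSize <= n && winFrac(from + 1L) > helixFrac)
    from <- from + 1L
  to <- n
  while (to - windowSize >= from && winFrac(to - windowSize + 1L) > helixFrac)
    to <- to - 1L
  if (to < from) to <- from
  if (from > 0L || to < n)
    psLog("info", "trimmed termini: scanning [%d, %d) of %d residues",
          from, to, n)
  c(from, to)
}

# Shift a vector left by k, zero-padding the tail (helper for rolling sums).
.shiftL <- function(x, k) {
  L <- length(x)
  if (k == 0L) x else c(x[(k + 1L):L], rep(0, k))
}

#' Enumerate all repeat candidates above a floor score
#'
#' Exhaustively scores every placement of the repeat template (start and the
#' three loop lengths within bounds) on the scan interval and keeps the
#' candidates with \code{S_repeat} strictly greater than \code{minScore}.
#' The tetrad term of a standalone candidate reads its Lcd2 slot at the
#' modal-loop fallback position before the repeat start.
#'
#' @param sequence Residue string.
#' @param profile A [RepeatProfile].
#' @param ss Optional [SSPrediction].
#' @param minScore Generation floor (default 10; true repeats typically
#'   score 30 to 150).
#' @param bounds Loop-length bounds as [defaultLoopBounds()].
#' @param interval 0-based half-open scan interval (default whole sequence).
#' @param sequenceId Identifier recorded in the pool.
#' @return A [CandidatePool].
#' @export
enumerateCandidates <- function(sequence, profile, ss = NULL, minScore = 10,
                                bounds = defaultLoopBounds(),
                                interval = NULL, sequenceId = "seq") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (is.null(interval)) interval <- c(0L, L)
  from <- interval[1]; to <- interval[2]

  emptyPool <- function() new("CandidatePool",
    candidates = data.frame(start = integer(0), lda = integer(0),
                            lab = integer(0), lbc = integer(0),
                            end = integer(0), S_aa = numeric(0),
                            S_loop = numeric(0), S_corr = numeric(0),
                            S_ss = numeric(0), S_repeat = numeric(0)),
    sequenceId = sequenceId, threshold = NA_real_)
  if (to - from < 24L) return(emptyPool())

  res <- strsplit(sequence, "")[[1]]
  codes <- match(res, AA20)
  lo <- logOddsMatrix(profile)

  # Per-position weighted log-odds vector for each scored template position;
  # non-standard residues contribute zero.
  pv <- lapply(scoredPositions(), function(k) {
    v <- lo[k, codes]
    v[is.na(v)] <- 0
    unname(v)
  })
  names(pv) <- scoredPositions()

  # Rolling 6-residue block sums anchored at each strand start.
  blockSum <- function(el) {
    B <- rep(0, L)
    for (j in 1:6) B <- B + .shiftL(pv[[paste0(el, j)]], j - 1L)
    B
  }
  B <- lapply(setNames(STRAND_ELEMENTS, STRAND_ELEMENTS), blockSum)

  W6 <- NULL
  if (!is.null(ss)) {
    if (length(ss@states) < L)
      stop("secondary-structure prediction shorter than the sequence")
    contrib <- ss@conf[1:L] * .SS_COEF[ss@states[1:L]]
    W6 <- rep(0, L)
    for (j in 1:6) W6 <- W6 + .shiftL(unname(contrib), j - 1L)
  }

  isST <- res %in% c("S", "T"); isD <- res == "D"
  isH <- res == "H"; isW <- res == "W"
  tet <- profile@tetrad

  lsda <- profile@loopScores$l_da$table
  lsab <- profile@loopScores$l_ab$table
  lsbc <- profile@loopScores$l_bc$table
  rng <- function(b) seq.int(b[1], b[2])

  acc <- list(); nacc <- 0L

  # All rolling vectors below are indexed by the 1-based candidate start s,
  # shifted so shared terms are computed once per loop level.
  isDlag <- c(FALSE, FALSE, FALSE, isD)[1:L]      # isD at s - 3
  useSS <- !is.null(W6)
  for (lda in rng(bounds$l_da)) {
    sc_da <- lsda$score[match(lda, lsda$l)]
    if (is.na(sc_da)) next
    t1 <- B$Sd + .shiftL(B$Sa, 6L + lda)
    if (lda >= 2L) t1 <- t1 + .shiftL(pv$Lda2, 7L)
    if (lda >= 3L) t1 <- t1 + .shiftL(pv$Lda3, 8L)
    h1 <- if (lda >= 3L) isDlag & .shiftL(isH, 8L) else rep(FALSE, L)
    w1 <- if (useSS) W6 + .shiftL(W6, 6L + lda) else NULL
    for (lab in rng(bounds$l_ab)) {
      sc_ab <- lsab$score[match(lab, lsab$l)]
      if (is.na(sc_ab)) next
      off2 <- 12L + lda + lab
      t2 <- t1 + .shiftL(B$Sb, off2)
      for (j in 1:4) if (lab >= j)
        t2 <- t2 + .shiftL(pv[[paste0("Lab", j)]], 11L + lda + j)
      triadOK2 <- h1 & .shiftL(isST, off2 + 3L)
      w2 <- if (useSS) w1 + .shiftL(W6, off2) else NULL
      for (lbc in rng(bounds$l_bc)) {
        sc_bc <- lsbc$score[match(lbc, lsbc$l)]
        if (is.na(sc_bc)) next
        span <- 24L + lda + lab + lbc
        lastStart <- to - span          # 0-based
        if (lastStart < from) next
        s <- (from:lastStart) + 1L      # 1-based candidate starts
        offC <- 18L + lda + lab + lbc

        saa <- t2 + .shiftL(B$Sc, offC)
        if (lbc >= 3L) saa <- saa + .shiftL(pv$Lbc3, offC - lbc + 2L)
        saa <- saa[s]

        sloop <- sc_da + sc_ab + sc_bc

        triadOK <- triadOK2[s]
        tetOK <- triadOK & isW[s + offC + 4L]
        penOK <- tetOK & isST[s + offC]
        scorr <- ifelse(penOK, tet$bonusPentad,
                 ifelse(tetOK, tet$bonusTetrad,
                 ifelse(triadOK, tet$bonusTriad, 0)))

        sss <- if (useSS) w2[s] + W6[s + offC] else 0

        tot <- saa + sloop + scorr + sss
        keep <- which(tot > minScore)
        if (length(keep)) {
          nacc <- nacc + 1L
          acc[[nacc]] <- cbind(start = s[keep] - 1L, lda = lda, lab = lab,
                               lbc = lbc, S_aa = saa[keep], S_loop = sloop,
                               S_corr = scorr[keep],
                               S_ss = if (useSS) sss[keep] else 0,
                               S_repeat = tot[keep])
        }
      }
    }
  }

  if (nacc == 0L) return(emptyPool())
  m <- do.call(rbind, acc)
  df <- data.frame(start = as.integer(m[, "start"]),
                   lda = as.integer(m[, "lda"]),
                   lab = as.integer(m[, "lab"]),
                   lbc = as.integer(m[, "lbc"]))
  df$end <- df$start + 24L + df$lda + df$lab + df$lbc
  df$S_aa <- m[, "S_aa"]; df$S_loop <- m[, "S_loop"]
  df$S_corr <- m[, "S_corr"]; df$S_ss <- m[, "S_ss"]
  df$S_repeat <- m[, "S_repeat"]
  df <- df[order(df$start, df$end), ]
  rownames(df) <- NULL
  new("CandidatePool", candidates = df, sequenceId = sequenceId,
      threshold = NA_real_)
}

#' Remove candidates dominated by high-scoring overlaps
#'
#' Processes candidates in descending score order (ties: smaller start, then
#' shorter span) and removes a candidate iff it overlaps an already retained
#' candidate whose \code{S_repeat} exceeds both the dominate floor (default
#' 35) and, strictly, the candidate's own score.
#'
#' @param pool A [CandidatePool].
#' @param dominateScore Score a dominator must exceed (default 35).
#' @return The filtered [CandidatePool].
#' @export
overlapFilter <- function(pool, dominateScore = 35) {
  df <- pool@candidates
  n <- nrow(df)
  if (n <= 1L) return(pool)
  ord <- order(-df$S_repeat, df$start, df$end - df$start)
  keep <- logical(n)
  domStart <- numeric(0); domEnd <- numeric(0); domScore <- numeric(0)
  for (i in ord) {
    dominated <- length(domStart) > 0L &&
      any(domStart < df$end[i] & df$start[i] < domEnd &
          domScore > df$S_repeat[i])
    if (!dominated) {
      keep[i] <- TRUE
      if (df$S_repeat[i] > dominateScore) {
        domStart <- c(domStart, df$start[i])
        domEnd <- c(domEnd, df$end[i])
        domScore <- c(domScore, df$S_repeat[i])
      }
    }
  }
  pool@candidates <- df[keep, , drop = FALSE]
  rownames(pool@candidates) <- NULL
  pool
}

#' Early exit for clear non-WD40 sequences
#'
#' @param pool A [CandidatePool].
#' @param threshold Early-exit score (default 45).
#' @return TRUE iff the pool is empty or its best score is strictly below
#'   the threshold (the sequence is then declared not-WD40 without domain
#'   assembly).
#' @export
earlyExit <- function(pool, threshold = 45) {
  df <- pool@candidates
  exit <- nrow(df) == 0L || max(df$S_repeat) < threshold
  if (exit)
    psLog("info", "early exit: S_max %s < %s",
          if (nrow(df)) num4(max(df$S_repeat)) else "(empty pool)",
          num4(threshold))
  exit
}

#' Pool threshold T
#'
#' Default policy: \code{T = max(floor, median(S_repeat))}, discarding about
#' half of the pool while never dropping below the generation floor. The
#' policy is pluggable.
#'
#' @param pool A [CandidatePool] (non-empty).
#' @param floor Generation floor (default 10).
#' @param policy Function mapping the score vector to T (default median).
#' @return Numeric threshold T.
#' @export
poolThreshold <- function(pool, floor = 10, policy = stats::median) {
  df <- pool@candidates
  if (nrow(df) == 0L) stop("cannot threshold an empty pool")
  max(floor, policy(df$S_repeat))
}

#' Apply a pool threshold
#'
#' @param pool A [CandidatePool].
#' @param T Threshold; candidates with \code{S_repeat < T} are discarded.
#' @return The thresholded pool (threshold recorded).
#' @export
applyPoolThreshold <- function(pool, T) {
  before <- nrow(pool@candidates)
  pool@candidates <- pool@candidates[pool@candidates$S_repeat >= T, ,
                                     drop = FALSE]
  rownames(pool@candidates) <- NULL
  pool@threshold <- T
  psLog("info", "pool threshold T = %s: %d -> %d candidates", num4(T),
        before, nrow(pool@candidates))
  pool
}

# Lcd gap score lookup for all gaps 0..maxGap (linear extrapolation beyond
# the fitted table, no per-call warning).
.lcdGapScores <- function(profile, maxGap) {
  loopScore(0:max(0L, maxGap), profile@loopScores$l_cd, warn = FALSE)
}

# Chain fitness used by both assembly engines: sum of repeat scores, plus
# Lcd gap scores, plus the repeat-count regulator.
.chainFitness <- function(ind, S, st, en, lcdVec, regTab) {
  len <- length(ind)
  if (len == 0L) return(-Inf)
  f <- sum(S[ind])
  if (len > 1L)
    f <- f + sum(lcdVec[st[ind[-1L]] - en[ind[-len]] + 1L])
  f + regTab[min(len, length(regTab))]
}

#' Exact optimal domain by dynamic programming
#'
#' Maximises the regulated domain score over all ordered non-overlapping
#' candidate subsets, by dynamic programming on candidates sorted by end
#' coordinate with a (last candidate x repeat count) state table. Serves as
#' the exact oracle for the genetic algorithm and is available as an
#' assembly engine.
#'
#' @param pool A (thresholded) [CandidatePool].
#' @param profile A [RepeatProfile].
#' @param maxRepeats Cap on the tracked repeat count (default 40, the
#'   regulator range).
#' @return A [DomainModel] with both plain and regulated scores filled;
#'   empty pool gives an empty domain.
#' @export
dpOptimal <- function(pool, profile, maxRepeats = 40L) {
  df <- pool@candidates
  n <- nrow(df)
  if (n == 0L)
    return(new("DomainModel", repeats = df, lcdLengths = integer(0),
               sequenceId = pool@sequenceId, score = 0,
               scoreRegulated = 0))
  ord <- order(df$end, df$start)
  df <- df[ord, , drop = FALSE]
  S <- df$S_repeat; st <- df$start; en <- df$end
  K <- min(n, maxRepeats)
  regTab <- regulatorTable(profile)
  lcdVec <- .lcdGapScores(profile, max(0L, max(st) - min(en)))

  M <- matrix(-Inf, n, K)
  P <- matrix(0L, n, K)
  M[, 1] <- S
  for (j in seq_len(n)) {
    m <- findInterval(st[j], en)   # en sorted: predecessors are a prefix
    if (m == 0L || K == 1L) next
    pred <- seq_len(m)
    gs <- lcdVec[st[j] - en[pred] + 1L]
    cand <- M[pred, seq_len(K - 1L), drop = FALSE] + gs
    cm <- apply(cand, 2, max)
    wm <- apply(cand, 2, which.max)
    ok <- is.finite(cm)
    if (any(ok)) {
      ks <- which(ok) + 1L
      M[j, ks] <- S[j] + cm[ok]
      P[j, ks] <- pred[wm[ok]]
    }
  }

  tot <- sweep(M, 2, regTab[seq_len(K)], "+")
  bestIdx <- which(tot == max(tot), arr.ind = TRUE)[1, ]
  j <- bestIdx[["row"]]; k <- bestIdx[["col"]]
  chain <- integer(k)
  for (q in k:1) { chain[q] <- j; j <- P[j, q] }
  dom <- domainModel(df[chain, , drop = FALSE], pool@sequenceId)
  scoreDomain(dom, profile, useRegulator = TRUE)
}

#' Combine repeats into a domain with a genetic algorithm
#'
#' Individuals are ordered, non-overlapping subsets of the candidate pool;
#' fitness is the regulated domain score. The first generation holds every
#' single repeat as an individual. Operators: mutation (replace one repeat
#' with a compatible alternative, or drop it), crossover (splice two
#' individuals at a random sequence coordinate) and elongation (append a
#' compatible repeat at either end). Each generation the best individual is
#' additionally polished by greedy insertion/deletion. The run converges
#' when the ten best individuals are identical, and is fully reproducible
#' under a fixed seed.
#'
#' @inheritParams dpOptimal
#' @param seed RNG seed.
#' @param popSize Population size (default 200).
#' @param pMutation,pCrossover,pElongation Operator rates (defaults 0.2,
#'   0.5, 0.3).
#' @param maxGenerations Generation cap (default 500).
#' @param eliteK Elite count carried over and used for the convergence test
#'   (default 10).
#' @return A [DomainModel] with both scores filled.
#' @export
gaCombine <- function(pool, profile, seed = 1L, popSize = 200L,
                      pMutation = 0.2, pCrossover = 0.5,
                      pElongation = 0.3, maxGenerations = 500L,
                      eliteK = 10L) {
  df <- pool@candidates
  n <- nrow(df)
  if (n == 0L)
    return(new("DomainModel", repeats = df, lcdLengths = integer(0),
               sequenceId = pool@sequenceId, score = 0,
               scoreRegulated = 0))
  S <- df$S_repeat; st <- df$start; en <- df$end
  regTab <- regulatorTable(profile)
  lcdVec <- .lcdGapScores(profile, max(0L, max(st) - min(en)))
  fitOf <- function(ind) .chainFitness(ind, S, st, en, lcdVec, regTab)
  maxCoord <- max(en)

  # insert candidate c into sorted chain ind if compatible; NULL otherwise
  tryInsert <- function(ind, c) {
    if (c %in% ind) return(NULL)
    p <- sum(st[ind] <= st[c])
    if (p > 0L && en[ind[p]] > st[c]) return(NULL)
    if (p < length(ind) && st[ind[p + 1L]] < en[c]) return(NULL)
    append(ind, c, after = p)
  }

  # greedy local search: insertions, deletions, single-repeat replacements
  # and (on small pools) depth-2 insertions, repeated to a local optimum.
  # Depth-2 moves let a chain absorb a pair of repeats whose first member
  # alone is unprofitable because of the intervening Lcd penalty.
  deepPolish <- n <= 25L
  polish <- function(ind, maxSweeps = 8L) {
    f <- fitOf(ind)
    for (sweep in seq_len(maxSweeps)) {
      improved <- FALSE
      for (c in seq_len(n)) {
        cand <- tryInsert(ind, c)
        if (!is.null(cand)) {
          fc <- fitOf(cand)
          if (fc > f) { ind <- cand; f <- fc; improved <- TRUE }
        }
      }
      q <- 1L
      while (q <= length(ind)) {
        base <- ind[-q]
        fb <- fitOf(base)
        if (fb > f) { ind <- base; f <- fb; improved <- TRUE; next }
        for (c in seq_len(n)) {
          cand <- tryInsert(base, c)
          if (!is.null(cand)) {
            fc <- fitOf(cand)
            if (fc > f) { ind <- cand; f <- fc; improved <- TRUE; break }
          }
        }
        q <- q + 1L
      }
      if (!improved && deepPolish) {
        for (c in seq_len(n)) {
          cand <- tryInsert(ind, c)
          if (is.null(cand)) next
          for (c2 in seq_len(n)) {
            cand2 <- tryInsert(cand, c2)
            if (!is.null(cand2) && fitOf(cand2) > f) {
              ind <- cand2; f <- fitOf(cand2); improved <- TRUE
              break
            }
          }
          if (improved) break
        }
      }
      if (!improved) {
        # nearest-run extension: grow contiguously at either end for up to
        # five repeats, accepting the run if the final chain improves even
        # though intermediate steps may not
        for (front in c(TRUE, FALSE)) {
          chain <- ind
          for (a in seq_len(5L)) {
            if (front) {
              ok <- which(en <= st[chain[1L]])
              if (!length(ok)) break
              pick <- ok[which.min(st[chain[1L]] - en[ok])]
            } else {
              ok <- which(st >= en[chain[length(chain)]])
              if (!length(ok)) break
              pick <- ok[which.min(st[ok] - en[chain[length(chain)]])]
            }
            chain <- sort(c(chain, pick))
            fc <- fitOf(chain)
            if (fc > f) { ind <- chain; f <- fc; improved <- TRUE }
          }
        }
      }
      if (!improved) break
    }
    ind
  }

  withSeed(seed, {
    pop <- lapply(seq_len(n), function(i) i)
    if (length(pop) > popSize)
      pop <- pop[order(-S)[seq_len(popSize)]]

    best <- pop[[1]]; bestFit <- fitOf(best)
    gen <- 0L; stagnant <- 0L
    repeat {
      gen <- gen + 1L
      fits <- vapply(pop, fitOf, numeric(1))
      ordf <- order(-fits)
      pop <- pop[ordf]; fits <- fits[ordf]
      improvedGen <- fits[1] > bestFit
      if (improvedGen) { best <- pop[[1]]; bestFit <- fits[1] }
      pb <- polish(best)
      if (fitOf(pb) > bestFit) {
        best <- pb; bestFit <- fitOf(pb); improvedGen <- TRUE
      }
      # also polish the best individual that differs from the leader
      alt <- which(!vapply(pop, identical, logical(1), y = best))[1]
      if (!is.na(alt)) {
        pa <- polish(pop[[alt]])
        if (fitOf(pa) > bestFit) {
          best <- pa; bestFit <- fitOf(pa); improvedGen <- TRUE
        }
      }
      stagnant <- if (improvedGen) 0L else stagnant + 1L

      topK <- pop[seq_len(min(eliteK, length(pop)))]
      if (gen >= 5L && length(topK) >= eliteK &&
          all(vapply(topK, identical, logical(1), y = topK[[1]])))
        break
      if (gen >= maxGenerations || stagnant >= 40L) break

      select <- function() {
        i <- sample.int(length(pop), 2L)
        pop[[i[which.max(fits[i])]]]
      }
      popSize <- max(popSize, eliteK + 2L)
      children <- vector("list", popSize)
      children[[1]] <- best
      # carry distinct elites only, so the convergence test reflects the
      # population's own agreement rather than elitist copies
      uniq <- pop[!duplicated(vapply(pop, paste, character(1),
                                     collapse = ","))]
      nk <- min(eliteK, length(uniq))
      for (q in seq_len(nk)) children[[q + 1L]] <- uniq[[q]]
      elongate <- function(child) {
        # append up to three compatible repeats at one end, preferring the
        # nearest (domains grow contiguously)
        steps <- sample.int(3L, 1L)
        front <- runif(1) < 0.5
        for (a in seq_len(steps)) {
          if (front) {
            ok <- which(en <= st[child[1L]])
            gap <- st[child[1L]] - en[ok]
          } else {
            ok <- which(st >= en[child[length(child)]])
            gap <- st[ok] - en[child[length(child)]]
          }
          if (!length(ok)) break
          pick <- if (runif(1) < 0.7) ok[which.min(gap)]
            else ok[sample.int(length(ok), 1L)]
          child <- sort(c(child, pick))
        }
        child
      }
      for (q in seq.int(nk + 2L, popSize)) {
        child <- select()
        doCross <- runif(1) < pCrossover
        doMut <- runif(1) < pMutation
        doElong <- runif(1) < pElongation
        if (!doCross && !doMut && !doElong) {
          # every offspring undergoes at least one operator
          doElong <- TRUE
        }
        if (doCross) {
          other <- select()
          x <- sample.int(maxCoord + 1L, 1L) - 1L
          child <- c(child[en[child] <= x], other[st[other] >= x])
          if (length(child) == 0L) child <- select()
        }
        if (doMut && length(child) > 0L) {
          q0 <- sample.int(length(child), 1L)
          if (runif(1) < 0.25 && length(child) > 1L) {
            child <- child[-q0]
          } else {
            base <- child[-q0]
            for (a in seq_len(5L)) {
              alt <- tryInsert(base, sample.int(n, 1L))
              if (!is.null(alt)) { child <- alt; break }
            }
          }
        }
        if (doElong && length(child) > 0L) child <- elongate(child)
        children[[q]] <- child
      }
      pop <- children
    }
    psLog("info", "GA finished after %d generations, fitness %s", gen,
          num4(bestFit))
    dom <- domainModel(df[sort(best), , drop = FALSE], pool@sequenceId)
    scoreDomain(dom, profile, useRegulator = TRUE)
  })
}

#' Classify an assembled repeat chain
#'
#' Slices the optimal repeat chain into domains (greedily, seven repeats per
#' domain where possible; the domain count follows the total-repeat counting
#' rule: more than 8, 16, 24, 32 repeats give 2, 3, 4, 5 domains), computes
#' each domain's ASr and tetrad evidence (the Lcd2 slot now uses the true
#' preceding-repeat context), and issues the verdict: WD40 iff some domain
#' has at least \code{minRepeats} repeats and either ASr at or above the
#' threshold or at least one full DHSW tetrad.
#'
#' @param assembly A [DomainModel] (the optimal chain).
#' @param sequence Residue string.
#' @param profile A [RepeatProfile].
#' @param asrThreshold ASr classification threshold (default 48).
#' @param minRepeats Minimum repeats per domain (default 6).
#' @param sequenceId Identifier.
#' @return List with \code{verdict}, \code{domains} (qualifying
#'   [DomainModel]s when WD40, all slices otherwise), \code{nDomains},
#'   \code{asr}, \code{tetradFound}.
#' @export
classify <- function(assembly, sequence, profile, asrThreshold = 48,
                     minRepeats = 6L, sequenceId = "seq") {
  df <- assembly@repeats
  N <- nrow(df)
  if (N == 0L)
    return(list(verdict = "not-WD40", domains = list(), nDomains = 0L,
                asr = numeric(0), tetradFound = FALSE))

  nDom <- as.integer(ceiling(N / 8))
  sizes <- if (nDom == 1L) N else c(rep(7L, nDom - 1L), N - 7L * (nDom - 1L))
  stopifnot(sum(sizes) == N, all(sizes >= 1L))
  idx <- split(seq_len(N), rep(seq_len(nDom), sizes))

  slices <- lapply(idx, function(i)
    scoreDomain(domainModel(df[i, , drop = FALSE], sequenceId), profile))
  asr <- vapply(slices, averageRepeatScore, numeric(1))

  # tetrad evidence with true Lcd context
  tetradPerDomain <- vapply(seq_along(idx), function(d) {
    rows <- idx[[d]]
    any(vapply(seq_along(rows), function(q) {
      i <- rows[q]
      cand <- repeatCandidate(sequence, df$start[i],
                              c(l_da = df$lda[i], l_ab = df$lab[i],
                                l_bc = df$lbc[i]), sequenceId)
      prevEnd <- if (i > 1L) df$end[i - 1L] else NA_integer_
      tetradMotifOf(tetradSlotResidues(cand, prevEnd)) %in%
        c("pentad", "tetrad")
    }, logical(1)))
  }, logical(1))

  qualify <- vapply(seq_along(slices), function(d)
    length(idx[[d]]) >= minRepeats &&
      (asr[d] >= asrThreshold || tetradPerDomain[d]), logical(1))

  if (any(qualify)) {
    list(verdict = "WD40", domains = unname(slices[qualify]),
         nDomains = nDom, asr = unname(asr[qualify]),
         tetradFound = any(tetradPerDomain[qualify]))
  } else {
    list(verdict = "not-WD40", domains = unname(slices), nDomains = 0L,
         asr = unname(asr), tetradFound = any(tetradPerDomain))
  }
}

#' Per-residue secondary structure from detected repeats
#'
#' Every residue inside any repeat's four strands is labelled E, everything
#' else C. Strand identifiers (repeat index plus strand letter) are attached
#' per segment.
#'
#' @param domains List of [DomainModel]s.
#' @param sequenceLength Length of the annotated sequence.
#' @return List with \code{ss} (character string) and \code{segments}
#'   (data.frame with \code{domain}, \code{repeat_index}, \code{strand},
#'   1-based inclusive \code{start}, \code{end}).
#' @export
emitSecondaryStructure <- function(domains, sequenceLength) {
  lab <- rep("C", sequenceLength)
  seg <- list(); nseg <- 0L
  rep_i <- 0L
  for (d in seq_along(domains)) {
    df <- domains[[d]]@repeats
    for (i in seq_len(nrow(df))) {
      rep_i <- rep_i + 1L
      so <- strandOffsets(c(l_da = df$lda[i], l_ab = df$lab[i],
                            l_bc = df$lbc[i]))
      for (snm in names(so)) {
        a <- df$start[i] + so[[snm]] + 1L        # 1-based inclusive
        b <- a + STRAND_LENGTH - 1L
        lab[a:b] <- "E"
        nseg <- nseg + 1L
        seg[[nseg]] <- data.frame(domain = d, repeat_index = rep_i,
                                  strand = tolower(sub("S", "", snm)),
                                  start = a, end = b)
      }
    }
  }
  segments <- if (nseg) do.call(rbind, seg)
    else data.frame(domain = integer(0), repeat_index = integer(0),
                    strand = character(0), start = integer(0),
                    end = integer(0))
  list(ss = paste(lab, collapse = ""), segments = segments)
}

#' Detect WD40 repeats and domains in a protein sequence
#'
#' The full pipeline: terminal trimming (with an external secondary-structure
#' prediction), exhaustive candidate enumeration above the generation floor,
#' the overlap filter, the early exit on the best candidate score, pool
#' thresholding, domain assembly by genetic algorithm (or the exact dynamic
#' program), the low-repeat restart rule (if the optimum has fewer than 7
#' repeats and T exceeds 10, T is reset to 10 and assembly restarts), and
#' final classification. The regulator is used during assembly only;
#' reported domain scores exclude it.
#'
#' @param sequence Residue string (or a length-1 named character vector).
#' @param profile A [RepeatProfile] (default the packaged profile).
#' @param ss Optional [SSPrediction] for the same sequence.
#' @param sequenceId Identifier (default the sequence name or "seq").
#' @param seed RNG seed for the assembly engine.
#' @param engine \code{"ga"} (default) or \code{"dp"} (exact).
#' @param minRepeatScore Generation floor (default 10).
#' @param dominateScore Overlap-filter dominator floor (default 35).
#' @param earlyExitScore Early-exit threshold on the best score (default 45).
#' @param asrThreshold Classification threshold on ASr (default 48).
#' @param minRepeats Minimum repeats per reported domain (default 6).
#' @param bounds Loop-length enumeration bounds.
#' @param gaControl Named list overriding [gaCombine()] parameters.
#' @param profileChecksum Optional md5 of the profile file, recorded in the
#'   report.
#' @return A [ClassificationReport].
#' @export
detectWD40 <- function(sequence, profile = defaultProfile(), ss = NULL,
                       sequenceId = NULL, seed = 1L,
                       engine = c("ga", "dp"), minRepeatScore = 10,
                       dominateScore = 35, earlyExitScore = 45,
                       asrThreshold = 48, minRepeats = 6L,
                       bounds = defaultLoopBounds(), gaControl = list(),
                       profileChecksum = "") {
  engine <- match.arg(engine)
  if (is.null(sequenceId))
    sequenceId <- names(sequence) %||% "seq"
  sequence <- toupper(as.character(sequence)[1])
  L <- nchar(sequence)
  thresholds <- list(min_repeat_score = minRepeatScore,
                     dominate_score = dominateScore,
                     early_exit_score = earlyExitScore,
                     asr_threshold = asrThreshold,
                     min_repeats = as.integer(minRepeats))

  blank <- function(earlyFlag, poolInfo) new("ClassificationReport",
    sequenceId = sequenceId, sequenceLength = L, verdict = "not-WD40",
    domains = list(), nDomains = 0L, asr = numeric(0), tetradFound = FALSE,
    ss = paste(rep("C", L), collapse = ""), earlyExit = earlyFlag,
    seed = as.integer(seed), engine = engine, thresholds = thresholds,
    profileChecksum = profileChecksum, poolInfo = poolInfo)

  interval <- trimTermini(sequence, ss)
  pool <- enumerateCandidates(sequence, profile, ss, minRepeatScore,
                              bounds, interval, sequenceId)
  nGenerated <- nrow(pool@candidates)
  pool <- overlapFilter(pool, dominateScore)
  nFiltered <- nrow(pool@candidates)
  info <- list(interval = interval, n_generated = nGenerated,
               n_after_overlap = nFiltered)

  if (earlyExit(pool, earlyExitScore))
    return(blank(TRUE, c(info, list(restarted = FALSE))))

  assemble <- function(thresholded, s) {
    if (engine == "dp") dpOptimal(thresholded, profile)
    else do.call(gaCombine, c(list(pool = thresholded, profile = profile,
                                   seed = s), gaControl))
  }

  T <- poolThreshold(pool, floor = minRepeatScore)
  thr <- applyPoolThreshold(pool, T)
  best <- assemble(thr, seed)
  restarted <- FALSE
  if (nRepeats(best) < 7L && T > minRepeatScore) {
    psLog("info", "restart: %d repeats at T = %s; resetting T to %s",
          nRepeats(best), num4(T), num4(minRepeatScore))
    restarted <- TRUE
    thr <- applyPoolThreshold(pool, minRepeatScore)
    best <- assemble(thr, seed)
  }
  info <- c(info, list(n_after_threshold = nrow(thr@candidates),
                       pool_T = thr@threshold, restarted = restarted))

  cls <- classify(best, sequence, profile, asrThreshold, minRepeats,
                  sequenceId)
  reportDomains <- if (cls$verdict == "WD40") cls$domains else list()
  ssOut <- emitSecondaryStructure(reportDomains, L)

  new("ClassificationReport",
      sequenceId = sequenceId, sequenceLength = L, verdict = cls$verdict,
      domains = reportDomains, nDomains = cls$nDomains,
      asr = if (cls$verdict == "WD40") cls$asr else numeric(0),
      tetradFound = cls$tetradFound && cls$verdict == "WD40",
      ss = ssOut$ss, earlyExit = FALSE, seed = as.integer(seed),
      engine = engine, thresholds = thresholds,
      profileChecksum = profileChecksum, poolInfo = info)
}
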