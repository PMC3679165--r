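# Profile training: alignment, frequencies, weights, loop-score fitting,
# tetrad statistics, similarity coefficient and split-half stability.

test_that("identical annotated repeats give single-residue columns", {
  rows <- handRepeatRows(n = 3)
  aln <- alignAnnotatedRepeats(rows)
  expect_equal(aln$n, 3L)
  for (k in scoredPositions()) {
    col <- aln$columns[[k]]
    if (length(col)) expect_length(unique(col), 1L)
  }
  # strand columns carry exactly the annotated residues
  expect_equal(aln$columns$Sd1, rep("K", 3))
  expect_equal(aln$columns$Sc6, rep("D", 3))
  expect_equal(aln$columns$Lab2, rep("P", 3))
})

test_that("overlong loops are dropped from loop columns but strands kept", {
  rows <- rbind(handRepeatRows(n = 2, lab = 2),
                handRepeatRows(n = 1, lab = 16))
  aln <- alignAnnotatedRepeats(rows)
  expect_length(aln$columns$Lab1, 2L)   # 16-residue Lab excluded
  expect_length(aln$columns$Sa1, 3L)    # strands still counted
})

test_that("malformed strand annotations are rejected by name", {
  rows <- handRepeatRows(n = 2)
  rows$sa_start[2] <- rows$sd_start[2] + 2   # overlaps Sd
  expect_error(alignAnnotatedRepeats(rows), "repeat 2")
  rows <- handRepeatRows(n = 2)
  rows$sc_start[1] <- nchar(rows$sequence[1]) - 2   # runs off the end
  expect_error(alignAnnotatedRepeats(rows), "repeat 1")
})

test_that("frequency estimation applies the 0.0001 pseudo-count", {
  rows <- handRepeatRows(n = 10)
  fr <- estimateFrequencies(alignAnnotatedRepeats(rows))
  # Sd1 column has 10 x K
  expect_equal(fr$P["Sd1", "K"], (10 + 1e-4) / (10 + 20e-4))
  expect_equal(unname(fr$P["Sd1", "V"]), 1e-4 / (10 + 20e-4))
  expect_true(all(abs(rowSums(fr$P) - 1) < 1e-9))
  expect_true(all(fr$P > 0))
  # Lab3/Lab4 columns are empty (lab = 2): background-filled
  expect_equal(fr$P["Lab3", ], defaultBackground())
})

test_that("position weights are information content in bits", {
  expect_equal(positionWeight(rep(1 / 20, 20)), 0)
  expect_equal(positionWeight(c(1, rep(0, 19))), log2(20))
  expect_equal(positionWeight(c(V = .5, I = .5)), log2(20) - 1)
  expect_equal(positionWeight(c(V = .5, I = .5), mode = "entropy"), 1)
})

test_that("loop-score fitting peaks at the mode and penalises long loops", {
  fit <- fitLoopScores(setNames(c(1, 2, 3, 50, 3, 1, 1, 1, 1, 1), 1:10),
                       bounds = c(1, 10))
  tab <- fit$table
  expect_equal(tab$l[which.max(tab$score)], 4)  # counts concentrated at 4
  beyond <- tab$l > fit$l0
  if (sum(beyond) > 1)
    expect_true(all(diff(tab$score[beyond]) < 0))
})

test_that("loop-score fitting matches an independent reimplementation", {
  counts <- setNames(c(5, 10, 5), 2:4)
  fit <- fitLoopScores(counts, bounds = c(1, 8), pseudoCount = 0.01,
                       t = 1, t0 = 1)
  # independent oracle, following the documented procedure step by step
  ls <- 1:8
  cnt <- c(0, 5, 10, 5, 0, 0, 0, 0)
  p <- (cnt + 0.01) / sum(cnt + 0.01)
  ps <- sapply(seq_along(ls), function(i) {
    w <- max(1, i - 1):min(8, i + 1); mean(p[w])
  })
  co <- coef(lm(log(ps) ~ ls + I(ls^2), weights = ps))
  sFit <- co[1] + co[2] * ls + co[3] * ls^2 + log(8)
  mode <- ls[which.max(sFit)]
  l0 <- ls[which(ls > mode & sFit < 1)[1]]
  expect_equal(fit$l0, l0)
  expect_equal(fit$table$score[ls <= l0], sFit[ls <= l0],
               ignore_attr = TRUE)
  # beyond l0 the linear penalty with slope t = 1 takes over
  lin <- 1 - 1 * (ls - l0)
  expect_equal(fit$table$score[ls > l0 + 1], lin[ls > l0 + 1],
               ignore_attr = TRUE)
})

test_that("linear penalty arithmetic: l0+10 scores about 5t below l0+5", {
  fit <- .prof@loopScores$l_cd
  d <- loopScore(fit$l0 + 5, fit) - loopScore(fit$l0 + 10, fit)
  expect_equal(d, 5 * fit$t, tolerance = 1e-6)
})

test_that("tetrad model counts pentads, tetrads and triads", {
  rows <- handRepeatRows(n = 10)
  # core has Sc = SIATWD: Sc1 = S, Sc5 = W; Sb4 = S; Lda3 = G (no His);
  # so no motif anywhere -> probabilities at pseudo-count level
  tm <- estimateTetradModel(alignAnnotatedRepeats(rows))
  expect_lt(tm$pPentad, 0.01)
  expect_true(tm$pTriad >= tm$pTetrad && tm$pTetrad >= tm$pPentad)

  # give 4 of 10 repeats a full pentad: D at the Lcd2 fallback slot and H
  # at Lda3 (Sc1/Sb4/Sc5 already match)
  core <- paste0("KLVFDE", "GGH", "VIKTSF", "PP", "ELASSG", "NN", "SIATWD")
  rows2 <- handRepeatRows(n = 10, core = core)
  pent <- paste0(strrep("A", 2), "D", "AA")        # D at sd_start - 3
  rows2$sequence[1:4] <- paste0(pent, core, strrep("A", 5))
  tm2 <- estimateTetradModel(alignAnnotatedRepeats(rows2))
  expect_equal(tm2$pPentad, (4 + 0.01) / (10 + 0.02))
  expect_equal(tm2$pTetrad, tm2$pPentad)   # every tetrad here is a pentad
  expect_gt(tm2$bonusPentad, 0)
})

test_that("similarity coefficient is a cosine", {
  X <- matrix(runif(40), 2, 20)
  expect_equal(similarityCoefficient(X, X), 1)
  expect_equal(similarityCoefficient(X, 3 * X), 1)   # scale-invariant
  A <- c(1, 0, 0, 1); B <- c(0, 1, 1, 0)
  expect_equal(similarityCoefficient(A, B), 0)       # disjoint supports
  expect_equal(similarityCoefficient(c(1, 0), c(1, 1) / sqrt(2)),
               1 / sqrt(2))                          # 45-degree toy
  Y <- matrix(runif(40), 2, 20)
  expect_equal(similarityCoefficient(X, Y), similarityCoefficient(Y, X))
  expect_error(similarityCoefficient(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(similarityCoefficient(1:4, 1:5), "shape")
})

test_that("split-half stability is 1 for duplicated repeats and seeded", {
  rows <- handRepeatRows(n = 20)
  sh <- splitHalfStability(rows, nTrials = 5, seed = 11)
  expect_equal(sh$values, rep(1, 5), tolerance = 1e-12)
  sh2 <- splitHalfStability(rows, nTrials = 5, seed = 11)
  expect_identical(sh$values, sh2$values)
  expect_error(splitHalfStability(handRepeatRows(n = 3)), "at least 4")
})

test_that("training on sampled repeats recovers the generating profile", {
  sims <- c()
  for (n in c(50, 200)) {
    rows <- do.call(rbind, lapply(seq_len(n / 5), function(i) {
      tr <- generateWD40(.prof, 5, seed = 5000 + i, flank = 6,
                         sequenceId = paste0("s", n, "_", i))
      propellerscan:::syntheticToAnnotated(tr)
    }))
    prof <- trainProfile(rows)
    sims <- c(sims, similarityCoefficient(prof, .prof))
  }
  expect_gt(sims[2], sims[1] - 0.02)   # similarity grows with sample size
  expect_gt(sims[2], 0.95)
})
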