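# Score terms of repeats and domains.

test_that("log-odds vanish when the profile equals the background", {
  p <- flatProfile()
  tr <- generateWD40(.prof, 1, seed = 3, flank = 6)
  df <- tr$repeats
  cand <- repeatCandidate(tr$sequence, df$start[1],
                          c(l_da = df$lda[1], l_ab = df$lab[1],
                            l_bc = df$lbc[1]))
  expect_equal(scoreAA(cand, p), 0, tolerance = 1e-12)
})

test_that("a two-position toy profile gives 2*log(10) for VV", {
  p <- twoPositionProfile()
  seqstr <- paste0("VV", strrep("A", 60))
  cand <- repeatCandidate(seqstr, 0, c(l_da = 6, l_ab = 4, l_bc = 4))
  expect_equal(scoreAA(cand, p), 2 * log(0.5 / 0.05), tolerance = 1e-12)
})

test_that("non-standard residues are scored at background with a warning", {
  p <- twoPositionProfile()
  seqstr <- paste0("VX", strrep("A", 60))
  cand <- repeatCandidate(seqstr, 0, c(l_da = 6, l_ab = 4, l_bc = 4))
  psLogLevel("warn")
  expect_message(sc <- scoreAA(cand, p), "non-standard")
  psLogLevel("quiet")
  expect_equal(sc, log(10), tolerance = 1e-12)
})

test_that("loop-length scoring is maximal at the modal lengths", {
  tabs <- .prof@loopScores
  best <- sapply(c("l_da", "l_ab", "l_bc"), function(nm) {
    tab <- tabs[[nm]]$table
    tab$l[which.max(tab$score)]
  })
  expect_equal(scoreLoopLengths(best[1], best[2], best[3], .prof),
               sum(sapply(c("l_da", "l_ab", "l_bc"), function(nm)
                 max(tabs[[nm]]$table$score))))
  # any other in-domain combination scores no higher
  expect_gte(scoreLoopLengths(best[1], best[2], best[3], .prof),
             scoreLoopLengths(best[1] + 2, best[2], best[3] + 3, .prof))
})

test_that("the tetrad term distinguishes pentad, triad and nothing", {
  # template with lda = 3, lab = 2, lbc = 2: slots at fixed offsets
  mk <- function(sc1, lcd2, lda3, sb4, sc5) {
    res <- rep("A", 50)
    res[3] <- lcd2           # start - 3, 0-based 2
    start <- 5
    res[start + 8 + 1] <- lda3          # Lda3 offset 8
    res[start + 12 + 3 + 2 + 3 + 1] <- sb4   # Sb4, offset 12+lda+lab+3
    sc <- start + 18 + 3 + 2 + 2
    res[sc + 1] <- sc1
    res[sc + 4 + 1] <- sc5
    repeatCandidate(paste(res, collapse = ""), start,
                    c(l_da = 3, l_ab = 2, l_bc = 2))
  }
  tet <- .prof@tetrad
  expect_equal(scoreCorr(mk("T", "D", "H", "S", "W"), .prof),
               tet$bonusPentad)
  expect_equal(scoreCorr(mk("A", "D", "H", "T", "F"), .prof),
               tet$bonusTriad)
  expect_equal(scoreCorr(mk("T", "A", "H", "S", "W"), .prof), 0)  # no Asp
  # tetrad: all but the leading Ser/Thr
  expect_equal(scoreCorr(mk("A", "D", "H", "S", "W"), .prof),
               tet$bonusTetrad)
})

test_that("the Lcd2 slot follows the preceding-repeat context", {
  res <- rep("A", 60)
  start <- 10
  res[start + 8 + 1] <- "H"
  res[start + 12 + 3 + 2 + 3 + 1] <- "S"
  sc <- start + 18 + 3 + 2 + 2
  res[sc + 1] <- "S"; res[sc + 4 + 1] <- "W"
  res[4 + 2] <- "D"     # position 2 of an Lcd loop starting at prevEnd = 4
  cand <- repeatCandidate(paste(res, collapse = ""), start,
                          c(l_da = 3, l_ab = 2, l_bc = 2))
  expect_equal(scoreCorr(cand, .prof, prevEnd = 4L),
               .prof@tetrad$bonusPentad)
  expect_equal(scoreCorr(cand, .prof), 0)  # fallback slot has no Asp
})

test_that("the external-SS term follows the stated coefficients", {
  tr <- generateWD40(.prof, 1, seed = 9, flank = 6)
  df <- tr$repeats
  n <- nchar(tr$sequence)
  cand <- repeatCandidate(tr$sequence, df$start[1],
                          c(l_da = df$lda[1], l_ab = df$lab[1],
                            l_bc = df$lbc[1]))
  allE <- new("SSPrediction", states = rep("E", n), conf = rep(9L, n))
  allH <- new("SSPrediction", states = rep("H", n), conf = rep(9L, n))
  conf0 <- new("SSPrediction", states = rep("E", n), conf = rep(0L, n))
  expect_equal(scoreSSTerm(cand, allE), 24 * 9 * 0.1)     # 21.6
  expect_equal(scoreSSTerm(cand, allH), -24 * 9 * 0.1)    # -21.6
  expect_equal(scoreSSTerm(cand, conf0), 0)
  expect_equal(scoreSSTerm(cand, NULL), 0)
  short <- new("SSPrediction", states = rep("E", 5), conf = rep(9L, 5))
  expect_error(scoreSSTerm(cand, short), "shorter")
})

test_that("S_repeat is the sum of its four terms", {
  tr <- generateWD40(.prof, 1, seed = 4, flank = 6)
  df <- tr$repeats
  n <- nchar(tr$sequence)
  cand <- repeatCandidate(tr$sequence, df$start[1],
                          c(l_da = df$lda[1], l_ab = df$lab[1],
                            l_bc = df$lbc[1]))
  ssp <- new("SSPrediction", states = rep("E", n), conf = rep(5L, n))
  br <- scoreBreakdown(scoreRepeat(cand, .prof, ssp))
  expect_equal(br[["S_repeat"]],
               sum(br[c("S_aa", "S_loop_len", "S_corr", "S_psipred")]))
  # dropping the prediction removes exactly the S_psipred term
  br0 <- scoreBreakdown(scoreRepeat(cand, .prof))
  expect_equal(br[["S_repeat"]] - br0[["S_repeat"]], br[["S_psipred"]])
})

test_that("the regulator peaks at seven-fold repeat numbers", {
  for (which in c("initial", "modified")) {
    r <- regulatorTable(.prof, which)
    expect_gt(r[7], r[5]); expect_gt(r[7], r[9])
    expect_gt(r[14], r[13]); expect_gt(r[14], r[15])
  }
  ri <- regulatorTable(.prof, "initial")
  expect_equal(ri[7], ri[14], tolerance = 1e-9)  # equal before modification
  expect_error(regulator(0, .prof), ">= 1")
  psLogLevel("warn")
  expect_message(v <- regulator(45, .prof), "clamp")
  psLogLevel("quiet")
  expect_equal(v, regulator(40, .prof))
})

test_that("domain scores add repeat, Lcd and regulator contributions", {
  pool <- poolFromTable(start = c(0, 50, 100), span = 38,
                        score = c(60, 55, 70))
  df <- candidates(pool)
  dom <- scoreDomain(domainModel(df), .prof)
  lcd <- loopScore(c(12, 12), .prof@loopScores$l_cd)
  expect_equal(dom@score, 60 + 55 + 70 + sum(lcd))
  domR <- scoreDomain(domainModel(df), .prof, useRegulator = TRUE)
  expect_equal(domR@scoreRegulated, domR@score + regulator(3, .prof))
  # single repeat: S_domain = S_repeat (+ R(1) when flagged)
  one <- scoreDomain(domainModel(df[1, ]), .prof, useRegulator = TRUE)
  expect_equal(one@score, 60)
  expect_equal(one@scoreRegulated, 60 + regulator(1, .prof))
  # a longer Lcd than the modal one strictly lowers the score
  pool2 <- poolFromTable(start = c(0, 38 + .prof@loopScores$l_cd$l0 + 8),
                         span = 38, score = c(60, 55))
  dom2 <- scoreDomain(domainModel(candidates(pool2)), .prof)
  pool3 <- poolFromTable(start = c(0, 42), span = 38, score = c(60, 55))
  dom3 <- scoreDomain(domainModel(candidates(pool3)), .prof)
  expect_lt(dom2@score, dom3@score)
  # overlapping repeats cannot form a domain
  expect_error(domainModel(candidates(poolFromTable(c(0, 10), 38,
                                                    c(50, 40)))),
               "overlap")
})

test_that("ASr excludes the tetrad term", {
  df <- candidates(poolFromTable(c(0, 50), 38, c(60, 40)))
  df$S_corr <- c(10, 0)
  df$S_repeat <- c(60, 40)
  dom <- domainModel(df)
  expect_equal(averageRepeatScore(dom), ((60 - 10) + 40) / 2)  # 45
  df$S_corr <- c(0, 0)
  expect_equal(averageRepeatScore(domainModel(df)), 50)
  expect_equal(averageRepeatScore(domainModel(df[1, ])), 60)
  expect_error(averageRepeatScore(domainModel(df[0, ])), "empty")
})
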