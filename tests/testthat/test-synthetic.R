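# Synthetic-data generation and evaluation metrics.

test_that("generation is reproducible and carries consistent truth", {
  a <- generateWD40(.prof, 7, seed = 4)
  b <- generateWD40(.prof, 7, seed = 4)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$repeats, b$repeats)
  df <- a$repeats
  expect_true(all(df$start[-1] >= df$end[-nrow(df)]))  # ordered, gaps >= 0
  expect_equal(df$end - df$start, 24 + df$lda + df$lab + df$lbc)
})

test_that("planted repeats separate from decoy placements by 3 sigma", {
  planted <- sapply(1:40, function(i) {
    tr <- generateWD40(.prof, 1, seed = 100 + i, flank = 6)
    df <- tr$repeats
    cand <- repeatCandidate(tr$sequence, df$start[1],
                            c(l_da = df$lda[1], l_ab = df$lab[1],
                              l_bc = df$lbc[1]))
    sum(scoreBreakdown(scoreRepeat(cand, .prof))[1:4])
  })
  decoy <- sapply(1:40, function(i) {
    d <- generateDecoy(80, seed = 200 + i)
    cand <- repeatCandidate(d$sequence, 10,
                            c(l_da = 6, l_ab = 4, l_bc = 4))
    sum(scoreBreakdown(scoreRepeat(cand, .prof))[1:4])
  })
  expect_gt(mean(planted) - 3 * sd(planted), mean(decoy) + 3 * sd(decoy))
})

test_that("pentad forcing yields the pentad bonus on every repeat", {
  tr <- generateWD40(.prof, 5, seed = 8, forcePentad = TRUE)
  df <- tr$repeats
  for (i in seq_len(nrow(df))) {
    cand <- repeatCandidate(tr$sequence, df$start[i],
                            c(l_da = df$lda[i], l_ab = df$lab[i],
                              l_bc = df$lbc[i]))
    prevEnd <- if (i > 1) df$end[i - 1] else NA_integer_
    expect_equal(scoreCorr(cand, .prof, prevEnd),
                 .prof@tetrad$bonusPentad)
  }
})

test_that("decoy modes behave as documented", {
  a <- generateDecoy(100, seed = 1)
  b <- generateDecoy(100, seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_error(generateDecoy(20, seed = 1), ">= 30")

  src <- generateWD40(.prof, 4, seed = 2)$sequence
  sh <- generateDecoy(seed = 3, mode = "shuffle", source = src)
  expect_equal(sort(strsplit(unname(sh$sequence), "")[[1]]),
               sort(strsplit(unname(src), "")[[1]]))

  h <- generateDecoy(200, seed = 4, mode = "helix")
  expect_s4_class(h$ss, "SSPrediction")
  iv <- trimTermini(unname(h$sequence), h$ss)
  expect_lt(iv[2] - iv[1], 200)   # at least one window trimmed
})

test_that("q3 counts matching positions", {
  expect_equal(q3("EEECC", "EEECC"), 100)
  expect_equal(q3("EEEEE", "CCCCC"), 0)
  expect_equal(q3("EEEEECCCCC", "EEEEEEEEEE"), 50)
  expect_error(q3("EC", "E"), "length")
  # symmetric under simultaneous relabeling
  p <- c("E", "C", "E", "H"); r <- c("E", "E", "C", "H")
  swap <- function(x) chartr("EC", "CE", x)
  expect_equal(q3(p, r), q3(swap(p), swap(r)))
})

test_that("detection metrics implement the loose and tight criteria", {
  tr <- generateWD40(.prof, 7, seed = 12)
  truth <- tr$repeats
  perfect <- data.frame(sd = truth$sd_start, sa = truth$sa_start,
                        sb = truth$sb_start, sc = truth$sc_start)
  expect_equal(detectionMetrics(perfect, tr, "loose")$accuracy, 100)
  expect_equal(detectionMetrics(perfect, tr, "tight")$accuracy, 100)
  # Sd shifted out of tolerance: loose unaffected, tight zero
  noSd <- perfect; noSd$sd <- noSd$sd + 5L
  expect_equal(detectionMetrics(noSd, tr, "loose")$accuracy, 100)
  expect_equal(detectionMetrics(noSd, tr, "tight")$accuracy, 0)
  # one of seven repeats missed entirely
  miss1 <- perfect[-1, ]
  expect_equal(detectionMetrics(miss1, tr, "loose")$accuracy,
               100 * 6 / 7, tolerance = 1e-9)
  # tight never exceeds loose
  for (seed in 1:5) {
    jitter <- perfect
    jitter$sd <- jitter$sd + withr::with_seed(seed,
      sample(-4:4, nrow(jitter), replace = TRUE))
    expect_lte(detectionMetrics(jitter, tr, "tight")$accuracy,
               detectionMetrics(jitter, tr, "loose")$accuracy)
  }
})

test_that("the jack-knife harness matches reproduction on clean data", {
  expect_error(jackknife(list(1, 2)), "at least 3")
  # like the real training set, every dataset protein carries the DHSW
  # tetrad hallmark, so the tetrad branch of the classifier is exercised
  dataset <- lapply(1:10, function(i)
    generateWD40(.prof, 7, seed = 4000 + i,
                 sequenceId = paste0("jk", i), forcePentad = TRUE))
  jk <- jackknife(dataset)
  expect_length(jk$q3, 10L)
  expect_true(all(jk$loose >= jk$tight))
  # reproduction run: train on all items, evaluate on each
  allRows <- do.call(rbind, lapply(dataset,
                                   propellerscan:::syntheticToAnnotated))
  prof <- trainProfile(allRows)
  repro <- sapply(dataset, function(item) {
    r <- detectWD40(unname(item$sequence), prof, engine = "dp")
    q3(ssString(r), propellerscan:::truthSS(item))
  })
  expect_lt(abs(jk$meanQ3 - mean(repro)), 3)
})
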