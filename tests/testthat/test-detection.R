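# Detection pipeline: trimming, enumeration, filters, assembly engines,
# classification and secondary-structure emission.

test_that("terminal trimming strips helix-rich ends only", {
  seqstr <- strrep("A", 400)
  expect_equal(trimTermini(seqstr), c(0, 400))
  allE <- new("SSPrediction", states = rep("E", 400), conf = rep(9L, 400))
  expect_equal(trimTermini(seqstr, allE), c(0, 400))
  mixed <- new("SSPrediction",
               states = c(rep("H", 100), rep("E", 300)),
               conf = rep(9L, 400))
  iv <- trimTermini(seqstr, mixed)
  expect_gte(iv[1], 85); expect_lte(iv[1], 105)
  expect_equal(iv[2], 400)
})

test_that("enumeration is exhaustive over planted repeats", {
  expect_equal(nrow(candidates(
    enumerateCandidates(strrep("A", 23), .prof))), 0L)
  tr <- generateWD40(.prof, 7, seed = 21)
  pool <- enumerateCandidates(unname(tr$sequence), .prof)
  df <- candidates(pool)
  truth <- tr$repeats
  for (i in seq_len(nrow(truth))) {
    # some candidate places every strand within one residue of the truth
    hit <- abs(df$start - truth$start[i]) <= 1 &
      abs((df$start + 6 + df$lda) - truth$sa_start[i]) <= 1 &
      abs((df$start + 12 + df$lda + df$lab) - truth$sb_start[i]) <= 1 &
      abs((df$start + 18 + df$lda + df$lab + df$lbc) -
            truth$sc_start[i]) <= 1
    expect_true(any(hit))
  }
  # a same-length background decoy yields a markedly smaller pool
  dec <- generateDecoy(nchar(tr$sequence), seed = 21)
  poolD <- enumerateCandidates(unname(dec$sequence), .prof)
  expect_lt(nrow(candidates(poolD)), nrow(df) / 2)
})

test_that("the overlap filter removes only dominated candidates", {
  # identical spans, scores 50 and 40: only the 50 survives
  p <- poolFromTable(c(0, 0), 38, c(40, 50))
  expect_equal(candidates(overlapFilter(p))$S_repeat, 50)
  # overlapping 30 and 25: dominator below 35, both survive
  p <- poolFromTable(c(0, 10), 38, c(30, 25))
  expect_equal(nrow(candidates(overlapFilter(p))), 2L)
  # non-overlapping candidates all survive
  p <- poolFromTable(c(0, 100, 200), 38, c(60, 20, 80))
  expect_equal(nrow(candidates(overlapFilter(p))), 3L)
  # chained domination: 50 beats 45 (overlap), 45 gone so 20 survives
  p <- poolFromTable(c(0, 20, 40), 38, c(50, 45, 20))
  kept <- candidates(overlapFilter(p))
  expect_setequal(kept$S_repeat, c(50, 20))
})

test_that("early exit uses a strict comparison at 45", {
  expect_true(earlyExit(poolFromTable(0, 38, 44.9)))
  expect_false(earlyExit(poolFromTable(0, 38, 45)))
  expect_true(earlyExit(poolFromTable(integer(0), 38, numeric(0))))
})

test_that("the pool threshold follows the median policy", {
  p <- poolFromTable(c(0, 50, 100, 150), 38, c(20, 30, 40, 50))
  T <- poolThreshold(p)
  expect_equal(T, 35)
  expect_equal(nrow(candidates(applyPoolThreshold(p, T))), 2L)
  expect_equal(poolThreshold(poolFromTable(c(0, 50), 38, c(12, 12))), 12)
  expect_equal(poolThreshold(poolFromTable(0, 38, 7)), 10)
})

test_that("dynamic programming matches brute force on random pools", {
  for (seed in 1:8) {
    pool <- randomPool(n = 9, seed = 700 + seed)
    dom <- dpOptimal(pool, .prof)
    expect_equal(dom@scoreRegulated, bruteForceBest(pool, .prof),
                 tolerance = 1e-9)
  }
  # empty pool -> empty domain; two overlapping -> the higher one
  expect_equal(nRepeats(dpOptimal(poolFromTable(integer(0), 38,
                                                numeric(0)), .prof)), 0L)
  two <- poolFromTable(c(0, 5), 38, c(50, 60))
  expect_equal(repeatTable(dpOptimal(two, .prof))$S_repeat, 60)
})

test_that("adding a compatible positive candidate never hurts the optimum", {
  for (seed in 1:5) {
    pool <- randomPool(n = 8, seed = 900 + seed, coordMax = 300)
    base <- dpOptimal(pool, .prof)@scoreRegulated
    df <- candidates(pool)
    extra <- df[1, ]
    extra$start <- max(df$end) + 4L
    extra$end <- extra$start + 38L
    extra$lda <- 6L; extra$lab <- 4L; extra$lbc <- 4L
    extra$S_aa <- 100; extra$S_loop <- 0; extra$S_corr <- 0
    extra$S_ss <- 0; extra$S_repeat <- 100
    pool@candidates <- rbind(df, extra)
    expect_gte(dpOptimal(pool, .prof)@scoreRegulated, base)
  }
})

test_that("the genetic algorithm is exact on small pools and seeded", {
  # unique maximal compatible set: the GA returns all 7 planted repeats
  p7 <- poolFromTable(seq(0, by = 42, length.out = 7), 38, rep(80, 7))
  ga <- gaCombine(p7, .prof, seed = 5)
  expect_equal(nRepeats(ga), 7L)
  # determinism
  pool <- randomPool(n = 12, seed = 33)
  a <- gaCombine(pool, .prof, seed = 8)
  b <- gaCombine(pool, .prof, seed = 8)
  expect_identical(repeatTable(a), repeatTable(b))
  # oracle equivalence on a handful of pools (the full sweep is part of
  # the acceptance suite)
  for (seed in 1:5) {
    pool <- randomPool(n = sample(4:12, 1), seed = 40 + seed)
    expect_equal(gaCombine(pool, .prof, seed = seed)@scoreRegulated,
                 dpOptimal(pool, .prof)@scoreRegulated, tolerance = 1e-9)
  }
})

test_that("classification applies the repeat-count and ASr criteria", {
  seqstr <- strrep("A", 600)
  mkAsm <- function(n, score) {
    df <- candidates(poolFromTable(seq(0, by = 42, length.out = n), 38,
                                   rep(score, n)))
    domainModel(df, "toy")
  }
  # 7 repeats at ASr 50 -> WD40, one domain
  cl <- classify(mkAsm(7, 50), seqstr, .prof)
  expect_equal(cl$verdict, "WD40")
  expect_equal(cl$nDomains, 1L)
  # boundary: ASr exactly 48 passes, just below fails (no tetrad in poly-A)
  expect_equal(classify(mkAsm(7, 48), seqstr, .prof)$verdict, "WD40")
  expect_equal(classify(mkAsm(7, 47.9), seqstr, .prof)$verdict, "not-WD40")
  # six repeats qualify, five do not
  expect_equal(classify(mkAsm(6, 60), seqstr, .prof)$verdict, "WD40")
  expect_equal(classify(mkAsm(5, 60), seqstr, .prof)$verdict, "not-WD40")
  # nine repeats -> two domains by the counting rule
  cl9 <- classify(mkAsm(9, 60), seqstr, .prof)
  expect_equal(cl9$nDomains, 2L)
  # ASr below threshold but a true DHSW tetrad rescues the verdict
  res <- rep("A", 600)
  start <- 42  # second candidate of the assembly below
  res[start - 3 + 1] <- "D"
  res[start + 8 + 1] <- "H"                   # lda = 6 holds Lda3 at 8
  res[start + 12 + 6 + 4 + 3 + 1] <- "S"      # Sb4
  res[start + 18 + 6 + 4 + 4 + 4 + 1] <- "W"  # Sc5
  seqT <- paste(res, collapse = "")
  clT <- classify(mkAsm(7, 40), seqT, .prof)
  expect_equal(clT$verdict, "WD40")
  expect_true(clT$tetradFound)
})

test_that("secondary-structure emission marks strand residues", {
  expect_equal(emitSecondaryStructure(list(), 10)$ss, strrep("C", 10))
  # one repeat with zero-length loops at the start: 24 E then C
  df <- candidates(poolFromTable(0, 38, 50))
  df$lda <- 0L; df$lab <- 0L; df$lbc <- 0L; df$end <- 24L
  out <- emitSecondaryStructure(list(domainModel(df)), 30)
  expect_equal(out$ss, paste0(strrep("E", 24), strrep("C", 6)))
  # a 7-repeat synthetic yields 28 six-residue E segments
  tr <- generateWD40(.prof, 7, seed = 13)
  rep7 <- detectWD40(unname(tr$sequence), .prof, engine = "dp")
  expect_equal(verdict(rep7), "WD40")
  seg <- emitSecondaryStructure(domains(rep7), nchar(tr$sequence))$segments
  expect_equal(nrow(seg), 28L)              # 7 repeats x 4 strands
  expect_true(all(seg$end - seg$start + 1L == 6L))
  lab <- strsplit(ssString(rep7), "")[[1]]
  inStrand <- unlist(Map(seq, seg$start, seg$end))
  expect_true(all(lab[inStrand] == "E"))
  expect_true(all(lab[-inStrand] == "C"))
})

test_that("the pipeline is deterministic and applies the restart rule", {
  tr <- generateWD40(.prof, 7, seed = 77)
  r1 <- detectWD40(unname(tr$sequence), .prof, seed = 3, engine = "ga")
  r2 <- detectWD40(unname(tr$sequence), .prof, seed = 3, engine = "ga")
  f1 <- tempfile(); f2 <- tempfile()
  writeReport(r1, f1); writeReport(r2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  unlink(c(f1, f2))
  # the restart rule fires when the first assembly is short
  expect_true(r1@poolInfo$restarted ||
                nRepeats(r1@domains[[1]]) >= 7L)
  expect_equal(verdict(r1), "WD40")
})

test_that("helix-rich decoys with an all-helix prediction are trimmed", {
  dec <- generateDecoy(300, seed = 5, mode = "helix")
  iv <- trimTermini(unname(dec$sequence), dec$ss)
  expect_lt(iv[2] - iv[1], 30)  # less than one window survives
  rep0 <- detectWD40(unname(dec$sequence), .prof, ss = dec$ss,
                     engine = "dp")
  expect_equal(verdict(rep0), "not-WD40")
})
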