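# Shared fixtures, built in code at test time.

psLogLevel("quiet")

# The packaged profile, loaded once.
.prof <- defaultProfile()

# A profile whose frequencies equal the background at every position
# (all log-odds vanish), with unit weights.
flatProfile <- function(background = defaultBackground()) {
  p <- .prof
  for (k in scoredPositions()) p@frequencies[k, ] <- background
  p@weights[] <- 1
  p
}

# A two-position toy: only Sd1 and Sd2 are informative, with P(V) = 0.5
# against a uniform background (0.05), unit weight; every other position
# sits at background with zero weight.
twoPositionProfile <- function() {
  p <- .prof
  bg <- setNames(rep(0.05, 20), AA20)
  p@background <- bg
  for (k in scoredPositions()) p@frequencies[k, ] <- bg
  p@weights[] <- 0
  for (k in c("Sd1", "Sd2")) {
    p@frequencies[k, ] <- (1 - 0.5) / 19 * rep(1, 20)
    p@frequencies[k, "V"] <- 0.5
    p@weights[k] <- 1
  }
  p
}

# Annotated-repeat rows for n copies of one hand-made repeat embedded in a
# poly-A context: Sd GHKLMN | Lda of `lda` residues | Sa VIWDEF | Lab ... etc.
handRepeatRows <- function(n = 2, lda = 3, lab = 2, lbc = 2, flank = 5,
                           core = NULL) {
  if (is.null(core)) {
    core <- paste0("KLVFDE", strrep("G", lda), "VIKTSF",
                   strrep("P", lab), "ELASSG", strrep("N", lbc), "SIATWD")
  }
  seqs <- paste0(strrep("A", flank), core, strrep("A", flank))
  sd <- flank
  sa <- sd + 6 + lda
  sb <- sa + 6 + lab
  sc <- sb + 6 + lbc
  data.frame(source_id = paste0("r", seq_len(n)), sequence = seqs,
             sd_start = sd, sa_start = sa, sb_start = sb, sc_start = sc)
}

# A candidate-pool object from bare interval/score triples.
poolFromTable <- function(start, span, score, sequenceId = "toy") {
  if (length(start) == 0L) {
    df <- data.frame(start = integer(0), lda = integer(0),
                     lab = integer(0), lbc = integer(0), end = integer(0),
                     S_aa = numeric(0), S_loop = numeric(0),
                     S_corr = numeric(0), S_ss = numeric(0),
                     S_repeat = numeric(0))
    return(new("CandidatePool", candidates = df, sequenceId = sequenceId,
               threshold = NA_real_))
  }
  df <- data.frame(start = as.integer(start), lda = 6L, lab = 4L, lbc = 4L)
  # force the requested span by adjusting lbc (span = 24 + loops)
  df$lbc <- as.integer(span - 24L - df$lda - df$lab)
  stopifnot(all(df$lbc >= 0L))
  df$end <- df$start + as.integer(span)
  df$S_aa <- score; df$S_loop <- 0; df$S_corr <- 0; df$S_ss <- 0
  df$S_repeat <- score
  df <- df[order(df$start, df$end), ]
  rownames(df) <- NULL
  new("CandidatePool", candidates = df, sequenceId = sequenceId,
      threshold = NA_real_)
}

# Random compatible/overlapping candidate pool for assembly tests.
randomPool <- function(n, seed, coordMax = 400L) {
  withr::with_seed(seed, {
    start <- sample.int(coordMax, n, replace = TRUE) - 1L
    lda <- sample(3:10, n, replace = TRUE)
    lab <- sample(1:8, n, replace = TRUE)
    lbc <- sample(1:8, n, replace = TRUE)
    df <- data.frame(start = start, lda = lda, lab = lab, lbc = lbc)
    df$end <- df$start + 24L + df$lda + df$lab + df$lbc
    df$S_aa <- runif(n, 10, 120)
    df$S_loop <- runif(n, -3, 3)
    df$S_corr <- ifelse(runif(n) < 0.3, 12, 0)
    df$S_ss <- 0
    df$S_repeat <- df$S_aa + df$S_loop + df$S_corr
    df <- df[order(df$start, df$end), ]
    rownames(df) <- NULL
    new("CandidatePool", candidates = df, sequenceId = "rand",
        threshold = NA_real_)
  })
}

# Brute-force optimum over all ordered non-overlapping subsets (exponential;
# oracle for dpOptimal on small pools).
bruteForceBest <- function(pool, profile) {
  df <- candidates(pool)
  n <- nrow(df)
  regTab <- regulatorTable(profile)
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) == 0L) next
    idx <- idx[order(df$start[idx])]
    if (length(idx) > 1L &&
        any(df$start[idx][-1L] < df$end[idx][-length(idx)])) next
    sc <- sum(df$S_repeat[idx]) +
      sum(loopScore(df$start[idx][-1L] - df$end[idx][-length(idx)],
                    profile@loopScores$l_cd, warn = FALSE)) +
      regTab[min(length(idx), 40L)]
    if (sc > best) best <- sc
  }
  best
}
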