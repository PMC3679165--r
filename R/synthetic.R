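# Synthetic sequences with ground truth, and the evaluation metrics:
# Q3, loose/tight repeat recovery, and the leave-one-out jack-knife.

.sampleAA <- function(n, p) sample(AA20, n, replace = TRUE, prob = p[AA20])

# Sample a loop length from the exponentiated, normalised score table.
.sampleLoopLen <- function(loopFit, lo = NULL) {
  tab <- loopFit$table
  keep <- if (is.null(lo)) rep(TRUE, nrow(tab)) else tab$l >= lo
  p <- exp(tab$score[keep] - max(tab$score[keep]))
  sample(tab$l[keep], 1L, prob = p / sum(p))
}

#' Generate a synthetic WD40 protein with ground truth
#'
#' Builds a protein of \code{nRepeats} planted repeats flanked by background
#' sequence. Strand and scored-loop residues are sampled from the profile's
#' per-position frequencies; unscored loop residues from the background;
#' loop lengths (including the inter-repeat Lcd linkers) from the
#' exponentiated, normalised loop-score tables. With \code{forcePentad},
#' the five tetrad slots of every repeat are overwritten with
#' Ser/Asp/His/Ser/Trp so each repeat carries a full pentad.
#'
#' @param profile A [RepeatProfile] to sample from.
#' @param nRepeats Number of planted repeats (>= 1).
#' @param seed RNG seed; generation is reproducible.
#' @param flank Length of the N- and C-terminal background flanks
#'   (default 20).
#' @param forcePentad Force the pentad motif on every repeat
#'   (default FALSE).
#' @param sequenceId Identifier for the generated record.
#' @return A list (\code{SyntheticTruth}) with \code{sequence} (named
#'   residue string), \code{repeats} (data.frame of 0-based \code{start},
#'   loop lengths, strand starts), \code{isWD40 = TRUE}, and the generator
#'   \code{params}.
#' @export
generateWD40 <- function(profile, nRepeats = 7L, seed = 1L, flank = 20L,
                         forcePentad = FALSE, sequenceId = "synthetic") {
  stopifnot(nRepeats >= 1L)
  withSeed(seed, {
    freq <- profile@frequencies
    bg <- profile@background
    chunks <- character(0)
    rows <- list()
    pos <- 0L

    nflank <- max(flank, 4L)           # room for the Lcd2 fallback slot
    lead <- .sampleAA(nflank, bg)
    if (forcePentad) lead[nflank - 2L] <- "D"   # slot at start - 3
    chunks <- c(chunks, paste(lead, collapse = ""))
    pos <- pos + nflank

    for (r in seq_len(nRepeats)) {
      lda <- .sampleLoopLen(profile@loopScores$l_da, lo = 3L)
      lab <- .sampleLoopLen(profile@loopScores$l_ab)
      lbc <- .sampleLoopLen(profile@loopScores$l_bc)
      ll <- c(l_da = lda, l_ab = lab, l_bc = lbc)
      span <- 24L + lda + lab + lbc
      res <- .sampleAA(span, bg)
      off <- scoredOffsets(ll)
      for (k in names(off)) {
        if (!is.na(off[[k]]))
          res[off[[k]] + 1L] <- sample(AA20, 1L, prob = freq[k, ])
      }
      if (forcePentad) {
        so <- strandOffsets(ll)
        res[so[["Sc"]] + 1L] <- "S"              # Sc1
        res[8L + 1L] <- "H"                      # Lda3
        res[so[["Sb"]] + 3L + 1L] <- "S"         # Sb4
        res[so[["Sc"]] + 4L + 1L] <- "W"         # Sc5
      }
      so <- strandOffsets(ll)
      rows[[r]] <- data.frame(start = pos, lda = lda, lab = lab, lbc = lbc,
                              end = pos + span,
                              sd_start = pos + so[["Sd"]],
                              sa_start = pos + so[["Sa"]],
                              sb_start = pos + so[["Sb"]],
                              sc_start = pos + so[["Sc"]])
      chunks <- c(chunks, paste(res, collapse = ""))
      pos <- pos + span

      if (r < nRepeats) {
        lcd <- .sampleLoopLen(profile@loopScores$l_cd,
                              lo = if (forcePentad) 2L else NULL)
        linker <- .sampleAA(lcd, bg)
        if (forcePentad && lcd >= 2L) linker[2L] <- "D"   # next Lcd2 slot
        chunks <- c(chunks, paste(linker, collapse = ""))
        pos <- pos + lcd
      }
    }
    chunks <- c(chunks, paste(.sampleAA(flank, bg), collapse = ""))
    seqstr <- paste(chunks, collapse = "")
    names(seqstr) <- sequenceId
    list(sequence = seqstr, repeats = do.call(rbind, rows), isWD40 = TRUE,
         params = list(nRepeats = nRepeats, seed = seed, flank = flank,
                       forcePentad = forcePentad))
  })
}

#' Generate a ground-truth-negative decoy sequence
#'
#' Three modes: \code{"iid"} samples residues independently from the
#' background (so decoy scores probe positional signal, not composition);
#' \code{"shuffle"} permutes the residues of a supplied WD40 sequence,
#' preserving its composition exactly; \code{"helix"} is an iid decoy paired
#' with an all-helix, full-confidence secondary-structure prediction.
#'
#' @param length Decoy length (>= 30; ignored for \code{"shuffle"}).
#' @param background Residue sampling distribution.
#' @param seed RNG seed.
#' @param mode \code{"iid"}, \code{"shuffle"} or \code{"helix"}.
#' @param source Residue string to permute (\code{"shuffle"} mode).
#' @param sequenceId Identifier.
#' @return A list like [generateWD40()]'s, with \code{isWD40 = FALSE} and,
#'   in helix mode, an \code{ss} element ([SSPrediction]).
#' @export
generateDecoy <- function(length = 350L, background = defaultBackground(),
                          seed = 1L, mode = c("iid", "shuffle", "helix"),
                          source = NULL, sequenceId = "decoy") {
  mode <- match.arg(mode)
  withSeed(seed, {
    if (mode == "shuffle") {
      if (is.null(source)) stop("shuffle mode needs a source sequence")
      res <- sample(strsplit(as.character(source), "")[[1]])
    } else {
      if (length < 30L) stop("decoy length must be >= 30")
      res <- .sampleAA(length, background)
    }
    seqstr <- paste(res, collapse = "")
    names(seqstr) <- sequenceId
    out <- list(sequence = seqstr, repeats = NULL, isWD40 = FALSE,
                params = list(mode = mode, seed = seed))
    if (mode == "helix")
      out$ss <- new("SSPrediction",
                    states = rep("H", nchar(seqstr)),
                    conf = rep(9L, nchar(seqstr)))
    out
  })
}

#' Three-state secondary-structure accuracy Q3
#'
#' Percentage of positions whose predicted label matches the reference.
#'
#' @param predicted,reference Equal-length character vectors or single
#'   strings of per-residue labels.
#' @return Percentage in \code{[0, 100]}.
#' @export
q3 <- function(predicted, reference) {
  p <- if (length(predicted) == 1L) strsplit(predicted, "")[[1]]
    else predicted
  r <- if (length(reference) == 1L) strsplit(reference, "")[[1]]
    else reference
  if (length(p) != length(r)) stop("label vectors differ in length")
  100 * mean(p == r)
}

# Reference E/C string from planted-repeat coordinates.
truthSS <- function(truth) {
  n <- nchar(truth$sequence)
  lab <- rep("C", n)
  df <- truth$repeats
  for (i in seq_len(nrow(df))) {
    for (cl in c("sd_start", "sa_start", "sb_start", "sc_start")) {
      a <- df[[cl]][i] + 1L
      lab[a:(a + STRAND_LENGTH - 1L)] <- "E"
    }
  }
  paste(lab, collapse = "")
}

# Predicted strand-start table from a report (0-based).
.predictedStrands <- function(report) {
  rows <- list(); k <- 0L
  for (d in seq_along(report@domains)) {
    df <- report@domains[[d]]@repeats
    for (i in seq_len(nrow(df))) {
      so <- strandOffsets(c(l_da = df$lda[i], l_ab = df$lab[i],
                            l_bc = df$lbc[i]))
      k <- k + 1L
      rows[[k]] <- data.frame(sd = df$start[i] + so[["Sd"]],
                              sa = df$start[i] + so[["Sa"]],
                              sb = df$start[i] + so[["Sb"]],
                              sc = df$start[i] + so[["Sc"]])
    }
  }
  if (k) do.call(rbind, rows) else
    data.frame(sd = integer(0), sa = integer(0), sb = integer(0),
               sc = integer(0))
}

#' Repeat-detection accuracy under the loose / tight criterion
#'
#' A planted repeat counts as identified if its strands Sa, Sb and Sc
#' (loose criterion) or additionally Sd (tight criterion) are each found: a
#' predicted strand finds a reference strand when the two six-residue
#' windows overlap by at least \code{overlapMin} residues, and all required
#' strands must come from the same predicted repeat.
#'
#' @param report A [ClassificationReport] (or a data.frame of predicted
#'   0-based strand starts \code{sd}, \code{sa}, \code{sb}, \code{sc}).
#' @param truth A \code{SyntheticTruth} from [generateWD40()] (or its
#'   \code{repeats} table).
#' @param criterion \code{"loose"} or \code{"tight"}.
#' @param overlapMin Minimum per-strand overlap in residues (default 4
#'   of 6).
#' @return List with \code{accuracy} (percentage of planted repeats found)
#'   and \code{hits} (per-repeat logical).
#' @export
detectionMetrics <- function(report, truth,
                             criterion = c("loose", "tight"),
                             overlapMin = 4L) {
  criterion <- match.arg(criterion)
  pred <- if (is.data.frame(report)) report else .predictedStrands(report)
  ref <- if (is.data.frame(truth)) truth else truth$repeats
  need <- if (criterion == "loose") c("sa", "sb", "sc")
    else c("sd", "sa", "sb", "sc")
  maxShift <- STRAND_LENGTH - overlapMin
  hits <- vapply(seq_len(nrow(ref)), function(i) {
    if (nrow(pred) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(pred)), function(j) {
      all(vapply(need, function(s) {
        abs(pred[[s]][j] - ref[[paste0(s, "_start")]][i]) <= maxShift
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  list(accuracy = 100 * mean(hits), hits = hits)
}

# Convert planted repeats of one synthetic protein to annotated-repeat rows.
syntheticToAnnotated <- function(truth) {
  df <- truth$repeats
  data.frame(source_id = names(truth$sequence),
             sequence = unname(truth$sequence),
             sd_start = df$sd_start, sa_start = df$sa_start,
             sb_start = df$sb_start, sc_start = df$sc_start)
}

#' Leave-one-out jack-knife evaluation
#'
#' For each item of an annotated dataset, retrains the profile on all other
#' items and evaluates detection and secondary-structure prediction on the
#' held-out item. The dataset is a list of items, each with
#' \code{sequence} (named residue string), \code{repeats} (planted/annotated
#' repeat table as in [generateWD40()]) and optionally a reference SS string
#' (\code{refSS}; derived from the repeat table if absent).
#'
#' @param dataset List of >= 3 items as above.
#' @param trainer Function(annotated repeat data.frame) -> [RepeatProfile]
#'   (default [trainProfile()]).
#' @param detector Function(sequence, profile, sequenceId) ->
#'   [ClassificationReport] (default [detectWD40()] with the exact engine).
#' @return List with per-item \code{q3}, \code{loose}, \code{tight}
#'   accuracies and their means.
#' @export
jackknife <- function(dataset, trainer = NULL, detector = NULL) {
  if (length(dataset) < 3L) stop("jack-knife needs at least 3 items")
  if (is.null(trainer)) trainer <- function(rows) trainProfile(rows)
  if (is.null(detector))
    detector <- function(sequence, profile, sequenceId)
      detectWD40(sequence, profile, sequenceId = sequenceId,
                 engine = "dp")
  annotated <- lapply(dataset, syntheticToAnnotated)
  q3v <- loose <- tight <- numeric(length(dataset))
  for (i in seq_along(dataset)) {
    prof <- trainer(do.call(rbind, annotated[-i]))
    item <- dataset[[i]]
    rep_i <- detector(unname(item$sequence), prof,
                      names(item$sequence) %||% paste0("item", i))
    refSS <- item$refSS %||% truthSS(item)
    q3v[i] <- q3(ssString(rep_i), refSS)
    loose[i] <- detectionMetrics(rep_i, item, "loose")$accuracy
    tight[i] <- detectionMetrics(rep_i, item, "tight")$accuracy
  }
  list(q3 = q3v, loose = loose, tight = tight,
       meanQ3 = mean(q3v), meanLoose = mean(loose),
       meanTight = mean(tight))
}
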