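---
title: "Detecting WD40 repeats and predicting propeller secondary structure"
author: "propellerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting WD40 repeats and predicting propeller secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propellerscan)
psLogLevel("quiet")
```

## The problem

WD40 domains are circular β-propellers of six to eight (mostly seven)
four-stranded blades. The *sequence* repeat runs Sd–Sa–Sb–Sc, phase-shifted
by one strand against the *structural* blade (Sa–Sb–Sc–Sd): the
C-terminal strand of each blade is donated by the next sequence repeat,
which is what closes the ring. Because the family tolerates almost any
residue at most positions (about 20% average pairwise identity), profile
HMMs and regular expressions under-annotate it badly — typically finding
3–6 of 7 repeats and truncating them. What stays conserved is
*structural*: a hydrogen-bonded Asp–His–Ser/Thr–Trp (DHSW) tetrad bridging
adjacent blades, two β-bulges used here as alignment landmarks, strand
lengths of six residues, narrow loop-length preferences, and the
seven-fold blade count. `propellerscan` encodes exactly these signals.

## Repeat model and scoring

Every candidate is a placement of the template Sd(6) – Lda(l_da) – Sa(6) –
Lab(l_ab) – Sb(6) – Lbc(l_bc) – Sc(6) at a start position; the inter-repeat
loop Lcd belongs to the domain. 31 positions are scored: all 24 strand
positions plus the conserved loop positions Lda2, Lda3, Lab1–Lab4 and Lbc3
(numbered inside each loop from its N-terminal end; see below). The score
of a candidate is the sum of four terms.

**Residue propensity `S_aa`.** For each scored position k with profile
frequencies $P_k$ and background $P_{all}$,
$S_{aa} = \sum_k w_k \ln\!\big(P_k(aa_k)/P_{all}(aa_k)\big)$. The weight
$w_k = \log_2 20 - H_k$ is the position's information content in bits.
The family literature describes the weight as the "information entropy" of
the position; we implement information *content* because the intent —
up-weighting conserved positions — requires it (raw entropy would do the
opposite), and a configuration switch (`weightMode = "entropy"`) preserves
the literal alternative. Natural logarithms are used throughout; the
pipeline's threshold constants are calibrated to the packaged profile on
this scale and are all configurable. Pseudo-count: $10^{-4}$ on every
residue frequency.

**Loop lengths `S_loop_len`.** Each loop class has a fitted score table
$S(l)$: lengths get a pseudo-count of 0.01, are normalised and smoothed
with a 3-point moving average, and a quadratic in $l$ is least-squares
fitted to the smoothed log-frequency, weighted by the smoothed frequency
so the fit tracks well-populated lengths; the fitted curve is expressed as
log-odds against a uniform length distribution. Beyond $l_0$ — the first
length past the mode where the fitted score drops below 1 — a linear
penalty $S(l) = 1 - t\,(l - l_0)$ takes over (blended over a window
$t_0$, default 1), because long loops are too rare to estimate yet must
not be forbidden. Defaults: slope $t = 2$ for the within-repeat loops,
$t = 0.8$ for the more tolerant Lcd linker. Training discards loops
longer than 15 residues from column statistics; enumeration uses
l_da, l_ab, l_bc ∈ [1, 15] and l_cd ∈ [0, 25], with linear extrapolation
(and, in user-facing calls, a warning) outside the table.

**Tetrad term `S_corr`.** The pentad slots are Sc1, Lcd2, Lda3, Sb4, Sc5
with required classes Ser/Thr, Asp, His, Ser/Thr, Trp. A full pentad earns
$\max(0, \ln(p_{pentad}/q_{pentad}))$ where $p$ is the motif probability in
the training set and $q$ its probability under independent background
draws; failing that, the DHSW tetrad (slots 2–5) or the DHS triad
(slots 2–4) earn the analogous smaller bonuses. The Lcd2 slot lies in the
loop *preceding* the repeat: inside an assembled domain the true
preceding-repeat end supplies it; for a standalone candidate the modal-loop
fallback position (three residues before Sd1) is used, and at a sequence
start the motif degrades to the slots that exist. The packaged motif
probabilities (0.40 / 0.55 / 0.70) reflect that every structurally
characterised family member carries at least one tetrad while individual
repeats often lack one.

**External secondary structure `S_psipred`.** When a PSIPRED-style
prediction is supplied, each of the 24 strand residues contributes
confidence × coefficient with coefficients (E, C, H) = (0.1, −0.025,
−0.1); loop residues contribute nothing. The term mainly rescues strand d,
the least conserved strand. Without a prediction the term is zero and the
pipeline runs in a degraded mode in which strand-d placement relies on
`S_aa` alone. Whether loop positions should also contribute was an open
choice; strand-only is implemented because the term's purpose is strand
placement.

## Domain assembly

All placements with `S_repeat > 10` are enumerated exhaustively
(`O(L · 15^3)` scorings, done incrementally with rolling block sums). A
candidate overlapping a retained candidate that scores above 35 *and*
strictly above it is discarded (descending score order; ties broken by
smaller start, then shorter span). If the best survivor scores below 45
the sequence is declared non-WD40 outright. The pool is then thresholded
at `T = max(10, median score)` — the published rule discards "more than
half" of the pool behind a threshold whose exact form is not public, so
the median policy is used and is pluggable.

Assembly maximises
$S_{domain} = \sum S_{repeat} + \sum S(l_{cd}) + R(N_{rep})$ over ordered,
non-overlapping candidate subsets. $R(N)$ is the repeat-count regulator:
the initial table is five equal Gaussians (amplitude 20, σ = 1) centred at
7, 14, 21, 28, 35; the packaged "modified" table uses wider Gaussians
(σ = 1.5) with amplitudes decaying 20…12 so that 6- and 8-repeat
propellers stay competitive during assembly. The exact modified curve in
the source literature is unpublished; ours is tuned only so that planted
6/7/8-repeat synthetics are recovered, and the provenance flag is stored
in the profile file. The regulator acts during assembly only; reported
domain scores exclude it.

Two engines share this objective. `dpOptimal()` is exact: dynamic
programming over candidates sorted by end coordinate with a
(candidate × repeat-count) state, which also handles the count-dependent
regulator. `gaCombine()` is the default stochastic engine: individuals are
repeat chains, the first generation holds every single repeat, and
offspring arise by crossover (splice two chains at a sequence coordinate),
mutation (replace one repeat with a compatible alternative, or drop it)
and elongation (append compatible repeats at an end, preferring the
nearest — domains grow contiguously — and occasionally several in a run,
so a chain can cross an unprofitable gap). Every offspring undergoes at
least one operator; the best chain is polished each generation by greedy
insertion/deletion/replacement (plus exhaustive two-step insertions on
pools of ≤ 25 candidates); the run converges when the ten best individuals
are identical (after a minimum of five generations, so elitist copies
cannot fake agreement), or after 500 generations, or after 40 generations
without improvement. The whole run is reproducible under a fixed seed. If
the optimised domain has fewer than 7 repeats while `T > 10`, `T` is reset
to 10 and assembly restarts. The mutation-deletion option and the
greedy polish are our additions to the published operator list: without a
shrink move the search cannot reach optima that exclude a low-margin
candidate, and the acceptance suite holds the GA to exact-DP equality on
pools of up to 12 candidates.

## Classification and output

A protein is WD40 when some assembled domain has at least 6 repeats and
either ASr ≥ 48 or at least one full DHSW tetrad (evaluated with true Lcd
context). ASr is the mean of `S_repeat − S_corr` over the domain's
repeats. The published criteria state both "more than 6" and "at least 6"
in different places; ≥ 6 is adopted (it matches the reported six-repeat
domain fraction) and is configurable. Totals above 8, 16, 24, 32 repeats
are reported as 2, 3, 4, 5 domains; repeats are assigned to domains
greedily, seven per domain where possible, since only the counting rule is
published. Every residue inside a detected strand is labelled E, the rest
C, with strand identifiers (d1, a1, b1, c1, d2, …) attached per segment.

## The packaged profile

No full per-position frequency table for the structure-anchored alignment
is published — only marginals for a handful of positions (Sa1:
V/I/L = 49.2/29.0/6.3%; Sa4; Sa6; Sc2; Sc4; Pro at Lab2 = 39.6%) and
qualitative descriptions of the rest (the Gly-His region in Lda, the
Ser/Thr tetrad slots, the β-bulge X positions, the Trp-Asp dipeptide
closing Sc, bulky hydrophobics in the strand cores, weak conservation in
Sd). The packaged profile is therefore an explicit synthetic
reconstruction (`makeDefaultProfile()`, file
`wd40_profile_default_synthetic.txt`): printed marginals are carried
exactly; every other position gets documented consensus frequencies, with
the residual mass restricted to chemically compatible residues and a
0.001 floor elsewhere. The overall conservation level was calibrated once,
before any acceptance measurement, so that repeats sampled from the
profile score in the published 30–150 range on the natural-log scale the
thresholds (10/35/45/48) assume; sampled repeats average ≈ 63 with the
strongest near 90. Loop tables are fitted from assumed unimodal length
distributions with modes at the modal template (l_da = 6,
l_ab = l_bc = l_cd = 4). Users with annotated repeats should train their
own profile (`trainProfile()`), which replaces every synthetic component
with estimates.

The background composition defaults to Swiss-Prot-style eukaryotic
amino-acid frequencies and is overridable everywhere it enters.

### Coordinate and anchoring conventions

Internally all coordinates are 0-based half-open; every file format is
1-based inclusive. The conserved loop positions are numbered on the modal
template — Sd(1–6), Lda(7–12), Sa(13–18), Lab(19–22), Sb(23–28),
Lbc(29–32), Sc(33–38) — and mapped onto loops of other lengths
N-terminally anchored: loop position *i* is the *i*-th residue after the
loop start, and a loop too short to hold a scored position contributes
background (zero log-odds) there, since its brevity is already priced by
the length score. How conserved loop positions should move when loop
length varies is not specified anywhere; N-anchoring is the simplest
deterministic rule and is confined to one helper should evidence favour
another.

## The synthetic generator and what the tests show

`generateWD40()` emulates the statistical structure the profile encodes:
strand and scored-loop residues are drawn from the per-position
frequencies, unscored loop residues and flanks from the background, loop
lengths from the exponentiated, normalised score tables (l_da ≥ 3 so the
His slot exists), with an optional flag that forces a full pentad onto
every repeat. Decoys are iid-background sequences (composition identical
to the positional null, so rejection measures positional signal only),
shuffles of real generated sequences, or helix-rich sequences paired with
an all-H prediction. The generator does **not** emulate homologous
correlation between repeats of one protein, insertions inside strands,
non-WD40 β-propellers (kelch, YVTN), or compositional drift across
proteomes — so passing recovery tests demonstrates correctness of the
machinery under the model's own assumptions, not performance on real
proteomes, for which the profile should be trained on curated repeats.

The jack-knife datasets are generated pentad-forced: every structurally
characterised member of the family carries at least one DHSW tetrad, and
profiles retrained on only ~60 repeats penalise residues unseen in
training heavily (the 10^-4 pseudo-count makes an unseen residue cost
several score units), so the tetrad branch of the classifier is what
keeps small-sample leave-one-out detection stable — on tetrad-free
synthetics the jack-knife is markedly less robust, which is a faithful
property of the method, not an artefact.

Problem sizes used by the tests and the acceptance script — 50
seven-repeat proteins (~300 residues each) with matched decoys, 100
random assembly pools of ≤ 12 candidates, profile recovery from 200
repeats, a 10-protein jack-knife — were chosen as the smallest sets at
which the binomial noise on the reported percentages stays a point or two,
and they complete in well under a minute each on a single core.

## Numerical choices and degenerate inputs

Scores are plain doubles; pseudo-counts guarantee finiteness for any
sequence over the 20-letter alphabet, and non-standard letters (X/B/Z/U)
score at background with a warning. Ties in the overlap filter resolve by
smaller start then shorter span; ties in the DP resolve to the
first-indexed predecessor, so both engines are deterministic. Empty pools
yield empty domains and a not-WD40 report; sequences shorter than 24
residues yield empty pools. Report and profile files carry all numerals at
17 significant digits (bit-exact round-trip) plus an md5 integrity
checksum; human-facing tables are printed at 4 decimals.

## Known limitations

The thresholds are calibrated to the packaged synthetic profile; a
retrained profile on real repeats will shift the score scale, and the
thresholds should be re-examined (they are arguments, not constants, for
this reason). The tetrad term uses one bonus per motif class regardless of
which member is missing. Velcro-closure across chains, 8-strand blade
variants and structural (blade-phase) output are out of scope. Running an
external secondary-structure predictor is the user's job; the package only
consumes its output.
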