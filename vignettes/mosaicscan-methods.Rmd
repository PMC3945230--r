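---
title: "Detecting phage genome mosaics and traces of homologous recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phage genome mosaics and traces of homologous recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscan)
```

## The problem

Temperate phage genomes are mosaics: collections of segments with different
evolutionary histories, assembled by horizontal exchange. When two phage
genomes that diverged long ago (background identity *b*, say 60%) have
recently exchanged a segment, that segment stands out as a local alignment
of high identity (operationally: more than 90% identity over at least
100 bp). If the exchange happened by homologous recombination, it must have
occurred across regions of pre-existing partial homology flanking the
exchanged segment — and those regions remain visible as flanking sequence
at an identity above background ("HR traces"). Counting mosaics and their
traces across a collection of phage, prophage and virulent-phage genomes
quantifies how much of phage evolution is driven by homology-directed
exchange.

`mosaicscan` implements this comparative analysis end to end:

1. **Pair screening** — fragment-based average nucleotide identity (ANI)
   with a relaxed scoring scheme; genome pairs that are too closely related
   for flanking homology to stand out above their overall relatedness are
   excluded, and near-identical genomes are collapsed.
2. **Mosaic detection** — a seed-and-extend local aligner finds hits of at
   least 100 bp with more than 90% identity on analyzed pairs.
3. **IS filtering** — hits that are mostly insertion-sequence sequence on
   either genome are removed (high-identity IS copies are repeats, not
   exchanges).
4. **Trace calling** — 2-kb flanks on each side of each mosaic are
   realigned by affine-gap dynamic programming; the identity of successive
   50-bp windows is measured, and a side carries a trace when a window near
   the mosaic boundary reaches the flank's background identity plus ten
   points.
5. **Summaries** — per lifestyle category (temperate--temperate,
   temperate--defective, defective--defective, virulent--virulent,
   virulent--other): pair counts, mosaic counts and densities, median
   mosaic length and identity, trace-count breakdown, and a null
   probability for chance traces.

A fully seeded synthetic cohort generator plants mosaics, anchors (the
partial homology the exchange occurred across), masked anchors and IS
repeats with a recorded truth table, so that every stage is testable
without downloading genomes.

## Alignment engines

Two engines are implemented in C++ and shared by all stages.

**Local search** (`find_local_hits`): exact-match words of the scoring
scheme's `word_size` are hashed on the first genome and scanned on both
strands of the second; each novel seed is extended without gaps under an
X-drop rule (drop threshold 20 times the match reward); overlapping hits
within 30 diagonals merge (at least 50% overlap on both genomes, higher
score wins); near-diagonal neighbours are chained and realigned with a
banded affine local aligner (band half-width 50). Two scoring presets are
used: *standard* (match +1, mismatch −2, gap open 5, extend 2, word 11;
megablast-like, for the >90% mosaic screen) and *relaxed* (match +3,
mismatch −4, gap open 5, extend 2, word 10), whose break-even identity of
4/7 lets alignments persist down to roughly 60% identity — this is what
makes ANI values near 60% measurable at all.

**Boundary trimming.** Under the standard scheme, extension remains
score-positive above 2/3 identity, so a hit would happily run through an
80%-identity anchor flanking a 97% mosaic and blur exactly the boundary
the trace analysis needs. Hit termini are therefore trimmed to the
maximal-scoring block under a trim scoring whose break-even identity sits
2.5 points below the reporting threshold (e.g. 0.875 for a 0.90 screen),
with two refinements chosen for boundary accuracy: ties resolve toward the
longer block, and a short trimmed terminal block (at most 25 columns) of
reasonable identity is restored, since it is a boundary mismatch cluster
that belongs to the hit rather than sustained flanking homology. The
break-even placement reflects the changepoint being sought: mosaic regimes
sit at 0.95–0.99, flanking-homology regimes near 0.80, and 0.875 is the
midpoint separating them. Boundary-estimation error between such regimes
is intrinsically on the order of ±15 bp; the tests hold detected
boundaries to that scale.

**Global alignment** (`global_align`): Needleman–Wunsch–Gotoh with
blast-style affine gaps (a gap of length L costs `open + L × extend`),
used to realign mosaic flanks. Traceback ties prefer match/mismatch over a
gap in the second sequence over a gap in the first, making outputs
bit-reproducible. Inputs are capped at 10 kb (quadratic memory); callers
chunk anything longer.

Gap columns count as non-matches in every identity, window identity and
perfect-segment computation. This is the conservative reading of "percent
identity" and is applied consistently (it is also why ANI and window
identities are slightly below the per-site identity of indel-free
simulated pairs would suggest — see below).

## ANI screening

The smaller genome of a pair is cut into 1000-bp fragments (the classical
fragment-ANI recipe uses 1020 bp; a round 1000 is used here and is
configurable); each fragment's best relaxed-scoring hit on the larger
genome contributes if it covers at least 70% of the fragment. ANI is the
mean identity of contributing best hits, coverage the fraction of
fragments contributing — so coverage is defined on the smaller genome.
Exclusion rules: redundant when ANI > 92 and coverage > 80 (the
lexicographically larger genome id is dropped); excluded when both genomes
are temperate/defective and ANI > 70 with coverage > 50, or both virulent
and ANI > 68 with coverage > 48. Mixed temperate–virulent pairs use the
temperate thresholds (the per-class rules do not cover the mixed case; the
stricter choice is configurable).

A caution on scale: optimal alignment of deeply diverged sequences is
opportunistic — gaps are placed wherever they happen to buy matches — so
measured identities of indel-free pairs simulated at 60% per-site identity
come out near 63–66%, not 60%. This alignment bias is inherent to
maximum-score alignment, affects every aligner, and is why the exclusion
thresholds are applied to measured ANI, not to a nominal divergence.

## Trace calling

For each mosaic, 2-kb flanks are taken outward from both boundaries on
both genomes (strand-aware: for minus-strand mosaics the second genome's
flanks are reverse-complemented so both sequences of a flank pair face the
same boundary). Each flank pair is globally realigned and tiled with
successive non-overlapping 50-column windows, the grid anchored at the
mosaic boundary. Fifty bp is close to the minimal homology usable by
phage single-strand annealing recombinases (about 30 bp for Redβ).

Three estimation decisions are deliberately explicit:

* **Background (b).** The flank's background identity is the median window
  identity of that flank's own profile (robust to the anchor's elevation
  for anchors up to about a quarter of the flank). A fixed pair-level
  value can be supplied instead (`b_method = "fixed"`), which is what the
  calibration experiments use.
* **Trace rule.** A side carries a trace when at least one window within
  the first `proximal_cols = 200` alignment columns of the boundary
  reaches `b + 0.10` (ten identity points, absolute). A guard refuses to
  call traces when `b + 0.10` is within one mismatch of saturation.
* **Proximal search.** Whether a qualifying window may lie anywhere in the
  2-kb flank or must sit near the boundary is a genuinely open choice. The
  package searches only the first 200 columns (four windows, the scale of
  the homology anchors the exchange occurred across), for a quantitative
  reason: with 50-bp windows at b = 0.60, a single window clears b + 10
  points by chance with probability ≈ 0.095 (binomial), so searching all
  40 windows of a 2-kb flank would flag ≈ 98% of anchor-free sides and
  the statistic would carry no information. Restricting to the boundary
  keeps the chance rate near 0.33 per side while losing essentially no
  power for genuine traces, which by mechanism abut the breakpoint.

**Null model.** The probability of observing traces at random is provided
in two forms. The analytic form treats each window as
Binomial(50, b): the per-window tail probability is
`q = P[Bin(50, b) ≥ ceil(50 (b + 0.10))]` and the probability of at least
one chance trace over k searched windows is `1 − (1 − q)^k`. The
permutation form column-shuffles a supplied flank alignment and reads the
tail off empirically; on indel-free data the two agree. Two honest
limitations are documented rather than hidden. First, the binomial form
assumes site independence, which realignment breaks: optimal alignment
smooths window identities, so the observed chance-trace rate on realigned
flanks runs somewhat below the analytic value — the binomial null is
conservative (an upper bound on chance traces). The calibration tests
therefore isolate the trace rule on the generative (colinear) alignment,
where the binomial model is exact. Second, with thousands of windows the
analytic "at least one anywhere" probability saturates toward 1; it
cannot reproduce vanishing cohort-level null probabilities, and no
derivation achieving that is available to mirror. The per-side null rate
is the informative quantity and is what the package reports alongside
summaries.

## The synthetic cohort generator

`simulate_cohort` draws, per pair, a random uniform-composition ancestor
and derives two genomes by independent per-site substitution calibrated so
the expected pairwise identity equals b (for b = 0.60 each copy mutates
23.8% of sites). Defaults describe the study conditions used throughout
the tests, chosen once: 10 pairs of 45-kb genomes at b = 0.60; three
mosaics per pair with lognormal lengths (median 450 bp, truncated to
150–800 bp) at identities uniform in 0.95–0.99; 200-bp anchors at
b + 0.20 planted on each side with probability 0.5; masking off; IS
repeats off; indels off. Masking (probability `p_mask`) overwrites one
planted anchor with unrelated sequence, emulating a later exchange with a
third genome that erases the trace on that side; increasing it converts
two-trace mosaics into one-trace mosaics, which is the mechanism invoked
for the preponderance of single traces in real genomes. IS repeats, when
enabled, are identical copies written into both genomes at unrelated
positions, exactly the decoys the IS filter must remove.

What the generator does *not* emulate: rate heterogeneity along the genome
(a two-rate mixture can be enabled in spirit by composing cohorts),
gene/codon structure, compositional bias, genome rearrangements, and
phylogenetic correlation between pairs (every pair has its own ancestor).
Passing recovery tests on this generator therefore demonstrates
correctness of the operational definitions — not that real phage genomes
satisfy the generator's assumptions. Indels are off by default so that
planted coordinates are exact and the binomial null is exactly right on
the generative alignment; a background indel mode exists for robustness
experiments and remaps truth coordinates accordingly.

Truth scoring (`score_against_truth`): a detection matches a planted
mosaic when the intervals overlap reciprocally by at least 80% on both
genomes, or both boundaries agree within 15 bp. Trace recall is measured
over testable sides of matched mosaics carrying an unmasked anchor.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; written reports are
  1-based inclusive (blast-like TSV).
* `N` never matches anything; characters outside A/C/G/T/N are mapped to
  N on input with a warning.
* Flanks shorter than 500 bp (genome ends) are untestable and are excluded
  from the trace-count denominator rather than zero-filled, avoiding
  biased b estimates on stubs.
* Alignments shorter than one window raise an error; a trailing partial
  window is dropped.
* Categories with zero pairs produce a summary row with empty statistics,
  not an error. Empty IS catalogs remove nothing. Genomes absent from the
  metadata are labeled `unknown`, drop out of category rows, but remain in
  the pair matrix.
* All randomness flows from a single integer seed; identical seeds give
  byte-identical FASTA, truth tables, mosaic tables and trace calls.

## Problem sizes used by the test-suite

The suite validates alignment scores against two independent oracles
(a plain-R Gotoh and the Biostrings implementation) on pairs up to 1 kb,
runs cohort recovery on the default 10-pair, 45-kb conditions, and uses
15–30 kb genomes for pipeline round trips; trace calibration uses at
least 300 simulated anchor-free sides and power at least 200 anchored
sides. These sizes are the package's chosen validation conditions; all
statistics scale to larger inputs unchanged.

## Known limitations

* The seed-and-extend engine is not a full Smith–Waterman: hits without a
  preserved exact word of `word_size` are invisible. At the identities
  where mosaics are defined (>90%) preserved 11-mers are abundant, and the
  tests hold the engine to at least 95% of the exhaustive local optimum on
  segment-sharing pairs.
* Mosaic boundaries against flanking homology are changepoint estimates
  with intrinsic error of roughly ±15 bp; window-granularity trace
  localization inherits the same scale.
* The analytic null is conservative on realigned flanks (above) and
  saturates over many windows; cohort-level "probability of any chance
  trace" should be read qualitatively.
* The ANI screen's absolute values carry alignment bias at deep
  divergence; thresholds are calibrated on measured values, and the
  relaxed scheme's floor is about 60% identity — pairs below that simply
  show near-zero coverage.
* Which ancestral genome donated a mosaic, the age of exchanges, and
  nucleotide-resolution breakpoints are out of scope.
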