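---
title: "Methods: simulating and detecting ping-pong piRNA signatures"
author: "pingpongr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting ping-pong piRNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pingpongr)
```

## Scope and model

`pingpongr` analyses small-RNA sequencing data from virus-infected insect
cells, where PIWI-interacting RNAs (piRNAs) are produced from viral and
transposon RNA by the ping-pong amplification loop. Two PIWI proteins
reciprocally cleave sense and antisense target RNA; because the responder
piRNA begins with a uridine (1U) that base-pairs with the adenosine at
position 10 of the initiator (10A), ping-pong pairs leave two sequence
fingerprints:

* the 5' ends of sense and antisense piRNAs overlap by exactly 10 nt, and
* the nucleotide composition at read position 1 (antisense, U) and
  position 10 (sense, A) is strongly biased.

The package quantifies both fingerprints, compares knockdown and control
libraries, scores IP-versus-input strand enrichment, ranks
co-purifying proteins from label-free quantification (LFQ) intensities,
builds neighbor-joining (NJ) trees over TUDOR protein domains, and scores
fluorescence-signal granularity — every statistic exercised end-to-end on
synthetic data with known ground truth.

## Coordinates and the overlap statistic

All coordinates are 0-based; `five_prime` is the forward-axis position of a
read's 5'-most base. For antisense reads that is the *rightmost* covered
base, so for a sense read `s` and antisense read `a` the offset
`d = a$five_prime - s$five_prime + 1` equals the number of overlapping 5'
nucleotides; `d = 10` is the ping-pong configuration.

`overlap_probability()` sums pair mass per offset `d` in 1..30 (wide enough
for every read length; the normalisation therefore differs from plots
truncated at 20, which is documented behaviour). Pair mass defaults to the
product of the two collapsed copy counts, matching a probability
interpretation on weighted libraries; `weight = "presence"` scores each
distinct pair once instead. The ping-pong z-score is

$$ z_{10} = \frac{p(10) - \mathrm{mean}\,p(d \ne 10)}{\mathrm{sd}\,p(d \ne 10)}, $$

with offset 10 excluded from the background, the standard construction.
`z10` is reported only when at least five offsets carry mass; a profile
with no pair mass at all returns all zeros and `NA`.

## The synthetic-data generator

The generator plants everything the statistics later measure, so every
pipeline result can be checked against ground truth.

* **References** — uniform-random DNA: an 11.7 kb viral genome (Sindbis
  scale), two 4 kb transposon consensus sequences (one ping-pong, one
  phased), a 400 nt host mRNA and twelve 22-nt miRNAs.
* **Ping-pong pairs** — anchor sites on each reference; the responder 5'
  sits 9 nt downstream of the initiator 5'. Because emitted reads are exact
  (reverse-complemented) substrings of the reference, the initiator's
  position-10 base and the responder's position-1 base are the *same*
  nucleotide; site pools are drawn with an exact fraction `bias_10A` (default
  0.9) of A-bearing sites, so both biases are recovered with plain
  multinomial error. `bias_1U` governs standalone 1U reads (the phased
  library), which have no overlap structure.
* **Hotspot** — 60% of virus-sense pair sites fall in one 200-nt window
  whose position is fixed per seed, emulating the concentration of viral
  piRNA production in a narrow region of the capsid gene without asserting
  its exact share.
* **Counts** — per-stratum read counts are Poisson around
  `pingpong_pair_rate` (default 1e4) times a per-library log-normal size
  factor (SD 0.05); under knockdown the mean is multiplied by the
  configured retention. Defaults (virus 0.25/0.20 sense/antisense,
  ping-pong transposon 0.85/0.45) reproduce the 75%/80% viral and 15%/55%
  transposon-family reduction structure the pipeline is designed to
  measure. Retentions for the phased transposon (0.40) and host mRNA (0.80)
  are the package's own choices in the plausible range for a strong and a
  mild effect, made once.
* **siRNAs** — 21-nt duplexes with 2-nt 3' overhangs drawn from shared
  duplex sites; their 5'-overlap mass sits at offset 19, keeping the
  piRNA/siRNA contrast testable. siRNA rates are identical in both
  conditions.
* **miRNAs** — verbatim copies of the miRNA references with exponential
  abundance weights; their total (default 5e4) is the normalisation
  denominator.
* **IP libraries** — the Ago3-like IP multiplies the virus-sense rate by a
  factor (default 4), the Piwi5-like IP the virus-antisense rate; the input
  library is symmetric. Log2 enrichment of a factor-4 IP is therefore 2 in
  expectation.
* **LFQ matrices** — protein baselines are N(25, 2) on the log2 scale with
  replicate noise SD 0.5; interactors gain `effect_log2` in bait columns.
  Missingness is left-censored: the dropout probability rises
  logistically as the underlying intensity falls, scaled to the requested
  overall rate. This reproduces the geometry of real volcano plots, where
  control-side censoring is what makes interactors stand out.
* **Domain alignments** — columns evolve independently down a given tree; a
  site substitutes with probability `1 - exp(-rate * b)` on a branch of
  length `b`, uniformly to one of the 19 other residues. Default length 50
  columns, the scale of a TUDOR domain.
* **Images** — 64×64 grids with a circular cytoplasm mask; granular cells
  put all signal into 3–10 Gaussian foci, diffuse cells spread it uniformly
  plus white noise (relative SD 0.05). Classes are normalised to identical
  summed masked intensity so only the spatial distribution differs.

What the generator does **not** emulate: RNA secondary structure, a
mechanistic phasing trail (phased reads are simply 1U-biased and
non-overlapping), adapter/quality artefacts, multimapping across near-
identical transposon copies, and peptide-level effects in LFQ data. Tests
passing on these simulations therefore validate the statistics and their
implementations, not the upstream read-processing steps real data would
need.

## Alignment policy

Reads are collapsed (identical sequences merged, counts summed,
lexicographic order) and placed on every reference at every position where
they match exactly, or with one substitution in 1-mismatch mode. A
1-mismatch hit whose mismatch falls at read position 1 or 10 is rejected so
sequencing-error tolerance cannot dilute the 1U/10A signal. A multi-mapping
read contributes its full count to every hit; categories are analysed
independently, mirroring the per-target structure of the downstream
figures, and no hierarchical read assignment is attempted. Reads containing
N are dropped before alignment. miRNAs are counted only as exact,
full-length, sense-strand matches, and that total is the normalisation
denominator (reads per million miRNA reads — scale-free, so any library-
depth factor cancels).

## Differential testing

Replicate comparisons use the equal-variance two-sample t-test (Welch by
flag), reporting percent reduction `100 * (1 - mean_kd / mean_ctl)` on the
means of normalised counts (not the mean of per-replicate ratios, which is
biased for small counts). Significance tiers are `*` < 0.05, `**` < 0.01,
`***` < 0.001, with no multiple-testing correction across categories by
default (a Benjamini–Hochberg flag exists). No count-model (negative
binomial) testing is attempted: with three replicates of strongly
miRNA-normalised counts the t-test on normalised values is the intended
analysis.

A note on permutation checks: the exhaustive 3v3 relabeling distribution
has only ten distinct values of |t| (each split pairs with its mirror
image), so permutation p-values move in steps of 0.1 and can only agree
closely with the t-distribution p in the strong-effect regime. The test
suite asserts their agreement there, which is where the knockdown effects
live.

## Interactome enrichment

Missing LFQ values are imputed from a Gaussian shifted 1.8 sample-SDs below
the sample mean with width 0.3 SDs — the standard left-censored imputation.
Per-protein two-sample t statistics are compared against a permutation null
built by relabelling samples (exhaustive when at most 100 relabelings
exist; 3v3 gives 20). The FDR estimate of a protein is the mean permuted
exceedance count of its |t| divided by the observed count, clipped to
[0, 1] and monotonised so q never decreases with |t| — a SAM-style
estimator with fudge factor s0 = 0. "Permutation-based FDR-corrected
t-tests" admits several concrete estimators; this fully specified one is
the package's choice and is documented here.
Volcano classification is strict: `log2_fc > 4.3` **and**
`-log10 p > 1.5`, both configurable; the bait protein is flagged
separately. Imputation compresses the fold change of low-baseline
interactors (their censored control cells are imputed near the sample
floor rather than at their true low values), so recovery of planted
interactors is perfect on complete matrices and slightly conservative
under heavy censoring — visible in the acceptance report when
`missing_rate > 0`.

## Domain phylogeny

Distances are p-distances with pairwise gap deletion (complete deletion
would waste too many columns of a ~50-residue domain); a Poisson correction
is available. NJ follows Saitou–Nei with the Q-criterion; ties break on the
smallest (row, column) pair so degenerate inputs resolve deterministically,
and negative branch estimates are clamped to zero with the deficit
recorded. On additive matrices the generating topology and branch lengths
are recovered exactly. Bootstrap supports resample columns with
replacement, rebuild the tree, and count replicates containing each
original bipartition (canonical key: the lexicographically smaller sorted
leaf-set string); leaves are canonically ordered first so input order
cannot change the resampling stream. Ortholog calling takes reciprocal
nearest cross-species neighbors by patristic distance; non-reciprocal
leaves — the signature of lineage-specific duplication — are reported
unpaired with their nearest neighbor listed. Each alignment row is one
leaf; concatenating or splitting multi-domain proteins is left to the
user.

## Granularity

Per-cell granularity is the coefficient of variation (population SD over
mean) of pixel intensities inside an externally supplied mask. CV is
invariant to uniform intensity scaling (so acquisition gain drops out) but
**not** to additive offsets; background subtraction is deliberately left to
the caller and none is applied by default. Population rather than sample SD
is used; with the required ≥100 mask pixels the difference is negligible.
No segmentation is performed — masks come traced.

## Numerical and design choices

* Alphabet is DNA (T, not U) throughout: sequencing reads are cDNA. Bias
  matrices report U for display.
* Zero-coverage bias columns are zero-filled and flagged in an attribute
  rather than emitted as NaN.
* Zero denominators in enrichment produce ±Inf sentinels with warnings;
  zero-variance t-tests produce p = 1 (equal means) or a p = 0 sentinel.
* All generators derive independent RNG streams from one master seed, so a
  config is a complete, byte-reproducible description of an experiment.

## Problem sizes

The shipped test suite and acceptance script run the study-scale
conditions: pair rate 1e4 per strand per category, 3+3 replicates,
500-protein LFQ matrices with 3v3 columns, 100-seed repetition for the
stochastic properties, 1000 bootstrap replicates for the clean-split
support check, 50 additive trees of up to 12 taxa in the acceptance script
(100 in the test suite), and 46–56 cells per image class. These sizes were
chosen so each property is measured at the scale its variance analysis
assumes while the whole suite completes in a few minutes on one CPU.
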