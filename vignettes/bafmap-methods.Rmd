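---
title: "Models and methods in bafmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bafmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bafmap)
```

`bafmap` covers the analysis stages that sit between aligned, peak-called
ChIP-seq data (and count-level screen/qPCR/proteomics data) and biological
conclusions about mSWI/SNF subcomplex occupancy. This vignette describes the
models, the tunable parameters and their defaults, the synthetic-data
generators the test suite relies on, and the design decisions made where the
underlying procedures are conventionally underspecified.

## Coordinates and interval algebra

All peak I/O uses the BED convention: 0-based starts, exclusive ends.
Internally peaks live in `GenomicRanges` (1-based closed); conversion happens
only at the file boundary, so coordinates round-trip bit-exactly. Two
intervals co-occur when their overlap length
`min(end) − max(start)` is at least `min_bp`; adjacent half-open intervals do
not overlap. `min_bp = 1` is the default everywhere, because peak callers
already impose their own significance thresholds and a single shared base is
the standard `bedtools intersect` notion of co-occupancy; raising `min_bp`
can only remove co-occupancy calls (a monotonicity the tests assert). Strand
is ignored: ChIP peaks are unstranded. Duplicate identical intervals within
a set are collapsed at load with a warning. ENCODE-blacklist subtraction is
available as an optional pre-step (`subtract_blacklist()`); no blacklist is
bundled.

## Subcomplex classification

A BRG1 peak is the anchor. The distinguishing subunits are DPF2 (BAF),
PBRM1 (PBAF) and BRD9 (ncBAF); the Boolean overlap triple at each anchor
maps deterministically onto eight classes, from `BAF+PBAF+ncBAF` down to
`BRG1_unassigned`. There is no hierarchy among subcomplexes: a site "bound
by all three" simply has all three Booleans true. Class counts always sum
to the number of BRG1 peaks (a partition, asserted as an invariant). PBRM1
peaks without BRG1 overlap are kept separately, since PBAF-like
promoter binding away from detectable ATPase peaks is a category of its own
in chromatin-state comparisons.

Co-occupancy tables report, per class × CRTF, the fraction of class sites
overlapped by at least one factor peak; empty classes report `NA`, never 0.
The reverse view (the share of a factor's peaks falling in each class) is
also emitted, since a high forward fraction can coexist with a small reverse
share when the factor binds broadly.

## Chromatin-state enrichment

Each peak is assigned to exactly one state by its midpoint, keeping peak
fractions a partition even when peaks straddle state boundaries; enrichment
is `log2[(peak fraction in s) / (bp of s / segmented bp)]`. Peaks whose
midpoints fall into unsegmented gaps are collected under a `"none"` state
whose genomic share is the gap's share of the genome (the row is omitted
when the segmentation covers everything). Count-weighting by midpoints was
chosen over bp-weighting because the binding categories compared (PBRM1
alone, PBRM1+BRG1, BRG1 alone, CRTFs) have very different width
distributions, and midpoint counting keeps the columns comparable.

## Peak-to-gene assignment and expression stratification

A gene is "bound" when at least one peak midpoint lies within ±50 kb of its
TSS — an enhancer-scale window; each peak is attributed to its nearest TSS
inside the window (ties broken by distance, then alphabetical gene symbol,
for determinism), and a gene inherits the occupancy class of its nearest
assigned peak. Expression changes per occupancy group are summarized by the
median log2 fold change with a seeded percentile bootstrap
(B = 2,000 by default) 95% confidence interval; the bootstrap is the
distribution-free default for medians of skewed fold-change distributions.

## Spike-in (ChIP-Rx) and in-peak normalization

RRPM scales each peak's read count per million spike-genome-mapped reads:
`raw × 1e6 / spike_total`. It is exactly linear in counts and inverse-linear
in the spike total, which is what makes occupancy comparable across
conditions whose IP efficiency differs. RPMPR scales per million reads in
the union peak set and sums to 1e6 per library — a within-library shape
normalization used for quartile displays.

Differential occupancy at a fixed site set uses
`Δ = log2(RRPM_t + c) − log2(RRPM_c + c)` with pseudocount `c = 0.5` (half a
read on the RRPM scale, the usual continuity correction; no pseudocount is
conventionally published for this readout). Writing the delta as a
difference of logarithms makes condition swap negate every value exactly to
the last bit. The across-site test is a paired Wilcoxon signed-rank: the
shift is displayed graphically in practice without a named test, and the
signed-rank makes no normality assumption about per-site log-ratios.
Quartile stratification ranks anchor peaks by signal into four bins whose
sizes differ by at most one (remainders to the lower quartiles, ties broken
by peak name for determinism); partner signal is 0 where no partner peak
overlaps.

## Screen scoring

Counts are normalized to reads per million per sample, replicate RPM columns
are averaged within (cell line, timepoint), and
`LFC = log2((late + 1)/(early + 1))` per guide and line (1 RPM pseudocount).
Guide-to-domain aggregation is the mean (median available); specificity is
the mean aggregate over RMS lines minus the mean over non-RMS lines, ranked
ascending so the most RMS-specific dependency is rank 1, ties broken by
target name. Negative-control guides form an empirical null; target z-scores
against that null are reported as an optional extra beyond the plain
ranking. Depth normalization introduces a small composition bias when many
guides drop out; the control-guide null absorbs exactly this, which is why
z-scores rather than raw specificity are the right flag at high hit
density.

## qPCR arithmetic

Amplification efficiency is fixed at 2 (perfect doubling), as the
power-of-two formulas imply. ChIP-qPCR percent recovery is
`2^(Ct_input − log2(X) − Ct_sample) × 100` with X the input dilution;
between-condition comparisons first correct sample Cts by the
exogenous-chromatin (Pgbs) primer difference, then use
`ΔΔCt = dCt_control − dCt_sample` and `FC = 2^(−ΔΔCt)`. Expression ΔΔCt uses
`dCt = mean Ct_target − mean Ct_reference` (GAPDH) per biological replicate.
Technical-replicate sets with SD > 0.5 cycles drop the replicate farthest
from the replicate median, iterating until SD ≤ 0.5 or two remain — the
published rule names the threshold but not the removal procedure, and
farthest-from-median is the deterministic choice that never empties the set.
Reported error bars are the min/max over biological replicates of the
back-transformed fold change, and a paired two-tailed t-test on per-replicate
dCt values accompanies each condition. Competition trajectories are
percentages of the day-2 baseline (`100 × pct(day)/pct(day 2)`).

## Proximity proteomics

Proteins need ≥ 2 peptides and ≤ 4 missing entries. Normalization is a
modified robust z-score per sample on log2 intensities:
`z = (x − median)/(1.4826 · MAD)`, rescaled to the median of the per-sample
medians and the median of the per-sample MADs so values stay on a
log2-intensity-like scale. Using medians-of-medians (rather than pooled
grand statistics) makes the transform exactly invariant to a location shift
of any single sample whose median rank does not cross the middle — the
property one wants from a between-run loading correction.

The two-group test shrinks per-protein pooled variances toward a prior
estimated by the method of moments on log variances (a scaled-F model with
per-protein residual degrees of freedom; the prior df comes from a
trigamma inversion). The moderated t uses the posterior variance with
augmented df. This is the standard empirical-Bayes construction, implemented
here directly so its behavior is a tested contract of this package; a unit
test cross-checks coefficients, prior df, t and p against an independent
implementation. Hits follow the volcano quadrant rule — log2FC > 2.5 and raw
p < 0.05; BH-adjusted p-values are reported alongside but do not gate the
default flag, matching how such volcano thresholds are applied in practice.

When all measurements of a protein are missing in one condition, the missing
group mean is replaced by the mean of the 10% smallest observed intensity
values in that condition across all proteins (ceiling of 0.1 × count, at
least one value), and the resulting log2FC is flagged as a pseudo fold
change. The 10% rule is applied to raw observed entries rather than
per-protein group averages — the finer granularity; the coarser reading
gives nearly identical imputations on realistic matrices. No other
imputation is performed. Note that a protein whose control is fully missing
*and* which misses a bait entry exceeds the 4-missing filter and never
reaches this route; the pseudo-fold-change contract applies to filtered-in
proteins.

## Synthetic data: what it emulates, and what it does not

All generators are driven by one root seed that fans out deterministically
to named child streams, so identical configs give byte-identical outputs
and no generator disturbs the caller's RNG state.

* **Peak sets** — a 3 × 10 Mb toy genome; 600-bp sites drawn uniformly over
  disjoint slots wide enough that jittered peaks of adjacent sites can never
  touch (same marginal uniformity as rejection placement, deterministic
  runtime; an overfull genome raises an error suggesting enlargement). Each
  site draws a latent class from the class multinomial; subunit peaks follow
  the class's Boolean triple with ≤ 100 bp jitter that preserves overlap;
  CRTF peaks follow a class × factor Bernoulli matrix concentrated on
  BAF-containing classes. Standalone PBRM1 sites model PBAF-only promoter
  binding. Signals are lognormal.
* **Spike-in libraries** — per-site lognormal weights shared across
  conditions; counts `Poisson(depth · weight · 2^effect)` at mean depth 100
  reads/site. The spike-mapped total is derived from the expected *baseline*
  (no-effect) library size at the configured 10% spike fraction: the spike
  models constant exogenous chromatin input, so a genuine global occupancy
  gain changes the human/spike ratio rather than being normalized away —
  the entire point of the ChIP-Rx design.
* **Screens** — negative-binomial counts (dispersion 0.2, depth 500
  reads/guide), 60 domains × 5 guides plus 30 controls across two RMS and
  two non-RMS lines with two replicates per timepoint; planted domains get
  log2 effect −2 in RMS lines only.
* **qPCR** — `Ct = baseline − log2(abundance) + N(0, 0.1)` cycles, 3
  biological × 3 technical replicates; the reference assay has abundance 1
  everywhere.
* **Proteomics** — 500 proteins, baseline log2 intensity N(20, 2), noise SD
  0.5, n = 4 per group, 20 planted 8-fold interactors; entries go missing
  with probability `plogis(−1.2 · (x − 16))` (missing-not-at-random, low
  intensities lost more often); five planted hits are forced fully missing
  in the control to exercise the pseudo-fold-change route.

What the generators do **not** emulate: read-level sequencing artifacts, GC
and mappability structure, fragment-length effects, peak-caller behavior,
correlated guide effects within a domain, batch effects, or the dependence
structure of real proteomes. Passing tests therefore demonstrate that each
algorithm recovers what it is designed to measure under its own stated
statistical model, not that the model captures every property of real data.

## Numerical choices and degenerate inputs

Zero spike totals, all-zero count vectors, zero-MAD samples, missing
baseline timepoints, absent control conditions and sites missing from a
library are all hard errors naming the offending entity — silent coercion
to 0 or NA is never used where a normalization becomes undefined.
Quartile and ranking tie-breaks are lexicographic for determinism. Empty
classes report `NA` fractions. The moderated test falls back to an
infinite-prior (fully pooled) variance when the variance distribution is
degenerate. Bootstrap and all simulations are seeded; bootstrap resampling
saves and restores the caller's RNG state.

## Pipeline and problem sizes

`run_pipeline()` executes simulate → classify → cooccupy → state-enrich →
chiprx → invade → integrate-expression, plus the independent screen, qpcr
and bioid stages, entirely under one run directory, and writes a manifest
(config, package version, md5 checksums keyed by relative path — no
timestamps) so identical runs are byte-identical. The test suite exercises
the stages at 200–10,000 sites, 100-seed replicates for the stochastic
recovery checks, and a 1,000-site double run for determinism — sizes chosen
so the full suite completes in well under a minute while keeping every
binomial recovery check adequately powered.

## Known limitations

* Read counting in peaks is upstream of this package: ChIP-Rx stages
  consume per-peak count tables, not BAM files.
* The moderated test contract is the shrinkage behavior, not bit
  compatibility with any particular implementation.
* Chromatin-state enrichment is midpoint/count-weighted; bp-weighted
  enrichment would differ for categories with very wide peaks.
* The planted-hit proteomics benchmark (20 planted 8-fold interactors,
  noise SD 0.5, n = 4/group) yields an observed log2FC distribution of
  N(3, 0.354²); with a 2.5 threshold the per-protein pass probability is
  ≈ 0.92, so runs recovering fewer than 18/20 planted hits are expected in
  a sizeable minority of seeds. This is a property of the thresholds at
  that effect size and noise, not an implementation defect.
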