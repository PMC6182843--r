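---
title: "Reference-gene stability and expression analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability and expression analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

## The problem

qPCR quantifies a transcript by the cycle `Cq` at which its amplification
signal crosses a threshold; one cycle difference corresponds to roughly a
two-fold difference in input when amplification is perfectly efficient.
Because samples differ in RNA input, reverse-transcription yield and
pipetting, target quantities are always expressed *relative to reference
genes* assumed uniformly expressed across conditions.  That assumption
must itself be validated: this package implements the standard validation
toolkit — efficiency calibration, four stability statistics, a consensus
selection, efficiency-corrected expression ratios with a randomization
test, and the Poisson tag-count test used when qPCR calls are compared
with a tag-sequencing experiment.

## Efficiency calibration

A serial dilution (by default five points, 10-fold apart, matching common
practice) gives the regression `Cq = b + m * log10(conc)`.  The per-cycle
amplification base is `E = 10^(-1/m)`; `m = -3.32` means perfect doubling
(`E = 2`, "100 %").  `fit_standard_curve()` uses ordinary least squares
and reports `r²` as the squared Pearson correlation with the sign of the
raw correlation kept in a separate column, since the fitted line always
falls and some reports print the signed coefficient.

Curves are accepted when the slope lies in the inclusive window
[−3.58, −3.10].  The window on the slope is the operative rule; the
often-quoted "90–110 %" efficiency gloss is not exactly equivalent
(−3.58 ⇒ 90.26 %, −3.10 ⇒ 110.17 %), so the slope bounds are
authoritative and the endpoints round to `E` = 1.9 and 2.1.

## From Cq to quantities

Methods that operate on the linear scale use relative quantities

`Q[g, s] = E_g^(min_s Cq[g, s] - Cq[g, s])`

so the most concentrated sample of each gene has `Q = 1`.  Gene-specific
efficiencies from calibration are used when available; otherwise `E = 2`.
Both modes are exposed because validation studies rarely state which was
fed into the stability tools.  All stability statistics are invariant to
per-gene additive Cq shifts, so the calibrator choice does not affect
rankings.

Technical replicates are averaged before any stability analysis;
biological replicates never are, because every stability statistic needs
biological variation to measure.  Samples missing any gene are dropped
(complete-case) with a message: all four methods assume a complete
matrix.  The preliminary screen (`cq_dispersion()`) flags genes whose Cq
standard deviation reaches 1 cycle (ddof-1, threshold configurable);
whether it runs on raw wells or technical-replicate means is a flag
(`use_tech_means`), since published tables rarely say which was used.

## The four stability statistics

**geNorm.**  For genes *j*, *k* the pairwise variation
`V[j,k] = sd_s(log2(Q[j,s]/Q[k,s]))`; the stability value of *j* is
`M_j = mean_k V[j,k]`.  The least stable gene (highest M) is removed and
M recomputed until two genes remain; those two cannot be ordered (only
ratios are measured) and share rank 1.5.  The number of reference genes
needed is decided by `V_n/n+1 = sd_s(log2(NF_n/NF_{n+1}))`, where `NF_n`
is the per-sample geometric mean of the *n* most stable genes' quantities:
the smallest *n* with `V_n/n+1` below the conventional 0.15 cutoff
suffices.  Ties in the exclusion argmax are broken by input order with a
warning.  With all `E = 2`, `V[j,k]` equals the SD of the per-sample Cq
difference, which is exactly the ΔCt method's pair statistic — the
package asserts this identity in its tests at 1e−12.

**NormFinder.**  Log2 quantities are centred per sample across genes
(removing shared loading effects exactly), then decomposed per
user-defined group (default control versus treated; per-time grouping via
`groups = "group_time"`).  The centring step biases the within-group
variances — with *k* genes the centred residual of gene *i* mixes all
genes' variances as `E[s²_i] = γ²_i (1 − 2/k) + Σ_j γ²_j / k²` — so the
raw variances are unmixed by solving that linear system and floored at
zero.  Inter-group deviations `d_ig` (group mean minus sample-size
weighted gene mean) are shrunk towards zero by
`τ²_g / (τ²_g + γ²_ig / n_g)`, with `τ²_g` the across-gene ddof-1
variance of the raw deviations.  The stability value is
`ρ_i = mean_g(|d̃_ig| + sqrt(γ²_ig / n_g))`; with a single group it
reduces to `sqrt(γ²_i)`.  Where the original description leaves latitude
the package fixes: variance floors at 0, `τ²` from the ddof-1 variance of
raw deviations, group sizes as weights.  Correctness is established
against an independently coded step-by-step oracle and by parameter
recovery on synthetic data, not by comparison with any binary tool
output.

**BestKeeper.**  Descriptive statistics are computed on raw Cq: geometric
and arithmetic means, extremes, dispersion, and `CV% = 100·SD/AM`.  The
default dispersion is the ddof-1 sample SD; the original spreadsheet
tool's mean-absolute-deviation variant is available (`sd_mode = "mad"`)
because printed tables usually cannot distinguish them at their rounding.
X-fold deviations translate cycles to fold changes on each gene's own
efficiency scale, `E^|Cq* − GM|`, signed negative when the extreme Cq is
*below* the geometric mean (more transcript than typical); `E^SD` is the
x-fold dispersion.  The BestKeeper index is the per-sample geometric mean
of all candidates' Cq; genes are ranked by descending Pearson correlation
with the index (two-sided t-test p-values floored at 0.001 for display).
Genes with dispersion above one cycle are flagged inconsistent and by
default demoted below all consistent genes.  Panels above ten genes
trigger a warning, matching the method's stated scope.

**ΔCt method.**  For every gene pair the per-sample Cq difference is
formed; a gene's score is the mean ddof-1 SD of its pairwise differences.
Because only between-gene differences enter, the statistic is invariant
both to per-gene constants and to shared per-sample loading shifts.

**Consensus.**  The package aggregates rankings by the geometric mean of
per-method ranks — a deliberately simple, order-invariant aggregate in
the style of popular web aggregators; it is plumbing, not one of the four
published statistics, and the per-method top-4 lists and their pairwise
overlaps are reported alongside so qualitative convergence can be judged
directly.  geNorm's unordered pair enters with shared rank 1.5 and can be
forced into the selected set (`anchor = "genorm"`).  The selected set
defaults to three genes: pairwise-variation analyses regularly show two
genes suffice, but three is the conventional safety margin against one
reference degrading in a new condition.

## Relative expression and the randomization test

The efficiency-corrected ratio for a target *t* against references *r* is

`R = E_t^(ΔCq_t) / geomean_r(E_r^(ΔCq_r))`, `ΔCq = mean(Cq_control) − mean(Cq_treated)`.

Equivalently, `log2 R` is the difference in group means of the per-sample
normalized log quantity `l_s = −b_t Cq_t,s + mean_r(b_r Cq_r,s)` with
`b = log2 E`; when all efficiencies are equal, any per-sample loading
constant cancels exactly.  Each treated time point is compared against
the accession's time-0 controls, matching the usual design where the
control group is sampled once.

Significance uses a fixed-reallocation randomization test: whole samples'
normalized quantities are reallocated between the groups (sizes
preserved), the statistic is `|log R|`, and the p-value is the fraction
of allocations at least as extreme as the observed one (which is always
included, keeping p > 0).  All `C(n1+n2, n1)` allocations are enumerated
exactly up to 100,000; beyond that a seeded Monte-Carlo sample of 2,000
(configurable) allocations is drawn with the observed allocation counted
in numerator and denominator.  The internals of the original REST tool
are unpublished, so this permutation scheme is fixed here and documented;
it is deterministic and oracle-checkable.

One resolution caveat follows directly: with three biological replicates
per side there are only 20 allocations and the two-sided p cannot fall
below 0.10, so no call is significant at 0.05.  `rest_analysis()`
therefore exposes `collapse_tech = FALSE`, which permutes individual
wells (9v9 for a 3×3 design) instead of biological means — finer
resolution at the cost of treating technical replicates as exchangeable
units.  Regulation calls are `UR`/`DR` when `p < alpha` and `R` is above
or below 1, otherwise `ns`; signed fold changes are `R` or `−1/R`.

Cross-platform validation uses the one-time-point rule: a comparison is
validated when the tag-sequencing call equals the qPCR call at at least
one time point, with `ns` counting as a call; the summary percentage is
rounded to the nearest integer.  The published call grid shipped in
`extdata` reproduces 9 validated comparisons of 16 (56 %).

## Tag-count differential expression

Given a tag seen `x` times in a library of `N1` total tags, the null
distribution of its count in a second library of `N2` is

`p(y|x) = (N2/N1)^y · (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`

— a negative binomial with size `x+1` and success probability
`N1/(N1+N2)`, the classical conditional Poisson test for tag counts.  The
`(x+y+1)` exponent makes the distribution sum to one, which the tests
verify by direct summation rather than assuming.  All evaluation goes
through log-gamma space (`pnbinom`), exact for counts far beyond
sequencing depths of interest.

Sidedness: the usual "double the smaller tail of `p(·|x)`" convention is
not symmetric under swapping the libraries — the discrepancy equals the
observed point mass, because the point ends up counted in both tails of
one orientation.  The package instead computes each direction's tail by
conditioning on the other library's count, `P(Y ≤ y | x)` and
`P(X ≤ x | y)`, doubles the smaller and caps at 1.  This is equivalent to
counting the observed point in exactly one tail, is exactly symmetric
under `(x, N1) ↔ (y, N2)` (asserted at 1e−12), and holds its nominal size
(analytically, rejection at 0.05 is 0.0496 at mean count 100).

Filtering: singlets — read as total count across both libraries equal to
one, with a per-library reading available since the phrase "sequenced
only once" is genuinely ambiguous — are excluded, as are sequences that
are not 26-mers anchored by `CATG` when sequences are provided.  Fold
changes use frequencies per million with zero counts replaced by one, and
the same signed convention as the qPCR side.  No multiple-testing
correction is applied by default, matching the per-tag `p < 0.05`
convention of tag studies; Benjamini–Hochberg is available
(`adjust = "BH"`).

## The synthetic-data generator

`simulate_cq()` draws

`Cq = μ_g + δ_g·1[treated] + s_sample + e_g,bio + t_g,well`

with Gaussian terms on the Cq scale: a shared per-sample loading effect
`s` (which induces exactly the inter-gene correlation that
sample-centring methods exploit and that cancels from ratio-based
statistics), per-gene biological noise `e`, and technical noise `t`.
Ground truth (each gene's designed class) accompanies every data set and
does not depend on the seed.

The default preset emulates a seven-gene candidate panel under stress in
two contrasting accessions (control plus three stress times, 3
biological × 3 technical replicates, 24 biological samples after
averaging): baselines 15.6–21.6 cycles; loading SD 0.35; biological noise
0.40–0.65 for the six stable genes and 1.10 for `EF1a`, which also
carries the designed 1.5-cycle treatment effect.  These values were
calibrated once so the *observed* per-gene Cq dispersions land where
validation studies report them — roughly 0.5–0.8 cycles for stable genes
and ≈1.35 for the unstable one, with CVs of 2–9 % — and are not adjusted
thereafter.

What the generator does *not* emulate: amplification-efficiency drift
between plates, non-Gaussian outliers (failed wells, evaporation),
co-regulated gene pairs, and heteroscedasticity at high Cq.  Passing the
recovery tests therefore shows the statistics behave correctly under the
error structure qPCR normalization assumes, not that any particular
laboratory data set satisfies that structure.

`simulate_dilution_series()` and `simulate_tags()` generate the
calibration and tag-count inputs analogously (Poisson counts at given
rates per million and library sizes, with designed null and fold-change
tags).

## Numerical conventions and degenerate inputs

* All SDs and variances are ddof-1 (sample) statistics.
* Ties (exclusion argmax, stability ranks, index correlations) break by
  input gene order, deterministically, with a warning; NormFinder ranks
  carry an explicit `tied` flag.
* The slope acceptance window is inclusive at both ends.
* Quantities must be strictly positive before logs; zero or negative Cq
  is rejected where geometric means are taken.
* Exact permutation p-values compare statistics with a 1e−12 slack so
  floating-point noise cannot drop mirror allocations.
* Dilution designs need at least 3 points and 2 distinct concentrations;
  stability methods need at least 3 genes (the NormFinder unmixing step
  divides by `k − 2`); single-gene BestKeeper panels degrade to the
  gene's own Cq with a warning.

## Scale of the verification suite

The test suite establishes correctness with, among others: oracle
equivalence of all four stability methods on 6-gene × 12-sample panels
(1e−10); the geNorm/ΔCt identity at `E = 2` (1e−12); parameter recovery
on 100 seeded preset data sets (the designed unstable gene ranks last for
every method in ≥95 runs and is never selected by the consensus); exact
3v3 enumeration against brute force and a 1,000-run null size check of
the randomization test at 5v5 (where the discrete allocation lattice
permits rejection at 0.05); and a 10,000-tag null size check plus a
direct-summation cross-check of the tag test up to counts of 200.  These
sizes keep the full suite around a minute on one core while leaving the
Monte-Carlo acceptance bands far wider than the simulation error.

## Known limitations

* Stability values from published tables cannot be reproduced without the
  underlying Cq data; fidelity rests on the oracle and recovery
  properties above.
* The exact reallocation test at the biological-sample level is
  conservative for tiny designs (see the resolution caveat); the
  well-level option changes the exchangeability assumption.
* BestKeeper's gene-versus-gene regression module and REST's
  confidence-interval output are out of scope; the ΔCt method is
  implemented on Cq differences only.
* The tag module treats each library pair as given: pooling of stress
  times into bulked libraries happens upstream and is not modelled.
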