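# qpcrstab

Selecting trustworthy reference genes is the make-or-break step of any
quantitative PCR (qPCR) expression study: every target-gene fold change is
measured *relative* to the normalizers, so an unstable normalizer silently
distorts every result. `qpcrstab` implements, as one coherent and tested R
package, the complete computational pipeline of a qPCR validation study:

* **Efficiency calibration** — per-primer amplification efficiency from
  serial-dilution standard curves, `E = 10^(-1/slope)`, with the
  conventional slope acceptance window of −3.58 to −3.10 (≈ 90–110 %).
* **Four reference-gene stability statistics** —
  * geNorm: expression stability `M` (mean SD of pairwise log₂ ratios),
    stepwise exclusion ranking, and the pairwise-variation series
    `V_n/n+1` between normalization factors that decides how many
    reference genes are needed (cutoff 0.15);
  * NormFinder: a model-based stability value combining bias-corrected
    intra-group variance with shrunken inter-group deviations;
  * BestKeeper: descriptive Cq statistics, x-fold deviations on each
    gene's own efficiency scale, and Pearson correlation with the
    per-sample geometric-mean index, with the SD > 1 inconsistency flag;
  * the comparative ΔCt method: mean SD of all pairwise Cq differences.
* **Consensus ranking** across methods (geometric mean of ranks, top-k
  overlaps, and selection of a reference set of three).
* **Efficiency-corrected relative expression** —
  `R = E_t^ΔCq_t / geomean_r(E_r^ΔCq_r)` with a fixed-reallocation
  randomization test (exact enumeration when feasible), signed fold
  changes (`FC = R` if `R ≥ 1`, else `−1/R`), UR/DR/ns regulation calls,
  and the cross-platform agreement rule against tag-sequencing calls.
* **Tag-count differential expression** — Audic–Claverie conditional
  Poisson test for tag libraries (HT-SuperSAGE-style 26-mers anchored at
  `CATG`), singlet and integrity filtering, tags-per-million fold changes
  with the zero→one convention.
* **Synthetic data** — seeded generators for Cq tables, dilution series
  and tag libraries with known ground truth, so the whole pipeline is
  testable end to end without laboratory data.

Everything is tidyverse-native: data frames in, tibbles out, with
`tidy()`/`glance()` methods and `autoplot()` figures for the fitted
objects.

## Worked example

Simulate a seven-gene candidate panel (two accessions, control plus three
salt-stress time points, 3 biological × 3 technical replicates) in which
`EF1a` is designed to be unstable, then screen, rank, and select:

```r
library(qpcrstab)

sim <- simulate_cq(cq_sim_config(seed = 42))
cq_dispersion(sim$cq)
#> # A tibble: 7 × 7
#>   assay gene      n mean_cq    sd cv_pct passes_screen
#>   <chr> <chr> <int>   <dbl> <dbl>  <dbl> <lgl>
#> 1 salt  ACT      72    20.3 0.752   3.70 TRUE
#> 2 salt  EF1a     72    17.3 1.64    9.52 FALSE
#> 3 salt  FBOX     72    21.9 0.670   3.06 TRUE
#> 4 salt  UBQ10    72    15.5 0.678   4.37 TRUE
#> 5 salt  UE21D    72    18.4 0.514   2.79 TRUE
#> 6 salt  UNK      72    20.0 0.647   3.24 TRUE
#> 7 salt  bTUB     72    19.8 0.710   3.59 TRUE
```

The screen flags `EF1a` (Cq SD above one cycle).  The four stability
methods and their consensus agree:

```r
gn <- genorm(sim$cq)
gn
#> geNorm stability ranking (lower M = more stable)
#> Most stable pair (unordered): bTUB / UE21D
#> # A tibble: 7 × 3
#>   gene   rank     m
#>   <chr> <dbl> <dbl>
#> 1 UE21D   1.5 0.456
#> 2 bTUB    1.5 0.456
#> 3 ACT     3   0.502
#> 4 UNK     4   0.576
#> 5 UBQ10   5   0.665
#> 6 FBOX    6   0.731
#> 7 EF1a    7   1.57
#> Optimal number of reference genes: 2 (V below cutoff 0.15)

cs <- build_consensus(list(genorm = gn,
                           normfinder = normfinder(sim$cq),
                           bestkeeper = bestkeeper(sim$cq),
                           deltact    = delta_ct(sim$cq)),
                      anchor = "genorm")
cs$selected
#> [1] "UE21D" "bTUB"  "ACT"
```

`V_2/3` is already below 0.15, so two genes would suffice; three are
selected as the conventional safety margin.  Relative expression of the
unstable gene against the selected reference set, each stress time versus
the time-0 controls (wells as permutation units):

```r
rest_analysis(sim$cq, targets = "EF1a",
              references = cs$selected,
              collapse_tech = FALSE, seed = 42)
#> # A tibble: 6 × 10
#>   gene  assay accession time_min ratio fold_change   p_value call
#> 1 EF1a  salt  sensitive       30 0.318       -3.15 0.0000411 DR
#> 2 EF1a  salt  sensitive       60 0.169       -5.91 0.0000411 DR
#> 3 EF1a  salt  sensitive       90 0.137       -7.28 0.0000411 DR
#> 4 EF1a  salt  tolerant        30 0.477       -2.10 0.207     ns
#> 5 EF1a  salt  tolerant        60 0.318       -3.14 0.00267   DR
#> 6 EF1a  salt  tolerant        90 0.125       -7.99 0.0000411 DR
```

The designed +1.5-cycle treatment shift is recovered as consistent
down-regulation (higher Cq = less transcript).  The published
tag-sequencing versus qPCR call grid summarizes with the one-time-point
agreement rule:

```r
summarize_agreement(cowpea_expression_calls())$pct_validated
#> [1] 56        # 9 of 16 comparisons validated
```

`run_pipeline(list(seed = 1), out_dir = "out")` chains all stages and
writes per-stage CSV/JSON outputs with fixed filenames
(`standard_curves.csv`, `dispersion_screen.csv`, `stability_*.csv`,
`consensus_ranks.csv`, `relative_expression.csv`, `summary.json`).

## Documentation

The methods vignette (`vignettes/reference-gene-stability.Rmd`) describes
the statistical models, the synthetic-data generator and its calibration,
numerical conventions, and known limitations.
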