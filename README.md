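# ctvar

Variance components and reference intervals for longitudinal qRT-PCR
biomarker panels.

## The problem

Circulating microRNAs measured by qRT-PCR are candidate clinical biomarkers
(the liver-enriched miR-122 is the canonical example), but a biomarker is
only usable prospectively if its normal range and its sources of variation
are known. A longitudinal healthy-volunteer study — `k` donors sampled at
`m` visits, each assay run in technical replicates on an array platform —
lets both be estimated, provided the analysis handles three things: Ct-level
quality control, normalization that removes per-sample handling artifacts,
and the within-donor correlation of repeated measurements.

`ctvar` implements that analysis as a tidyverse-style pipeline:

1. **Ingest & QC** (`read_replicate_table()`, `qc_replicates()`,
   `filter_assay_completeness()`): a replicate passes when its Ct lies in
   `[4, 25]`; a (sample, assay) cell reports the mean Ct of passing
   replicates when at least 2 pass; assays measured in fewer than 95% of
   samples are dropped (samples are never dropped).
2. **Normalization** (`select_normalizer_panel()`, `delta_ct()`): ΔCt
   against either (a) the per-sample mean Ct of an adaptively selected
   endogenous panel, or (b) an exogenous spike-in control. The panel is
   chosen by iterative stability elimination on the pairwise statistic
   `v(i,j) = SD_samples(Ct_i − Ct_j)`; relative expression is `2^(−ΔCt)`.
3. **Variance decomposition** (`fit_anova()`, `fit_reml()`): the one-way
   random-effects model `y_ij = μ + b_i + e_ij`, `b_i ~ N(0, σ²_b)`,
   `e_ij ~ N(0, σ²_w)`, fit per assay by method-of-moments ANOVA (with the
   unbalanced coefficient `m₀ = (N − Σn_i²/N)/(k−1)`) and, as a
   cross-check, by profiled REML. ICC = `σ²_b / (σ²_b + σ²_w)`.
4. **Reference intervals** (`effective_sample_size()`,
   `total_reference_interval()`, `component_fold_range()`): 95% intervals
   `center ± t_{df} · σ_total` with degrees of freedom from the Kish
   effective sample size `n_eff = N / (1 + (m̄−1)·ICC)`, `df = n_eff − 1`;
   fold-change span `2^(interval width)`. Component fold ranges use
   `t` at the component's own df (miRNA convention) or a fixed ±2 SD
   (clinical-chemistry convention).
5. **Cohort orchestration** (`run_study()`, `stratified_intervals()`,
   `correlate_with_enzymes()`) and a **synthetic-data generator**
   (`simulate_study()`) with recorded ground truth for parameter-recovery
   validation.

## Worked example

```r
library(ctvar)

sim    <- simulate_study(simulation_config(seed = 42))   # 40 donors x 6 visits x 4 replicates
cfg    <- study_config(spike_in_assay = "spike-in-control",
                       correlate_assay = "miR-122")
report <- run_study(sim$ct, sim$metadata, cfg)
report
#> Cohort study report
#>   assays analysed: 18 | schemes: panel, spike_in
#>   normalizer panel: miR-106a, miR-17-5p, miR-19b-3p, miR-20a-5p, miR-20b
#>   enzymes: ALT, AST

dplyr::filter(report$assays, assay_id == "miR-122")
#>     scheme mean_dct sigma2_between sigma2_within   icc percent_between
#> 1    panel     4.40           1.64          1.45 0.531            53.1
#> 2 spike_in     5.04           1.63          1.49 0.523            52.3
#>     scheme lower_dct upper_dct fold_total fold_between fold_within
#> 1    panel    0.8901     7.909      129.7        36.23       26.83
#> 2 spike_in    1.5104     8.574      133.8        36.05       28.24
```

The generator's miR-122 truth is `σ²_b = 1.47`, `σ²_w = 1.49` on the ΔCt
scale: this single realization recovers an ICC near 0.5 (variation split
roughly evenly between and within donors) and a total 95% reference span of
~130-fold in relative expression — a high-variability marker. The enzyme
table shows the opposite pattern for ALT (~83% of variance between donors,
~5-fold total span under the ±2 SD convention):

```r
report$enzymes
#>   enzyme component std_dev variance percent fold
#> 1    ALT   between   0.548   0.3002    83.4 4.57
#> 2    ALT    within   0.244   0.0598    16.6 1.97
#> 3    ALT     total   0.600   0.3600   100.0 5.28
#> ...
```

`plot_reference_intervals(report)` and `plot_variance_components(report)`
draw the per-assay interval and component-split figures;
`write_study_report(report, "out/")` emits all tables as TSV.

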