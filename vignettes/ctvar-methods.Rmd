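---
title: "Methods: variance components and reference intervals for qRT-PCR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance components and reference intervals for qRT-PCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvar)
library(dplyr)
```

## The measurement model

A longitudinal qRT-PCR biomarker study measures a panel of assays on serum
from `k` donors at `m` visits, each sample run in technical replicates.
`ctvar` models the observed cycle threshold for assay $a$, donor $d$,
visit $v$, replicate $r$ as

$$
Ct_{advr} = \mu_a + s_{dv} + b_{ad} + w_{adv} + \varepsilon_{advr},
$$

with independent Gaussian terms: a donor-level random intercept
$b_{ad} \sim N(0, \sigma^2_{b,a})$ (stable donor-to-donor differences), a
visit-level deviation $w_{adv} \sim N(0, \sigma^2_{w,a})$ (within-donor
biological fluctuation), a per-sample handling shift $s_{dv}$ shared by
*every* assay in the sample including the exogenous spike-in channel
(extraction efficiency, reverse-transcription yield, loading), and
replicate noise $\varepsilon$. The scientific targets are, per assay, the
biological components $\sigma^2_b$ and $\sigma^2_w$ and the population
reference interval of single measurements — which requires the handling
shift $s$ to be removed by normalization, and the replicate noise to be
averaged out.

## Quality control

Replicates pass QC when the Ct is present and inside `[ct_min, ct_max]`
(defaults 4 and 25 cycles, the plausible detection window of a 40-cycle
array protocol after pre-amplification). A (sample, assay) cell reports the
arithmetic mean of passing replicates when at least `min_replicates`
(default 2) pass, and is missing otherwise; no trimming is applied.
Whether a Ct of exactly 25 passes is a convention choice that instrument
vendors disagree on; the default is inclusive (`qc_config(inclusive_bounds
= TRUE)`), with the strict alternative one flag away. Assays are retained
only when at least 95% of samples have a reportable mean Ct; samples are
never dropped by completeness, only assays, so the donor-visit design is
preserved. The spike-in control is exempt from the completeness filter
because it is the normalizer, not an analyte.

## Normalization

Two ΔCt schemes are provided.

**Endogenous panel.** An adaptive stability-selection algorithm picks
`panel_size` (default 5) assays whose Ct values co-move across samples:
for candidates $i, j$ let $v(i,j)$ be the SD across samples of
$Ct_i - Ct_j$; assay stability is $M_i = \mathrm{mean}_{j \ne i}\, v(i,j)$;
the least stable assay is removed and scores recomputed until the panel
remains. This is the classic pairwise-variation elimination scheme for
reference-gene selection, used here as a deterministic surrogate for
adaptive normalizer-selection tools whose internals are not published. Two
properties matter: $v(i,j)$ is invariant to any per-sample shift common to
both assays, so the algorithm rewards *co-movement* (tracking $s_{dv}$)
rather than mere flatness; and it is deterministic, with ties broken so
that a fully tied candidate field leaves the lexicographically first ids.
On fixtures with up to 12 candidates the greedy elimination agrees exactly
with exhaustive best-subset search (tested). The mean pairwise Pearson
correlation of the final panel is reported as a diagnostic — near-zero
correlation means there is no shared sample-level signal for the panel to
cancel, and a warning is emitted (threshold 0.2).

ΔCt is the assay Ct minus the mean Ct of the panel members; a sample
missing any panel member loses its panel-scheme ΔCt for *all* assays,
keeping the reference definition uniform across assays. The panel is
selected once on the full retained matrix and held fixed for all
downstream analyses, including stratified ones — stratum-specific panels
would confound stratum comparisons with normalizer changes.

**Spike-in.** ΔCt is the assay Ct minus the Ct of the exogenous control.
This removes $s_{dv}$ only to the extent that the spike-in channel shares
it — which is the premise of spike-in normalization (it controls
processing, not in-vivo biology).

Relative expression is $2^{-\Delta Ct}$; the arithmetic mean of ΔCt maps to
the geometric mean of expression. Whether the panel reference is the
arithmetic mean of Ct or the geometric mean of linear expression is
immaterial: they coincide under the base-2 transform.

## Variance decomposition

Per assay, the one-way random-effects model is fit to the per-sample ΔCt
grouped by donor. The primary estimator is method-of-moments ANOVA:
$\hat\sigma^2_w = MSW$,
$\hat\sigma^2_b = \max\{0, (MSB - MSW)/m_0\}$ with
$m_0 = (N - \sum_i n_i^2/N)/(k-1)$, which handles the unbalanced designs
that arise when the completeness filter removes cells (e.g. an assay
observed in 228 of 240 samples). Negative moment estimates are truncated
to zero. The estimators are implemented directly rather than delegated to
a mixed-model package so that the computation is owned and auditable; a
profiled-REML estimator (`fit_reml()`, one-dimensional search over the
variance ratio $\lambda = \sigma^2_b/\sigma^2_w$ with $\sigma^2_w$
profiled out in closed form) serves as an internal cross-check. On
balanced designs with interior solutions the two coincide — a known
equivalence that the test suite verifies to $10^{-6}$ relative on 100
random datasets, alongside agreement with an independent mixed-model
fitter on unbalanced data. Whether the original analyses of such cohorts
used ML or REML is typically unstated; on a balanced 40 × 6 design the
distinction is immaterial at the reported precision.

The ICC is $\sigma^2_b/(\sigma^2_b+\sigma^2_w)$, defined as 0 when the
total is 0, and the percentage split is the component over the total.

## Reference intervals and the effective sample size

The 95% reference interval for single measurements is
$\text{center} \pm t_{df}\,\hat\sigma_{total}$. Because repeated samples
from one donor are correlated, the $t$ degrees of freedom are not $N-1$:
the Kish design effect $D = 1 + (\bar m - 1)\,ICC$ with mean cluster size
$\bar m = N/k$ gives an effective sample size $n_{eff} = N/D$, and
$df = n_{eff} - 1$. The df is kept continuous rather than floored —
`qt()` accepts real df, flooring would discretely widen intervals, and the
continuous choice reproduces the published interval chains this package is
validated against (for ICC ≈ 0.5 at 40 × 6, $n_{eff} \approx 69$ and the
multiplier ≈ 2.00). For an ICC of 0 the interval approaches the normal
±1.96 SD limit; for ICC 1 it is governed by the donor count alone.

The fold-change span is $2^{\text{width}}$, identical to the ratio of the
relative-expression bounds. Per-component fold ranges support three
conventions (`component_fold_range()`):

* `t_component_df` (default for miRNA ΔCt tables): $2^{2 t \cdot SD}$ with
  df $= k-1$ for the between component and $N-k$ for within — each
  component at the df of its own ANOVA stratum. For the total component
  this policy falls back to the effective-n df, since the total has no
  single stratum.
* `fixed_2sd` (default for clinical-chemistry analytes): $2^{4 \cdot SD}$.
* `t_effective_n`: the total-interval multiplier applied to any component.

Enzymes (ALT, AST) are analysed on the log2 scale through the same
variance-component and interval machinery, with the `fixed_2sd` policy.

## The synthetic-data generator

`simulate_study()` draws data from exactly the model above, so parameter
recovery is a meaningful validation: the estimators should be unbiased for
the generator truths, and estimated intervals should cover ~95% of fresh
observations. Defaults describe a realistic longitudinal cohort:

* **Design**: 40 donors × 6 visits × 4 technical replicates.
* **Assay truths** (`inst/extdata/default_assay_truths.csv`): 18 assays
  spanning the variance regimes of abundant serum miRNAs — five tightly
  co-moving low-variance assays (σ² of 0.01–0.05) suitable as a normalizer
  panel, mid-variance assays, and a high-variance liver marker
  (σ²_b = 1.47, σ²_w = 1.49, mean Ct 17.6). Mean Cts sit inside the QC
  window so that only genuine tail events fail QC.
* **Handling shift**: SD 0.5 cycles. No published estimate exists for this
  nuisance; 0.5 cycles is large enough that normalization visibly matters
  and small enough that the QC window is rarely crossed.
* **Replicate noise**: SD 0.15 cycles, a typical array-platform technical
  SD. Acceptance-level checks are insensitive to this choice by
  construction, since cells report replicate means (0.15²/4 ≈ 0.006
  cycles² added to the within component).
* **Spike-in channel**: mean Ct 12.8, handling shift and replicate noise
  only — no biological components, encoding the premise that an exogenous
  control reflects processing alone.
* **Degradation**: 1% missing replicates, 2% out-of-range replicates.
  Out-of-range injection replaces the Ct with a uniform draw on (25, 30] —
  failure on the high side, the common qPCR mode (late or no
  amplification); low-side failures are rarer and are exercised in tests
  directly.
* **Strata**: donors alternate between two ethnicity labels;
  `ethnicity_variance_ratio` scales the biological variance of one stratum
  to emulate differential variability, for testing stratified analyses.
* **Enzymes**: log2-scale one-way draws with ALT-like (0.28/0.06,
  between-dominated) and AST-like (0.06/0.07, balanced) truths.

All stochastic terms are drawn as standard normals and scaled, so two
configurations differing only in variance magnitudes share their entire
realized structure under the same seed — which is what makes the
shift-cancellation test exact, and guards against the R quirk that a
zero-SD `rnorm` call does not consume the RNG stream.

What the generator does *not* emulate: amplification-efficiency
differences between assays, melt-curve failures, non-Gaussian heavy-tailed
biological variation, circadian or dietary covariate structure, and any
dependence between missingness and signal level (missingness is injected
completely at random, whereas real low-abundance assays fail
preferentially). Passing parameter-recovery tests therefore demonstrates
correctness of the estimators under the stated model, not robustness to
these violations.

## Numerical and design choices

* **Degenerate inputs**: zero total variance gives ICC 0, a point interval
  and fold 1; a single donor, or all-singleton donors, raise classed
  errors rather than returning undefined components.
* **REML boundary**: the profiled objective is minimized over
  $\lambda \in [0, 10^6]$ and compared against the boundary value
  $\lambda = 0$, so MSB < MSW cleanly yields a zero between component;
  hitting the upper bound raises a numerical error.
* **Tie-breaks** in panel elimination are lexicographic (removing the
  lexicographically last id among equally unstable assays), making the
  selection fully deterministic.
* **Stratification** is donor-level only; a donor's visits are never split
  across strata, and strata with fewer than 2 donors are skipped with a
  warning rather than fitted.
* **Correlations** with enzyme levels use $-\Delta Ct$ (log2 expression, so
  higher = more expressed) against log2 enzyme level, pairwise complete;
  no multiple-testing correction is applied anywhere in the package.
* **Problem sizes** used by the test suite and acceptance script — studies
  of 40 × 6 with up to 500 simulation replicates, fixtures of ≤ 15 assays
  — were chosen as the smallest sizes at which Monte-Carlo error is well
  below the tolerances being asserted.

## Known limitations

* The panel-selection surrogate is a pairwise-variation scheme; other
  adaptive normalizer-selection algorithms may choose different panels on
  real data, and no claim of equivalence to any specific published tool is
  made.
* Reference intervals assume Gaussian ΔCt; heavy tails in real serum data
  would make 95% coverage optimistic. Nonparametric intervals are out of
  scope.
* The effective-sample-size df is an approximation for unbalanced designs
  (it uses the mean cluster size); for severely unbalanced cohorts a
  Satterthwaite-type df would be preferable.
* Donor-level exclusions on clinical-chemistry criteria are expected to
  happen before ingestion; the package does not automate upper-limit-of-
  normal screening, whose thresholds are laboratory-specific.
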