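---
title: "Measuring and analysing leukocyte telomere length across pregnancy with telopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and analysing leukocyte telomere length across pregnancy with telopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telopipe)
library(dplyr)
```

## The measurement model

Relative leukocyte telomere length (LTL) is expressed as a **T/S ratio**: the
telomere-repeat qPCR signal (T) divided by the single-copy-gene signal (S,
human beta-globin) for the same DNA sample. Each qPCR run carries a reference
DNA dilution series (26, 8.75, 2.9, 0.97, 0.324, 0.108 ng); ordinary least
squares of Cq on log10(quantity) gives the run's standard curve, and the
per-cycle amplification efficiency follows from the slope as

$$E = \left(10^{-1/\text{slope}} - 1\right) \times 100\%.$$

Unknowns are run in triplicate wells per target. The quantity of template in
a well is interpolated as $10^{(Cq - \text{intercept})/\text{slope}}$, and
the sample's raw T/S is the ratio of the mean retained T and S
concentrations.

### Triplicate QC: Dixon's Q on the Cq scale

One well of a triplicate occasionally fails grossly (evaporation, double
loading, mis-seal), displacing its Cq by several cycles. Dixon's Q test for
$n = 3$ flags the extremum farther from the median when
$Q = \text{gap}/\text{range}$ exceeds the two-tailed critical value (0.970 at
$\alpha = 0.05$; 0.941 and 0.994 at 0.10 and 0.01 — $\alpha$ is exposed as
`dixon_alpha` because the level is a convention, not a measurement).

The test is applied to the **Cq values**, not the interpolated quantities.
This is a deliberate numerical choice: well noise is approximately normal on
the Cq scale, where the test is symmetric in the outlier's direction. On the
quantity scale the transform $10^{-Cq/|s|}$ is so convex that a well
displaced toward *low* quantity compresses the statistic toward the ratio of
the two good wells ($Q \to b/c$ as the outlier $a \to 0$); whenever the good
wells differ by more than ~3%, a 5–10-cycle outlier then escapes the test
entirely and corrupts the triplicate mean. Averaging of the retained wells
still happens on the concentration scale (mean of quantities, not
mean-Cq-then-interpolate — the two differ under noise because the transform
is convex).

### Duplicates, third runs, and batch adjustment

Every sample's T/S is measured on two runs. If the duplicates differ by more
than 7% the sample is measured a third time and the mean of the two closest
values is reported (ties in closeness go to the pair containing the earliest
run). The base of the 7% percentage is the mean of the two values — a
symmetric convention, configurable (`denominator = "first"` or `"min"`)
because the rule's base is a convention rather than a measurement.

Between-run drift is corrected with 8 control DNAs repeated on every run
(3 T wells + 3 S wells each, i.e. 6 wells per control). A per-control
reference is the mean of the first 10 runs; each run's adjustment factor is
the mean over controls of reference/observed, so a run reading high is scaled
down, and adjusted = raw × factor. The orientation is verified by a
cancellation property: on noiseless synthetic plates the adjustment removes
any planted run multiplier to machine precision.

Concordance and third-run resolution operate on **adjusted** values. The two
replicates of a sample live on different runs, so a single run factor cannot
be applied to a cross-run mean; adjusting first is the only coherent order.

Assay precision is summarised as the coefficient of variation: per-control
SD/mean of the adjusted T/S values across runs, averaged over the 8 controls.

## Cohort analysis

Draws are windowed into three timepoints: up to $20^{0/7}$ weeks (T1),
$20^{1/7}$–$36^{6/7}$ weeks (T2), and $37^{0/7}$ weeks through 9 weeks
postpartum (T3). A draw at exactly $20^{0/7}$ weeks sits on a boundary the
window definitions leave open; it is assigned to T1 with a warning.
Postpartum draws are placed on a common pseudo-gestational-age scale as GA at
delivery plus postpartum weeks, capped at 50 weeks. GA is always serialized
as two integer columns (weeks, days) to avoid the $35^{5/7}$-style decimal
ambiguity.

Within-person change between two timepoints is tested with the two-sided
Wilcoxon signed-rank test on per-subject differences. Conventions the source
analyses leave unstated are fixed as: zero differences dropped (Wilcoxon's
original treatment); the exact distribution when the informative $n \le 25$
with untied absolute differences; otherwise the normal approximation with
mid-rank tie correction. The three pairwise comparisons (1–2, 2–3, 1–3) are
reported without multiplicity correction, matching the descriptive reporting
style; `holm = TRUE` adds Holm-adjusted p-values. Postpartum LTL is compared
between vaginal and cesarean births with the Wilcoxon rank-sum test (exact
when the combined $n \le 20$ without ties), and the age-adjusted effect is
estimated by OLS of log(LTL) on a cesarean indicator plus maternal age with
a 95% CI. Exactness of both tests is verified against full enumeration of
sign assignments / group labelings for $n \le 10$.

Descriptive tables follow the clinical convention: categorical cells as
n (percent to 1 decimal, half-up rounding), with each variable's percentage
denominator excluding its own missing values; continuous variables as
mean ± SD. Per-item survey completeness is respondents over the item's
eligible denominator.

## Stress-profile screening

The 79 survey features are mixed-type. Inferred typing uses: ≤ 2 observed
levels → binary; non-numeric or integer-coded with ≤ 6 levels → categorical;
otherwise numeric. The rule intentionally classifies a 7-level Likert item as
numeric; where that is not wanted, declared types override inference (the
packaged generator declares all of its types).

Univariate association with LTL dispatches by type — Kendall's tau-b
(numeric), Kruskal–Wallis (categorical), Wilcoxon rank-sum (binary) — run
separately against two outcomes: Timepoint 1 LTL and the mean of available
timepoints. No multiplicity correction is applied at the screening stage;
the network display encodes raw p-values.

For the correlation network, missing cells are first median-imputed (numeric:
median; binary: median rounded to the nearest observed level, lower on ties;
categorical: mode, lowest-coded level on ties). The Spearman correlation
matrix of the numerically coded features is computed, and the rows of its
absolute-value matrix are embedded in 2-D with t-SNE. The embedding
parameters are fixed for determinism and recorded in the result's `params`:
perplexity $\min(15, (p-1)/3)$, exact (theta = 0) gradient, no PCA
preprocessing, a fixed seed. Nodes are sized by $-\log_{10}(p)$, coloured
when $p < 0.1$ (orange positive, blue negative association), bold when
$p < 0.05$; edges connect pairs with $|r| \ge 0.3$ (thin) and $|r| \ge 0.7$
(thick). Edge classes are checked against brute-force pair-by-pair counts.

Collective predictive power is assessed with support-vector regression
(radial kernel, `e1071` defaults — no hyperparameter search by design)
under 10-fold cross-validation, reporting out-of-fold $R^2$ and MSE.
Because "significant predictive power" needs a reference for a CV metric,
significance is defined against a permutation null: the outcome is permuted
100 times with the same fold assignment, and the observed $R^2$ must exceed
the null's 95th percentile.

## What the synthetic generator emulates

`sim_config()` / `simulate_study()` generate the full measurement chain with
known ground truth:

* per-subject baseline T/S ~ Normal(1.15, 0.26), the study's headline level;
* a planted within-person trajectory: total change `within_person_drift`
  (default −0.07 T/S) across pregnancy, parameterised as progress 0 at 12
  pseudo-GA weeks (the mean T1 draw) and 1 at 43 weeks (the mean T3 draw);
* per-draw biological fluctuation (`residual_log_sd`, default 0.13 on the
  log scale) chosen so the paired T1–T3 difference SD is near 0.21;
* a cesarean rate of 39.1% with a planted −0.18 log T/S shift on postpartum
  draws;
* draw windows mirroring the study: T1 ~ N(12.0, 2.6) weeks, T2 ~ N(26.5,
  1.8), delivery ~ N(39.1, 1.3) truncated to ≥ 37 weeks, ~91% of T3 draws
  postpartum (≤ 63 days), with per-timepoint draw probabilities matching the
  observed 41/39/35 of 46 sample counts;
* plates: the printed dilution series, 8 control DNAs, triplicate wells,
  Cq noise (default SD 0.04 cycles), log-normal per-run drift applied to the
  T target (a common multiplier on both targets would cancel in the ratio
  and be unobservable), and gross outlier wells displaced by 5–10 cycles
  with random sign at `outlier_rate`;
* a 79-feature survey: one designated `sleep_quality` feature whose latent
  score shifts baseline T/S by `sleep_effect` (default 0.16 per SD,
  back-solved from the reported strength of the sleep association at
  $n = 27$), and 78 effect-free features loading on 8 latent factors
  (loadings drawn once per seed) rendered as numeric/binary/categorical
  columns with MCAR missingness.

The Cq noise default is a prescribed calibration: with triplicate averaging,
the T/S ratio combining two targets, and control-based adjustment, an SD of
0.04 cycles puts the pipeline's control CV near the 2.2% design point
(verified empirically at ~1.9–2.3% across seeds).

**What it does not emulate.** No raw fluorescence curves (Cq is generated
directly), no plate-position or edge effects, no PCR inhibition or
DNA-quality gradients, no informative missingness in the survey, no
confounding between stress features and delivery mode, and between-run drift
magnitude (default log-SD 0.06) is a free parameter because no study value
exists. Passing parameter-recovery tests therefore demonstrates correctness
of the estimators under these idealised conditions, not robustness to the
artefacts real plates can show.

## Numerical and design choices

* **Dixon on Cq, averaging on quantities** — see above; the asymmetry on the
  quantity scale is the reason.
* **Run factors are arithmetic means** of the 8 control factors, matching the
  described correction; a geometric mean would be the log-scale analogue but
  the arithmetic convention is kept.
* **Half-up rounding** to 1 decimal for printed percentages (base `round()`
  is round-half-even and disagrees on exact .05 boundaries).
* **Exactness switches**: signed-rank exact at informative $n \le 25$
  (untied), rank-sum exact at combined $n \le 20$ (untied) — beyond that the
  normal approximation with tie correction is numerically indistinguishable
  at the suite's tolerances.
* **Degenerate inputs**: zero-range triplicates skip the Q test; constant
  features return a degenerate association with $p = 1$; constant columns in
  the correlation matrix get zero correlation with a warning; all-missing
  features are a typing error.
* **Determinism**: every stochastic stage (generator, embedding, CV folds,
  permutations) derives its stream from an explicit integer seed; identical
  configurations are byte-identical, which the suite asserts.
* **Problem sizes in the checks**: oracle-equivalence checks run 10,000
  random triplicates/triples and full enumeration up to $n = 10$; parameter
  recovery uses cohorts of 200–500 subjects; calibration rates use
  2000 (type-I) and 200 (power) simulated cohorts; the permutation-CV null
  behaviour uses 100 simulated 27-subject studies. These sizes keep
  Monte-Carlo error well inside the asserted bands.

## Worked example

```{r example, eval = FALSE}
library(telopipe)

config <- sim_config(n_subjects = 46, seed = 11)
res <- run_pipeline(config)
res
#> Telomere pipeline results
#>   samples quantified: 107 (46 subjects)
#>   assay CV: 1.99%
#>   mean T/S at timepoint 1: 1.11 +/- 0.29
#>   mean T/S at timepoint 2: 1.19 +/- 0.33
#>   mean T/S at timepoint 3: 0.99 +/- 0.27
#>   cesarean effect on log T/S: -0.241 (95% CI -0.439 to -0.042)

res$timepoint_comparisons
autoplot(res$network)
plot_trajectories(res$ltl)
```

## Known limitations

* The generator's trajectory is linear in pseudo-GA progress; real telomere
  dynamics may be nonlinear, and the paired estimators here do not model
  trajectory shape.
* `delivery_mode_model()` adjusts for maternal age only, mirroring the
  analysis it implements; it is not a general confounder-adjustment tool.
* Dixon's Q with $n = 3$ has limited power for moderate (1–3 cycle)
  displacements; only gross failures are reliably removed.
* t-SNE coordinates are a visualization device: distances in the embedding
  are not calibrated, and only edge classes (not positions) are asserted by
  tests.
* The SVR significance call is relative to its own permutation null; it is
  not an absolute measure of predictive value.
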