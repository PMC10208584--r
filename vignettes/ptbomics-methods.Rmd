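---
title: "Methods: multiomic and epidemiological modeling of preterm-birth cohorts"
author: "ptbomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomic and epidemiological modeling of preterm-birth cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbomics)
```

## The setting

Preterm birth (PTB) — delivery before 37 completed weeks of gestation — is
studied here through two coupled designs: a large multi-site epidemiological
cohort in which maternal covariates (anthropometry, bloodwork, medical and
obstetric history, socioeconomic determinants, ultrasound measurements)
predict the PTB outcome; and a smaller case-control subcohort, matched
within site on gestational age (GA) at sampling, whose plasma proteome,
metabolome and lipidome are profiled in early-to-mid pregnancy. `ptbomics`
implements the full analysis machinery for such a design: the correlation
interactome across omic layers, multivariate prediction of clinical targets
(PTB, time-to-delivery, GA at sampling, BMI, age, gravidity) under a
repeated cross-validation scheme, minimal-panel selection, a
gestational-clock discrepancy analysis, and a minimum-spanning-tree (MST)
covariate network — plus a synthetic-data generator that emulates the study
so every stage is testable without access to restricted participant data.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults define the
conditions under which the package's statistical guarantees are stated.

**Full cohort.** `generateFullCohort()` draws (by default) 2,000
participants over five sites. Covariates are generated per clinical
category from latent-factor models — covariates within a category share a
latent factor, so within-category correlation exists for the network stage
to find. The PTB outcome follows a logistic model whose strongest risk
covariates are multiple fetuses, prior preterm birth and prior Cesarean
delivery; the intercept is calibrated by root finding so the realized
prevalence matches the 11.4% regime of a large multi-site pregnancy cohort,
and the effect sizes are set so the population risk score discriminates at
AUROC ≈ 0.70, the regime such cohorts report. At the default 2,000
participants the learned cross-validated model recovers part of that
(AUROC ≈ 0.6) — the expected small-sample attenuation for weak, sparse,
largely binary effects. GA at birth is continuous (weeks), consistent with the outcome (PTB iff GA
< 37), and excludes extreme preterm (< 28 weeks); GA at sampling is an
early-to-mid pregnancy visit (mean 12.2, SD 3.2 weeks). Obstetric-history
covariates are missing for about a fifth of participants, mirroring the
heterogeneous completeness of antenatal registries; the tree learner
handles those natively and the covariate network uses pairwise-complete
correlations.

**Matched subcohort.** Cases and controls are selected site by site
(proportionally to site case counts) and matched greedily without
replacement on GA at sampling; the design targets the ~49% case fraction of
a 231-participant case-control subcohort. Greedy nearest-neighbour matching
is a deliberate, simple choice: with realistic site sizes the median
within-pair GA gap is far below one week.

**Omic layers.** Each omic is generated on a Gaussian-copula latent layer:
standard-normal features with equicorrelated intra-omic blocks
(`z = sqrt(rho) u_b + sqrt(1-rho) e`), inter-omic coupling by sharing block
factors between omic pairs (concentrated in lipid–metabolite and
protein–metabolite links, the pairs that dominate real interactomes), and
marginal transforms that mirror assay scales: unbounded NPX-like proteome
(`5 + 2z`), right-skewed log-normal metabolome (`exp(1 + 0.8z)`), positive
lipid concentrations (`10 exp(0.5 + 0.6z)`). All transforms are strictly
monotone, so Spearman structure and monotone signals pass through them
unchanged. Missing cells are MCAR at 2% by default.

**Planted signals and their calibration.** Signal features are overwritten
as `a_j * t + sqrt(1 - a_j^2) * e` on the latent scale, with `t` the
standardized target. Loadings are calibrated in closed form from relative
signal-to-noise weights: with independent feature noises, SNRs add, so the
optimal linear read-out of features with loadings `a_j` has population
`R^2 = S/(1+S)` with `S = sum a_j^2/(1-a_j^2)`; given a target `R^2` and
weights `w_j`, the generator solves for the `a_j` exactly
(`signalLoadings()`). Default targets: time-to-delivery `R^2 = 0.5`
(6 proteome features), GA at sampling 0.7 (14 features across proteome and
metabolome), BMI 0.65, maternal age 0.35, gravidity 0.30 (with two features
loading on the age-orthogonal component of gravidity, making them
age-independent markers by construction).

Three signal-geometry choices matter and were made once, by design:

* The three designated minimal-panel features carry weight 20 versus 1 for
  the remaining time-to-delivery features (direct correlation about 0.49
  each with time-to-delivery), making the panel an engineered ground truth
  for stability selection.
* Panel features additionally carry a secondary loading (−0.25) on the
  gestational-age axis, composed so the feature keeps unit latent variance.
  This mirrors how the strongest real time-to-delivery correlates are
  placental and fetal proteins that track gestational progression itself,
  and it matters for identifiability: in a multivariate tree model the
  third of three features sharing one latent target is partially redundant,
  while any GA-informative feature adds orthogonal gain. Coupling the panel
  to the GA axis makes panel features marginally dominant (correlation
  about 0.67 with time-to-delivery, comparable to the strongest correlates
  reported in real interactomes) without adding a new latent dimension, so
  gain-based tallies rank them first consistently.
* The GA-at-sampling signal is spread thinly over 14 features. Because
  time-to-delivery = GA at birth − GA at sampling, GA features are
  inescapably informative for time-to-delivery (their correlation is about
  −0.73 times their GA loading); concentrating the clock signal in few
  features would make single clock features as strong as panel features and
  the selection problem unidentifiable at this scale. Spreading the clock
  over many individually-weak features keeps the panel dominant while
  preserving the clock's total accuracy.

**The clock shift.** For PTB participants, GA-signal features take the
value they would have at (true GA + `clock_shift_weeks`), default 1 week.
This makes "the omic clock runs ahead in the PTB group" an engineered
truth whose direction and approximate size downstream analyses must
recover.

**What the generator does not emulate.** No assay chemistry (mass spectra,
probe effects, NPX normalization), no site-specific covariate
distributions, no non-monotone or interaction signals, no informative
missingness. Passing tests therefore demonstrate that the machinery
recovers planted structure of the stated form at the stated sizes — not
that any particular biological claim holds in real data.

## The interactome

All feature pairs are scored by Spearman correlation: midranks, then
product-moment correlation of the ranks. Two-sided p-values use the t
approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom —
chosen over permutation because the analytic threshold is then exactly
invertible: the Bonferroni-corrected significance level `alpha/n_tests`
corresponds to `|rho| > t*/sqrt(t*^2 + df)` with `t*` the upper
`alpha/(2 n_tests)` t quantile (`bonferroniRhoThreshold()`; evaluated in
log space so 10^7-scale families do not underflow). At the full study
dimensions — 231 participants, 6,157 features, 18,951,246 pairs — this
threshold is 0.38.

Design details: Bonferroni adjustment multiplies each raw p by the count of
all `F(F-1)/2` pairs, including pairs whose rho is undefined (constant
features are kept with `NA` statistics and a warning, and never counted
significant). Strength bins are half-open above (`weak` (threshold, 0.6],
`moderate` (0.6, 0.8], `strong` (0.8, 1.0]) so boundary values fall
deterministically in the lower bin. Normalized link weights divide each
omic pair's significant count by its possible-pair count (`F_i(F_i-1)/2`
within, `F_i F_j` between omics). The bootstrap null resamples each
feature's values independently with replacement — destroying cross-feature
coupling while keeping marginals — and re-runs the identical pipeline.
Dataset modularity is the smallest number of principal components of the
standardized matrix reaching 90% cumulative explained variance, bounded by
numerical rank. The 2-D correlation-space embedding uses classical
multidimensional scaling on the dissimilarity `1 − |rho|`; the embedder is
deliberately pluggable — the package's contract is geometric (planted
blocks land closer within than between) and any embedding honouring the
dissimilarity satisfies it, with the MDS default having the advantage of
exact determinism.

## The repeated cross-validation harness

All multivariate models share one estimation scheme (`repeatedCV()`):
participants are split evenly into a training and a test half; a
gradient-boosted tree ensemble (xgboost; shallow trees, depth 3, learning
rate 0.1, 150 rounds, row/column subsampling 0.8 by default) is fitted on
the training half and predicts the test half; after `n_reps` (default 50)
seeded repetitions, each participant's final prediction is the average over
the repetitions in which they were in the test half. Contributing models
never saw the participant, and the harness records the full train-membership
ledger so this no-leakage property is asserted structurally in the tests
rather than assumed.

Choices the scheme leaves open were fixed as follows: classification splits
are stratified by outcome (guaranteeing trainable splits at 11%
prevalence); the imbalance-weighted loss uses positive-class weight
`n_neg/n_pos` of each training half; repetition r uses `seed + r`, making
results independent of execution order; AUROC/AUPRC 95% CIs come from a
participant-level percentile bootstrap (1,000 resamples by default) of the
averaged predictions, while Pearson r uses the Fisher-z interval.

Metrics are hand-specified where their definition matters: AUROC is the
tie-aware normalized Mann-Whitney U; AUPRC is the interpolation-free step
sum over recall increments, with tied-score blocks contributing their
block-end precision (so an uninformative constant score collapses exactly
to the prevalence); Lift is AUPRC over prevalence, 1 being chance. Per-site
tables recompute metrics from the same averaged predictions;
`siteTransferComparison()` contrasts within-site models against the
integrated model per site; `prevalenceMatchedEval()` samples evaluation
cohorts at a target prevalence (all controls kept, cases subsampled — the
maximal cohort achieving the rate) to estimate performance in
realistic-prevalence populations.

## Minimal-panel stability selection

`stabilitySelect()` splits participants once 70/30, then repeatedly (100
iterations) refits the learner on seeded 80% subsamples of the training
split drawn without replacement, tallying the top 10 features by total-gain
importance. The 3 most frequently selected features (ties: frequency, then
lexicographic feature id — making selection invariant to column order) form
the panel, which is evaluated by repeated CV within the training split and
scored exactly once on the untouched test split. Subsample fraction,
replacement, and the importance metric are configurable since different
studies fix them differently; the defaults above are the package's.

The stability flag is calibrated by a permutation null rather than an iid
binomial envelope: tree learners re-select the same spurious features on
overlapping subsamples, so under pure noise the top tally concentrates far
above the `n_iter * top_k / F` binomial expectation. The
null run repeats the subsampling schedule with the target permuted —
preserving that concentration mechanism without signal. Because a single
spurious feature can stay persistently favoured under a fixed permutation
while a whole panel of them cannot, the flag compares the panel-sized
(n_final-th highest) tallies: selection is called stable only when the real
panel tally exceeds its null counterpart by a one-sided Fisher test at the
1% level.

## The gestational clock

`fitClock()` cross-validates a GA-at-sampling model on the omics and
defines each participant's discrepancy as predicted − ultrasound GA, so an
"accelerated clock" is a positive discrepancy. PTB versus term
discrepancies are compared with the two-sided rank-sum test (the package
reports the unadjusted test plus a matched-pairs sensitivity variant when
pair labels are available, since whether to adjust for sampling GA is a
genuinely open choice). Regression dilution matters for interpreting the
size: cross-validated predictions shrink toward the mean with slope roughly
equal to the model's explained variance, attenuating a planted forward
shift; because the default design also writes the (shifted) GA axis into
the panel features, the clock model reads the shift through many features
and the observed group difference lands near its planted 1-week size. The
tests assert a positive group shift below the planted-plus-noise ceiling,
with near-zero overall bias. `errorProfile()`
exposes the same shrinkage as a negative residual-on-truth slope
(slope ≈ s − 1 for a shrinkage factor s). `ttdToBirthGA()` adds the known
sampling GA to predicted time-to-delivery — exact addition, tested
bitwise — to turn time-to-delivery models into PTB discriminators.

## The covariate network

Per clinical category, the Spearman matrix of numerically-coded covariates
(binary as 0/1, ordinal as codes; rank correlation makes finer coding
immaterial) is computed on pairwise-complete observations (minimum 10 per
pair) and reduced to an MST on weights `1 − |rho|` (ties broken by
lexicographic pair id). Category MSTs are unioned, and extra edges join any
covariate pair significant after Bonferroni correction over all tested
pairs. Node scores: PTB association as −log10 of the Bonferroni-adjusted
rank-sum p, and multiomic predictability as −log10 of the Pearson p from
the repeated-CV regression of the covariate on the combined omics. Layout
is seeded Fruchterman-Reingold and never alters topology. Zero-variance
covariates stay as isolated nodes with a warning.

## Numerical and scale choices

Default problem sizes are 2,000 participants in the full cohort and 231 in
the subcohort with 120/430/64 features per omic (the full study scale of
13,841 participants and 1196/4329/632 features is configuration, not code:
every routine is written blockwise or vectorized and the desk-scale
quantities — pair counts, thresholds — are computed at full scale
analytically). The test suite runs the complete pipeline at these reduced
sizes; the vignette-level guarantees (time-to-delivery cross-validated r in
about [0.55, 0.8] for the planted R² = 0.5; panel recovery; positive clock
shift) are statements about those defaults.

Known limitations: mean imputation is computed on the analysis cohort as a
whole, not split-wise inside cross-validation — the scheme follows the
stated procedure it implements, and the (small, at 2% missingness) optimism
this can introduce is acknowledged rather than silently fixed; the learner
family is gradient-boosted trees only; no pathway/enrichment analysis (it
requires external annotation databases); and the synthetic generator's
scope is exactly the structural features listed above.
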