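---
title: "Normative brain-age modelling with nPAD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative brain-age modelling with nPAD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brain-age models regress chronological age on regional neuroimaging
features in a healthy reference cohort; applied to a new individual they
return a "brain age", and the gap between brain age and chronological age
(the predicted age difference, PAD) is used as a marker of atypical brain
aging in conditions such as schizophrenia. Raw PAD has a well-known
defect: because every regression shrinks predictions toward the training
mean, PAD is negatively correlated with chronological age (young subjects
are over-predicted, old subjects under-predicted), which confounds any
association between PAD and an age-related clinical variable.

This package implements a normative alternative. A Gaussian-process
regression (GPR) of predicted age on chronological age and sex, fitted in
the reference cohort, supplies at every (age, sex) the mean
$\bar{x}_{peers}$ and standard deviation $\hat{S}_{peers}$ of predicted
age among same-age, same-sex peers. An individual's score is then

$$\mathrm{nPAD} \;=\; \frac{\mathrm{PredictedAge} - \bar{x}_{peers}}
  {\hat{S}_{peers}},$$

a z-score relative to the normative distribution. Because the reference
point is the peers' predicted age (which carries the same shrinkage), the
age-related bias cancels by construction, and scores are comparable
across models and modalities. The conventional linear correction
("cPAD": residualize PAD on age with a slope/intercept fitted in the
reference cohort) is provided as a benchmark.

## Pipeline anatomy

1. **Brain-age predictor** (`train_predictor`, `predict_age`,
   `crossvalidate_10fold`). Modality-specific: GM (regional volumes +
   cortical thickness), WM (tract GFA + MD), or multimodal. Sex is a
   predictor. The default backend is a cascade feedforward network with
   12 tanh blocks of width 16 and dense skip connectivity: block $i$
   receives the standardized inputs concatenated with all previous block
   outputs, and a linear head reads the inputs together with every block
   output, so a linear ground truth is representable by the head alone.
   Training is full-batch Adam (lr 0.01) with L2 weight decay (0.02) and
   early stopping (patience 25) on an internal 15% validation split. The
   "cascade" reading -- dense feed-forward skip connectivity -- is the
   standard interpretation of cascade networks; exact layer sizes of
   published cascade brain-age models are rarely specified, so these are
   declared package defaults, all overridable. A closed-form ridge
   backend (`backend = "ridge"`, penalty 1 on standardized predictors)
   and a constant mean-age backend exist because every downstream score
   is predictor-agnostic; simulation-heavy validation uses ridge so that
   conclusions do not hinge on network convergence.
2. **Normative model** (`fit_normative_gpr`, `peer_moments`,
   `score_npad`). Exact GPR with the sum kernel
   $k = \sigma_f^2\,e^{-(a-a')^2/2\ell^2} + \sigma_s^2\,[s{=}s'] +
   \sigma_n^2\,[i{=}j]$: a smooth age trend, a constant per-sex offset,
   and white noise. Hyperparameters maximize the marginal likelihood
   (L-BFGS-B on log-parameters with analytic gradients, 5 seeded
   restarts; length-scale initialized at half the age SD and bounded to
   [1, 50] years; noise initialized at the OLS residual SD with a floor
   at 5% of it). The reported $\hat{S}_{peers}$ is the **total**
   predictive SD (latent variance + noise): a normative range describes
   where individual predicted ages fall, not where the latent mean sits;
   the latent-only alternative would understate peer spread roughly by
   the model's noise-to-signal ratio.
3. **Benchmarks and diagnostics** (`score_pad`, `fit_bias_correction`,
   `score_cpad`, `age_bias_report`). cPAD uses the slope-intercept
   residual form only; quadratic variants are out of scope. The bias
   report tabulates Pearson correlations of PAD/cPAD/nPAD with age per
   cohort, with a permutation option for small samples.
4. **Group statistics** (`ancova_group_comparison` with Type-II F via
   `car::Anova`; `paired_modality_test`; `modality_correlation_comparison`
   with Fisher r-to-z; `sex_difference_analysis` as Welch t within
   group; `exclude_outliers`; `phenotype_regressions`; `bh_adjust` on
   top of `stats::p.adjust`). The nPAD group comparison adjusts
   education; the cPAD benchmark adjusts sex and education (nPAD already
   conditions on sex through the normative model).
5. **Interaction mapping** (`fit_feature_interaction`,
   `scan_all_features`). Per feature, OLS of
   `npad ~ feature + group + feature:group + age + sex + education` with
   control coded 0 and case 1, so the interaction coefficient is the
   case-specific increment of the feature-nPAD slope; effect size is
   Cohen's $f^2 = (R^2_{full}-R^2_{reduced})/(1-R^2_{full})$. GM
   features are scanned against nPAD-GM and WM features against nPAD-WM
   (a multimodal scan exists behind a flag, off by default, since
   reported analyses of this design scan GM and WM only); volumes and
   thickness are both scanned -- the scan never pre-filters by feature
   type.

### Out-of-fold normative fitting

The normative model and the cPAD correction are fitted, by default in
`run_pipeline`, on the reference cohort's **out-of-fold**
cross-validation predictions rather than on in-sample predictions of the
final model. In-sample predictions of a flexible regressor are optimistic:
they understate both the peer SD (so held-out nPAD would have SD > 1) and
the age bias that held-out subjects actually experience (so cPAD/nPAD on
an independent cohort would retain a residual positive age correlation).
Out-of-fold predictions are still training-set predictions, and make the
reference-fitted moments transfer to new data.

## Benjamini-Hochberg families

The correction is applied within each analysis block, the default policy
exposed as an argument wherever it applies: the three modalities of a
group comparison form one family per metric; the three modalities of the
sex-difference analysis form one family per group; each phenotype
regression class (clinical factors, symptom scores, FSIQ) forms one
family across its phenotype predictors and the three nPAD outcomes
(covariates such as education are reported but not corrected); an
interaction scan forms one family per modality (124 GM tests, 90 WM
tests), with a pooled option. Within-block correction matches how such
tables are conventionally reported; the pooled alternative is stricter
and available by flag.

## The synthetic study

`synthetic_config()` defines a complete generative world so that every
stage has a recoverable target. Feature $j$ of subject $i$ follows

$$x_{ij} = \mu_j + \beta_j a^*_i + \kappa_j a^{*2}_i + \gamma_j s_i +
  \varepsilon_{ij}, \qquad a^*_i = a_i + \eta_i,$$

where $a_i$ is chronological age and $\eta_i$ a **latent aging
deviation** in age-equivalent years. Design features, and why they are
there:

* **Aging directions.** Volumes, thickness and GFA decline
  ($\beta_j \le 0$); MD rises. 80% of features per block carry a slope;
  slopes vary uniformly within a factor 0.5--1.5 of the block's typical
  rate. A small quadratic term ($\kappa_j/\beta_j$ up to 0.004) gives the
  GPR genuine nonlinearity to capture; in a purely linear world the GPR
  would be indistinguishable from OLS.
* **Latent aging heterogeneity in normals** (`latent_aging_sd`, default
  5 y). Healthy people differ in biological brain age -- this is the very
  premise of normative modelling. Technically it is also what makes the
  case-control statistics well calibrated: the feature-nPAD coupling
  induced by the latent deviation exists equally in both groups, so it
  cancels out of every group-by-feature interaction, and the two groups
  have comparable nPAD variance (plain OLS interaction t-tests assume
  homoscedastic groups).
* **Cases** draw their deviation from $N(\delta, \tau^2)$ with
  $\delta$ = 4.5 y advanced aging and $\tau$ = 6.5 y, slightly wider than
  normal heterogeneity. The shift is applied in age-equivalent years, so
  recovering it through the pipeline (predict, normalize, compare) is a
  genuine computation rather than an identity.
* **Noise** (`noise_sd`) is parameterised in age-equivalent years per
  block -- a feature's residual SD is `noise_sd` times its block's
  typical slope magnitude -- because the four blocks live on scales four
  orders of magnitude apart (mL, mm, unitless GFA, mm$^2$/s) and a single
  absolute SD would be meaningless. Defaults (GM 45, WM 30) make the WM
  model the more accurate one and put cross-validated MAE in the 4.5--6.5
  year range typical of regional-feature brain-age models at
  $n \approx 500$.
* **Planted interaction features** (default 10, thickness block) are
  drawn from the features *without* a normal-aging slope -- regions
  recruited only by the disease process -- and in cases they track the
  latent advanced-aging shift with gain `interaction_slope_delta`
  (default 9 typical-slopes per year of advanced aging, signed along the
  block's aging direction, so planted thickness features thin faster and
  would-be MD features rise faster; the scan's interaction coefficients
  inherit those signs). Two designs were rejected after simulation: a
  case-only *chronological*-age slope increment leaks through the
  brain-age predictor into case nPAD as an age-proportional trend that
  biases the interaction test of every aging feature (the pooled model
  has no age-by-group term to absorb it), and planting inside
  aging-signal features does the same through the predictor's weights.
  The adopted design expresses the same biology -- a feature whose
  relationship with nPAD is group-specific -- with clean error control.
  The gain default sits at the maximum of the detection-power curve; the
  resulting single-feature effects have Cohen's $f^2$ around 0.05--0.07,
  mid-range for reported significant regional interactions. Larger gains
  stop helping because the control group's slope estimate, on a feature
  that is pure noise in controls, bounds the contrast's standard error.
* **Phenotypes** (cases only) are drawn around published clinical means
  (onset 23.4 (6.9) y, duration 7.5 (7.0) y, chlorpromazine-equivalent
  dose 312.8 (269.8) mg, PANSS 13.1/15.8/28.2, FSIQ 93.8 (12.9)), with
  configurable couplings to the standardized latent shift: negative
  symptoms +0.5, FSIQ -0.5, onset age -0.3. Education is drawn
  group-dependently (controls ~1.5 y higher), so covariate adjustment is
  exercised for real.
* **Ages**: reference/test ages follow a right-skewed shifted gamma on
  14--92 y (mean ~36, SD ~16, matching a population-based lifespan
  cohort); case/control ages are truncated normal (31 (8.4) y on 16--62).
  Sex is Bernoulli(0.47 male).

What the generator does **not** emulate: scanner and site effects,
feature-feature correlation beyond the shared latent deviation,
non-Gaussian residuals, missing data, longitudinal structure, and any
spatial organisation of ROIs. Passing tests therefore demonstrate the
statistical machinery under a clean, known world -- not robustness to the
messiness of real imaging data.

## Numerical choices

* Standardization: per-feature centre/scale learned on training data;
  zero-variance features are a named error, never silently dropped.
* Ridge: closed-form solve of the regularised normal equations with an
  unpenalized intercept; penalty 1 on standardized predictors is
  essentially un-regularised at $p \approx 215, n \approx 480$ but keeps
  the solve well-posed.
* GP numerics: Cholesky with a jitter of $10^{-8}\sigma_f^2$; queries
  more than 5 years outside the training age range are answered but carry
  an extrapolation flag into every score table.
* Cross-validation folds: seeded shuffle then contiguous split; fold
  models are seeded `seed + fold`.
* Outlier rule: single pass; means/SDs from the pre-exclusion sample; a
  subject is excluded iff any screened field deviates more than 3 sample
  SDs.
* Ties in the interaction ranking are broken by feature name for
  determinism.
* Degenerate inputs: constant predictions give `rho = NaN` with a
  warning (MAE stays valid); zero-variance paired differences are flagged
  (t reported as 0 or signed infinity); single-sex groups are skipped
  with a note.

## Validation sizes

The test suite validates against the study-scale conditions: a reference
cohort of ~480-500, case/control of ~150/130, 20 replicate worlds for the
z-scoring and bias properties, and 200 replicate case-control draws for
power, recovery and scan operating characteristics. The bias-freeness
check replicates validation cohorts around one fixed study (one reference
world, one fitted correction), matching how a study's bias table is
evaluated on an independent test set: the correction slope estimated on
~500 reference subjects carries irreducible $1/\sqrt{n}$ noise that would
otherwise dominate the check.

## Known limitations

* The cascade architecture is a faithful interpretation, not a
  reconstruction, of any specific published network; with ~200 features
  and ~500 subjects it offers no accuracy advantage over ridge here.
* $\hat{S}_{peers}$ is homoscedastic in all but the kernel-driven sense;
  heteroscedastic-likelihood or warped GPs are out of scope, so strongly
  age-dependent prediction-error variance would be only partly captured.
* cPAD is the linear correction only.
* The exact-match sex kernel assumes a constant sex offset across the
  lifespan; an age-by-sex interaction in predicted age would need the
  per-sex fitting option.

## A minimal session

```{r example}
library(npad)

cfg <- synthetic_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "npad-run", backend = "ridge")

res$cv_reports$multimodal          # 10-fold rho and MAE
res$bias_report                    # PAD vs cPAD vs nPAD age correlations
res$group_comparisons              # case-control ANCOVA per metric
head(as.data.frame(res$interaction_scan))
```
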