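---
title: "Changepoint trajectories of regional brain volumes on the CAP axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Changepoint trajectories of regional brain volumes on the CAP axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatsig)
```

## The scientific problem

Huntington's disease is caused by a CAG repeat expansion in *HTT*; longer
repeats bring earlier onset. The CAG-Age Product,

$$\mathrm{CAP} = \mathrm{Age} \times (\mathrm{CAG} - L), \qquad L = 33.66,$$

places carriers with different repeat lengths on a single disease-burden
axis, so cross-sectional and longitudinal scans from several studies can be
analysed together. Regional brain volumes are approximately normal in
carriers very far from onset, then decline — steeply and early in the basal
ganglia circuit, slowly and late almost everywhere else. `flatsig` models
each region's volume along CAP as a **left-flat sigmoid**: exactly constant
up to a changepoint $\tau$, then a monotone sigmoidal decline.

## The model

For scan $i$ with CAP score $c_i$ and covariate row $z_i$,

$$y_i = v_0 - \delta\, S\!\left(\frac{c_i - \tau}{s}\right)_{\!+} +
        z_i^\top \beta + \varepsilon_i, \qquad
  S(u) = \frac{2}{1 + e^{-u}} - 1,$$

with $S$ applied only for $c_i > \tau$, $\delta \ge 0$, $s > 0$.
The parameters, in units:

| parameter | meaning | units |
|---|---|---|
| $v_0$ | pre-changepoint level | response units (mm³, or dimensionless if normalized) |
| $\delta$ | total eventual drop | response units |
| $\tau$ | changepoint: CAP at first slope change | CAP units |
| $s$ | transition width; the slope at $\tau^+$ is $-\delta/(2s)$ | CAP units |
| $\beta$ | additive study, group and centred-ICV effects | response units |

The half-logistic ramp was chosen over a full logistic because it is
*exactly* flat left of $\tau$ (matching the far-from-onset approximation
that volumes are constant), continuous at $\tau$, monotone, and sigmoidal to
the right. The functional form is isolated in `left_flat_sigmoid()`, so an
alternative shape is a one-function swap.

Two response variables are supported per region: the raw volume in mm³ with
ICV (head size) as a covariate, and the volume normalized by whole-brain
volume, which isolates *preferential* atrophy — a region declining no faster
than the brain as a whole has a flat or rising ratio. ICV is kept as a
covariate in the normalized analysis by default (`use_icv` in
`run_config()` drops it), since normalization and head-size adjustment are
distinct corrections; both behaviours are supported because the choice is
genuinely open.

Covariates enter additively on the response scale with reference coding
(alphabetically first study and group fixed at zero, ICV mean-centred), so
the fitted trajectory at reference levels *is* the trend line.

## Estimation

For fixed $(\tau, s)$ the model is linear in $(v_0, \delta, \beta)$, so the
fit profiles: an outer grid on $\tau$, an inner search over $s$, innermost
linear least squares with $\delta \ge 0$ enforced (a negative unconstrained
drop collapses to the flat model, $\delta = 0$). Implementation details that
matter:

* **Tau grid.** Multiples of `tau_step` (default 5 CAP units) spanning the
  5th–95th percentile of observed CAP, plus one extra point at the observed
  minimum. The extra point means the family contains, at large $s$,
  arbitrarily good approximations to any non-increasing straight line, which
  keeps the linear model numerically nested in the sigmoid family — without
  it, a pure-line dataset could be fitted worse by the "richer" model.
  The changepoint is reported on this grid; `converged = FALSE` flags a
  boundary solution.
* **Width search.** 25 log-spaced values between `tau_step/2` and 20× the
  observed CAP range, evaluated for every $\tau$ in one matrix-vector
  product against a pre-orthogonalised design, followed by a continuous
  golden-section refinement (tolerance $10^{-9}$ on the log scale) at the
  eight leading $\tau$ candidates. Refining several candidates, not just the
  coarse winner, prevents grid coarseness from flipping the selected
  changepoint between near-tied neighbours; with noise-free data the four
  parameters are recovered to better than $10^{-6}$ relative.
* **Ties and degeneracy.** Ties on RSS are broken toward the smallest
  $\tau$; collinear covariates are a hard error naming the columns; fits are
  deterministic — no random initialisation.
* **Pooling.** Scans are treated as independent at fit time (a regression,
  not a mixed model). Within-subject correlation is honoured at *inference*
  time by subject-block resampling, which keeps the point estimate simple
  and the uncertainty honest.

The nested comparisons share covariates: a constant model (no CAP term) and
a straight line in CAP. By construction the RSS ordering
constant ≥ linear ≥ sigmoid holds for data with a non-increasing CAP trend;
for responses that *rise* with CAP (relatively spared regions under
whole-brain normalization) the monotone non-increasing family collapses to
the flat model and the linear model can fit better — which is exactly how
such regions fail the model comparison and drop out of the changepoint
table.

## Inference

Because $\tau$ is estimated, the improvement statistic
$T = \frac{(RSS_{lin} - RSS_{sig})/RSS_{sig}\,(n - p_{sig})}{p_{sig} - p_{lin}}$
has no F distribution; inference is by a **semi-parametric bootstrap**:
parametric fitted mean plus nonparametric resampled residuals.

* **Changepoint SD** — residuals from the sigmoid fit are resampled in
  subject blocks (a subject's whole residual vector moves together, drawn
  from donors with the same number of scans so lengths and correlation
  structure match exactly), re-attached to the fitted mean, and the model
  refitted; `tau_sd` is the SD of the replicate changepoints.
  Boundary-converged replicates are dropped with accounting (a warning above
  20%) rather than retried, to keep determinism.
* **Model-comparison p-value** — null data are generated from the fitted
  *linear* model (the comparison being reported; the constant null is
  available via `null_model`), both models are refitted per replicate, and
  $p = (\#\{T^* \ge T\} + 1)/(B + 1)$, the add-one convention, so
  $1/(B+1) \le p \le 1$.
* No multiplicity correction by default (per-region reporting);
  `changepoint_table(adjust_p = TRUE)` applies Benjamini–Hochberg.

A known limitation, visible in the calibration experiments: with strong
within-subject correlation the observed statistic and its own bootstrap null
are positively coupled, which makes the test somewhat conservative (rejection
below nominal) rather than anti-conservative — the safe direction for a
screening comparison.

## The synthetic cohort generator

`generate_cohort()` inverts the analysis model so every stage is testable
without restricted clinical data. Defaults are chosen to emulate the merged
three-study table the method targets: 178 controls and 357 carriers split
~12/36/52% across three study arms; control CAG 15–31 (mean 20.4, SD 3.5),
carrier CAG 38–55 (mean 42.7, SD 2.4); enrollment ages 18–72 with mean
carrier age decreasing by 2.5 years per CAG above the mean, so that carrier
CAP spans roughly 150–650 as in the pooled studies; one to five visits about
a year apart with 0.85 per-visit retention; ICV 1.5×10⁶ ± 1.3×10⁵ mm³ with a
head-size effect on every volume; ±2% study batch offsets; whole-brain
volume declining by its own sigmoid (10% of its baseline 0.80 fraction of
ICV, changepoint 250) so normalized analyses have real structure; 3%
homoscedastic Gaussian noise per region (a `"t5"` option exists for
robustness experiments); 2% of scans flagged as QC artefacts. The per-region
truths in `default_roi_truths()` are synthetic fixtures — basal ganglia
early (τ 250–320) and deep (30–45% drops), cortex later and shallower,
hippocampus/cerebellum nearly spared — not estimates from any dataset.

What the generator does *not* emulate: segmentation error structure beyond
additive noise, scanner/protocol drift within a study, informative dropout
(attrition is independent of disease stage), measurement-error correlation
across regions, and developmental (rather than degenerative) striatal
differences. Passing tests therefore demonstrate internal validity of the
estimator and its inference under the model's own assumptions, not
performance on real imaging tables.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run the same experiments; sizes
were chosen to exercise each property at desk scale:

* zero-noise identifiability (60 carriers) — exact recovery to $10^{-6}$;
* optimizer vs exhaustive (τ × s) grid on 50 observations — RSS agreement to
  $10^{-6}$ relative;
* changepoint recovery: 300 subjects, 3% noise, true τ = 300 — median error
  over 20 seeds within 15 CAP units (observed: 0);
* type-I calibration: 200 linear-truth datasets (50 subjects, residual
  ICC ≈ 0.2), 199 bootstrap replicates each — rejection at α = 0.05 within
  [0.02, 0.09];
* coverage: 100 cohorts of 60 subjects with a moderate signal
  (20% drop) so the changepoint has genuine uncertainty spanning several
  grid steps — τ̂ ± 2·SD covers the truth 88–99% of the time. (With a strong
  signal the estimate pins to the true grid point and empirical coverage
  degenerates to 100%; the moderate-signal design keeps the check
  informative.)
* staging order: six regions with changepoints staggered by 50 CAP units —
  Spearman ρ of recovered vs true ordering ≥ 0.9 (median over 20 seeds), and
  on the full default scenario a basal ganglia region ranks first in ≥ 90%
  of seeds.

## Worked example

```{r example, eval = FALSE}
scenario <- default_hd_scenario(seed = 1)
cohort <- generate_cohort(scenario)
kept <- assign_cap(cohort, cap_config())       # CAP + under-40 control filter

d <- design_response(kept, "putamen")
fit <- flatsig(design_formula(d), d, subject = "subject_id")
summary(fit)

cp <- changepoint(fit, bootstrap_opts(n_reps = 199, seed = 1))
cp      # tau_hat, tau_sd, p_value, sigmoid_preferred
```

## Known limitations

* The changepoint lives on a grid; its resolution (default 5 CAP units) is a
  floor on achievable precision and shows up as quantisation in bootstrap
  SDs for very strong signals.
* The monotone non-increasing constraint means rising trajectories are
  never fitted — intended for atrophy, wrong for ventricles or other
  expanding compartments (analyse their negation, or the normalized ratio of
  other regions instead).
* Scans are pooled at fit time; subject-level heterogeneity in $\tau$ is not
  modelled, only absorbed into residual correlation handled by the block
  bootstrap.
* The CAP threshold constant $L$ and the control multiplier are
  configuration, not estimates; conclusions near the extremes of the CAP
  axis (below ~200, above ~600) extrapolate thin data in the designs this
  package targets, just as in the cohorts it emulates.
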