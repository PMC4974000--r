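---
title: "Covariate-adjusted ROC regression for OCT glaucoma markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted ROC regression for OCT glaucoma markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octroc)
library(dplyr)
```

## The problem

A single ROC curve summarises the average discrimination of a diagnostic
marker over everyone it was evaluated on. But the accuracy of optical
coherence tomography (OCT) thickness markers for glaucoma is not a constant
of nature: it depends on how advanced the disease is, on the patient's age,
on the geometry of the eye (axial length, refraction) and on the size of
the optic disc. `octroc` implements the ROC regression ("ROC-GLM") approach
that models the ROC curve itself as a function of such covariates,

$$\mathrm{ROC}(q \mid x) \;=\;
  \Phi\!\left(\alpha_1 + \alpha_2\,\Phi^{-1}(q) + \beta^\top x\right),$$

where $q$ is the false-positive rate, $\Phi$ the standard normal CDF,
$\alpha_1$ and $\alpha_2$ the intercept and slope of the (binormal) ROC
curve, and $\beta$ the covariate effects. A positive $\beta_k$ means the
covariate improves discrimination; a negative one degrades it. The area
under the covariate-specific curve has the closed form

$$\mathrm{AUC}(x) \;=\;
  \Phi\!\left(\frac{\alpha_1 + \beta^\top x}{\sqrt{1 + \alpha_2^2}}\right),$$

valid whenever $\alpha_2 > 0$. `roc_auc()` uses this expression and the
test suite verifies it against Gauss–Legendre quadrature of the curve to
$10^{-6}$.

The package covers the full analysis around the model: cohort ingestion and
eligibility screening, Humphrey 30-2 visual-field classification, Bennett
magnification correction of the measured optic-disc area, group
characteristics tables, the ROC regression itself with bootstrap
inference, and a synthetic cohort generator so that every stage can be
exercised and validated without patient data.

## Estimation: placement values and binary indicators

The model is fitted by the placement-value (Alonzo–Pepe) construction.
Marker values are first *oriented* so that larger always means more
diseased (`orient_marker()`; thickness markers thin with glaucoma, so they
default to `lower_is_diseased`). Each case's oriented value is then
expressed as a placement value: the fraction of controls at least as
disease-like,

$$\mathrm{pv}_i = \frac{1}{n_0}\,\#\{\,\text{controls} \ge y_i\,\},$$

so the ROC curve is exactly the CDF of the case placement values. Over a
grid of interior false-positive rates $q_1 < \dots < q_m$ the binary
indicators $u_{ij} = 1\{\mathrm{pv}_i \le q_j\}$ are expanded
(`expand_indicators()`) and regressed, with a probit link, on
$[1, \Phi^{-1}(q_j), x_i]$ by maximum likelihood (`roc_glm()`). The
coefficient on $\Phi^{-1}(q)$ is $\alpha_2$, the intercept is $\alpha_1$.

Design choices that were genuinely open, and how they were resolved:

* **Tie rule.** Controls exactly equal to a case count as more diseased
  (`ties = "inclusive"`), the conservative deterministic choice; the strict
  rule is available as a switch. With continuous markers the two coincide
  almost surely.
* **Reference distribution.** The pooled empirical control distribution is
  used, not a covariate-adjusted one: all covariate structure lives inside
  the ROC linear predictor. This matches a design in which healthy-eye
  marker values are treated as exchangeable.
* **FPR grid.** `fpr_grid(m = 100)` uses $q_j = (2j-1)/2m$, a dense uniform
  interior grid that avoids the probit singularities at 0 and 1. The grid
  is a tunable of the estimator; estimates are insensitive to $m$ beyond a
  few dozen points because neighbouring indicators are highly correlated.
* **Covariate scales.** Covariates enter raw (percent, years, diopters, mm,
  mm²), uncentered, so fitted intercepts are directly comparable with
  published coefficient tables on the same scales.
* **Inference.** The naive probit standard errors are computed but labelled
  invalid (`tidy()` marks them `naive_probit_invalid`): the $m$ indicators
  of one case are strongly dependent, so the working likelihood is not a
  real likelihood. Reported inference comes from `roc_glm_boot()`, which
  resamples cases and controls separately with replacement, recomputes
  placement values against each control resample, refits, and forms
  percentile 95% intervals; p-values use the normal approximation with the
  bootstrap SE.

### Numerical details

Single fits go through `stats::glm.fit`. Bootstrap and simulation-study
refits use an internal Fisher-scoring routine that exploits the block
structure of the indicator design (covariates constant within a case, the
$\Phi^{-1}(q)$ column constant across cases) to assemble the weighted
normal equations in $O(nm)$ without materialising the $nm \times p$ design
matrix, warm-started from the parent fit. The two paths solve the same
likelihood and are asserted equal in the test suite. The linear predictor
is clamped at $\pm 8$ probit units, where the indicator likelihood is flat
and working weights underflow; quasi-separation (e.g. a marker constant in
both groups) raises a warning, not an error. Bootstrap replicates that fail
to converge are dropped, and the run errors if more than 10% fail.

All randomness fans out from one master seed through named substreams
(eye selection, simulation, bootstrap), so any stage is independently
reproducible; fits, bootstraps and whole pipeline runs are byte-identical
under a fixed seed.

## Magnification correction

Instrument-measured optic-disc area is rescaled to true area with
Bennett's correction,

$$A_{\text{true}} = A_{\text{measured}} \times
  3.382^2 \times 0.01306^2 \times (\mathrm{AL} - 1.82)^2,$$

with the axial length AL in mm (`bennett_corrected_area()`). The factor is
exactly 1 at $\mathrm{AL} = 1.82 + 1/(3.382 \times 0.01306) \approx
24.46$ mm, is strictly increasing in AL, and the correction is linear in
the measured area. Axial lengths at or below the 1.82 mm nodal offset are a
domain error. Constants are configurable via `bennett_constants()` but
default-pinned; the corrected area is stored alongside, never over, the
measured value.

## Visual-field criteria

`vf_reliable()` applies the reliability screen (fixation loss < 20% and
false positives < 33%, both strict). `vf_defect_clusters()` implements the
cluster rule on 30-2 pattern-deviation maps: at least 3 contiguous
non-edge points depressed at $p<5\%$, one of them at $p<1\%$. Conventions
the instrument literature leaves open are set as follows and are
configurable or data-driven:

* the 30-2 grid ships as a packaged table (76 points, 6° spacing offset 3°
  from the meridians) with edge membership and the two blind-spot points
  marked explicitly, so the edge definition is data, not code;
* "edge" means the outermost ring — points with fewer than eight lattice
  neighbours inside the pattern;
* contiguity is the 8-neighbourhood on the 6° lattice;
* clusters may not span the horizontal midline by default
  (`span_midline = FALSE`), the common convention in glaucoma criteria.

`vf_classify_glaucomatous()` is the disjunction of a qualifying cluster
and a glaucoma hemifield test outside normal limits;
`vf_confirmed_defect()` requires at least two reliable examinations that
each classify as glaucomatous.

## The synthetic cohort generator

No patient-level data ship with the package. `generate_cohort()` creates
case–control cohorts whose *true* covariate-specific ROC is exactly the
probit model above, via the binormal identity: with controls' oriented
marker $\sim N(\mu_0, \sigma_0^2)$ and a case with covariates $x$ drawing
its marker from

$$N\!\left(\mu_0 + \tfrac{\sigma_0}{\alpha_2}(\alpha_1 + \beta^\top x),\;
  \left(\tfrac{\sigma_0}{\alpha_2}\right)^2\right),$$

one gets $\mathrm{ROC}(q \mid x) = \Phi(\alpha_1 + \alpha_2\Phi^{-1}(q) +
\beta^\top x)$ exactly. Only the cases' covariates shift the marker,
mirroring the pooled-reference fitting convention.

Covariates are drawn per group from normal marginals emulating an
early-glaucoma case–control cohort of 173 glaucomatous and 63 unaffected
eyes (age 55.2 (11.3) vs 53.7 (11.7) years; VFI 89.0 (9.9) vs 99.3 (1.1)
percent; spherical equivalent −2.3 (3.1) vs −1.8 (3.7) D; axial length
24.69 (1.48) vs 24.12 (1.58) mm; corrected disc area 1.98 (0.41) vs 2.00
(0.47) mm²), with truncation (VFI ≤ 100, positive areas, AL above the
Bennett offset) enforced by rejection so requested group sizes are exact.
The measured disc area is back-computed from the generated corrected area
through the Bennett factor so the magnification stage round-trips, and
quality fields are set to passing values.

What the generator deliberately does **not** emulate: cross-covariate
correlation (covariates are drawn independently; real refraction and axial
length are strongly negatively correlated), measurement-level artefacts
(signal-strength effects, segmentation failure), non-normal marker tails,
and any dependence of the controls' marker on their covariates. Passing
recovery and coverage tests therefore validate the estimation machinery
under the model's own assumptions — they do not certify performance on
real cohorts where those assumptions bend.

`recovery_study()` wraps the generate → fit → compare loop and reports
per-coefficient bias, Monte-Carlo SE, RMSE and bootstrap-CI coverage. The
package's own validation (see `tests/testthat/test-acceptance.R`) runs 100
replicates at $n = 600/300$ with $B = 100$ bootstrap resamples per
replicate — sizes chosen so the whole study completes in minutes while the
Monte-Carlo SEs are small enough to detect meaningful bias.

## The pipeline

`run_pipeline(pipeline_config(...))` composes the full analysis: ingest
(file or synthetic truth) → eligibility exclusions (acuity worse than
20/40, i.e. logMAR > 0.30; IOP > 21 mmHg; cylinder outside ±3 D; any
signal strength < 6 — boundaries retained, exclusions applied before the
random one-eye-per-subject selection) → Bennett correction → group
characteristics table (pooled Student t for continuous variables, Fisher
exact for categoricals) → per-marker ROC regressions with all five
covariates → AUC grids and ROC curve point sets, plus a manifest capturing
seed, counts and warnings. The 20/40 ↔ 0.30 logMAR conversion carries a
$10^{-9}$ tolerance so a stored 0.30 is never excluded by floating-point
noise. Missing eligibility fields log a warning and never exclude.

`reproduce_reference_tables()` is the desk-scale path: it evaluates the
closed-form AUC over the standard profile grids directly from the packaged
reference coefficient table, with no fitting. The reference table stores
the average-RNFL age coefficient as −0.0160: the printed positive value is
inconsistent with its own confidence interval (−0.0311, −0.0009) and with
the AUC grids the coefficients imply, so the sign is corrected and flagged
in a `sign_corrected` column rather than silently.

The baseline evaluation profile is age 55 years, spherical equivalent
−2.15 D, axial length 24.5 mm, corrected disc area 2 mm², with VFI 100%
when severity is varied and VFI 92% when axial length or disc area is
varied (`baseline_profile()`).

## A worked example

```{r example}
truth <- synthetic_truth_reference("gcipl_avg", n_cases = 300,
                                   n_controls = 150)
cohort <- generate_cohort(truth, seed = 7)
fit <- roc_glm(cohort, "gcipl_avg", covariates = names(truth$betas))
glance(fit)
fit <- roc_glm_boot(fit, B = 200, seed = 8)
tidy(fit)
auc_profile_table(fit, baseline_profile(vfi = c(100, 90, 80, 70)))
```

```{r plot, fig.width = 6, fig.height = 4}
profs <- baseline_profile(vfi = c(100, 85, 70))
profs$label <- paste0("VFI ", c(100, 85, 70), "%")
autoplot(fit, profs)
```

## Known limitations

* The control reference is pooled; if healthy-eye marker levels truly vary
  with covariates, stage-one adjustment (not implemented) would be needed.
* Percentile intervals at $B = 100$–$1000$ are Monte-Carlo noisy in the
  far tails; the p-values are normal approximations, not exact.
* The cluster classifier's adjacency, hemifield and edge conventions are
  reasonable defaults, not instrument-vendor specifications.
* AUC summaries extrapolate linearly in covariates; profiles far outside
  the fitted covariate range inherit all the usual risks of
  extrapolation.
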