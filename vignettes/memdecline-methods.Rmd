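---
title: "Methods: stage-stratified modelling of biomarker change and memory decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-stratified modelling of biomarker change and memory decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdecline)
```

## The scientific question

In the early Alzheimer's continuum, the coupling between accumulating
pathology and cognitive decline appears to differ by sex and by disease
stage: females tend to maintain verbal memory in the preclinical stage
despite rising pathology, then decline faster than males once mild cognitive
impairment (MCI) is established. `memdecline` implements the full analytic
chain needed to study this on longitudinal cohort data: actuarial diagnostic
staging at baseline, demographically corrected cognitive scoring, within-person
change scores for both a CSF biomarker ratio (pTau181/A&beta;42) and a verbal
memory composite, and random-intercept linear mixed models in which the
change-on-change association is moderated by sex and diagnostic group.

## Diagnostic staging

Staging is *actuarial* (Jak/Bondi-style), not consensus-based. Six tests map
onto three cognitive domains:

* psychomotor speed / executive function: Trail-Making Test A and B (timed;
  lower is better),
* language: category fluency and the Boston Naming Test,
* episodic memory: RAVLT delayed recall and recognition.

Each score is converted to a z-score via a *normative regression* — an
ordinary least-squares fit of the raw score on age, sex and education in a
separate unimpaired reference sample (`fit_norms()`). Norms are deliberately
never fit on the analytic cohort itself, which would make impairment rates
circular. A score is impaired when it lies strictly more than 1 SD below the
predicted normative value (`z < -1`; the boundary counts as unimpaired). A
participant is MCI if one domain has both tests impaired, or every domain has
at least one impaired test; otherwise the participant is cognitively normal
(CN). CN participants who are AD-biomarker positive — CSF ratio at or above
the cut-point, or any supplied PET modality flag, an OR across modalities —
are labelled preclinical AD; biomarker-negative CN participants leave the
analytic sample. Dementia is an upstream input label and excludes the
participant. The ratio cut-point is a configuration parameter (default
0.025, with the boundary counting as positive); it is a documented
convention, not an endorsed clinical threshold, and any serious application
should set it to the assay-specific published value.

Note one inherited design feature: RAVLT delayed recall participates both in
staging and in the memory outcome. A configuration switch to drop the memory
domain from staging is *not* provided at the top level; sensitivity analyses
can instead stage with custom norms restricted to the other tests.

## Outcome and change scores

The verbal memory composite z-scores RAVLT immediate recall (0–75) and
delayed recall (0–15) against the *baseline analytic sample* means and SDs
and averages the two; the same constants are applied at every visit so that
longitudinal change stays in baseline SD units. A missing component makes
the composite missing — no single-component fallback.

Change is measured by *lagged residuals*: for each variable, one pooled OLS
regression of the visit-t value on the visit-(t−1) value across all adjacent
person-visit pairs; the residual — the deviation from the value expected
given the prior level — is the change score at visit t. Pooling across
participants is the only estimable choice at 2–5 visits per person;
per-person lag regressions would be hopeless. Residualizing on the prior
level removes the autocorrelation a raw difference score carries, at the
cost of mild attenuation when stable between-person differences leak into
the pooled autoregression (quantified below). Pairs bridging a missing visit
are excluded — the one-visit lag is literal — and dropped pairs are counted
in the audit metadata. Change residuals are left unstandardized, which is
why biomarker coefficients are numerically large: the ratio changes by a few
hundredths per year, so a coefficient near −20 means roughly −0.6 composite
SD per 0.03 increase in the ratio.

## The models

`fit_lmm()` fits, by REML through `lme4`,

$$
\mathrm{memchange}_{it} = \beta_0 + \beta_1\,\mathrm{biochange}_{it}
 + \beta_2\,\mathrm{sex}_i + \beta_3\,\mathrm{group}_i
 + \beta_4\,\mathrm{age}^c_i + \beta_5\,\mathrm{edu}^c_i + \beta_6\,\mathrm{APOE4}_i
 + \text{(two- and three-way interactions)} + b_i + \varepsilon_{it},
$$

with $b_i \sim N(0, \tau_{00})$, $\varepsilon_{it} \sim N(0, \sigma^2)$. The
full model carries the interaction set {biomarker&times;sex,
biomarker&times;group, sex&times;group, biomarker&times;sex&times;group};
stratified models within each diagnostic group drop the group terms, and a
sensitivity model restricts the MCI stratum to biomarker-positive
participants. Covariates are baseline age and education, centred at the
analytic-sample mean, and APOE-&epsilon;4 carrier status. Sex is a 0/1
indicator, female = 1 by default; the coding is configurable rather than
hard-wired because the substantive interpretation of the sex main effect and
interactions flips with it, and both conventions appear in the literature.
Group is coded MCI = 1.

Inference is Wald throughout: 95% CIs are $\hat\beta \pm 1.96\,\mathrm{SE}$
and p-values come from the normal reference distribution. This matches the
symmetric intervals conventionally reported for models of this size
(hundreds of participants, ~4 change observations each), where
small-sample degree-of-freedom corrections are immaterial; Kenward-Roger or
Satterthwaite adjustments are out of scope. REML is the default; the ML
switch changes variance components slightly and the fixed effects barely.
The intraclass correlation is $\tau_{00}/(\tau_{00}+\sigma^2)$. A
$\hat\tau_{00}$ at the boundary (0) is returned with a warning, never
silently; a rank-deficient fixed-effect design or a single-sex stratum is an
error that names the offending terms rather than a silent term drop. No
multiple-testing adjustment is applied.

## The synthetic cohort generator

Real cohorts of this kind sit behind controlled-access agreements, so the
package carries a first-class generator whose defaults *are* the reference
study conditions:

| parameter | default | rationale |
|---|---|---|
| baseline age | 74 &plusmn; 6.5 y (truncated 55–88) | typical early-AD cohort |
| education | 16 &plusmn; 2.7 y | well-educated volunteer samples |
| APOE-&epsilon;4 prevalence | 0.57 | enriched AD-risk cohort |
| baseline pTau181/A&beta;42 | 0.044 &plusmn; 0.028 | assay-scale ratio units |
| visits | 5, annual, gap-free | ~4-year follow-up |
| biomarker innovation SD | 0.028 (ratio units) | matches observed change-score spread |
| biomarker AR slope | 0.9 | slowly drifting pathology |
| memory AR slope | 0.7 | annual test-retest stability of list-learning scores |
| ratio cut-point | 0.025 | configurable convention |

Four effect presets supply the generative fixed effects and variance
components (`effect_preset()`): `"full"` (pooled two-group model, three-way
interaction −17.47, $\tau_{00} = 0.12$, $\sigma^2 = 0.56$), `"preclinical"`
and `"mci"` (the stratum models), and `"null"` (all interactions zero, for
type-I calibration). These encode the magnitude of change-on-change coupling
reported for CSF-ratio and verbal-memory trajectories across the early AD
continuum and serve as recoverable ground truth. Each preset is a
self-contained reference condition: the stratum slopes *implied* by the
pooled `"full"` preset (for example, an MCI-stratum biomarker slope of
−19.97 + 22.91 = +2.94 under its coding) differ from the `"mci"` and
`"preclinical"` presets, which carry the stratified models' own scale.
Stratified fits on a pooled-preset cohort therefore recover the implied
values, and the single-group presets exist precisely so stratum-scale
recovery can be tested against a consistent truth. In raw mode all
coefficients are additionally attenuated by roughly the factor the
concordance bound quantifies (the pipeline change scores carry scale ~0.7
relative to the hidden innovations), another reason estimator-level checks
run in direct mode.

In **direct mode** the generator keeps its hidden truth columns: the random
intercept, the biomarker change innovations $u_{it} \sim N(0,
\mathrm{SD}^2_{\mathrm{innov}})$, and the memory change values $y_{it} =
x_{it}'\beta + b_i + \varepsilon_{it}$. Fitting the model to these variables
tests the *estimator* under exactly the assumed data-generating process. In
**raw mode** the truth is withheld and only reconstructed series are
emitted — the ratio as an AR(1) with innovations $u_{it}$, the RAVLT scores
as an observed-score autoregression driven by $y_{it}$ — so the full
pipeline (staging, composite, lagged residuals) must recover change itself.

Choices worth recording:

* **Memory AR slope 0.7, not 1.** Observed test scores regress toward the
  mean because each measurement carries occasion-specific error; annual
  test-retest correlations for list-learning scores sit near 0.7. A random
  walk (slope 1) would instead accumulate every person-level effect into the
  series, and the pooled lag regression then absorbs part of the persistent
  drift: recovered change correlates only ~0.86 with truth. At slope 0.7 the
  raw-mode pipeline recovers change scores correlating >0.92 with the hidden
  innovations (biomarker: >0.97); the residual attenuation from the random
  intercept leaking into the autoregression is expected and is exactly why
  direct mode exists for estimator tests.
* **Label consistency.** MCI-labelled participants are drawn with both
  episodic-memory tests impaired (the amnestic presentation that dominates
  AD-trajectory cohorts) with a margin of 0.3 SD beyond the z = −1 rule;
  preclinical-labelled participants have no impaired score, with a 0.25 SD
  margin, and their baseline ratio is truncated at the cut-point so they are
  biomarker positive. The margins exist so that staging against *estimated*
  norms (a reference sample of ~2000) reproduces the generated labels in
  more than 99% of participants.
* **Exogenous innovations.** Biomarker innovations are drawn independently
  of covariates, mirroring the model's treatment of biomarker change as an
  exogenous regressor. One visible consequence: per-replicate standard
  errors in simulated strata are *tighter* than those of observational
  cohorts, whose biomarker changes are noisier and correlated with
  unmodelled processes. Simulated significance rates therefore do not mimic
  any particular published p-value; only the coefficients and variance
  components are generative targets.
* **The female memory advantage** enters through the normative sex
  coefficients on the RAVLT (≈0.6 SD at baseline), so it appears in raw
  scores and the uncorrected composite but is absorbed by the
  demographically corrected staging z-scores — as it should be.
* Ratios are floored at zero after the AR step; RAVLT scores are rounded to
  integers and clamped to their ranges. Both matter only in raw mode and are
  part of what the concordance bound absorbs.

What the generator does **not** emulate: dropout and mortality, irregular
visit schedules, practice effects, assay batch effects, progression to
dementia during follow-up, and covariate-dependent biomarker dynamics.
Passing recovery tests therefore demonstrate that the estimator and pipeline
are correct under the stated assumptions — not that those assumptions hold
in any particular cohort.

## Verification strategy and problem sizes

The test suite checks every primitive against an independent oracle:
closed-form OLS on printed fixtures for normative scoring and lagged
residuals, exhaustive enumeration of all 64 impairment profiles against a
brute-force implementation of the two actuarial criteria (45 MCI / 19 CN),
a fixed-covariance GLS solution on a balanced fixture and an OLS-equivalence
construction for the degenerate $\tau_{00} = 0$ case, and Monte-Carlo
recovery runs in which replicate-mean estimates must sit within two
Monte-Carlo standard errors of the generative truth, with 95% Wald coverage
inside its binomial error band. Recovery uses 200 replicates at the preset
cell sizes (401 pooled; 265 MCI; 138 preclinical); type-I calibration uses
500 replicates of 100-participant null cohorts, sizes chosen to put the
Monte-Carlo error well below the effects of interest while keeping a full
run in the tens of seconds on one core.

## Known limitations

* Random slopes are deliberately absent: with ~4 change observations per
  participant the random-intercept model is the reading consistent with the
  reported variance structure, and richer structures are weakly identified.
* The lagged-residual regression is pooled across diagnostic groups (a
  configuration switch could fit it within group; the pooled fit is the
  default because the two-group analysis interprets a common change scale).
* Wald inference is mildly anticonservative in very small strata; the
  calibration suite bounds this at the sizes the package targets.
* The generator's staging margins make labels nearly deterministic; cohorts
  with genuinely borderline profiles will show more staging disagreement
  than the >99% figure above.
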