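---
title: "Normative distance-from-hyperplane analysis of reward responsiveness: models and design choices"
author: "rewardDFH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative distance-from-hyperplane analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `rewardDFH`, the
assumptions it makes, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical
and design decisions taken where the problem left genuine freedom.

## 1. The analysis model

The pipeline treats "how clearly does this brain distinguish received
reward from received punishment" as a learnable, dimensional quantity.

**Features.** One response estimate per region per condition per subject,
in arbitrary GLM units: by default 412 regions (400 cortical parcels plus
bilateral thalamus, caudate, putamen, accumbens, hippocampus, amygdala).
Feature rows must be complete; subjects or regions with missing coverage
must be resolved upstream. The container is a `SummarizedExperiment`
subclass (`RewardCohort`) with regions as rows and the `2 x n_subjects`
observations as columns.

**Standardization.** Region-wise mean/s.d. estimated on the TD training
observations with both conditions pooled. Pooling is deliberate: the
classifier must *learn* condition differences, so per-condition scaling
(which would remove them) is not offered. Constant training regions are an
error, not silently dropped — they indicate an upstream extraction fault.

**Feature selection.** L1-penalized logistic classification of condition
(reward coded 1) over a 50-value log-spaced penalty path (`glmnet`),
choosing the penalty by 10-fold subject-grouped cross-validated deviance
with the one-standard-error rule. Grouped folds keep a subject's two rows
together; splitting them would let the classifier exploit subject identity
rather than condition. The selected-feature count is a dataset property,
not a target: on other data any sparse set may emerge. An empty selection
(no signal at any penalty) is flagged, and downstream training falls back
to the full region set with a warning rather than aborting, so chance-level
data still yield an evaluable — chance-level — classifier.

**Classifier and DFH.** A linear soft-margin SVM (`e1071`/libsvm, cost
`C = 1` by default, convergence tolerance `1e-6`) on the standardized
selected features. The signed distance from the hyperplane is
`d = (w.x + b) / ||w||`, which is invariant to any positive rescaling of
`(w, b)`; orientation is enforced after every fit by negating `(w, b)` if
the mean training reward distance is not positive. `C` matters little in
the near-separable regime the task produces, since the margin term
dominates; it is exposed for harder data.

**Norming.** Only reward-condition distances are normed:
`z = (d - mu_train) / sigma_train` with the sample s.d. (`ddof = 1`;
the estimator choice is stated because at `n = 65` it changes sigma by
~1%). Five categories follow, with boundary ties assigned to the *inner*
(more normative) bin: `z = 1` and `z = -1` are normative, `z = -2` falls
in the `-2..-1` band. The interval language the field uses does not fix
closure; ties are measure-zero but a deterministic, documented rule makes
records reproducible. Punishment-condition DFH is reported as
`d_pun = -d` so that larger values mean a stronger punishment-side
response; it gets no categories.

**Group statistics.** Pearson chi-square without continuity correction on
category-count tables (groups x categories), with zero-total columns
dropped and df adjusted — small TD samples legitimately leave extreme bins
empty. Collapsed schemes: `low3` (normative + the two low bins) isolates
the deficient tail, `high3` the exaggerated tail. Correlations are
Pearson, pairwise-complete, two-sided, tiered at 0.05/0.01/0.005 with no
multiplicity correction (an explicit reporting choice, mirroring
starred-threshold conventions; adjust externally if needed). Severity
comparisons are Welch t tests (typical minus deficient); Welch rather than
pooled-variance because group sizes and variances differ by construction.
Sensitivity analyses refit the comparison as OLS on group + age + IQ + sex
and report the adjusted group coefficient next to the unadjusted contrast.

**Cross-validated performance.** Subject-grouped 10-fold CV with the
*entire* preprocessing (standardizer, selection, hyperplane) refit in
every fold, pooling held-out confusion counts; reward is the positive
class for sensitivity/specificity. This is the leakage-safe estimate;
a fixed held-out split can be obtained by training on one subject set and
scoring another with `signedDistance()`.

## 2. The synthetic cohort generator

No participant-level data ship with the package, so the generator
provides cohorts under which the analysis's claims are true by
construction, making parameter recovery a meaningful test surface.

The generative model for subject `s`, condition `c`, region `r`:

```
y[s, c, r] = u_s                                  subject effect, N(0, subjectSd)
           + I(c = reward)     * g_s * dRew[r]    attenuated reward contrast
           + I(c = punishment) *       dPun[r]    punishment contrast
           + eps                                  N(0, noiseSd)
```

`dRew` is nonzero on 20 reward-preferring regions (14 cortical parcels
plus bilateral caudate/putamen/accumbens), `dPun` on 14 cortical
punishment-preferring regions. The gain `g_s` is 1 for TD subjects and
`min(lambda_dx)` over a clinical subject's diagnoses — comorbidity takes
the *worst* attenuation, the simplest rule under which comorbid subjects
are at least as affected as single-diagnosis ones. Punishment responses
are never attenuated, so punishment rows are distributionally identical
across groups (and, by the generator's fixed RNG consumption order,
*numerically* identical across attenuation settings at a given seed — a
deliberately strong testing hook).

Symptom scales are affine in the deficit: `intercept + beta * (1 - g_s) +
noise`, truncated to each instrument's range. Scales tied in the
literature to reward-response integrity (conduct problems, reactive
aggression, ADHD indices, emotional problems/depression, callous traits,
neglect exposure) have positive `beta`; anxiety, proactive aggression,
abuse, substance-use and irritability scales have `beta = 0`, so
discriminant validity of the downstream correlations is testable.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| group sizes | 65 / 39 / 195 | the study design the pipeline targets |
| `nRegions` | 412 | 400 parcels + 12 subcortical |
| `deltaReward`, `deltaPunishment` | 1.0 | contrast = 1 residual s.d.: a strong condition effect, as expected for reward receipt vs loss |
| `subjectSd` | 0.5 | between-subject level shifts half as large as within-cell noise |
| `noiseSd` | 1.0 | unit residual scale (features are in arbitrary units anyway) |
| `attenuation` | CD 0.4, ADHD 0.5, MDD 0.6, GAD 0.8 | ordering follows the relative strength of reported reward-processing deficits; externalizing worst |
| `diagnosisRates` | CD .54, ADHD .72, MDD .18, GAD .32 | marginal prevalences matching the clinical subgroup sizes of the target design (105/140/35/63 of 195); flags drawn independently, all-zero rows resampled |
| `missingRate` | 0 | determinism by default; raise it to exercise pairwise-complete statistics |
| age/sex/IQ | independent of features | the target analysis found no demographic DFH association; `confoundAge = TRUE` induces an age-group link plus an age-symptom slope to exercise the sensitivity models |

What the generator does **not** emulate: voxel-level or time-series
structure, hemodynamics, realistic inter-region covariance (residuals are
i.i.d. across regions), realistic psychometrics (scores are truncated
Gaussians, not item sums), site/motion artifacts, and any relationship
between demographics and brain features beyond the optional age switch.
Passing tests therefore demonstrate the *pipeline's* correctness and
calibration under its assumed data-generating process — not that real
parcel data satisfy those assumptions.

## 3. Numerical choices and degenerate inputs

- Penalty path: 50 log-spaced values chosen by `glmnet`; an explicit grid
  can be supplied. A single-value grid skips CV and fits directly (used to
  probe the infinite-penalty limit).
- SVM tolerance `1e-6`; fits on duplicated data with `C` halved reproduce
  the original `(w, b)` to the same order, which the tests assert.
- Orientation, scale invariance and the self-norming identity (training
  z-scores have mean 0, s.d. 1 to 1e-10) are enforced/verified rather than
  assumed.
- Degenerate cases: single-class labels, constant regions, all-equal
  training distances, empty groups and collinear covariates raise typed
  errors; empty selections and zero-count contingency columns degrade
  gracefully with warnings (the latter with df adjustment).
- Chance band for permutation tests: under within-subject label
  permutation, a subject's two held-out predictions are dependent, so the
  null accuracy band uses the *subject* as the exchangeable unit
  (Binomial(n_subjects, 0.5) quantiles), not the observation count;
  observation-level bands are anti-conservative for dispersion reasons
  unrelated to leakage.
- Null-calibration runs fit the hyperplane without the L1 stage: under the
  null the two compared groups are exchangeable given any training-derived
  hyperplane, so the category chi-square's null distribution does not
  depend on the selection route, and skipping it keeps a 1000-cohort
  calibration cheap.
- Pipeline seeding: one base seed fans out as `seed + 1000 * stage`
  (simulation inherits the configuration's own seed), so any stage can be
  reproduced in isolation.

## 4. Problem sizes used by the test suite

Unit tests run on reduced cohorts (typically 20/12/30 subjects, 40
regions). The acceptance-style checks use: 100 random hyperplanes (<= 5
dims) against a projection oracle; 1000 random tables against the direct
chi-square formula; 50 permutation cohorts of 40 subjects and 60 regions;
20 selection-recovery cohorts at full 412 regions (training n = 65,
delta 1.5, noise 0.5) plus 20 pure-noise cohorts; 100 study-sized power
cohorts and 1000 null-calibration cohorts at 60 regions; and 20
symptom-coupling cohorts at 60 regions. The 60-region cohorts keep the
34 discriminative regions intact and shrink only the null background.

## 5. Known limitations

- The five-category scheme discards information relative to analyzing `z`
  continuously; it is retained because the categorical contrasts are the
  analysis of interest, but `scoreCohort()` exposes `z` for ordinal or
  continuous modelling.
- With 39 TD test subjects the extreme bins carry expected counts near or
  below 1; the chi-square approximation there relies on the pooled table,
  and the package's own calibration check (type-I 5% +/- 2% at study
  size) should be re-run if group sizes change materially.
- `sigma_train` from 65 subjects is itself noisy; category boundaries
  inherit that noise. Small training samples trigger an explicit
  "unstable norms" warning in `runPipeline()`.
- The SVM is linear by design (the hyperplane *is* the deliverable);
  nonlinear kernels would break the DFH interpretation and are out of
  scope.
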