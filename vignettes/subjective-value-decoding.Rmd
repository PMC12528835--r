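---
title: "Modeling and decoding subjective value under risk and ambiguity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and decoding subjective value under risk and ambiguity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdecoder)
```

## The problem

How strongly and how widely does the brain encode the subjective value (SV)
of uncertain rewards, and does that encoding differ between groups — for
example between healthy comparison participants and a clinical population?
`svdecoder` implements the full computational chain needed to ask this
question with model-based fMRI: an economic task design, a utility model and
its estimation, first-level GLMs with SV modulators, trial-wise multivoxel
decoding of SV level, and permutation-based group inference including a
network-level "widespreadness" index. Because raw neuroimaging data for such
studies are rarely shareable, the package also ships a first-class synthetic
cohort generator that emulates the statistical structure every downstream
stage assumes, so the whole pipeline is testable end to end.

## The task and the choice model

Each trial offers a certain $5 against a lottery paying $0 or `v`
(`v` from $4 to $66, 21 amounts). Half the trials state the win probability
explicitly (known risk: 25, 50, 75%); in the other half an objectively 50%
lottery is partially occluded (ambiguity levels: 24, 50, 74% occlusion).
`build_choice_set()` crosses the 20 non-catch amounts with the 6 uncertainty
levels once each (120 unique trials over four runs of 30) and opens every run
with a dominated $4 catch trial, giving 124 trials. Onsets accumulate a fixed
6.5 s display/response/confirmation sequence plus a uniform 4.25–5.75 s
jitter; the response-time compensation in the inter-trial interval makes
trial duration response-independent, so onsets need only the jitter draw.
A note on counts: the task is usually described as "runs of 30 trials", but
the total of 124 implies 31 per run once the catch trial is included; the
generator produces 31 per run and treats the catch trial as outside the
30-trial count.

The subjective value of an option is

$$SV = \left[p - \beta \frac{A}{2}\right] v^{\alpha},$$

with risk tolerance $\alpha$ ($\alpha < 1$ risk-averse), ambiguity attitude
$\beta$ (reported as ambiguity tolerance $-\beta$), and the safe option
evaluated at $p = 1, A = 0$. Choices follow the logistic rule

$$\Pr(\text{lottery}) = \frac{1}{1 + e^{\gamma\,(SV_{lottery} - SV_{safe})}},$$

implemented exactly as written: value-consistent choosers therefore have
$\gamma < 0$, and $\gamma$ is left unbounded with its sign free.

```{r model}
sched <- build_choice_set(4, seed = 1)
nrow(sched)
subjective_value(0.5, 0, 20, alpha = 0.599, beta = 0)  # risk-averse chooser
choice_probability(6, 5, gamma = -1)
```

### Estimation

`fit_preferences()` minimizes the negative log-likelihood under the bounds
$0 \le \alpha \le 10$, $-5 \le \beta \le 5$ (L-BFGS-B), with probabilities
clipped to $[10^{-12}, 1-10^{-12}]$ so deterministic simulators keep a finite
likelihood. Multistart matters here: likelihood is flat wherever extreme
$\alpha$ saturates every choice probability, and quasi-Newton steps stall on
that clipped plateau. The optimizer therefore always includes three fixed
anchor starts in the interpretable region — $(1, 0, -1)$, $(0.6, 0.5, -2)$,
$(1.5, -0.5, -0.5)$ — before the seeded uniform draws over the bounded box;
with uniform-only starts a sizable share of fits never leaves the plateau.
Fit quality is summarized by McFadden's pseudo-$R^2$ against the chance
model, $1 - LL/(n \log 2)$ (study reports in this task family quote a pseudo-$R^2$
without defining it; McFadden-vs-chance is the standard choice for binary
choice data). Missing-response trials are censored, never imputed; catch
trials enter the likelihood like any other non-missing trial.

```{r fit}
truth <- list(alpha = 0.6, beta = 0.5, gamma = -2)
choices <- simulate_choices(sched, truth, missing_rate = 0.02, seed = 2)
fit_preferences(choices, n_starts = 10, seed = 3)
```

## The synthetic cohort generator

`cohort_spec()` describes two groups by truncated-normal distributions over
$(\alpha, \beta, \gamma)$. Defaults are the study conditions the package
emulates: group sizes 27 and 33; $\alpha$ centered on the published group
medians (0.599 and 0.628), $\beta$ on 0.524 and 0.352, both with SDs chosen
to span the mildly averse-to-seeking range such tasks elicit; $\gamma$
centered on $-1$ (SD 0.4), which yields pseudo-$R^2$ values in the
moderate-to-good range (about 0.4–0.6) reported for this kind of task; and a
2% missing-response rate, a typical scanner no-response frequency.

`synthetic_atlas()` is an abstract stand-in for a combined cortical +
subcortical functional parcellation: 200 "cortical" parcels split evenly
over seven large-scale networks plus 16 "subcortical" parcels as an eighth
network, with disjoint voxel-index sets (20–60 voxels cortical, 10–30
subcortical, mirroring the smaller real subcortical parcels). No spatial
embedding is simulated — decoding needs only labeled voxel sets.

`simulate_beta_series()` writes the SV signal into trial patterns as

$$\beta_{t} = a_r \, z(SV_t) \, w_r(\text{context}_t) + \varepsilon,$$

with per-ROI amplitude $a_r$, within-participant standardized lottery SV
$z$, unit-norm voxel weight vectors $w_r$, and i.i.d. Gaussian noise. The
signal is *graded* (linear in $z$), not binarized, so the median-split
decoder faces the realistic situation in which boundary trials are
intrinsically hard; accuracy consequently saturates well below 100% even at
high amplitude. `shared_across_contexts` mixes a context-shared weight
vector with context-specific ones: at 1 risk and ambiguity trials share one
pattern (cross-context decoding succeeds), at 0 the patterns are orthogonal
in expectation (cross-context decoding sits at chance). The default
amplitude 0.5 against unit noise produces single-ROI accuracies in the
60–70% range typical of value regions. `simulate_bold_run()` additionally
builds TR-resolution BOLD from HRF-convolved decision epochs and the scaled
SV modulator, plus optional slow drift (cosines below the high-pass cutoff),
leakage from a 13-column confound table, and white noise; with all noise at
0 the GLM must recover the generating betas to machine precision, which the
tests assert.

What the generator does *not* emulate: temporally autocorrelated or
physiological noise, head motion, spatial smoothness, inter-regional
correlation, and any misspecification of the utility model itself. Passing
tests therefore demonstrate that the machinery is correct and calibrated
under the assumed data structure, not that real data meet those assumptions.

## First-level GLMs

`build_design()` reproduces the two first-level models: a decision-epoch
regressor (4 s boxcars) with a single parametric SV modulator
(lottery SV by default; chosen-option SV and |ΔSV| difficulty variants are
available), and a beta-series model with one regressor per trial. Modulators
are scaled within run to [0, 1] by the run maximum (negative SVs, possible
under extreme ambiguity aversion, are floored at 0 first so the stated range
holds) and mean-centered within run before convolution, so the epoch
regressor carries the mean response — the convention of the software the
design imitates. The canonical double-gamma HRF (peak 5 s, undershoot 15 s,
ratio 6) is normalized to unit peak. `fit_glm()` projects out an SPM-style
discrete-cosine basis (cutoff 128 s) from data and design and solves OLS per
voxel; no prewhitening is applied because the synthetic noise is white
(documented limitation). Rank-deficient designs fail with the offending
columns named. Sphere extraction (`sphere_extract()`, `value_rois()`)
averages betas in 5 mm spheres at the canonical valuation-system
coordinates: vmPFC (−1, 46, −7), bilateral ventral striatum (±10, 10, −4),
PCC (−4, −30, 36). Group tests are the classic one-sample and
pooled-variance two-sample t tests.

## Decoding

Trials are labeled low/high SV by a median split of the run-max-normalized
lottery SV computed from *individual* parameters ("normalized SV" is
interpreted as the same run-max scaling used for the univariate modulator;
task protocols of this kind do not define it separately). Median-tied trials are
assigned one at a time, in seeded random order, to the currently smaller
class — the balancing goal is standard, the mechanism
(seeded round-robin) is this package's choice. Catch trials participate
unless the caller excludes them. Trials whose spatial mean beta lies more
than 3 SD from the ROI's across-trial mean are removed first
(`remove_outlier_trials()`).

`loro_cv_decode()` is a linear support-vector classifier (`e1071`/libsvm,
cost C = 1, no feature rescaling — betas are used as-is, matching
beta-pattern decoding convention; the kernel is linear because the reference
toolbox default is) under leave-one-run-out cross-validation. Because median
splits leave slightly imbalanced training sets, each fold runs `n_boot`
bootstrap iterations that equalize label counts by randomly removing
majority-class training samples; fold accuracy is the bootstrap mean and the
result averages folds. With exactly balanced labels and `n_boot = 1` this
reduces to plain CV (asserted in the tests). Bootstrap subsampling is global
across the three training runs, not stratified by run.
`cross_context_decode()` trains on one uncertainty context in the retained
runs and tests on the other context in the held-out run, in both directions,
using within-context median splits.

## Permutation inference and widespreadness

`permutation_null()` builds the per-participant null by permuting the
trial labels once per repetition and rerunning the identical CV (the
permuted labels serve in training and in scoring the held-out run, exactly
as the true labels do in the observed analysis). This dataset-wise
relabeling makes the observed statistic and the null draws exchangeable
under the no-information hypothesis. The alternative reading — refreshing
the permutation independently inside each training fold — was implemented
and measured during development: it decorrelates the four folds'
classifiers and shrinks the null SD from ≈0.057 to ≈0.037 under signal-free
data, inflating false positives to ≈13% at α = 0.05, so it was rejected.
Permuted p values are the proportion of null statistics *strictly greater*
than the observed one, exactly as such protocols state it — no +1
smoothing, ties not counted — so p = 0 is attainable and the floor is
1/n_perm. One consequence worth knowing: when a statistic saturates (e.g.
proportions of 1 in both groups, observed difference 0 and all null
differences 0), the strict rule returns p = 0; interpret such cells via the
observed effect size, which the result tables always carry.

`group_difference_permutation()` reshuffles group membership of CV scores.
`widespreadness()` reports, per group × network × threshold (0.05, 0.01,
0.001), the proportion of ROIs whose permuted p beats the threshold, plus
all-ROI proportions and the cross-group overlap of significant ROIs
(intersection/union). `widespreadness_group_test()` permutes group labels
and recomputes the per-pseudo-group ROI p values from the *cached*
per-participant null matrices rather than re-decoding — the statistics are
identical and the runtime drops by orders of magnitude; this is why
`permutation_null()` retains the per-participant null matrix.

## Numerical and design choices

- Probability clipping at $[10^{-12}, 1-10^{-12}]$ before logs.
- SV ties in the choice rule need no special-casing (the logistic gives 0.5).
- Anchor + uniform multistarts for the MLE (see above); default 20 starts.
- Jitter modeled as uniform on [4.25, 5.75] s; per-trial duration is
  response-independent by construction.
- Drift is generated from cosines slower than the 128 s cutoff so the
  high-pass removes it exactly; confound leakage is zero by default.
- Raw SVs enter the choice likelihood (no centering); whether the published
  fits standardized them is unstated, and parameter recovery confirms the
  raw-SV likelihood identifies the parameters.
- Single-modulator designs only; serial orthogonalization never arises.

## Problem sizes in the test suite

The bundled tests and the acceptance script run the full pipeline at desk
scale, chosen so the whole suite completes in minutes on one CPU: bootstrap
counts of 1–20 instead of 1000, 19–99 inner label permutations and 99–300
group permutations instead of 1000, cohorts of 4–20 participants, and
reduced atlases (e.g. 24 ROIs over 4 networks) for the widespreadness
property checks, with the default 216-ROI/8-network atlas asserted
separately. Monte-Carlo tolerances in the tests are set accordingly (e.g.
±1.5 percentage points around chance for signal-free decoding averaged over
20 participants × 3 ROIs). The identical-process calibration of the
widespreadness group test feeds the cached-null machinery directly with
exchangeable synthetic accuracy matrices (200 replicate cohorts), which
tests the inference step at a cost unattainable by re-decoding.

## Known limitations

- White-noise GLM (no prewhitening) and abstract, non-spatial ROIs.
- The strict-greater p value is anti-conservative under heavy ties; the
  full-scale procedure (1000 bootstraps) makes ties negligible, but very
  coarse accuracy lattices (tiny n_boot, few trials) can distort it.
- The generator's SV signal is linear and stationary; reliability
  differences between groups are modeled only through amplitude/extent.
- Leave-one-run-out CV at chance is mildly pessimistic (mean accuracy a few
  tenths of a point below 50%), a known property of cross-validated
  accuracy, visible in the signal-free calibration numbers.
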