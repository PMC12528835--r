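# svdecoder

Subjective value modeling and multivoxel pattern decoding under risk and
ambiguity.

## What this is for

Decision neuroscience studies of risky choice infer each participant's
*subjective value* (SV) of uncertain rewards from their choices, and then ask
where and how reliably the brain encodes that quantity — in canonical value
regions (vmPFC, ventral striatum, PCC) and across large-scale networks — and
whether groups (e.g. a clinical population vs. comparison controls) differ in
the fidelity or spatial extent of that encoding. `svdecoder` implements the
whole computational chain as reusable, tested R functions:

- **Task design** — the 124-trial choice set (certain $5 vs. a lottery for
  $4–$66 at known-risk levels 25/50/75% or ambiguity levels 24/50/74%),
  with run structure, catch trials and event timing;
- **Choice model** — the modified power-utility model
  `SV = [p − β·A/2]·v^α` with the logistic choice rule
  `Pr(lottery) = 1 / (1 + exp(γ·(SV_lottery − SV_safe)))`, constrained
  maximum-likelihood estimation (0 ≤ α ≤ 10, −5 ≤ β ≤ 5, γ free), model-free
  summaries and preference classification;
- **Synthetic cohorts** — agents, choices, confounds, trial-wise multivoxel
  beta patterns and BOLD runs with controllable SV signal amplitude, spatial
  distribution over a 216-parcel / 8-network synthetic atlas, and
  context-shared vs. context-specific codes;
- **First-level GLMs** — canonical-HRF designs with run-max-scaled SV
  modulators (lottery / chosen / difficulty variants), beta-series models,
  discrete-cosine high-pass, sphere-ROI extraction at canonical valuation
  coordinates, group t tests;
- **Decoding** — median-split SV labeling with tie balancing, 3-SD trial
  outlier removal, leave-one-run-out linear SVC (C = 1) with bootstrap label
  balancing, and cross-context generalization (train risk → test ambiguity
  and vice versa);
- **Group inference** — label-permutation nulls per participant and ROI,
  permuted p values (strict "greater than" counting), group-difference
  permutation on CV scores, and the network-level **widespreadness index**
  (proportion of significantly decodable ROIs per network at p < .05/.01/.001)
  with its group-label permutation test.

## Worked example

Fit preferences from simulated choices, build trial patterns, decode SV
level, and test significance by permutation:

```r
library(svdecoder)

sched   <- build_choice_set(4, seed = 1)               # 124 trials, 4 runs
truth   <- list(alpha = 0.6, beta = 0.5, gamma = -2)
choices <- simulate_choices(sched, truth, missing_rate = 0.02, seed = 2)
fit     <- fit_preferences(choices, n_starts = 10, seed = 3)
fit
#> Preference fit: alpha = 0.551, beta = 0.438 (ambiguity tolerance -0.438), gamma = -2.370
#>   nll = 42.12 over 122 trials, pseudo-R2 = 0.502

atlas  <- synthetic_atlas(n_cortical = 4, n_subcortical = 2,
                          networks_cortical = c("limbic", "default"), seed = 4)
sig    <- signal_spec(atlas, amplitude = 0.8)
beta   <- simulate_beta_series(sched, fit$params, sig, seed = 5, choices = choices)
labels <- sv_labels(sched, fit$params, seed = 6, choices = choices)

sapply(beta, function(ser)
  loro_cv_decode(remove_outlier_trials(ser), labels, n_boot = 20,
                 seed = 7)$mean_accuracy)
#> ctx_default_001 ctx_default_002  ctx_limbic_001  ctx_limbic_002          sub_01
#>           0.515           0.620           0.574           0.522           0.666
#>          sub_02
#>           0.675

nul <- permutation_null(beta[5], list(labels), n_perm = 99, n_boot = 1, seed = 8)
sprintf("observed %.3f vs null mean %.3f, p_perm = %.3f",
        nul$observed, mean(nul$group_null), nul$p_perm)
#> "observed 0.639 vs null mean 0.507, p_perm = 0.000"
```

The fitted participant is risk-averse (α < 1) and ambiguity-averse
(−β < 0), with a moderate-to-good fit (pseudo-R² ≈ 0.5). SV level is
decodable above the 50% chance level in every ROI carrying signal — accuracy
varies with parcel size, as expected for a fixed signal-to-noise ratio — and
the permutation test puts the observed accuracy above all 99 label-permuted
reruns (p at the 1/n_perm floor).

The end-to-end pipeline (cohort → fits → decoding → widespreadness) runs
from a single config via `run_pipeline()`, or from a shell through the thin
wrapper `inst/scripts/sv-pipeline`; every stage writes TSV/JSON artifacts
plus a manifest with seeds and checksums.

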