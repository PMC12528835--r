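# Shared fixtures, built in code. Sizes are deliberately small; seeds fixed.

fixture_schedule <- function(seed = 11L) build_choice_set(4L, seed = seed)

fixture_choices <- function(schedule = fixture_schedule(),
                            params = list(alpha = 0.6, beta = 0.5,
                                          gamma = -2),
                            missing_rate = 0, seed = 21L) {
  simulate_choices(schedule, params, missing_rate, seed = seed)
}

# Tiny atlas: 4 cortical ROIs over 2 networks + 2 subcortical.
fixture_atlas <- function(voxel_range = c(10L, 14L), seed = 31L) {
  synthetic_atlas(n_cortical = 4L, n_subcortical = 2L,
                  networks_cortical = c("limbic", "default"),
                  voxel_range = voxel_range,
                  voxel_range_subcortical = voxel_range, seed = seed)
}

# Beta series + labels for one simulated participant.
fixture_participant <- function(amplitude = 0.8, mix = 1, seed = 41L,
                                params = list(alpha = 0.6, beta = 0.5,
                                              gamma = -2),
                                atlas = fixture_atlas(),
                                split_kind = "overall", noise_sd = 1) {
  sched <- build_choice_set(4L, seed = seed)
  sig <- signal_spec(atlas, amplitude = amplitude,
                     shared_across_contexts = mix, noise_sd = noise_sd,
                     voxel_weight_seed = seed)
  list(
    schedule = sched,
    beta = simulate_beta_series(sched, params, sig, seed = seed + 1L),
    labels = sv_labels(sched, params, split_kind = split_kind,
                       seed = seed + 2L)
  )
}
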