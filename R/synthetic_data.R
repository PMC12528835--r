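#' Specification of a synthetic two-group cohort
#'
#' Describes the generative distributions of the preference parameters per
#' group. Defaults reproduce the study conditions the package emulates: a
#' comparison-control group (n = 27) and a patient group (n = 33), both
#' mildly risk-averse (alpha around 0.6) and ambiguity-averse (beta around
#' 0.4-0.5), with moderate choice stochasticity (gamma around -1, the sign
#' convention under which higher-valued lotteries are chosen more often).
#' Parameters are drawn from normal distributions truncated to the model
#' bounds (alpha in \[0, 10\], beta in \[-5, 5\]).
#'
#' @param n_per_group Integer vector of length 2: group sizes.
#' @param group_labels Character vector of length 2.
#' @param alpha,beta,gamma Lists of two `c(mean, sd)` pairs (one per group).
#' @param missing_rate Probability a trial has no response, in \[0, 0.2\].
#' @param seed Integer master seed for the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(27L, 33L),
                        group_labels = c("control", "patient"),
                        alpha = list(c(mean = 0.599, sd = 0.30),
                                     c(mean = 0.628, sd = 0.30)),
                        beta = list(c(mean = 0.524, sd = 0.70),
                                    c(mean = 0.352, sd = 0.70)),
                        gamma = list(c(mean = -1.0, sd = 0.40),
                                     c(mean = -1.0, sd = 0.40)),
                        missing_rate = 0.02,
                        seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1),
            length(group_labels) == 2L,
            length(alpha) == 2L, length(beta) == 2L, length(gamma) == 2L)
  if (missing_rate < 0 || missing_rate > 0.2) {
    stop("`missing_rate` must lie in [0, 0.2]")
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    group_labels = group_labels,
    alpha = alpha, beta = beta, gamma = gamma,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Draw one simulated agent's preference parameters
#'
#' Deterministic in `(spec$seed, index)`: the same pair always yields the
#' same agent. Index runs over the whole cohort (first group first).
#'
#' @param spec A [cohort_spec()].
#' @param index Agent index, `1..sum(n_per_group)`.
#' @return List with `id`, `group`, `alpha`, `beta`, `gamma`.
#' @export
simulate_agent <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"),
            index >= 1, index <= sum(spec$n_per_group))
  g <- if (index <= spec$n_per_group[1]) 1L else 2L
  withr::with_seed(spec$seed + 7919L * as.integer(index), {
    a <- .rtrunc_norm(1, spec$alpha[[g]]["mean"], spec$alpha[[g]]["sd"], 0, 10)
    b <- .rtrunc_norm(1, spec$beta[[g]]["mean"], spec$beta[[g]]["sd"], -5, 5)
    cst <- stats::rnorm(1, spec$gamma[[g]]["mean"], spec$gamma[[g]]["sd"])
  })
  list(id = sprintf("sub%03d", index), group = spec$group_labels[g],
       alpha = unname(a), beta = unname(b), gamma = unname(cst))
}

#' Simulate trial-by-trial choices from the utility model
#'
#' Generative direction of the choice model: per trial a Bernoulli draw with
#' the logistic lottery probability; a fraction of trials is then flagged as
#' missing (no response) uniformly at random.
#'
#' @param schedule A [build_choice_set()] schedule.
#' @param params List with `alpha`, `beta`, `gamma`.
#' @param missing_rate Per-trial missingness probability.
#' @param seed Integer seed.
#' @param participant_id Participant label.
#' @return A [choice_dataset()].
#' @export
simulate_choices <- function(schedule, params, missing_rate = 0, seed = 1L,
                             participant_id = "sub001") {
  stopifnot(inherits(schedule, "trial_schedule"))
  th <- .param_triple(params)
  sv <- .sv_columns(schedule, th["alpha"], th["beta"])
  pr <- choice_probability(sv$lottery, sv$safe, th["gamma"])
  withr::with_seed(as.integer(seed), {
    resp <- ifelse(stats::runif(nrow(schedule)) < pr, "lottery", "safe")
    if (missing_rate > 0) {
      resp[stats::runif(nrow(schedule)) < missing_rate] <- "missing"
    }
  })
  choice_dataset(schedule, resp, participant_id)
}

#' Synthetic region-of-interest atlas
#'
#' Abstract (non-spatial) stand-in for a combined cortical + subcortical
#' functional parcellation: by default 200 "cortical" parcels assigned
#' near-evenly to seven large-scale networks plus 16 "subcortical" parcels
#' forming an eighth network (216 ROIs, 8 networks). Each ROI is a disjoint
#' set of voxel indices; cortical parcels draw 20-60 voxels, subcortical
#' parcels 10-30 (mirroring their smaller real-world size). Geometry is
#' abstract: decoding needs only the labeled voxel sets.
#'
#' @param n_cortical,n_subcortical Parcel counts.
#' @param networks_cortical Cortical network names.
#' @param voxel_range,voxel_range_subcortical Inclusive voxel-count ranges.
#' @param seed Integer seed for voxel counts.
#' @return A `roi_atlas` data frame: `roi_id`, `name`, `network`,
#'   `n_voxels`, and list column `voxel_ids` (disjoint global indices).
#' @export
synthetic_atlas <- function(n_cortical = 200L, n_subcortical = 16L,
                            networks_cortical = c(
                              "visual", "somatomotor", "dorsal-attention",
                              "salience/ventral-attention", "limbic",
                              "control", "default"),
                            voxel_range = c(20L, 60L),
                            voxel_range_subcortical = c(10L, 30L),
                            seed = 1L) {
  stopifnot(n_cortical >= length(networks_cortical), n_subcortical >= 0)
  net <- sort(rep_len(networks_cortical, n_cortical))
  network <- c(net, rep("subcortical", n_subcortical))
  n_roi <- n_cortical + n_subcortical
  withr::with_seed(as.integer(seed), {
    nv <- c(
      sample(seq(voxel_range[1], voxel_range[2]), n_cortical, replace = TRUE),
      if (n_subcortical > 0)
        sample(seq(voxel_range_subcortical[1], voxel_range_subcortical[2]),
               n_subcortical, replace = TRUE)
    )
  })
  ends <- cumsum(nv)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  atlas <- data.frame(
    roi_id = seq_len(n_roi),
    name = c(sprintf("ctx_%s_%03d", gsub("[^a-z]+", "_", net),
                     stats::ave(seq_len(n_cortical), net, FUN = seq_along)),
             if (n_subcortical > 0) sprintf("sub_%02d", seq_len(n_subcortical))),
    network = network,
    n_voxels = nv,
    stringsAsFactors = FALSE
  )
  atlas$voxel_ids <- mapply(seq, starts, ends, SIMPLIFY = FALSE)
  structure(atlas, class = c("roi_atlas", "data.frame"))
}

#' Multivoxel signal specification for synthetic beta series
#'
#' Controls how strongly and where standardized lottery subjective value (SV)
#' is written into trial-wise voxel patterns. Per ROI, unit-norm voxel weight
#' vectors define the SV-coding direction; `shared_across_contexts` mixes a
#' context-shared direction with context-specific ones (1 = identical
#' pattern for risk and ambiguity trials; 0 = independent patterns, so
#' cross-context decoding is at chance in expectation).
#'
#' @param atlas A [synthetic_atlas()].
#' @param amplitude Scalar or per-ROI vector (named or atlas order) of signal
#'   scales, >= 0. Default 0.5 against unit noise gives single-ROI decoding
#'   accuracies in the 60-70% range typical of value regions.
#' @param shared_across_contexts Scalar or per-ROI mix weight in \[0, 1\].
#' @param noise_sd Standard deviation of i.i.d. voxel noise (> 0).
#' @param voxel_weight_seed Seed of the voxel weight vectors (spatial code).
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(atlas, amplitude = 0.5, shared_across_contexts = 1,
                        noise_sd = 1, voxel_weight_seed = 1L) {
  stopifnot(inherits(atlas, "roi_atlas"), noise_sd > 0)
  n <- nrow(atlas)
  amp <- if (length(amplitude) == 1L) rep(amplitude, n) else {
    if (!is.null(names(amplitude))) amplitude[as.character(atlas$roi_id)]
    else amplitude
  }
  stopifnot(length(amp) == n, all(is.finite(amp)), all(amp >= 0))
  mix <- rep_len(shared_across_contexts, n)
  stopifnot(all(mix >= 0 & mix <= 1))
  structure(list(atlas = atlas, amplitude = as.numeric(amp), mix = mix,
                 noise_sd = noise_sd,
                 voxel_weight_seed = as.integer(voxel_weight_seed)),
            class = "signal_spec")
}

#' Per-ROI trial beta-series container
#'
#' @param roi_id ROI identifier.
#' @param X Trials-by-voxels matrix of single-trial estimates.
#' @param run_id Run label per row.
#' @param trial_id Schedule trial id per row.
#' @param participant_id Participant label.
#' @return A `beta_series` object.
#' @export
beta_series <- function(roi_id, X, run_id, trial_id,
                        participant_id = "sub001") {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(run_id), nrow(X) == length(trial_id))
  structure(list(roi_id = roi_id, X = X, run_id = run_id,
                 trial_id = trial_id, participant_id = participant_id),
            class = "beta_series")
}

.unit <- function(x) x / sqrt(sum(x^2))

.roi_weights <- function(signal, roi_row) {
  nv <- signal$atlas$n_voxels[roi_row]
  m <- signal$mix[roi_row]
  withr::with_seed(signal$voxel_weight_seed + 104729L * roi_row, {
    w_shared <- .unit(stats::rnorm(nv))
    w_risk <- .unit(stats::rnorm(nv))
    w_amb <- .unit(stats::rnorm(nv))
  })
  list(risk = .unit(sqrt(m) * w_shared + sqrt(1 - m) * w_risk),
       ambiguity = .unit(sqrt(m) * w_shared + sqrt(1 - m) * w_amb))
}

#' Simulate trial-wise multivoxel beta series for every ROI
#'
#' For each ROI r with context weight vectors `w_r` (unit norm, seeded) the
#' pattern on trial t is
#' `amplitude_r * z(SV_lottery_t) * w_r(context_t) + noise`, with `z` the
#' within-participant standardization of the lottery SV over all trials and
#' i.i.d. Gaussian voxel noise. The SV signal enters linearly (graded), so
#' the downstream median-split decoder faces a realistic continuous signal.
#' Rows for missing-response trials (if `choices` is given) are dropped, so
#' rows align with non-missing schedule trials.
#'
#' @param schedule A [build_choice_set()] schedule.
#' @param params List with `alpha`, `beta` (and optionally `gamma`).
#' @param signal A [signal_spec()].
#' @param seed Integer seed of the trial noise.
#' @param choices Optional [choice_dataset()]; its missing trials are
#'   excluded.
#' @param participant_id Participant label.
#' @return Named list (by ROI name) of [beta_series()] objects; attribute
#'   `atlas` carries the atlas.
#' @export
simulate_beta_series <- function(schedule, params, signal, seed = 1L,
                                 choices = NULL, participant_id = "sub001") {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(signal, "signal_spec"))
  th <- .param_ab(params)
  sv <- subjective_value(schedule$p, schedule$A, schedule$v,
                         th[["alpha"]], th[["beta"]])
  z <- as.numeric(scale(sv))
  keep <- rep(TRUE, nrow(schedule))
  if (!is.null(choices)) {
    stopifnot(nrow(choices) == nrow(schedule))
    keep <- choices$response != "missing"
  }
  atlas <- signal$atlas
  out <- vector("list", nrow(atlas))
  names(out) <- atlas$name
  for (r in seq_len(nrow(atlas))) {
    nv <- atlas$n_voxels[r]
    w <- .roi_weights(signal, r)
    W <- rbind(risk = w$risk, ambiguity = w$ambiguity)
    S <- signal$amplitude[r] * z * W[schedule$context, , drop = FALSE]
    noise <- withr::with_seed(as.integer(seed) + 1299709L * r, {
      matrix(stats::rnorm(nrow(schedule) * nv, sd = signal$noise_sd),
             nrow(schedule), nv)
    })
    X <- (S + noise)[keep, , drop = FALSE]
    out[[r]] <- beta_series(atlas$roi_id[r], X, schedule$run_id[keep],
                            schedule$trial_id[keep], participant_id)
  }
  attr(out, "atlas") <- atlas
  out
}

#' Simulate nuisance confound series
#'
#' Thirteen series mimicking a standard preprocessing confound table: one
#' framewise-displacement-like positive series, six slowly drifting
#' motion-like series, six component-like white noise series.
#'
#' @param n_scans Number of volumes.
#' @param seed Integer seed.
#' @return `n_scans` x 13 matrix with named columns.
#' @export
simulate_confounds <- function(n_scans, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    fd <- abs(stats::rnorm(n_scans, 0.1, 0.05))
    motion <- sapply(seq_len(6), function(i)
      cumsum(stats::rnorm(n_scans, 0, 0.02)))
    comp <- sapply(seq_len(6), function(i) stats::rnorm(n_scans))
  })
  out <- cbind(fd, motion, comp)
  colnames(out) <- c("framewise_displacement",
                     paste0("motion_", c("tx", "ty", "tz", "rx", "ry", "rz")),
                     paste0("comp_", seq_len(6)))
  out
}

#' Simulate a BOLD run for one ROI
#'
#' Generates a time-by-voxels BOLD series (TR 1 s) from the task design:
#' HRF-convolved 4 s decision epochs plus the run-max-scaled, mean-centered
#' SV modulator, multiplied by per-voxel ground-truth betas, plus optional
#' slow drift (built from discrete-cosine components slower than the 128 s
#' high-pass cutoff), confound leakage, and white noise. Ground truth is
#' returned so GLM recovery can be checked exactly.
#'
#' @param schedule A [build_choice_set()] schedule.
#' @param run Which run to simulate.
#' @param params List with `alpha`, `beta`.
#' @param signal A [signal_spec()].
#' @param roi_row Row index of the ROI in the atlas.
#' @param TR Repetition time in seconds (default 1).
#' @param noise_sd,drift_sd,confound_leak Noise scales (default 0: noiseless).
#' @param seed Integer seed.
#' @return A `bold_run` list: `bold` (time x voxels), `confounds`
#'   (time x 13), `truth` (list: `X` task design, `B` true betas), `TR`,
#'   `roi_row`.
#' @export
simulate_bold_run <- function(schedule, run, params, signal, roi_row = 1L,
                              TR = 1, noise_sd = 0, drift_sd = 0,
                              confound_leak = 0, seed = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(signal, "signal_spec"))
  sched <- schedule[schedule$run_id == run, , drop = FALSE]
  if (!nrow(sched)) stop("no trials in run ", run)
  dur <- attr(schedule, "run_duration_s")[run]
  n_scans <- ceiling((dur + 20) / TR) # cover the HRF tail

  th <- .param_ab(params)
  sv <- subjective_value(sched$p, sched$A, sched$v, th[["alpha"]],
                         th[["beta"]])
  mod <- scale_modulator(sv, sched$run_id)
  mod <- mod - mean(mod)
  X <- cbind(
    decision = .convolved_regressor(sched$onset_s, sched$duration_s,
                                    n_scans, TR),
    sv = .convolved_regressor(sched$onset_s, sched$duration_s, n_scans, TR,
                              amplitude = mod)
  )

  nv <- signal$atlas$n_voxels[roi_row]
  w <- .roi_weights(signal, roi_row)$risk
  B <- rbind(decision = rep(0.5, nv), sv = signal$amplitude[roi_row] * w)

  confounds <- simulate_confounds(n_scans, seed = as.integer(seed) + 7L)
  bold <- X %*% B
  withr::with_seed(as.integer(seed), {
    if (drift_sd > 0) {
      dct <- .dct_basis(n_scans, TR, cutoff_s = 128)
      if (ncol(dct)) {
        bold <- bold + dct %*% matrix(stats::rnorm(ncol(dct) * nv,
                                                   sd = drift_sd),
                                      ncol(dct), nv)
      }
    }
    if (confound_leak > 0) {
      L <- matrix(stats::rnorm(ncol(confounds) * nv, sd = confound_leak),
                  ncol(confounds), nv)
      bold <- bold + confounds %*% L
    }
    if (noise_sd > 0) {
      bold <- bold + matrix(stats::rnorm(n_scans * nv, sd = noise_sd),
                            n_scans, nv)
    }
  })
  structure(list(bold = bold, confounds = confounds,
                 truth = list(X = X, B = B), TR = TR, roi_row = roi_row),
            class = "bold_run")
}

#' Simulate a full cohort: agents, choices and (optionally) beta series
#'
#' @param spec A [cohort_spec()].
#' @param signal Optional [signal_spec()]; if supplied each participant also
#'   gets per-ROI beta series. A list of two specs applies one per group
#'   (e.g. to restrict group-2 signal to a network subset).
#' @param n_runs Runs per participant (default 4).
#' @return A `synthetic_cohort`: list of participants, each with `id`,
#'   `group`, `params`, `schedule`, `choices`, and `beta` (if signal given).
#' @export
simulate_cohort <- function(spec, signal = NULL, n_runs = 4L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(signal) && inherits(signal, "signal_spec")) {
    signal <- list(signal, signal)
  }
  n <- sum(spec$n_per_group)
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    agent <- simulate_agent(spec, i)
    g <- if (i <= spec$n_per_group[1]) 1L else 2L
    sched <- build_choice_set(n_runs, seed = spec$seed + 31L * i)
    choices <- simulate_choices(sched, agent, spec$missing_rate,
                                seed = spec$seed + 31L * i + 1L,
                                participant_id = agent$id)
    p <- list(id = agent$id, group = agent$group,
              params = agent[c("alpha", "beta", "gamma")],
              schedule = sched, choices = choices)
    if (!is.null(signal)) {
      p$beta <- simulate_beta_series(sched, agent, signal[[g]],
                                     seed = spec$seed + 31L * i + 2L,
                                     choices = choices,
                                     participant_id = agent$id)
    }
    participants[[i]] <- p
  }
  names(participants) <- vapply(participants, `[[`, "", "id")
  structure(participants, spec = spec, class = "synthetic_cohort")
}
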