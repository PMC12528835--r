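#' Canonical double-gamma hemodynamic response function
#'
#' Standard canonical HRF (gamma density peaking at 5 s minus an undershoot
#' gamma peaking at 15 s, scaled 1/6), sampled at the acquisition TR and
#' normalized to unit peak.
#'
#' @param TR Sampling interval in seconds.
#' @param duration Kernel length in seconds (default 32).
#' @return Numeric kernel sampled at `seq(0, duration, by = TR)`.
#' @export
canonical_hrf <- function(TR, duration = 32) {
  stopifnot(TR > 0)
  t <- seq(0, duration, by = TR)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Run-max scaling of a parametric modulator
#'
#' Within each run, negative values are floored at 0 and the series is
#' divided by its run maximum, mapping onto \[0, 1\] with each run's maximum
#' at exactly 1. (Negative subjective values can arise under extreme
#' ambiguity aversion; flooring preserves the stated \[0, 1\] range.)
#'
#' @param sv Per-trial values.
#' @param run_id Run label per trial.
#' @return Scaled values in \[0, 1\].
#' @export
#' @examples
#' scale_modulator(c(2, 4, 8), rep(1, 3))  # 0.25 0.50 1.00
scale_modulator <- function(sv, run_id) {
  stopifnot(length(sv) == length(run_id))
  x <- pmax(sv, 0)
  out <- numeric(length(x))
  for (r in unique(run_id)) {
    i <- run_id == r
    m <- max(x[i])
    if (m <= 0) stop("degenerate run ", r, ": maximum SV is not positive")
    out[i] <- x[i] / m
  }
  out
}

# SPM-style discrete cosine high-pass basis: the K slowest cosines with
# period longer than `cutoff_s`, excluding the constant.
.dct_basis <- function(n, TR, cutoff_s = 128) {
  K <- floor(2 * n * TR / cutoff_s)
  if (K < 1) return(matrix(0, n, 0))
  t <- seq_len(n) - 1
  D <- sapply(seq_len(K), function(k)
    sqrt(2 / n) * cos(pi * (2 * t + 1) * k / (2 * n)))
  matrix(D, n, K)
}

# Boxcar (optionally amplitude-modulated) regressor convolved with the
# canonical HRF, built on a fine time grid and sampled at scan times.
.convolved_regressor <- function(onsets, durations, n_scans, TR,
                                 amplitude = 1) {
  dt <- TR / 16
  n_fine <- ceiling(n_scans * TR / dt) + 1L
  u <- numeric(n_fine)
  amplitude <- rep_len(amplitude, length(onsets))
  durations <- rep_len(durations, length(onsets))
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(floor((onsets[i] + durations[i]) / dt), n_fine)
    u[a:b] <- u[a:b] + amplitude[i]
  }
  h <- canonical_hrf(dt)
  x <- stats::convolve(u, rev(h), type = "open")[seq_len(n_fine)]
  x[round(seq(0, n_scans - 1) * TR / dt) + 1L]
}

#' Build a first-level design matrix for one run
#'
#' Columns: a 4 s decision-epoch regressor over non-missing trials, a
#' missing-trial regressor (when `choices` contains missing responses), the
#' selected HRF-convolved parametric modulator (run-max scaled to \[0, 1\]
#' and mean-centered before convolution, so the epoch regressor carries the
#' mean response), nuisance confounds, and a constant. `per_trial` instead
#' yields one regressor per non-missing trial (beta-series model, no
#' modulator).
#'
#' @param schedule A [build_choice_set()] schedule restricted to one run (or
#'   a full schedule plus `run`).
#' @param modulator One of "sv_lottery", "sv_chosen", "sv_difficulty",
#'   "none", "per_trial".
#' @param params List with `alpha`, `beta` (group-median or individual, per
#'   the caller's choice); required unless `modulator` is "none"/"per_trial".
#' @param choices Optional [choice_dataset()] aligned to the schedule;
#'   required for "sv_chosen" and for a missing-trial regressor.
#' @param confounds Optional time-by-13 confound matrix.
#' @param n_scans Number of volumes; defaults to the schedule's run duration.
#' @param run Run to select when `schedule` spans several.
#' @param TR Repetition time in seconds.
#' @return A `design_matrix` list: `X` (time x regressors, named), `TR`,
#'   `highpass_s` (128), `modulator`.
#' @export
build_design <- function(schedule,
                         modulator = c("sv_lottery", "sv_chosen",
                                       "sv_difficulty", "none", "per_trial"),
                         params = NULL, choices = NULL, confounds = NULL,
                         n_scans = NULL, run = NULL, TR = 1) {
  modulator <- match.arg(modulator)
  stopifnot(inherits(schedule, "trial_schedule"))
  full <- schedule
  if (!is.null(run)) {
    keep <- schedule$run_id == run
    schedule <- schedule[keep, , drop = FALSE]
    if (!is.null(choices)) choices <- choices[keep, , drop = FALSE]
  }
  if (length(unique(schedule$run_id)) != 1L) {
    stop("`schedule` must cover a single run (use `run =` to select one)")
  }
  if (is.null(n_scans)) {
    dur <- attr(full, "run_duration_s")[unique(schedule$run_id)]
    n_scans <- ceiling((dur + 20) / TR)
  }
  missing <- if (!is.null(choices)) choices$response == "missing"
             else rep(FALSE, nrow(schedule))

  cols <- list()
  on <- schedule$onset_s
  du <- schedule$duration_s
  if (modulator == "per_trial") {
    for (i in which(!missing)) {
      cols[[sprintf("trial_%03d", schedule$trial_id[i])]] <-
        .convolved_regressor(on[i], du[i], n_scans, TR)
    }
  } else {
    cols$decision <- .convolved_regressor(on[!missing], du[!missing],
                                          n_scans, TR)
    if (modulator != "none") {
      if (is.null(params)) stop("`params` needed for an SV modulator")
      th <- .param_ab(params)
      sv_l <- subjective_value(schedule$p, schedule$A, schedule$v,
                               th[["alpha"]], th[["beta"]])
      sv_s <- subjective_value(1, 0, schedule$safe_value, th[["alpha"]],
                               th[["beta"]])
      val <- switch(modulator,
        sv_lottery = sv_l,
        sv_chosen = {
          if (is.null(choices)) stop("`choices` needed for sv_chosen")
          ifelse(choices$response == "lottery", sv_l, sv_s)
        },
        sv_difficulty = abs(sv_s - sv_l)
      )
      m <- scale_modulator(val[!missing], schedule$run_id[!missing])
      m <- m - mean(m)
      cols[[modulator]] <- .convolved_regressor(on[!missing], du[!missing],
                                                n_scans, TR, amplitude = m)
    }
  }
  if (any(missing)) {
    cols$missing <- .convolved_regressor(on[missing], du[missing],
                                         n_scans, TR)
  }
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_scans) {
      stop("confound table not aligned to scan length")
    }
    for (j in seq_len(ncol(confounds))) {
      nm <- colnames(confounds)[j]
      cols[[if (is.null(nm) || nm == "") paste0("confound_", j) else nm]] <-
        confounds[, j]
    }
  }
  cols$constant <- rep(1, n_scans)
  X <- do.call(cbind, cols)
  structure(list(X = X, TR = TR, highpass_s = 128, modulator = modulator),
            class = "design_matrix")
}

#' Fit a voxelwise ordinary-least-squares GLM
#'
#' Applies the discrete-cosine high-pass filter (cutoff 128 s) to both data
#' and design (the constant is preserved), then solves OLS per voxel.
#'
#' @param bold Time-by-voxels data matrix.
#' @param design A [build_design()] object.
#' @return A `glm_fit` list: `betas` (regressors x voxels, named rows),
#'   `df_residual`, `design`.
#' @export
fit_glm <- function(bold, design) {
  stopifnot(inherits(design, "design_matrix"))
  bold <- as.matrix(bold)
  X <- design$X
  if (nrow(bold) != nrow(X)) stop("data and design have different lengths")
  D <- .dct_basis(nrow(X), design$TR, design$highpass_s)
  filt <- function(M) {
    if (!ncol(D)) return(M)
    M - D %*% crossprod(D, M) # D has orthonormal columns
  }
  const <- colnames(X) == "constant"
  Xf <- X
  Xf[, !const] <- filt(X[, !const, drop = FALSE])
  yf <- filt(bold)
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrx$pivot[(qrx$rank + 1):ncol(Xf)]]
    stop("singular design; aliased columns: ", paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrx, yf)
  rownames(betas) <- colnames(Xf)
  structure(list(betas = betas, df_residual = nrow(Xf) - ncol(Xf),
                 design = design),
            class = "glm_fit")
}

#' Spherical region of interest in millimeter space
#'
#' @param center Length-3 numeric, mm coordinates of the sphere center.
#' @param radius Radius in mm (default 5).
#' @param name Optional label.
#' @return A `sphere_roi` list.
#' @export
sphere_roi <- function(center, radius = 5, name = NULL) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = radius, name = name),
            class = "sphere_roi")
}

#' Canonical valuation-system sphere ROIs
#'
#' Four 5 mm spheres centered on meta-analytic coordinates of the brain's
#' valuation system: vmPFC (-1, 46, -7), left and right ventral striatum
#' (+/-10, 10, -4), PCC (-4, -30, 36).
#'
#' @return Named list of [sphere_roi()] objects.
#' @export
value_rois <- function() {
  list(
    vmPFC = sphere_roi(c(-1, 46, -7), name = "vmPFC"),
    vStr_L = sphere_roi(c(-10, 10, -4), name = "vStr_L"),
    vStr_R = sphere_roi(c(10, 10, -4), name = "vStr_R"),
    PCC = sphere_roi(c(-4, -30, 36), name = "PCC")
  )
}

#' Volumetric map with a voxel-to-mm affine
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-index (1-based) to mm affine.
#' @return A `beta_map` list.
#' @export
beta_map <- function(data, affine) {
  stopifnot(length(dim(data)) == 3, all(dim(affine) == c(4, 4)))
  structure(list(data = data, affine = affine), class = "beta_map")
}

#' Regular millimeter grid affine
#'
#' Convenience affine for an axis-aligned grid: voxel (1,1,1) sits at
#' `origin` and spacing is `spacing` mm along each axis.
#'
#' @param spacing Voxel size in mm.
#' @param origin mm coordinate of the first voxel center.
#' @return 4x4 affine matrix.
#' @export
grid_affine <- function(spacing = 2, origin = c(0, 0, 0)) {
  A <- diag(c(rep(spacing, 3), 1))
  A[1:3, 4] <- origin - spacing # 1-based indices: origin + (i-1)*spacing
  A
}

.voxel_centers_mm <- function(map) {
  d <- dim(map$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  t(map$affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
}

#' Mean beta inside sphere ROIs
#'
#' Averages map values over voxels whose center lies within each sphere's
#' radius of its mm center.
#'
#' @param map A [beta_map()].
#' @param rois List of [sphere_roi()] objects (e.g. [value_rois()]).
#' @return Named numeric vector of sphere means.
#' @export
sphere_extract <- function(map, rois) {
  stopifnot(inherits(map, "beta_map"))
  if (inherits(rois, "sphere_roi")) rois <- list(rois)
  mm <- .voxel_centers_mm(map)
  vals <- as.vector(map$data)
  out <- vapply(rois, function(roi) {
    d2 <- colSums((t(mm) - roi$center)^2)
    inside <- d2 <= roi$radius^2
    if (!any(inside)) stop("empty sphere at (",
                           paste(roi$center, collapse = ", "), ")")
    mean(vals[inside])
  }, numeric(1))
  names(out) <- if (!is.null(names(rois))) names(rois)
                else vapply(rois, function(r) r$name %||% "roi", "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One- and two-sample t tests on per-participant betas
#'
#' Classic second-level tests: a one-sample t test of the mean effect against
#' zero and, when `groups` is given, a pooled-variance two-sample t test of
#' the group difference. Two-tailed p values.
#'
#' @param betas Numeric vector, one value per participant.
#' @param groups Optional factor/character of two group labels.
#' @param mu Null value for the one-sample test.
#' @return A data frame with rows `one_sample` (and `two_sample`): estimate,
#'   t, df, p.
#' @export
group_tests <- function(betas, groups = NULL, mu = 0) {
  if (stats::sd(betas) == 0 && all(betas == mu)) {
    one <- data.frame(test = "one_sample", estimate = mean(betas) - mu,
                      t = 0, df = length(betas) - 1, p = 1)
  } else {
    if (stats::sd(betas) == 0) stop("degenerate input: zero variance")
    tt <- stats::t.test(betas, mu = mu)
    one <- data.frame(test = "one_sample", estimate = unname(tt$estimate) - mu,
                      t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value)
  }
  out <- one
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    stopifnot(nlevels(groups) == 2L, all(table(groups) >= 2))
    a <- betas[groups == levels(groups)[1]]
    b <- betas[groups == levels(groups)[2]]
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      if (mean(a) != mean(b)) stop("degenerate input: zero within-group variance")
      two <- data.frame(test = "two_sample", estimate = 0,
                        t = 0, df = length(betas) - 2, p = 1)
    } else {
      tt2 <- stats::t.test(a, b, var.equal = TRUE)
      two <- data.frame(test = "two_sample",
                        estimate = unname(diff(rev(tt2$estimate))),
                        t = unname(tt2$statistic),
                        df = unname(tt2$parameter), p = tt2$p.value)
    }
    out <- rbind(one, two)
  }
  rownames(out) <- NULL
  out
}
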