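#' Median-split labeling of trials into low and high subjective value
#'
#' Trials below the median of the (run-max-normalized) lottery SV are labeled
#' "low", trials above it "high". Trials exactly at the median are assigned
#' one at a time, in seeded random order, to whichever class is currently
#' smaller (coin flip on exact balance), which keeps the label counts as
#' balanced as the ties allow. `within_context` computes separate medians for
#' risk and ambiguity trials.
#'
#' @param sv Per-trial normalized SV values.
#' @param context Per-trial context ("risk"/"ambiguity"); required for
#'   `within_context`.
#' @param split_kind "overall" or "within_context".
#' @param seed Integer seed for tie assignment.
#' @return Factor with levels `low`, `high`; attribute `split_kind`.
#' @export
label_by_median_split <- function(sv, context = NULL,
                                  split_kind = c("overall", "within_context"),
                                  seed = 1L) {
  split_kind <- match.arg(split_kind)
  stopifnot(length(sv) >= 2)
  lab <- rep(NA_character_, length(sv))
  split_one <- function(idx) {
    x <- sv[idx]
    if (length(unique(x)) == 1L) {
      stop("degenerate labeling: all SVs identical")
    }
    med <- stats::median(x)
    l <- rep(NA_character_, length(x))
    l[x < med] <- "low"
    l[x > med] <- "high"
    ties <- which(is.na(l))
    if (length(ties)) {
      ties <- ties[sample.int(length(ties))]
      for (t in ties) {
        n_low <- sum(l == "low", na.rm = TRUE)
        n_high <- sum(l == "high", na.rm = TRUE)
        l[t] <- if (n_low < n_high) "low"
                else if (n_high < n_low) "high"
                else sample(c("low", "high"), 1)
      }
    }
    lab[idx] <<- l
  }
  withr::with_seed(as.integer(seed), {
    if (split_kind == "overall") {
      split_one(seq_along(sv))
    } else {
      if (is.null(context)) stop("`context` required for within_context split")
      for (ctx in unique(context)) split_one(which(context == ctx))
    }
  })
  structure(factor(lab, levels = c("low", "high")), split_kind = split_kind)
}

#' Label a schedule's trials by subjective value
#'
#' Convenience wrapper: computes the lottery SV from individual-specific
#' parameters, normalizes it per run (run-max scaling, as for the univariate
#' modulator), and applies [label_by_median_split()]. Missing-response trials
#' (if `choices` is given) are excluded.
#'
#' @param schedule A [build_choice_set()] schedule.
#' @param params List with `alpha`, `beta`.
#' @param split_kind "overall" or "within_context".
#' @param seed Integer seed for tie assignment.
#' @param choices Optional [choice_dataset()] whose missing trials are
#'   dropped.
#' @return Data frame: `trial_id`, `run_id`, `context`, `sv_norm`, `label`.
#' @export
sv_labels <- function(schedule, params, split_kind = "overall", seed = 1L,
                      choices = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"))
  keep <- if (!is.null(choices)) choices$response != "missing"
          else rep(TRUE, nrow(schedule))
  d <- schedule[keep, , drop = FALSE]
  th <- .param_ab(params)
  sv <- subjective_value(d$p, d$A, d$v, th[["alpha"]], th[["beta"]])
  svn <- scale_modulator(sv, d$run_id)
  lab <- label_by_median_split(svn, context = d$context,
                               split_kind = split_kind, seed = seed)
  data.frame(trial_id = d$trial_id, run_id = d$run_id, context = d$context,
             sv_norm = svn, label = lab, stringsAsFactors = FALSE)
}

#' Remove outlier trials from a beta series
#'
#' Drops trials whose spatial mean beta lies more than `sd_thresh` standard
#' deviations from the ROI's mean across trials (default 3 SD), the standard
#' guard against noisy single-trial estimates.
#'
#' @param series A [beta_series()].
#' @param sd_thresh SD threshold (default 3).
#' @return The filtered `beta_series`; attribute `dropped_trials` records the
#'   removed trial ids.
#' @export
remove_outlier_trials <- function(series, sd_thresh = 3) {
  stopifnot(inherits(series, "beta_series"))
  if (nrow(series$X) < 10) {
    warning("fewer than 10 trials; outlier screen is unreliable")
  }
  m <- rowMeans(series$X)
  keep <- abs(m - mean(m)) <= sd_thresh * stats::sd(m)
  out <- series
  out$X <- series$X[keep, , drop = FALSE]
  out$run_id <- series$run_id[keep]
  out$trial_id <- series$trial_id[keep]
  attr(out, "dropped_trials") <- series$trial_id[!keep]
  out
}

# Align a labels data frame (from sv_labels) to the rows of a beta series.
.aligned_labels <- function(series, labels) {
  if (is.factor(labels) || is.character(labels)) {
    stopifnot(length(labels) == nrow(series$X))
    return(data.frame(trial_id = series$trial_id,
                      label = factor(labels, levels = c("low", "high")),
                      context = NA_character_))
  }
  i <- match(series$trial_id, labels$trial_id)
  if (anyNA(i)) stop("labels missing for some beta-series trials")
  data.frame(trial_id = series$trial_id,
             label = factor(labels$label[i], levels = c("low", "high")),
             context = if ("context" %in% names(labels)) labels$context[i]
                       else NA_character_)
}

.svc_fit <- function(X, y, C) {
  e1071::svm(x = X, y = y, kernel = "linear", cost = C, scale = FALSE)
}

.svc_accuracy <- function(fit, X, y) {
  mean(stats::predict(fit, X) == y)
}

# Indices of a label-balanced subsample: all of the minority class plus a
# random subsample of the majority class of equal size.
.balanced_idx <- function(y) {
  n <- table(y)
  if (min(n) == max(n)) return(seq_along(y))
  minority <- names(n)[which.min(n)]
  keep_min <- which(y == minority)
  keep_maj <- sample(which(y != minority), min(n))
  sort(c(keep_min, keep_maj))
}

# Core leave-one-run-out CV engine shared by observed decoding and
# permutation nulls. For each held-out run, `n_boot` bootstrap iterations
# each balance the training labels by subsampling the majority class, train
# a linear SVC (cost C) and score the held-out run; fold accuracy is the
# bootstrap mean. Permutation nulls rerun this engine on a label vector
# permuted once per repetition (carried through training and test scoring),
# the relabeling scheme under which the CV statistic is exactly exchangeable.
.loro_engine <- function(X, y, run, test_filter = NULL, train_filter = NULL,
                         n_boot = 1L, C = 1) {
  runs <- sort(unique(run))
  fold_acc <- rep(NA_real_, length(runs))
  names(fold_acc) <- paste0("run", runs)
  skipped <- character(0)
  for (f in seq_along(runs)) {
    r <- runs[f]
    tr <- run != r
    te <- run == r
    if (!is.null(train_filter)) tr <- tr & train_filter
    if (!is.null(test_filter)) te <- te & test_filter
    y_tr <- y[tr]
    if (!all(c("low", "high") %in% y_tr) || !any(te)) {
      skipped <- c(skipped, names(fold_acc)[f])
      next
    }
    X_tr <- X[tr, , drop = FALSE]
    accs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- .balanced_idx(y_tr)
      fit <- .svc_fit(X_tr[idx, , drop = FALSE], droplevels(y_tr[idx]), C)
      accs[b] <- .svc_accuracy(fit, X[te, , drop = FALSE], y[te])
    }
    fold_acc[f] <- mean(accs)
  }
  if (length(skipped)) {
    if (all(is.na(fold_acc))) stop("every fold skipped (single-label folds)")
    warning("skipped folds with a single training label: ",
            paste(skipped, collapse = ", "))
  }
  list(fold_accuracies = fold_acc,
       mean_accuracy = mean(fold_acc, na.rm = TRUE),
       skipped = skipped)
}

#' Leave-one-run-out cross-validated SV decoding within an ROI
#'
#' Binary linear support-vector classification (cost `C = 1` by default) of
#' low versus high SV trials, leave-one-run-out: each run is held out in turn
#' and `n_boot` bootstrap iterations equalize the training label counts by
#' randomly removing samples from the majority class before training. Fold
#' accuracy is the mean over bootstraps; the result averages folds.
#'
#' @param series A [beta_series()] (run [remove_outlier_trials()] first to
#'   apply the 3-SD trial screen).
#' @param labels A [sv_labels()] data frame, or a low/high factor aligned to
#'   the series rows.
#' @param n_boot Bootstrap repetitions per fold (default 1000).
#' @param C SVC regularization constant (default 1).
#' @param seed Integer seed (bootstrap subsampling).
#' @return A `decoding_result` list: `roi_id`, `scheme`, `fold_accuracies`,
#'   `mean_accuracy`, `n_boot`, `C`, `seed`, `skipped_folds`.
#' @export
loro_cv_decode <- function(series, labels, n_boot = 1000L, C = 1, seed = 1L) {
  stopifnot(inherits(series, "beta_series"), n_boot >= 1)
  lab <- .aligned_labels(series, labels)
  if (length(unique(series$run_id)) < 2) stop("need at least 2 runs")
  res <- withr::with_seed(as.integer(seed), {
    .loro_engine(series$X, lab$label, series$run_id, n_boot = n_boot, C = C)
  })
  structure(list(roi_id = series$roi_id, scheme = "within",
                 fold_accuracies = res$fold_accuracies,
                 mean_accuracy = res$mean_accuracy,
                 n_boot = n_boot, C = C, seed = as.integer(seed),
                 skipped_folds = res$skipped),
            class = "decoding_result")
}

#' Cross-context SV decoding (train in one uncertainty context, test in the
#' other)
#'
#' Two passes under leave-one-run-out cross-validation: train on low/high SV
#' trials of one context (risk or ambiguity) from the retained runs and test
#' on the other context's trials of the held-out run, with the same bootstrap
#' label balancing as [loro_cv_decode()]. Labels should come from a
#' `within_context` median split. The result averages both directions and all
#' folds.
#'
#' @inheritParams loro_cv_decode
#' @param labels A [sv_labels()] data frame carrying `context`
#'   (`split_kind = "within_context"`).
#' @return A `decoding_result` with `scheme = "cross_context"` and
#'   `direction_means` (risk->ambiguity, ambiguity->risk).
#' @export
cross_context_decode <- function(series, labels, n_boot = 1000L, C = 1,
                                 seed = 1L) {
  stopifnot(inherits(series, "beta_series"), n_boot >= 1)
  lab <- .aligned_labels(series, labels)
  if (anyNA(lab$context)) stop("labels must carry per-trial context")
  if (length(unique(series$run_id)) < 2) stop("need at least 2 runs")
  dirs <- list(c(train = "risk", test = "ambiguity"),
               c(train = "ambiguity", test = "risk"))
  res <- withr::with_seed(as.integer(seed), {
    lapply(dirs, function(d) {
      .loro_engine(series$X, lab$label, series$run_id,
                   train_filter = lab$context == d["train"],
                   test_filter = lab$context == d["test"],
                   n_boot = n_boot, C = C)
    })
  })
  folds <- c(res[[1]]$fold_accuracies, res[[2]]$fold_accuracies)
  names(folds) <- c(paste0("risk_to_amb_", names(res[[1]]$fold_accuracies)),
                    paste0("amb_to_risk_", names(res[[2]]$fold_accuracies)))
  structure(list(roi_id = series$roi_id, scheme = "cross_context",
                 fold_accuracies = folds,
                 mean_accuracy = mean(folds, na.rm = TRUE),
                 direction_means = c(
                   risk_to_ambiguity = res[[1]]$mean_accuracy,
                   ambiguity_to_risk = res[[2]]$mean_accuracy),
                 n_boot = n_boot, C = C, seed = as.integer(seed),
                 skipped_folds = c(res[[1]]$skipped, res[[2]]$skipped)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding (%s) ROI %s: mean accuracy %.3f over %d folds (n_boot %d)\n",
              x$scheme, as.character(x$roi_id),
              x$mean_accuracy, length(x$fold_accuracies), x$n_boot))
  invisible(x)
}
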