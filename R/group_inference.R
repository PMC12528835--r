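#' Permutation null distribution of decoding accuracy for one ROI
#'
#' For each participant, decodes the observed data and then `n_perm`
#' label-permuted versions: per repetition the participant's low/high label
#' vector is permuted once and the full bootstrap-balanced cross-validation
#' is rerun on the relabeled trials (the permuted labels serve in training
#' and in scoring the held-out run, exactly as the true labels do in the
#' observed analysis), and fold accuracies are averaged. Relabeling the
#' whole dataset once per repetition makes the observed statistic and the
#' null draws exchangeable under the no-information hypothesis, which is
#' what keeps the permuted p values calibrated; per-fold label refreshes
#' would shrink the null's variance. The group null is the
#' participant-average of each permutation; the permuted p value is the
#' proportion of group-null accuracies strictly greater than the observed
#' group mean (so p = 0 is possible and the floor is 1/n_perm).
#'
#' @param series_list List of [beta_series()] (one per participant) for the
#'   same ROI.
#' @param labels_list List of [sv_labels()] frames, aligned to
#'   `series_list`.
#' @param n_perm Number of label permutations (>= 100 recommended).
#' @param n_boot Bootstrap repetitions per fold.
#' @param C SVC regularization constant.
#' @param seed Integer seed.
#' @param scheme "within" or "cross_context".
#' @return A `decoding_null` list: `roi_id`, `observed_by_participant`,
#'   `observed` (group mean), `per_participant_null` (participants x
#'   n_perm), `group_null`, `p_perm`, `n_perm`.
#' @export
permutation_null <- function(series_list, labels_list, n_perm = 1000L,
                             n_boot = 1L, C = 1, seed = 1L,
                             scheme = c("within", "cross_context")) {
  scheme <- match.arg(scheme)
  stopifnot(length(series_list) == length(labels_list),
            length(series_list) >= 1)
  if (n_perm < 100) {
    warning("n_perm < 100: the permutation p floor (1/n_perm) is unstable")
  }
  ids <- vapply(series_list, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  P <- length(series_list)

  obs <- numeric(P)
  nulls <- matrix(NA_real_, P, n_perm,
                  dimnames = list(ids, NULL))
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(P)) {
      s <- series_list[[i]]
      lab <- .aligned_labels(s, labels_list[[i]])
      run_one <- function(y) {
        if (scheme == "within") {
          .loro_engine(s$X, y, s$run_id, n_boot = n_boot,
                       C = C)$mean_accuracy
        } else {
          a <- .loro_engine(s$X, y, s$run_id,
                            train_filter = lab$context == "risk",
                            test_filter = lab$context == "ambiguity",
                            n_boot = n_boot, C = C)
          b <- .loro_engine(s$X, y, s$run_id,
                            train_filter = lab$context == "ambiguity",
                            test_filter = lab$context == "risk",
                            n_boot = n_boot, C = C)
          mean(c(a$fold_accuracies, b$fold_accuracies), na.rm = TRUE)
        }
      }
      obs[i] <- run_one(lab$label)
      for (j in seq_len(n_perm)) nulls[i, j] <- run_one(sample(lab$label))
    }
  })
  names(obs) <- ids
  group_null <- colMeans(nulls)
  observed <- mean(obs)
  structure(list(
    roi_id = series_list[[1]]$roi_id,
    observed_by_participant = obs,
    observed = observed,
    per_participant_null = nulls,
    group_null = group_null,
    p_perm = mean(group_null > observed),
    n_perm = as.integer(n_perm)
  ), class = "decoding_null")
}

#' Per-group permuted p values from a cached null
#'
#' Re-uses the per-participant observed accuracies and null matrices of a
#' [permutation_null()] computed over the pooled cohort to obtain each
#' group's observed mean accuracy and permuted p value.
#'
#' @param null A `decoding_null`.
#' @param groups Named vector/factor of group labels (names = participant
#'   ids).
#' @return Data frame: `group`, `observed`, `p_perm`.
#' @export
group_pvalues <- function(null, groups) {
  stopifnot(inherits(null, "decoding_null"))
  ids <- names(null$observed_by_participant)
  g <- groups[ids]
  if (anyNA(g)) stop("groups must be named by participant id")
  out <- lapply(unique(as.character(g)), function(lev) {
    sel <- which(g == lev)
    o <- mean(null$observed_by_participant[sel])
    gn <- colMeans(null$per_participant_null[sel, , drop = FALSE])
    data.frame(group = lev, observed = o, p_perm = mean(gn > o),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Permutation test of a group difference in cross-validation scores
#'
#' The observed statistic is `mean(a) - mean(b)`; the null reshuffles group
#' membership `n_perm` times. The one-sided permuted p value is the
#' proportion of null differences strictly greater than the observed one.
#'
#' @param scores_a,scores_b Per-participant accuracies (or any scores).
#' @param n_perm Number of membership permutations.
#' @param seed Integer seed.
#' @return List: `observed`, `null` (length n_perm), `p`.
#' @export
group_difference_permutation <- function(scores_a, scores_b, n_perm = 1000L,
                                         seed = 1L) {
  stopifnot(length(scores_a) >= 1, length(scores_b) >= 1)
  obs <- mean(scores_a) - mean(scores_b)
  pool <- c(scores_a, scores_b)
  na <- length(scores_a)
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(j) {
      i <- sample.int(length(pool), na)
      mean(pool[i]) - mean(pool[-i])
    }, numeric(1))
  })
  list(observed = obs, null = null, p = mean(null > obs))
}

.check_networks <- function(atlas, roi_ids) {
  i <- match(roi_ids, atlas$roi_id)
  if (anyNA(i) || anyNA(atlas$network[i])) {
    stop("configuration error: ROI without network assignment")
  }
  atlas$network[i]
}

#' Widespreadness table: proportion of significantly decodable ROIs
#'
#' Per group, network and significance threshold, the proportion of ROIs
#' whose permuted decoding p value falls below the threshold; also overall
#' (all-ROI) proportions (network "all") and, for two groups, the
#' cross-group overlap share of significant ROIs (intersection / union).
#'
#' @param p_table Data frame with columns `roi_id`, `group`, `p_perm`.
#' @param atlas A [synthetic_atlas()] (or any `roi_atlas`).
#' @param thresholds Significance thresholds (default 0.05, 0.01, 0.001).
#' @return A `widespreadness_table` list: `by_network` (group, network,
#'   threshold, n_roi, n_sig, proportion), `overlap` (threshold,
#'   n_both, n_union, share).
#' @export
widespreadness <- function(p_table, atlas,
                           thresholds = c(0.05, 0.01, 0.001)) {
  stopifnot(all(c("roi_id", "group", "p_perm") %in% names(p_table)))
  p_table$network <- .check_networks(atlas, p_table$roi_id)
  groups <- unique(p_table$group)
  rows <- list()
  for (g in groups) {
    d <- p_table[p_table$group == g, ]
    for (thr in thresholds) {
      sig <- d$p_perm < thr
      by_net <- stats::aggregate(sig, by = list(network = d$network),
                                 FUN = function(x) c(sum(x), length(x)))
      for (k in seq_len(nrow(by_net))) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, network = by_net$network[k], threshold = thr,
          n_roi = by_net$x[k, 2], n_sig = by_net$x[k, 1],
          proportion = by_net$x[k, 1] / by_net$x[k, 2])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, network = "all", threshold = thr,
        n_roi = nrow(d), n_sig = sum(sig), proportion = mean(sig))
    }
  }
  by_network <- do.call(rbind, rows)
  overlap <- NULL
  if (length(groups) == 2) {
    overlap <- do.call(rbind, lapply(thresholds, function(thr) {
      s1 <- p_table$roi_id[p_table$group == groups[1] & p_table$p_perm < thr]
      s2 <- p_table$roi_id[p_table$group == groups[2] & p_table$p_perm < thr]
      n_both <- length(intersect(s1, s2))
      n_union <- length(union(s1, s2))
      data.frame(threshold = thr, n_both = n_both, n_union = n_union,
                 share = if (n_union > 0) n_both / n_union else NA_real_)
    }))
  }
  structure(list(by_network = by_network, overlap = overlap),
            class = "widespreadness_table")
}

#' Group-label permutation test of the widespreadness index
#'
#' Re-uses the cached per-participant observed and null accuracies (from
#' [permutation_null()] run once per ROI over the pooled cohort). For the
#' true group labels and for `n_perm` random relabelings, per-ROI permuted
#' p values are recomputed per (pseudo-)group, thresholded, and aggregated
#' into network proportions; the p value per network and threshold is the
#' proportion of null proportion-differences (group 1 minus group 2)
#' strictly greater than the observed difference.
#'
#' @param nulls Named list of `decoding_null` objects, one per ROI, all
#'   computed over the same pooled cohort.
#' @param groups Named vector of two group labels (names = participant ids).
#' @param atlas A `roi_atlas` covering the ROIs in `nulls`.
#' @param thresholds Significance thresholds.
#' @param n_perm Number of group-label permutations.
#' @param seed Integer seed.
#' @return Data frame: `network`, `threshold`, `prop_1`, `prop_2`,
#'   `observed_diff`, `p_perm`, with group 1/2 the first/second label of
#'   `unique(groups)`.
#' @export
widespreadness_group_test <- function(nulls, groups, atlas,
                                      thresholds = c(0.05, 0.01, 0.001),
                                      n_perm = 1000L, seed = 1L) {
  stopifnot(length(nulls) >= 1)
  if (!all(vapply(nulls, inherits, TRUE, "decoding_null"))) {
    stop("`nulls` must be decoding_null objects; rerun permutation_null ",
         "with caching over the pooled cohort")
  }
  ids <- names(nulls[[1]]$observed_by_participant)
  g <- as.character(groups[ids])
  if (anyNA(g)) stop("groups must be named by participant id")
  levs <- unique(g)
  stopifnot(length(levs) == 2)
  roi_ids <- vapply(nulls, `[[`, nulls[[1]]$roi_id, "roi_id")
  networks <- .check_networks(atlas, roi_ids)
  P <- length(ids)
  R <- length(nulls)

  # membership matrix: row 1 = observed labels, rows 2..n_perm+1 = permuted
  memb <- matrix(NA, n_perm + 1L, P)
  memb[1, ] <- g == levs[1]
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(n_perm)) memb[j + 1L, ] <- sample(memb[1, ])
  })
  n1 <- sum(memb[1, ])
  n2 <- P - n1

  # p[perm, roi, group]: permuted decoding p value per pseudo-group
  p_arr <- array(NA_real_, c(n_perm + 1L, R, 2L))
  M1 <- memb / n1        # averaging weights, group 1
  M2 <- (!memb) / n2     # group 2
  for (r in seq_len(R)) {
    obs_i <- nulls[[r]]$observed_by_participant[ids]
    null_i <- nulls[[r]]$per_participant_null[ids, , drop = FALSE]
    for (side in 1:2) {
      Mw <- if (side == 1) M1 else M2
      o <- as.vector(Mw %*% obs_i)          # (n_perm+1) observed means
      gn <- Mw %*% null_i                   # (n_perm+1) x n_inner
      p_arr[, r, side] <- rowMeans(gn > o)
    }
  }

  out <- list()
  for (net in unique(networks)) {
    sel <- which(networks == net)
    for (thr in thresholds) {
      prop1 <- rowMeans(p_arr[, sel, 1, drop = FALSE] < thr)
      prop2 <- rowMeans(p_arr[, sel, 2, drop = FALSE] < thr)
      d <- prop1 - prop2
      out[[length(out) + 1L]] <- data.frame(
        network = net, threshold = thr,
        prop_1 = prop1[1], prop_2 = prop2[1], observed_diff = d[1],
        p_perm = mean(d[-1] > d[1]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "group_levels") <- levs
  res
}
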