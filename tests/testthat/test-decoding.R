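test_that("median split labels follow the tie-balancing rule", {
  # enumeration oracle for the stated rule: below median low, above high,
  # median-tied trials split to balance
  sv <- c(0.2, 0.4, 0.6, 0.6, 0.8, 1.0)
  lab <- label_by_median_split(sv, seed = 1)
  expect_equal(as.character(lab[sv < 0.6]), c("low", "low"))
  expect_equal(as.character(lab[sv > 0.6]), c("high", "high"))
  expect_equal(sum(lab == "low"), 3L)
  expect_equal(sum(lab == "high"), 3L)

  # strictly increasing distinct SVs, even n: exact half split
  sv2 <- seq(0.1, 1, length.out = 20)
  lab2 <- label_by_median_split(sv2, seed = 2)
  expect_equal(unname(table(lab2)["low"]), 10L)
  expect_true(all(lab2[1:10] == "low") && all(lab2[11:20] == "high"))

  # heavy ties never unbalance by more than the tie count allows
  sv3 <- c(1, 2, rep(3, 7), 4, 5)
  lab3 <- label_by_median_split(sv3, seed = 3)
  expect_lte(abs(sum(lab3 == "low") - sum(lab3 == "high")), 1L)

  expect_error(label_by_median_split(rep(1, 6)), "degenerate")
})

test_that("within-context splits balance each context internally", {
  sv <- c(seq(0.1, 0.5, length.out = 10), seq(10, 20, length.out = 10))
  ctx <- rep(c("risk", "ambiguity"), each = 10)
  lab <- label_by_median_split(sv, context = ctx,
                               split_kind = "within_context", seed = 4)
  for (c0 in c("risk", "ambiguity")) {
    tab <- table(lab[ctx == c0])
    expect_equal(unname(tab["low"]), 5L)
    expect_equal(unname(tab["high"]), 5L)
  }
  # overall split on the same data would be maximally unbalanced per context
  lab_all <- label_by_median_split(sv, seed = 4)
  expect_true(all(lab_all[ctx == "risk"] == "low"))
})

test_that("sv_labels normalizes per run before splitting", {
  s <- fixture_schedule()
  lab <- sv_labels(s, list(alpha = 0.6, beta = 0.5), seed = 5)
  expect_equal(nrow(lab), 124L)
  expect_true(all(lab$sv_norm >= 0 & lab$sv_norm <= 1))
  expect_equal(as.numeric(tapply(lab$sv_norm, lab$run_id, max)), rep(1, 4))
  expect_lte(abs(sum(lab$label == "low") - sum(lab$label == "high")), 2L)
})

test_that("3-SD outlier screen drops constructed outliers and little else", {
  # constructed outlier: one trial shifted +10 SD in spatial mean
  X <- withr::with_seed(6L, matrix(rnorm(120 * 20), 120, 20))
  X[17, ] <- X[17, ] + 10 * sd(rowMeans(X))
  ser <- beta_series(1, X, rep(1:4, each = 30), seq_len(120))
  out <- remove_outlier_trials(ser)
  expect_identical(attr(out, "dropped_trials"), 17L)
  expect_equal(nrow(out$X), 119L)

  # homogeneous noise: expected drop rate is the 3-SD Gaussian tail (~0.27%)
  drops <- withr::with_seed(7L, {
    vapply(1:40, function(i) {
      Xi <- matrix(rnorm(124 * 15), 124, 15)
      si <- beta_series(1, Xi, rep(1:4, each = 31), seq_len(124))
      length(attr(remove_outlier_trials(si), "dropped_trials"))
    }, numeric(1))
  })
  expect_lt(mean(drops), 2)   # paper-scale: small average, range 0-4
  expect_true(all(drops <= 4))
})

test_that("decoding separates separable patterns and is at chance when shuffled", {
  # truly separable patterns: class means +/- w, tiny isotropic noise
  p <- fixture_participant(seed = 51)
  lab0 <- p$labels
  w <- withr::with_seed(81L, rnorm(12))
  w <- w / sqrt(sum(w^2))
  sgn <- ifelse(lab0$label == "high", 1, -1)
  X <- outer(sgn, w) + withr::with_seed(82L,
    matrix(rnorm(nrow(lab0) * 12, sd = 0.1), nrow(lab0), 12))
  ser <- remove_outlier_trials(
    beta_series(1, X, lab0$run_id, lab0$trial_id))
  res <- loro_cv_decode(ser, p$labels, n_boot = 3, seed = 8)
  expect_length(res$fold_accuracies, 4L)               # fourfold
  expect_gte(res$mean_accuracy, 0.95)
  expect_true(all(res$fold_accuracies >= 0 & res$fold_accuracies <= 1))

  # shuffled labels: chance
  lab_sh <- p$labels
  lab_sh$label <- withr::with_seed(9L, sample(lab_sh$label))
  res_sh <- loro_cv_decode(ser, lab_sh, n_boot = 3, seed = 8)
  expect_lt(abs(res_sh$mean_accuracy - 0.5), 0.12)
})

test_that("decoding is invariant to voxel permutation and common rescaling", {
  p <- fixture_participant(amplitude = 0.8, seed = 52)
  ser <- p$beta[[2]]
  base <- loro_cv_decode(ser, p$labels, n_boot = 2, seed = 10)

  perm <- ser
  perm$X <- ser$X[, withr::with_seed(11L, sample(ncol(ser$X)))]
  expect_equal(loro_cv_decode(perm, p$labels, n_boot = 2,
                              seed = 10)$mean_accuracy,
               base$mean_accuracy)

  # common affine rescaling of all features (SVM cost rescaled to compensate)
  sc <- ser
  sc$X <- ser$X * 3
  expect_equal(loro_cv_decode(sc, p$labels, n_boot = 2, seed = 10,
                              C = 1 / 9)$mean_accuracy,
               base$mean_accuracy)
})

test_that("accuracy grows with generator signal amplitude", {
  accs <- vapply(c(0, 0.5, 2), function(a) {
    p <- fixture_participant(amplitude = a, seed = 53)
    mean(vapply(p$beta[1:2], function(ser)
      loro_cv_decode(ser, p$labels, n_boot = 2, seed = 12)$mean_accuracy,
      numeric(1)))
  }, numeric(1))
  expect_gt(accs[2], accs[1] - 0.03)  # monotone within sampling error
  expect_gt(accs[3], accs[2])
  expect_gt(accs[3], 0.75)  # graded signal: boundary trials cap the ceiling
})

test_that("with balanced labels and n_boot = 1 the bootstrap path equals plain CV", {
  p <- fixture_participant(amplitude = 0.8, seed = 54)
  ser <- p$beta[[1]]
  row_lab <- factor(p$labels$label[match(ser$trial_id, p$labels$trial_id)],
                    levels = c("low", "high"))
  # force exact balance: same number of each class within every run
  m <- min(table(ser$run_id, row_lab))
  keep <- unlist(lapply(split(seq_len(nrow(ser$X)), ser$run_id), function(i) {
    c(i[row_lab[i] == "low"][seq_len(m)], i[row_lab[i] == "high"][seq_len(m)])
  }))
  keep <- sort(keep)
  ser$X <- ser$X[keep, ]; ser$run_id <- ser$run_id[keep]
  ser$trial_id <- ser$trial_id[keep]
  lab2 <- p$labels[p$labels$trial_id %in% ser$trial_id, ]

  res <- loro_cv_decode(ser, lab2, n_boot = 1, seed = 13)

  # independent plain-CV oracle (no bootstrap machinery)
  y <- factor(lab2$label[match(ser$trial_id, lab2$trial_id)],
              levels = c("low", "high"))
  oracle <- vapply(1:4, function(r) {
    tr <- ser$run_id != r
    fit <- e1071::svm(x = ser$X[tr, ], y = y[tr], kernel = "linear",
                      cost = 1, scale = FALSE)
    mean(predict(fit, ser$X[!tr, ]) == y[!tr])
  }, numeric(1))
  expect_equal(unname(res$fold_accuracies), oracle)
})

test_that("cross-context decoding dissociates shared from specific codes", {
  # shared pattern: both within and cross-context decoding beat chance
  ps <- fixture_participant(amplitude = 2, mix = 1, seed = 55,
                            split_kind = "within_context")
  ser_s <- ps$beta[[1]]
  within_s <- loro_cv_decode(ser_s, ps$labels, n_boot = 2, seed = 14)
  cross_s <- cross_context_decode(ser_s, ps$labels, n_boot = 2, seed = 14)
  expect_gt(within_s$mean_accuracy, 0.62)
  expect_gt(cross_s$mean_accuracy, 0.62)
  expect_length(cross_s$fold_accuracies, 8L)  # 4 folds x 2 directions
  # direction symmetry on an exchangeable generator
  expect_lt(abs(cross_s$direction_means[1] - cross_s$direction_means[2]), 0.2)

  # context-specific patterns: within >> chance, cross ~ chance
  pc <- fixture_participant(amplitude = 2, mix = 0, seed = 56,
                            split_kind = "within_context")
  ser_c <- pc$beta[[1]]
  within_c <- loro_cv_decode(ser_c, pc$labels, n_boot = 2, seed = 15)
  cross_c <- cross_context_decode(ser_c, pc$labels, n_boot = 2, seed = 15)
  expect_gt(within_c$mean_accuracy, 0.62)
  expect_lt(abs(cross_c$mean_accuracy - 0.5), 0.12)
})

test_that("degenerate folds are skipped with a warning", {
  p <- fixture_participant(amplitude = 0.5, seed = 57)
  ser <- p$beta[[1]]
  lab <- p$labels
  # runs 2-4 carry a single label, so only fold 1 has single-label training
  lab$label <- factor(ifelse(lab$run_id == 1, as.character(lab$label), "low"),
                      levels = c("low", "high"))
  expect_warning(r <- loro_cv_decode(ser, lab, n_boot = 1, seed = 16),
                 "skipped")
  expect_equal(sum(is.na(r$fold_accuracies)), 1L)
  expect_equal(r$skipped_folds, "run1")
  lab$label <- factor("low", levels = c("low", "high"))
  expect_error(suppressWarnings(loro_cv_decode(ser, lab, n_boot = 1,
                                               seed = 16)),
               "skipped")
})
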