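# Build a minimal decoding_null object directly (synthetic accuracy caches),
# used to exercise the inference machinery without re-running SVMs.
make_null <- function(roi_id, obs, null_mat) {
  ids <- names(obs)
  structure(list(
    roi_id = roi_id,
    observed_by_participant = obs,
    observed = mean(obs),
    per_participant_null = `rownames<-`(null_mat, ids),
    group_null = colMeans(null_mat),
    p_perm = mean(colMeans(null_mat) > mean(obs)),
    n_perm = ncol(null_mat)
  ), class = "decoding_null")
}

test_that("permuted p values follow the strict counting definition", {
  obs <- c(s1 = 0.75)
  # null {0.5, 0.76, 0.74}: exactly one value strictly greater -> p = 1/3
  n <- make_null(1, obs, matrix(c(0.5, 0.76, 0.74), 1))
  expect_equal(n$p_perm, 1 / 3)
  # observed below every null value -> p = 1
  n2 <- make_null(1, c(s1 = 0.4), matrix(c(0.5, 0.76, 0.74), 1))
  expect_equal(n2$p_perm, 1)
  # ties are not counted as greater
  n3 <- make_null(1, c(s1 = 0.5), matrix(rep(0.5, 4), 1))
  expect_equal(n3$p_perm, 0)
})

test_that("permutation_null decodes observed and permuted label sets", {
  ps <- lapply(1:3, function(i)
    fixture_participant(amplitude = 1.5, seed = 60L + i))
  series <- lapply(seq_along(ps), function(i) {
    s <- ps[[i]]$beta[[1]]
    s$participant_id <- sprintf("sub%02d", i)
    s
  })
  labels <- lapply(ps, `[[`, "labels")
  nul <- suppressWarnings(
    permutation_null(series, labels, n_perm = 40, n_boot = 1, seed = 17))
  expect_equal(dim(nul$per_participant_null), c(3L, 40L))
  expect_equal(nul$observed, mean(nul$observed_by_participant))
  expect_equal(nul$group_null, colMeans(nul$per_participant_null))
  # real signal: observed well above the null and p at the floor
  expect_gt(nul$observed, max(nul$group_null))
  expect_equal(nul$p_perm, 0)
  # null centered on chance
  expect_lt(abs(mean(nul$group_null) - 0.5), 0.05)
  expect_warning(
    permutation_null(series[1], labels[1], n_perm = 20, n_boot = 1, seed = 1),
    "n_perm")
})

test_that("group difference permutation matches exhaustive enumeration", {
  a <- c(0.92, 0.88, 0.9)
  b <- c(0.52, 0.47, 0.51)
  g <- group_difference_permutation(a, b, n_perm = 2000, seed = 18)
  expect_equal(g$observed, mean(a) - mean(b))

  # exhaustive oracle over all choose(6,3) = 20 assignments, strict counting
  pool <- c(a, b)
  combos <- combn(6, 3)
  null_ex <- apply(combos, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  p_ex <- mean(null_ex > g$observed)
  expect_equal(p_ex, 0)  # only the identity split ties; ties are not greater
  expect_lt(abs(g$p - p_ex), 2 / sqrt(2000))

  # identical groups: p is moderate on average over seeds
  ps <- vapply(1:30, function(s)
    group_difference_permutation(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7),
                                 n_perm = 200, seed = s)$p, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)

  # swapping the arguments flips the p value (up to ties)
  g1 <- group_difference_permutation(c(0.9, 0.7), c(0.6, 0.5), n_perm = 500,
                                     seed = 19)
  g2 <- group_difference_permutation(c(0.6, 0.5), c(0.9, 0.7), n_perm = 500,
                                     seed = 19)
  # 2+2 has 6 splits; the identity tie accounts for up to 1/6 of the mass
  expect_lt(abs((1 - g1$p) - g2$p), 1 / 6 + 0.05)
})

test_that("p floors halve when n_perm doubles", {
  obs <- c(s1 = 0.99)
  null1 <- make_null(1, obs, matrix(runif(100, 0.4, 0.6), 1))
  null2 <- make_null(1, obs, matrix(runif(200, 0.4, 0.6), 1))
  expect_equal(1 / null1$n_perm, 2 / null2$n_perm)
})

test_that("widespreadness proportions count significant ROIs per network", {
  atlas <- synthetic_atlas(n_cortical = 24, n_subcortical = 0,
                           networks_cortical = c("limbic", "default"),
                           seed = 1)
  # network of 12 ROIs with 5 significant -> 0.4167
  p_tab <- data.frame(
    roi_id = rep(atlas$roi_id, 2),
    group = rep(c("a", "b"), each = 24),
    p_perm = c(ifelse(seq_len(24) %in% which(atlas$network == "default")[1:5],
                      0.001, 0.5),
               rep(1, 24)))
  ws <- widespreadness(p_tab, atlas, thresholds = c(0.05))
  bn <- ws$by_network
  expect_equal(bn$proportion[bn$group == "a" & bn$network == "default"],
               5 / 12, tolerance = 1e-12)
  expect_equal(round(5 / 12, 4), 0.4167)
  expect_equal(bn$proportion[bn$group == "a" & bn$network == "limbic"], 0)
  expect_equal(bn$proportion[bn$group == "a" & bn$network == "all"], 5 / 24)
  # all p = 1 -> all proportions 0
  expect_true(all(bn$proportion[bn$group == "b"] == 0))
  # overlap share: no overlap here
  expect_equal(ws$overlap$n_both, 0L)

  # invariant to ROI order and network-preserving relabeling
  perm <- sample(nrow(p_tab))
  ws2 <- widespreadness(p_tab[perm, ], atlas, thresholds = c(0.05))
  expect_equal(ws2$by_network[order(ws2$by_network$group,
                                    ws2$by_network$network), ],
               bn[order(bn$group, bn$network), ], ignore_attr = TRUE)

  bad <- p_tab
  bad$roi_id[1] <- 999
  expect_error(widespreadness(bad, atlas), "network")
})

test_that("widespreadness group test flags restricted networks", {
  # direct construction: group A decodable everywhere, group B only in the
  # "default" network; per-ROI nulls are exchangeable chance accuracies
  atlas <- synthetic_atlas(n_cortical = 16, n_subcortical = 0,
                           networks_cortical = c("limbic", "default"),
                           seed = 2)
  ids <- sprintf("sub%02d", 1:12)
  groups <- setNames(rep(c("a", "b"), each = 6), ids)
  n_inner <- 60
  nulls <- withr::with_seed(20L, {
    lapply(seq_len(nrow(atlas)), function(r) {
      has_signal <- ifelse(names(groups) %in% ids[1:6], TRUE,
                           atlas$network[r] == "default")
      obs <- setNames(ifelse(has_signal, rnorm(12, 0.72, 0.03),
                             rnorm(12, 0.5, 0.03)), ids)
      make_null(atlas$roi_id[r], obs,
                matrix(rnorm(12 * n_inner, 0.5, 0.03), 12, n_inner))
    })
  })
  gt <- widespreadness_group_test(nulls, groups, atlas,
                                  thresholds = c(0.05, 0.01),
                                  n_perm = 300, seed = 21)
  lim <- gt[gt$network == "limbic" & gt$threshold == 0.05, ]
  def <- gt[gt$network == "default" & gt$threshold == 0.05, ]
  expect_gt(lim$observed_diff, 0.5)   # B loses the limbic network
  expect_lt(lim$p_perm, 0.05)
  # the unrestricted network shows no group effect: both groups saturate
  expect_lt(abs(def$observed_diff), 0.3)
  expect_gt(def$prop_2, 0.7)
})

test_that("widespreadness group test is calibrated under identical processes", {
  atlas <- synthetic_atlas(n_cortical = 50, n_subcortical = 0,
                           networks_cortical = "default", seed = 3)
  ids <- sprintf("sub%02d", 1:12)
  groups <- setNames(rep(c("a", "b"), each = 6), ids)
  n_inner <- 60
  rejections <- withr::with_seed(22L, {
    vapply(1:200, function(rep_i) {
      nulls <- lapply(seq_len(nrow(atlas)), function(r) {
        obs <- setNames(rnorm(12, 0.55, 0.04), ids)
        make_null(atlas$roi_id[r],
                  obs, matrix(rnorm(12 * n_inner, 0.5, 0.04), 12, n_inner))
      })
      gt <- widespreadness_group_test(nulls, groups, atlas,
                                      thresholds = 0.05, n_perm = 99,
                                      seed = rep_i)
      gt$p_perm[1] < 0.05
    }, logical(1))
  })
  # ~5% rejections; band allows for the discreteness of proportion ties
  expect_gte(mean(rejections), 0.005)
  expect_lte(mean(rejections), 0.12)
})
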