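test_that("the permutation mean-difference test enumerates small problems", {
  # C(6,3) = 20 arrangements; |diff| = 10 is attained only by the observed
  # split and its mirror, so the smallest attainable two-sided p is 2/20
  r <- permutation_mean_diff_test(c(10, 11, 12), c(0, 1, 2))
  expect_true(r$exhaustive)
  expect_equal(r$statistic, 10)
  expect_equal(r$p, 0.1)

  # identical groups: p near 1 under enumeration
  r2 <- permutation_mean_diff_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(r2$p, 0.5)

  # constant pooled data: p = 1 by convention
  r3 <- permutation_mean_diff_test(c(2, 2, 2), c(2, 2))
  expect_equal(r3$p, 1)

  expect_error(permutation_mean_diff_test(1, c(1, 2)), "at least 2")
  # missing values are dropped before testing
  r4 <- permutation_mean_diff_test(c(10, 11, 12, NA), c(0, 1, 2))
  expect_equal(r4$p, r$p)
})

test_that("sampled and exhaustive permutation p-values agree within MC error", {
  set.seed(61)
  A <- rnorm(5, 1); B <- rnorm(5)
  ex <- permutation_mean_diff_test(A, B)                       # C(10,5) = 252
  sm <- permutation_mean_diff_test(A, B, n_perm = 4000, seed = 2,
                                   exhaustive_limit = 1)
  expect_true(ex$exhaustive); expect_false(sm$exhaustive)
  expect_gt(sm$p, 0)
  expect_equal(sm$p, ex$p, tolerance = 4 * sqrt(ex$p * (1 - ex$p) / 4000) + 1e-3)
  # determinism given seed
  sm2 <- permutation_mean_diff_test(A, B, n_perm = 4000, seed = 2,
                                    exhaustive_limit = 1)
  expect_identical(sm$p, sm2$p)
})

test_that("the coupling screen tests each feature and flags significance", {
  atlas <- make_atlas(16)
  mk_prof <- function(id, bump) {
    node <- rnorm(16, mean = bump * (atlas$network == "LN"))
    names(node) <- atlas$region
    glob <- rnorm(8); names(glob) <- NETWORKS
    structure(list(id = id, whole_brain = 0.5, global_network = glob,
                   node = node, within_network = node, between_network = node),
              class = "nc_coupling")
  }
  set.seed(71)
  pa <- lapply(1:10, function(i) mk_prof(paste0("P", i), -2))
  pb <- lapply(1:10, function(i) mk_prof(paste0("C", i), 0))
  scr <- coupling_group_screen(pa, pb, scale = "node", n_perm = 400, seed = 3)
  expect_equal(nrow(scr), 16)
  expect_identical(scr$feature, atlas$region)
  ln <- atlas$network == "LN"
  expect_true(all(scr$significant[ln]))
  expect_true(all(scr$statistic[ln] < 0))
  expect_lt(mean(scr$significant[!ln]), 0.5)
  # BH adjustment is never more liberal than no adjustment
  scr_bh <- coupling_group_screen(pa, pb, scale = "node", n_perm = 400,
                                  seed = 3, adjust = "BH")
  expect_true(all(scr_bh$p_adj >= scr$p - 1e-12))
  expect_error(coupling_group_screen(pa, pb, scale = "bogus"))
})

test_that("summary-statistic t tests reproduce the demographics table", {
  # age: 53.40 +/- 2.89 (n = 25) vs 54.11 +/- 12.09 (n = 18)
  w <- welch_t_from_summary(53.40, 2.89, 25, 54.11, 12.09, 18)
  expect_equal(round(w$t, 2), -0.24)
  expect_equal(w$t, -0.2441819, tolerance = 1e-6)
  # pooled-variance variant on the same summaries
  p <- welch_t_from_summary(53.40, 2.89, 25, 54.11, 12.09, 18,
                            var_equal = TRUE)
  expect_equal(round(p$t, 2), -0.28)
  expect_equal(p$df, 41)
  # equal means give t = 0
  expect_equal(welch_t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
  expect_error(welch_t_from_summary(1, 0, 5, 2, 1, 5), "positive")
})

test_that("the 2x2 chi-square matches the gender table and edge cases", {
  # 17/8 males/females vs 9/9
  g <- chi_square_2x2(17, 8, 9, 9)
  expect_equal(round(g$chi2, 2), 1.42)
  expect_equal(g$df, 1)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$chi2, 0)
  # perfectly separated table: all expected counts 10, chi2 = 4 * 100/10
  expect_equal(chi_square_2x2(20, 0, 0, 20)$chi2, 40)
  expect_error(chi_square_2x2(5, 0, 3, 0), "marginals")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "nonnegative")
})
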