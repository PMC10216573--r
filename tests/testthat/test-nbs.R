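make_stack <- function(values_by_edge, R) {
  # values_by_edge: n_subjects x n_edges matrix over the upper triangle
  idx <- which(upper.tri(matrix(0, R, R)))
  lapply(seq_len(nrow(values_by_edge)), function(s) {
    m <- matrix(0, R, R)
    m[idx] <- values_by_edge[s, ]
    m + t(m)
  })
}

test_that("edge t statistics match hand computation and are antisymmetric", {
  R <- 4
  n_edges <- R * (R - 1) / 2
  A <- matrix(0.5, 3, n_edges); A[, 1] <- c(1, 2, 3)
  B <- matrix(0.5, 3, n_edges); B[, 1] <- c(4, 5, 6)
  sA <- make_stack(A, R); sB <- make_stack(B, R)
  t1 <- edge_t_stats(sA, sB)
  # pooled SD 1, SE = sqrt(2/3): t = -3 / 0.8165
  expect_equal(t1[1, 2], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(t1[1, 3], 0)  # zero pooled variance -> 0
  expect_equal(t1, t(t1))
  t2 <- edge_t_stats(sB, sA)
  expect_equal(t2, -t1)
  expect_equal(edge_t_stats(sA, sA), matrix(0, R, R))
  expect_error(edge_t_stats(sA[1], sB), "at least 2")
})

test_that("suprathreshold components match a brute-force flood fill", {
  # deterministic small cases
  t0 <- matrix(0, 5, 5)
  expect_identical(suprathreshold_components(t0, 1), list())

  path <- matrix(0, 4, 4)
  path[1, 2] <- path[2, 3] <- path[3, 4] <- 5
  path <- path + t(path)
  cc <- suprathreshold_components(path, 1)
  expect_length(cc, 1)
  expect_equal(cc[[1]]$extent, 3)
  expect_equal(cc[[1]]$nodes, 1:4)

  # random 12-node matrices vs the oracle
  set.seed(31)
  for (rep in 1:25) {
    tm <- random_symmetric(12, -2, 2)
    thr <- runif(1, 0, 1.5)
    got <- suprathreshold_components(tm, thr)
    idx <- which(upper.tri(tm), arr.ind = TRUE)
    keep <- tm[upper.tri(tm)] > thr
    ref <- floodfill_components(idx[keep, , drop = FALSE], 12)
    expect_equal(length(got), length(ref))
    sig <- function(l) paste(vapply(l, function(cc)
      paste(cc$extent, paste(cc$nodes, collapse = ","), sep = ":"), ""),
      collapse = ";")
    ord <- function(l) l[order(vapply(l, function(cc) min(cc$nodes), 0))]
    expect_identical(sig(ord(got)), sig(ord(ref)))
  }
})

test_that("nbs_test is deterministic, strict at the threshold, never p = 0", {
  a <- make_atlas(12)
  set.seed(41)
  co <- simulate_cohort(6, 6, a, effect_spec(
    fc_block = list(list(networks = c("DMN", "FPN"), shift = 0.5))),
    T_len = 60, voxels_per_region = 20, seed = 41)
  fc <- lapply(co$subjects, function(s) build_fc(s$timeseries, a))
  grp <- vapply(co$subjects, `[[`, "", "group")
  r1 <- nbs_test(fc[grp == "patient"], fc[grp == "control"], primary_p = 0.01,
                 n_perm = 200, direction = "gt", seed = 5)
  r2 <- nbs_test(fc[grp == "patient"], fc[grp == "control"], primary_p = 0.01,
                 n_perm = 200, direction = "gt", seed = 5)
  expect_identical(r1$components, r2$components)
  for (cc in r1$components) {
    expect_gt(cc$corrected_p, 0)
    expect_lte(cc$corrected_p, 1)
    expect_equal(nrow(cc$edges), cc$extent)
    expect_setequal(cc$nodes, unique(as.vector(cc$edges)))
  }
  # an empty observation yields no components and no p-values
  null_stack <- replicate(4, matrix(0, 12, 12), simplify = FALSE)
  r0 <- nbs_test(null_stack, null_stack, n_perm = 120, seed = 1)
  expect_identical(r0$components, list())
  expect_warning(nbs_test(fc[grp == "patient"], fc[grp == "control"],
                          n_perm = 50, seed = 1), "fewer than 100")
})

test_that("network-pair tallies count unordered pairs and conserve totals", {
  a <- make_atlas(16)
  dm <- network_members(a, "DMN")
  comp <- list(edges = cbind(dm[1], dm[2]))
  tl <- tally_network_pairs(comp, a)
  expect_identical(names(tl$counts), "DMN-DMN")
  expect_equal(tl$total, 1)

  # reported share: 11 DMN-FPN edges out of 49 is 22.45%
  fp <- network_members(a, "FPN")
  sn <- network_members(a, "SN"); ln <- network_members(a, "LN")
  e_dmfp <- cbind(rep(dm[1], 11), rep(fp[1], 11))
  other <- rbind(cbind(rep(sn[1], 20), rep(ln[1], 20)),
                 cbind(rep(sn[1], 18), rep(dm[1], 18)))
  tl2 <- tally_network_pairs(list(edges = rbind(e_dmfp, other)), a)
  expect_equal(tl2$total, 49)
  expect_equal(unname(tl2$counts["DMN-FPN"]), 11)
  expect_equal(unname(round(tl2$percent["DMN-FPN"], 2)), 22.45)
  expect_equal(sum(tl2$counts), tl2$total)

  set.seed(7)
  ed <- cbind(sample(16, 30, TRUE), sample(16, 30, TRUE))
  ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
  tl3 <- tally_network_pairs(list(edges = ed), a)
  expect_equal(sum(tl3$counts), nrow(ed))
  expect_error(tally_network_pairs(list(edges = cbind(1, 99)), a),
               "outside the atlas")
})
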