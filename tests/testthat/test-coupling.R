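test_that("gaussianize produces Blom scores and is rank-invariant", {
  # n = 3: ranks (3, 1, 2) map through (r - 0.375)/(n + 0.25)
  g <- gaussianize(c(3, 1, 2))
  expect_equal(g, qnorm((c(3, 1, 2) - 0.375) / 3.25), tolerance = 1e-12)
  expect_equal(g[3], 0)
  expect_equal(g[1], -g[2])
  expect_equal(g[1], 0.8694239, tolerance = 1e-6)

  # the median of an odd-length distinct vector maps to 0
  v <- c(10, 2, 7, 4, 5)
  expect_equal(gaussianize(v)[which(v == 5)], 0)

  # any strictly increasing transform gives the identical output
  set.seed(2)
  x <- rnorm(25)
  expect_identical(gaussianize(x), gaussianize(exp(3 * x) + 10))

  expect_message(z <- gaussianize(rep(4, 6)), "identical")
  expect_equal(z, rep(0, 6))
  expect_error(gaussianize(1:2), "at least 3")
})

test_that("whole-brain coupling hits the exact identities", {
  set.seed(51)
  R <- 12
  sc <- random_symmetric(R, 0.05, 1)
  idx <- upper.tri(sc)
  fc <- matrix(0, R, R)
  fc[idx] <- gaussianize(sc[idx])
  fc <- fc + t(fc)
  expect_equal(whole_brain_coupling(sc, fc), 1, tolerance = 1e-12)
  expect_equal(whole_brain_coupling(sc, -fc), -1, tolerance = 1e-12)

  # invariance to strictly monotone SC transforms
  set.seed(52)
  pair <- random_coupled_pair(R, 52)
  w1 <- whole_brain_coupling(pair$sc, pair$fc)
  w2 <- whole_brain_coupling(pair$sc^3, pair$fc)  # cube is monotone on (0,1)
  expect_equal(w1, w2, tolerance = 1e-12)

  flat <- matrix(0, R, R); flat[1, 2] <- flat[2, 1] <- 0.5
  expect_error(whole_brain_coupling(flat, pair$fc), "fewer than 3")
})

test_that("every coupling scale equals its brute-force edge-list oracle", {
  atlas <- make_atlas(20)
  for (seed in 1:5) {
    pair <- random_coupled_pair(20, seed)
    sc <- pair$sc; fc <- pair$fc
    expect_equal(whole_brain_coupling(sc, fc), naive_whole_brain(sc, fc),
                 tolerance = 1e-12)
    for (i in c(1, 7, 20)) {
      expect_equal(node_coupling(sc, fc, i), naive_node_coupling(sc, fc, i),
                   tolerance = 1e-12)
      expect_equal(within_network_coupling(sc, fc, atlas, i),
                   naive_partner_coupling(sc, fc, atlas, i, TRUE),
                   tolerance = 1e-12)
      expect_equal(between_network_coupling(sc, fc, atlas, i),
                   naive_partner_coupling(sc, fc, atlas, i, FALSE),
                   tolerance = 1e-12)
    }
    for (nw in NETWORKS) {
      expect_equal(global_network_coupling(sc, fc, atlas, nw),
                   naive_global_network(sc, fc, atlas, nw),
                   tolerance = 1e-12)
    }
  }
})

test_that("node coupling handles identities, flips and degeneracies", {
  atlas <- make_atlas(8)
  pair <- random_coupled_pair(8, 99)
  sc <- pair$sc
  expect_equal(node_coupling(sc, sc, 3), 1, tolerance = 1e-12)
  # flipping the sign of the FC row flips the correlation
  fc2 <- -sc
  expect_equal(node_coupling(sc, fc2, 3), -1, tolerance = 1e-12)
  # constant row -> missing marker
  flat <- matrix(0.4, 8, 8); diag(flat) <- 0
  expect_true(is.na(node_coupling(flat, sc, 1)))
  expect_error(node_coupling(sc[1:3, 1:3], sc[1:3, 1:3], 1), "at least 4")
})

test_that("within and between partner sets partition each node's partners", {
  atlas <- make_atlas(24)
  for (i in c(1, 10, 24)) {
    nw <- atlas$network[i]
    within_set <- setdiff(network_members(atlas, nw), i)
    between_set <- which(atlas$network != nw)
    expect_length(intersect(within_set, between_set), 0)
    expect_setequal(c(within_set, between_set, i), 1:24)
  }
  # 2-region network: global coupling undefined
  sizes <- c(SN = 2, LN = 3, VN = 3, SMN = 3, FPN = 3, DMN = 3, DAN = 3,
             SVAN = 3)
  small <- make_atlas(network_sizes = sizes)
  pair <- random_coupled_pair(23, 5)
  expect_true(is.na(global_network_coupling(pair$sc, pair$fc, small, "SN")))
  expect_true(is.na(within_network_coupling(pair$sc, pair$fc, small, 1)))
})

test_that("coupling profiles bundle all five scales with missing markers", {
  atlas <- make_atlas(20)
  pair <- random_coupled_pair(20, 8)
  pr <- coupling_profile(pair$sc, pair$fc, atlas, id = "S1")
  expect_s3_class(pr, "nc_coupling")
  expect_length(pr$node, 20)
  expect_length(pr$global_network, 8)
  expect_identical(names(pr$global_network), NETWORKS)
  vals <- c(pr$whole_brain, pr$global_network, pr$node, pr$within_network,
            pr$between_network)
  expect_true(all(is.na(vals) | (vals >= -1 & vals <= 1)))
})
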