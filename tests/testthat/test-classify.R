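two_clouds <- function(n_per, d, p = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = d), n_per, p))
  y <- factor(rep(c("control", "patient"), each = n_per),
              levels = c("control", "patient"))
  list(x = x, y = y)
}

test_that("feature selection picks exactly the significant screen columns", {
  atlas <- make_atlas(8)
  mk_prof <- function(id, shift) {
    node <- rnorm(8) + shift * (seq_len(8) <= 3)
    names(node) <- atlas$region
    glob <- rnorm(8); names(glob) <- NETWORKS
    structure(list(id = id, whole_brain = 0, global_network = glob,
                   node = node, within_network = node, between_network = node),
              class = "nc_coupling")
  }
  set.seed(81)
  pa <- lapply(1:8, function(i) mk_prof(paste0("P", i), 3))
  pb <- lapply(1:8, function(i) mk_prof(paste0("C", i), 0))
  scr <- coupling_group_screen(pa, pb, scale = "node", n_perm = 300, seed = 4)
  feats <- select_features(pa, pb, scr, scale = "node")
  expect_identical(feats$features, scr$feature[scr$significant])
  expect_equal(ncol(feats$x), sum(scr$significant))
  expect_equal(nrow(feats$x), 16)
  expect_identical(levels(feats$y), c("control", "patient"))

  scr0 <- scr; scr0$significant <- FALSE
  expect_error(select_features(pa, pb, scr0, scale = "node"),
               "no significant features")
})

test_that("well-separated clouds are classified nearly perfectly", {
  d <- two_clouds(20, d = 5, seed = 9)
  rep_ <- loocv_classify(d$x, d$y)
  expect_gte(rep_$accuracy, 0.95)
  # single perfectly rank-separating feature
  x1 <- matrix(c(1:10, 101:110), ncol = 1)
  y1 <- factor(rep(c("control", "patient"), each = 10),
               levels = c("control", "patient"))
  expect_equal(loocv_classify(x1, y1)$accuracy, 1)
})

test_that("reported metrics are exactly recomputable from fold predictions", {
  d <- two_clouds(12, d = 1.2, seed = 10)
  rep_ <- loocv_classify(d$x, d$y)
  pr <- rep_$predictions
  expect_equal(rep_$accuracy, mean(pr$predicted == pr$truth))
  expect_equal(rep_$sensitivity,
               mean(pr$predicted[pr$truth == "patient"] == "patient"))
  expect_equal(rep_$specificity,
               mean(pr$predicted[pr$truth == "control"] == "control"))
  n_pos <- sum(pr$truth == "patient"); n_neg <- sum(pr$truth == "control")
  expect_equal(rep_$accuracy,
               (rep_$sensitivity * n_pos + rep_$specificity * n_neg) /
                 (n_pos + n_neg))
})

test_that("fold standardization does not leak the held-out subject", {
  # an outlier subject inflates whole-sample scaling; a leaky variant that
  # standardizes once on everyone must disagree somewhere
  set.seed(4)
  n <- 14
  x <- cbind(rnorm(n), rnorm(n))
  x[1, ] <- c(8, -8)
  y <- factor(rep(c("control", "patient"), each = n / 2),
              levels = c("control", "patient"))
  x[y == "patient", 1] <- x[y == "patient", 1] + 1.2
  proper <- loocv_classify(x, y)$predictions$predicted
  xs <- scale(x)
  leaky <- vapply(seq_len(n), function(i) {
    fit <- e1071::svm(xs[-i, , drop = FALSE], y[-i], kernel = "linear",
                      cost = 1, scale = FALSE)
    as.character(predict(fit, xs[i, , drop = FALSE]))
  }, character(1))
  expect_false(identical(proper, leaky))
})

test_that("label permutation separates signal from chance", {
  d <- two_clouds(10, d = 4, seed = 12)
  pt <- permutation_test_classifier(d$x, d$y, n_perm = 200, seed = 3)
  expect_lte(pt$p, 0.05)
  expect_gt(pt$p, 0)
  # determinism given seed
  pt2 <- permutation_test_classifier(d$x, d$y, n_perm = 200, seed = 3)
  expect_identical(pt$p, pt2$p)
  expect_error(permutation_test_classifier(d$x, d$y, n_perm = 0), ">= 1")
})

test_that("labels independent of features score near the majority rate", {
  accs <- vapply(1:6, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(20 * 3), 20, 3)
    y <- factor(rep(c("control", "patient"), each = 10),
                levels = c("control", "patient"))
    loocv_classify(x, y, seed = s)$accuracy
  }, numeric(1))
  expect_lt(mean(accs), 0.72)
  expect_gt(mean(accs), 0.25)
})
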