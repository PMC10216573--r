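#' Two-sided permutation test on a group mean difference
#'
#' Statistic = mean(A) - mean(B).  When the number of distinct label
#' arrangements choose(n, nA) is at most `exhaustive_limit` the null is
#' enumerated exhaustively and p = #\{|perm statistic| >= |observed|\} / #
#' arrangements (the identity arrangement keeps p away from 0); otherwise
#' `n_perm` random label shuffles are drawn and
#' p = (1 + #\{|perm| >= |obs|\}) / (1 + n_perm).  Missing values are
#' dropped before testing.
#'
#' @param valuesA,valuesB numeric vectors (>= 2 non-missing each).
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @param exhaustive_limit enumerate exactly when the arrangement count is
#'   at or below this.
#' @return list of class `nc_permtest`: `statistic`, `p`, `n_perm` (actual
#'   draws or arrangement count), `exhaustive`, `seed`.
#' @export
permutation_mean_diff_test <- function(valuesA, valuesB, n_perm = 5000,
                                       seed = 1, exhaustive_limit = 10000) {
  valuesA <- valuesA[!is.na(valuesA)]
  valuesB <- valuesB[!is.na(valuesB)]
  nA <- length(valuesA); nB <- length(valuesB)
  if (nA < 2 || nB < 2) stop("need at least 2 non-missing values per group")
  pool <- c(valuesA, valuesB)
  obs <- mean(valuesA) - mean(valuesB)
  if (stats::sd(pool) == 0) {
    return(structure(list(statistic = obs, p = 1, n_perm = 0L,
                          exhaustive = TRUE, seed = seed),
                     class = "nc_permtest"))
  }
  n <- nA + nB
  # mean(A) - mean(B) = sum(A) * (1/nA + 1/nB) - sum(pool)/nB, so only the
  # A-subset sum is needed per arrangement
  const <- sum(pool) / nB
  fac <- 1 / nA + 1 / nB
  n_arr <- choose(n, nA)
  if (n_arr <= exhaustive_limit) {
    combs <- utils::combn(n, nA)
    stats_all <- colSums(matrix(pool[combs], nrow = nA)) * fac - const
    p <- sum(abs(stats_all) >= abs(obs) - 1e-12) / n_arr
    return(structure(list(statistic = obs, p = p, n_perm = as.integer(n_arr),
                          exhaustive = TRUE, seed = seed),
                     class = "nc_permtest"))
  }
  set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm[b] <- sum(pool[sample.int(n, nA)]) * fac - const
  }
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  structure(list(statistic = obs, p = p, n_perm = as.integer(n_perm),
                 exhaustive = FALSE, seed = seed),
            class = "nc_permtest")
}

#' Permutation screen of coupling differences between groups
#'
#' Runs [permutation_mean_diff_test()] feature by feature at one coupling
#' scale: per region for `node`, `within` and `between`, per network for
#' `global`.  Features are significant at p < 0.05 uncorrected by default
#' (an opt-in Benjamini-Hochberg adjustment is available).
#'
#' @param profilesA,profilesB lists of [coupling_profile()] objects for the
#'   two groups (A is conventionally the patient group).
#' @param scale one of `"node"`, `"within"`, `"between"`, `"global"`.
#' @param n_perm permutations per feature.
#' @param seed master seed; per-feature seeds derived from it.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with `feature`, `statistic` (mean A - mean B), `p`,
#'   `p_adj`, `significant`.
#' @export
coupling_group_screen <- function(profilesA, profilesB,
                                  scale = c("node", "within", "between", "global"),
                                  n_perm = 5000, seed = 1,
                                  adjust = c("none", "BH"), alpha = 0.05) {
  scale <- match.arg(scale)
  adjust <- match.arg(adjust)
  field <- switch(scale, node = "node", within = "within_network",
                  between = "between_network", global = "global_network")
  matA <- t(vapply(profilesA, `[[`, profilesA[[1]][[field]], field))
  matB <- t(vapply(profilesB, `[[`, profilesB[[1]][[field]], field))
  feats <- colnames(matA)
  res <- lapply(seq_along(feats), function(j) {
    a <- matA[, j][!is.na(matA[, j])]
    b <- matB[, j][!is.na(matB[, j])]
    if (length(a) < 2 || length(b) < 2) {
      # feature undefined for too many subjects: excluded, never imputed
      return(data.frame(feature = feats[j], statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    tst <- permutation_mean_diff_test(a, b, n_perm = n_perm,
                                      seed = derive_seed(seed, j))
    data.frame(feature = feats[j], statistic = tst$statistic, p = tst$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Welch (or pooled) two-sample t from summary statistics
#'
#' Reconstructs the two-sample t test from printed group means, standard
#' deviations and sizes, as needed to check a demographics table.  Welch's
#' unequal-variance form with Satterthwaite degrees of freedom is the
#' default; `var_equal = TRUE` gives the pooled-variance form.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (sds > 0, ns >= 2).
#' @param var_equal use the pooled-variance t.
#' @return list `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 var_equal = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square on a 2x2 table
#'
#' Pearson chi-square without continuity correction, as used for a
#' male/female by group contingency table.
#'
#' @param a,b,c,d cell counts, row-wise: (a, b) group 1, (c, d) group 2.
#' @return list `chi2`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers")
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all row and column marginals must be positive")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
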