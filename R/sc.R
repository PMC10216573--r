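#' Kernel density estimate as a discrete probability mass
#'
#' Gaussian-kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a supplied grid and renormalized to sum to 1, turning the
#' density into the discrete mass vector the Jensen-Shannon computation
#' needs.  All regions of one subject share a grid so their masses are
#' directly comparable.
#'
#' @param values numeric vector (>= 10 finite values).
#' @param grid strictly increasing evaluation grid.
#' @return list of class `nc_pdf`: `grid` and `mass` (sums to 1).
#' @export
estimate_density <- function(values, grid) {
  if (length(values) < 10) stop("need at least 10 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  h <- stats::bw.nrd0(values)
  if (!is.finite(h) || h <= 0) {
    h <- 1e-3 * diff(range(grid))
    message("zero-bandwidth sample; falling back to bandwidth ", signif(h, 3))
  }
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = values, sd = h)),
                 numeric(1))
  total <- sum(dens)
  if (total <= 0) stop("density is zero everywhere on the grid")
  structure(list(grid = grid, mass = dens / total), class = "nc_pdf")
}

#' Jensen-Shannon divergence between two discrete PDFs
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2, logarithms in
#' base 2 (so the result lies in [0, 1]) and the convention 0 * log 0 = 0.
#'
#' @param p,q `nc_pdf` objects on identical grids, or bare mass vectors of
#'   equal length.
#' @return divergence in bits, in [0, 1].
#' @export
js_divergence <- function(p, q) {
  pm <- if (inherits(p, "nc_pdf")) p$mass else p
  qm <- if (inherits(q, "nc_pdf")) q$mass else q
  if (inherits(p, "nc_pdf") && inherits(q, "nc_pdf") &&
      !isTRUE(all.equal(p$grid, q$grid, tolerance = 0))) {
    stop("PDFs are defined on different grids")
  }
  if (length(pm) != length(qm)) stop("mass vectors differ in length")
  m <- (pm + qm) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  d <- (kl(pm) + kl(qm)) / 2
  min(max(d, 0), 1)
}

#' Jensen-Shannon distance-based similarity
#'
#' The Jensen-Shannon *distance* is sqrt(JSD); similarity is 1 minus that
#' distance, so identical distributions score 1 and disjoint ones score 0.
#' `variant = "one_minus_jsd"` uses 1 - JSD instead (both stay in [0, 1]).
#'
#' @inheritParams js_divergence
#' @param variant `"jsd_sqrt"` (default) or `"one_minus_jsd"`.
#' @export
jss_similarity <- function(p, q, variant = c("jsd_sqrt", "one_minus_jsd")) {
  variant <- match.arg(variant)
  d <- js_divergence(p, q)
  if (variant == "jsd_sqrt") 1 - sqrt(d) else 1 - d
}

#' Build a subject's grey-matter structural connectome
#'
#' One shared evaluation grid spans the subject's pooled value range, padded
#' by three pooled-Silverman bandwidths on each side; every region's kernel
#' density is discretized on it and all pairwise Jensen-Shannon similarities
#' are assembled into a symmetric similarity matrix (diagonal stored as 0).
#'
#' @param voxel_samples named list of per-region value vectors, in atlas
#'   order (each >= 10 values).
#' @param atlas the subject's `nc_atlas`.
#' @param grid_size number of grid points.
#' @param variant similarity variant, see [jss_similarity()].
#' @return an SC `nc_connectivity`.
#' @export
build_sc <- function(voxel_samples, atlas, grid_size = 128,
                     variant = c("jsd_sqrt", "one_minus_jsd")) {
  variant <- match.arg(variant)
  R <- nrow(atlas)
  if (length(voxel_samples) != R) stop("one value vector per region required")
  short <- vapply(voxel_samples, length, 0L) < 10
  if (any(short)) {
    stop("fewer than 10 values for region(s): ",
         paste(atlas$region[short], collapse = ", "))
  }
  pooled <- unlist(voxel_samples, use.names = FALSE)
  h0 <- stats::bw.nrd0(pooled)
  if (!is.finite(h0) || h0 <= 0) h0 <- max(1e-6, 1e-3 * max(abs(pooled), 1))
  lo <- min(pooled) - 3 * h0
  hi <- max(pooled) + 3 * h0
  grid <- seq(lo, hi, length.out = grid_size)
  mass <- vapply(voxel_samples, function(v) estimate_density(v, grid)$mass,
                 numeric(grid_size))
  # pairwise JSD in one pass over the mass matrix (columns = regions)
  S <- matrix(0, R, R)
  for (i in seq_len(R - 1)) {
    pi_ <- mass[, i]
    for (j in (i + 1):R) {
      s <- jss_similarity(pi_, mass[, j], variant = variant)
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  connectivity_matrix(S, atlas, kind = "SC")
}
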