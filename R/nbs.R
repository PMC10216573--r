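# stack of connectomes -> n_subjects x n_edges matrix over the unique edges
stack_edges <- function(stack) {
  R <- nrow(stack[[1]])
  idx <- edge_index(R)
  t(vapply(stack, function(m) as.numeric(unclass(m))[idx], numeric(length(idx))))
}

# vectorized pooled-variance two-sample t over edge columns; zero pooled
# variance yields t = 0
edge_t_vec <- function(X, is_a) {
  nA <- sum(is_a); nB <- sum(!is_a)
  mA <- colMeans(X[is_a, , drop = FALSE])
  mB <- colMeans(X[!is_a, , drop = FALSE])
  vA <- (colSums(X[is_a, , drop = FALSE]^2) - nA * mA^2) / (nA - 1)
  vB <- (colSums(X[!is_a, , drop = FALSE]^2) - nB * mB^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tv <- (mA - mB) / se
  tv[!is.finite(tv)] <- 0
  tv
}

#' Edge-wise two-sample t statistics
#'
#' Pooled-variance two-sample t (group A minus group B) at every unique
#' edge, df = nA + nB - 2.  Edges with zero pooled variance get t = 0.
#'
#' @param stackA,stackB lists of conformable connectivity matrices (>= 2
#'   subjects each).
#' @return symmetric R x R matrix of t values with zero diagonal.
#' @export
edge_t_stats <- function(stackA, stackB) {
  if (length(stackA) < 2 || length(stackB) < 2) {
    stop("need at least 2 subjects per group")
  }
  R <- nrow(stackA[[1]])
  X <- rbind(stack_edges(stackA), stack_edges(stackB))
  is_a <- c(rep(TRUE, length(stackA)), rep(FALSE, length(stackB)))
  tv <- edge_t_vec(X, is_a)
  out <- matrix(0, R, R)
  out[edge_index(R)] <- tv
  out + t(out)
}

#' Connected components of the suprathreshold graph
#'
#' Edges with t strictly above `t_crit` form an undirected graph; its
#' connected components are returned with extent = edge count, sorted by
#' extent descending (ties by smallest node index, so the order is
#' deterministic).
#'
#' @param t symmetric R x R statistic matrix.
#' @param t_crit primary threshold; strict inequality.
#' @return list of components, each `list(nodes, edges, extent)` where
#'   `edges` is a 2-column matrix of node indices (row < col).
#' @export
suprathreshold_components <- function(t, t_crit) {
  R <- nrow(t)
  ep <- edge_endpoints(R)
  keep <- t[edge_index(R)] > t_crit
  if (!any(keep)) return(list())
  ed <- ep[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)
  comps <- lapply(seq_len(comp$no), function(k) {
    nodes <- sort(which(comp$membership == k))
    sel <- ed[, 1] %in% nodes
    edges <- ed[sel, , drop = FALSE]
    list(nodes = nodes, edges = edges, extent = nrow(edges))
  })
  # drop igraph's isolated-vertex padding: keep components with >= 1 edge
  comps <- Filter(function(cc) cc$extent > 0, comps)
  ord <- order(-vapply(comps, `[[`, 0L, "extent"),
               vapply(comps, function(cc) min(cc$nodes), 0L))
  comps[ord]
}

# max component extent for a permutation (no component bookkeeping)
max_extent <- function(tv, ep, t_crit) {
  keep <- tv > t_crit
  if (!any(keep)) return(0L)
  ed <- ep[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[ed[, 1]]
  max(tabulate(memb))
}

#' Network-based statistic
#'
#' Localizes group differences to connected subnetworks with family-wise
#' error control: edges are tested with a two-sample t, thresholded at a
#' one-tailed primary p-value, and each observed connected component's
#' extent (edge count) is referred to the permutation null distribution of
#' the maximal component extent obtained by shuffling group labels.
#' Corrected p = (1 + #\{permutation max extent >= observed\}) / (1 + n_perm).
#'
#' @inheritParams edge_t_stats
#' @param primary_p one-tailed primary threshold in (0, 0.5).
#' @param n_perm number of label permutations (a warning below 100).
#' @param direction `"gt"` tests A > B, `"lt"` tests A < B, `"two_sided"`
#'   uses |t| with a two-tailed primary threshold.
#' @param seed RNG seed for the permutations.
#' @return object of class `nc_nbs`: list with `components` (each
#'   `nodes`, `edges`, `extent`, `corrected_p`), `t_crit`, `direction`,
#'   `primary_p`, `n_perm`, `seed`, `null_max_extent`.
#' @export
nbs_test <- function(stackA, stackB, primary_p = 0.001, n_perm = 5000,
                     direction = c("gt", "lt", "two_sided"), seed = 1) {
  direction <- match.arg(direction)
  if (length(stackA) < 2 || length(stackB) < 2) {
    stop("need at least 2 subjects per group")
  }
  if (primary_p <= 0 || primary_p >= 0.5) stop("primary_p must be in (0, 0.5)")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  nA <- length(stackA); nB <- length(stackB)
  df <- nA + nB - 2
  t_crit <- if (direction == "two_sided") stats::qt(1 - primary_p / 2, df)
            else stats::qt(1 - primary_p, df)
  R <- nrow(stackA[[1]])
  ep <- edge_endpoints(R)
  X <- rbind(stack_edges(stackA), stack_edges(stackB))
  is_a <- c(rep(TRUE, nA), rep(FALSE, nB))
  orient <- function(tv) switch(direction, gt = tv, lt = -tv, two_sided = abs(tv))
  t_obs <- orient(edge_t_vec(X, is_a))
  tmat <- matrix(0, R, R)
  tmat[edge_index(R)] <- t_obs
  tmat <- tmat + t(tmat)
  comps <- suprathreshold_components(tmat, t_crit)
  set.seed(seed)
  n <- nA + nB
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm_a <- logical(n)
    perm_a[sample.int(n, nA)] <- TRUE
    null_max[b] <- max_extent(orient(edge_t_vec(X, perm_a)), ep, t_crit)
  }
  for (k in seq_along(comps)) {
    comps[[k]]$corrected_p <-
      (1 + sum(null_max >= comps[[k]]$extent)) / (1 + n_perm)
  }
  structure(list(components = comps, t_crit = t_crit, direction = direction,
                 primary_p = primary_p, n_perm = n_perm, seed = seed,
                 null_max_extent = null_max),
            class = "nc_nbs")
}

#' @export
print.nc_nbs <- function(x, ...) {
  cat("NBS (", x$direction, ", primary p = ", x$primary_p, ", ",
      x$n_perm, " permutations)\n", sep = "")
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (cc in x$components) {
      cat(sprintf("  component: %d nodes, %d edges, corrected p = %.4g\n",
                  length(cc$nodes), cc$extent, cc$corrected_p))
    }
  }
  invisible(x)
}

#' Tally a component's edges by network pair
#'
#' Assigns each edge of an NBS component to the unordered pair of its
#' endpoints' networks and counts edges per pair.
#'
#' @param component one element of an `nc_nbs` `components` list (or any
#'   list with an `edges` index matrix).
#' @param atlas the `nc_atlas` the indices refer to.
#' @return list of class `nc_tally`: `counts` (named vector, names
#'   `"A-B"` with the two networks in alphabetical order), `percent`,
#'   `total`.
#' @export
tally_network_pairs <- function(component, atlas) {
  ed <- component$edges
  if (any(ed < 1 | ed > nrow(atlas))) stop("edge endpoint outside the atlas")
  n1 <- atlas$network[ed[, 1]]
  n2 <- atlas$network[ed[, 2]]
  key <- paste(pmin(n1, n2), pmax(n1, n2), sep = "-")
  counts <- table(key)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- sort(counts, decreasing = TRUE)
  structure(list(counts = counts,
                 percent = 100 * counts / sum(counts),
                 total = sum(counts)),
            class = "nc_tally")
}
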