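#' Rank-based inverse normal transform (Blom scores)
#'
#' Maps values to normal quantiles of their ranks using the Blom offset,
#' qnorm((rank - 0.375) / (n + 0.25)), with average ranks for ties.  The
#' transform is strictly monotone in the input ranks, so any strictly
#' increasing transform of the input yields the identical output.
#'
#' @param values numeric vector, length >= 3.
#' @return numeric vector of Gaussianized scores (all zeros, with a message,
#'   when every value is identical).
#' @export
gaussianize <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (length(unique(values)) == 1) {
    message("all values identical; Gaussianized scores are all zero")
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.375) / (n + 0.25))
}

# internal: Pearson (or Spearman) correlation that returns NA_real_ for
# degenerate inputs instead of warning
safe_cor <- function(x, y, method = "pearson") {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Whole-brain structure-function coupling
#'
#' Selects the strictly positive unique SC edges, Gaussianizes them
#' (rank-based inverse normal transform), and Pearson-correlates the result
#' with the FC values at the same edges (FC edges zeroed by thresholding
#' participate with value 0).
#'
#' @param sc,fc conformable SC and FC matrices (`nc_connectivity` or plain
#'   symmetric matrices).
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return a scalar in [-1, 1].
#' @export
whole_brain_coupling <- function(sc, fc, method = "pearson") {
  idx <- edge_index(nrow(sc))
  scv <- as.numeric(unclass(sc))[idx]
  fcv <- as.numeric(unclass(fc))[idx]
  sel <- scv > 0
  if (sum(sel) < 3) stop("fewer than 3 strictly positive SC edges")
  safe_cor(gaussianize(scv[sel]), fcv[sel], method = method)
}

#' Regional-node coupling
#'
#' Correlation of the R-1 off-diagonal entries of one region's SC row with
#' its FC row (self-connection excluded).
#'
#' @inheritParams whole_brain_coupling
#' @param region region index or label.
#' @param gaussianize_sc Gaussianize the SC side before correlating.
#' @return scalar in [-1, 1], or NA when either row is constant.
#' @export
node_coupling <- function(sc, fc, region, method = "pearson",
                          gaussianize_sc = FALSE) {
  R <- nrow(sc)
  if (R < 4) stop("need at least 4 regions")
  i <- region_pos(sc, region)
  scv <- unclass(sc)[i, -i]
  fcv <- unclass(fc)[i, -i]
  if (gaussianize_sc) scv <- gaussianize(scv)
  safe_cor(scv, fcv, method = method)
}

#' Global-network coupling
#'
#' Correlation over the unique within-network edge set (both endpoints in
#' the network); networks with fewer than 3 regions give NA.
#'
#' @inheritParams node_coupling
#' @param atlas an `nc_atlas`.
#' @param network a network name.
#' @export
global_network_coupling <- function(sc, fc, atlas, network,
                                    method = "pearson",
                                    gaussianize_sc = FALSE) {
  mem <- network_members(atlas, network)
  if (length(mem) < 3) return(NA_real_)
  sub_sc <- unclass(sc)[mem, mem]
  sub_fc <- unclass(fc)[mem, mem]
  idx <- upper.tri(sub_sc)
  scv <- sub_sc[idx]
  fcv <- sub_fc[idx]
  if (gaussianize_sc) scv <- gaussianize(scv)
  safe_cor(scv, fcv, method = method)
}

#' Within- and between-network coupling of one region
#'
#' For a region, the within-network variant correlates its SC and FC values
#' to the other regions of its own network; the between-network variant uses
#' the regions of all other networks.  The two partner sets partition the
#' region's R-1 partners.  Partner sets smaller than 3 give NA.
#'
#' @inheritParams global_network_coupling
#' @param region region index or label.
#' @export
within_network_coupling <- function(sc, fc, atlas, region,
                                    method = "pearson",
                                    gaussianize_sc = FALSE) {
  i <- region_pos(sc, region)
  partners <- setdiff(network_members(atlas, atlas$network[i]), i)
  couple_partners(sc, fc, i, partners, method, gaussianize_sc)
}

#' @rdname within_network_coupling
#' @export
between_network_coupling <- function(sc, fc, atlas, region,
                                     method = "pearson",
                                     gaussianize_sc = FALSE) {
  i <- region_pos(sc, region)
  partners <- which(atlas$network != atlas$network[i])
  couple_partners(sc, fc, i, partners, method, gaussianize_sc)
}

couple_partners <- function(sc, fc, i, partners, method, gaussianize_sc) {
  if (length(partners) < 3) return(NA_real_)
  scv <- unclass(sc)[i, partners]
  fcv <- unclass(fc)[i, partners]
  if (gaussianize_sc) scv <- gaussianize(scv)
  safe_cor(scv, fcv, method = method)
}

region_pos <- function(m, region) {
  if (is.character(region)) {
    i <- match(region, rownames(m))
    if (is.na(i)) stop("unknown region: ", region)
    i
  } else {
    if (region < 1 || region > nrow(m)) stop("region index out of range")
    as.integer(region)
  }
}

#' Full coupling profile of one subject
#'
#' The five coupling scales in one object: the whole-brain scalar, the eight
#' global-network values, and the regional-node, within-network and
#' between-network vectors (one value per region; undefined entries are NA,
#' never silent zeros).
#'
#' @inheritParams global_network_coupling
#' @param id subject identifier carried through to group summaries.
#' @return object of class `nc_coupling`: list with `id`, `whole_brain`,
#'   `global_network` (named over [NETWORKS]), `node`, `within_network`,
#'   `between_network` (named over regions).
#' @export
coupling_profile <- function(sc, fc, atlas, id = NA_character_,
                             method = "pearson", gaussianize_sc = FALSE) {
  R <- nrow(atlas)
  node <- vapply(seq_len(R), function(i)
    node_coupling(sc, fc, i, method, gaussianize_sc), numeric(1))
  within <- vapply(seq_len(R), function(i)
    within_network_coupling(sc, fc, atlas, i, method, gaussianize_sc), numeric(1))
  between <- vapply(seq_len(R), function(i)
    between_network_coupling(sc, fc, atlas, i, method, gaussianize_sc), numeric(1))
  glob <- vapply(NETWORKS, function(nw)
    global_network_coupling(sc, fc, atlas, nw, method, gaussianize_sc), numeric(1))
  names(node) <- names(within) <- names(between) <- atlas$region
  structure(list(id = id,
                 whole_brain = whole_brain_coupling(sc, fc, method),
                 global_network = glob,
                 node = node,
                 within_network = within,
                 between_network = between),
            class = "nc_coupling")
}
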