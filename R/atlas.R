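#' The eight intrinsic brain networks
#'
#' Canonical order of the seven Yeo cortical networks plus the subcortical
#' network used throughout the package: subcortical (SN), limbic (LN),
#' visual (VN), somatomotor (SMN), frontoparietal (FPN), default mode (DMN),
#' dorsal attention (DAN) and salience/ventral attention (SVAN).
#'
#' @export
NETWORKS <- c("SN", "LN", "VN", "SMN", "FPN", "DMN", "DAN", "SVAN")

#' Construct a region-to-network atlas
#'
#' An atlas fixes the region order shared by every matrix in an analysis and
#' assigns each region to one of the eight intrinsic networks.  With
#' `network_sizes = "balanced"` the regions are split as evenly as possible
#' over the eight networks, in the canonical network order; alternatively a
#' named integer vector gives the number of regions per network (e.g. sizes
#' echoing a 246-region whole-brain parcellation).
#'
#' @param n_regions total number of regions; ignored when `network_sizes` is
#'   a named vector (the sizes then define it).
#' @param network_sizes `"balanced"` or a named integer vector over (a subset
#'   of) [NETWORKS].
#' @return an object of class `nc_atlas`: a data.frame with columns `region`
#'   (unique labels, order defines matrix order) and `network`.
#' @examples
#' a <- make_atlas(40)
#' table(a$network)
#' @export
make_atlas <- function(n_regions, network_sizes = "balanced") {
  if (identical(network_sizes, "balanced")) {
    if (n_regions < length(NETWORKS)) {
      stop("balanced atlas needs at least ", length(NETWORKS), " regions")
    }
    base <- n_regions %/% length(NETWORKS)
    extra <- n_regions %% length(NETWORKS)
    sizes <- stats::setNames(
      base + as.integer(seq_along(NETWORKS) <= extra), NETWORKS)
  } else {
    sizes <- network_sizes
    if (is.null(names(sizes)) || !all(names(sizes) %in% NETWORKS)) {
      stop("network_sizes must be named with networks among: ",
           paste(NETWORKS, collapse = ", "))
    }
    if (any(sizes < 1)) stop("every requested network must be nonempty")
    if (!missing(n_regions) && sum(sizes) != n_regions) {
      stop("network_sizes sum (", sum(sizes), ") != n_regions (", n_regions, ")")
    }
  }
  nets <- rep(names(sizes), times = sizes)
  region <- unlist(lapply(names(sizes), function(nw) {
    paste0(nw, "_", seq_len(sizes[[nw]]))
  }), use.names = FALSE)
  atlas <- data.frame(region = region, network = nets,
                      stringsAsFactors = FALSE)
  validate_atlas(atlas)
}

#' @rdname make_atlas
#' @param x a data.frame with `region` and `network` columns.
#' @export
validate_atlas <- function(x) {
  if (!all(c("region", "network") %in% names(x))) {
    stop("atlas needs 'region' and 'network' columns")
  }
  if (anyDuplicated(x$region)) {
    stop("duplicate region label(s): ",
         paste(unique(x$region[duplicated(x$region)]), collapse = ", "))
  }
  bad <- setdiff(unique(x$network), NETWORKS)
  if (length(bad)) stop("unknown network(s): ", paste(bad, collapse = ", "))
  x <- x[, c("region", "network")]
  class(x) <- c("nc_atlas", "data.frame")
  x
}

#' Atlas file I/O
#'
#' Tab-separated with a `region<TAB>network` header; the row order in the
#' file is the canonical matrix order.
#'
#' @param atlas an `nc_atlas`.
#' @param path file path.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_atlas(x)
}

#' Region indices of one network
#' @param atlas an `nc_atlas`.
#' @param network a network name.
#' @return integer vector of row positions in atlas order.
#' @export
network_members <- function(atlas, network) {
  if (!network %in% NETWORKS) stop("unknown network: ", network)
  which(atlas$network == network)
}
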