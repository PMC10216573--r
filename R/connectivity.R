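#' Connectivity matrix container
#'
#' A connectome is an R x R symmetric matrix tied to an atlas.  The diagonal
#' is stored as 0 and excluded from all computations.  Functional (FC)
#' matrices hold signed correlations in [-1, 1]; structural (SC) matrices
#' hold Jensen-Shannon similarities in [0, 1].
#'
#' @param values numeric R x R matrix.
#' @param atlas an `nc_atlas` with R regions.
#' @param kind `"FC"` or `"SC"`.
#' @return an object of class `nc_connectivity` (a matrix with attributes
#'   `atlas` and `kind`, region labels as dimnames).
#' @export
connectivity_matrix <- function(values, atlas, kind = c("FC", "SC")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  R <- nrow(atlas)
  if (!is.numeric(values) || nrow(values) != R || ncol(values) != R) {
    stop("values must be a numeric ", R, " x ", R, " matrix")
  }
  if (any(!is.finite(values))) stop("connectivity values must be finite")
  if (max(abs(values - t(values))) > 1e-12) {
    stop("connectivity matrix is asymmetric beyond 1e-12")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  off <- values[upper.tri(values)]
  if (kind == "FC" && any(off < -1 - 1e-12 | off > 1 + 1e-12)) {
    stop("FC values must lie in [-1, 1]")
  }
  if (kind == "SC" && any(off < -1e-12 | off > 1 + 1e-12)) {
    stop("SC values must lie in [0, 1]")
  }
  dimnames(values) <- list(atlas$region, atlas$region)
  structure(values, atlas = atlas, kind = kind,
            class = c("nc_connectivity", "matrix", "array"))
}

#' @rdname connectivity_matrix
#' @param x an `nc_connectivity`.
#' @export
conn_kind <- function(x) attr(x, "kind")

#' @rdname connectivity_matrix
#' @export
conn_atlas <- function(x) attr(x, "atlas")

#' Matrix file I/O
#'
#' Canonical interchange format: a tab-separated R x R numeric grid with the
#' region labels as header row and first column.  Reading as a connectome
#' validates symmetry, finiteness and (when an atlas is supplied) the region
#' order.
#'
#' @param m matrix (plain or `nc_connectivity`).
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  vals <- unclass(m)
  # %.17g guarantees a bitwise round-trip through the text format
  chr <- matrix(sprintf("%.17g", vals), nrow(vals), ncol(vals))
  df <- as.data.frame(chr, stringsAsFactors = FALSE)
  names(df) <- colnames(m)
  utils::write.table(cbind(region = rownames(m), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param atlas optional `nc_atlas`; if given, labels and order must match
#'   and the result is validated as a connectome of `kind`.
#' @param kind connectome kind used when `atlas` is supplied.
#' @export
read_matrix <- function(path, atlas = NULL, kind = c("FC", "SC")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  if (!identical(colnames(m), labels)) {
    stop("matrix row and column labels disagree")
  }
  if (is.null(atlas)) return(m)
  if (!identical(labels, atlas$region)) {
    stop("matrix region labels/order do not match the atlas")
  }
  connectivity_matrix(m, atlas, kind = match.arg(kind))
}

# indices of the R(R-1)/2 unique off-diagonal edges, in column-major
# upper-triangle order; shared by every module so edge vectors line up
edge_index <- function(R) which(upper.tri(matrix(0, R, R)))

# n_edges x 2 matrix of (row, col) endpoints for edge_index(R)
edge_endpoints <- function(R) {
  idx <- edge_index(R)
  cbind(row = ((idx - 1L) %% R) + 1L, col = ((idx - 1L) %/% R) + 1L)
}
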