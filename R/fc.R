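#' Pearson functional connectivity with exact p-values
#'
#' Correlates every pair of regional time series and converts each
#' correlation to a two-sided p-value through the exact t transform
#' t = r * sqrt((T - 2) / (1 - r^2)) with T - 2 degrees of freedom.
#'
#' @param timeseries T x R numeric matrix (T >= 4), columns = regions.
#' @return list with `r` and `p`, both R x R symmetric with zero diagonal
#'   (`p` diagonal also 0 by the stored-as-zero convention).
#' @export
pearson_fc <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  T_len <- nrow(timeseries)
  if (T_len < 4) stop("need at least 4 timepoints")
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(timeseries)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance time series for region(s): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(timeseries)
  rc <- pmin(pmax(r, -1), 1)
  tt <- rc * sqrt((T_len - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = T_len - 2)
  diag(r) <- 0
  diag(p) <- 0
  list(r = r, p = p)
}

#' FDR-based edge retention
#'
#' Applies Benjamini-Hochberg over the R(R-1)/2 unique off-diagonal
#' p-values; edges surviving at level `q` keep their signed correlation,
#' all others are set to 0.
#'
#' @param r,p conformable symmetric matrices from [pearson_fc()].
#' @param atlas the `nc_atlas` the matrix is tied to.
#' @param q FDR level in (0, 1).
#' @return an FC `nc_connectivity`.
#' @export
fdr_threshold <- function(r, p, atlas, q = 0.05) {
  if (!all(dim(r) == dim(p))) stop("r and p must be conformable")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  R <- nrow(r)
  idx <- edge_index(R)
  padj <- stats::p.adjust(p[idx], method = "BH")
  keep <- padj <= q
  out <- matrix(0, R, R)
  out[idx[keep]] <- r[idx[keep]]
  out <- out + t(out)
  connectivity_matrix(out, atlas, kind = "FC")
}

#' Build a subject's functional connectome
#'
#' Convenience wrapper: [pearson_fc()] followed by [fdr_threshold()].
#'
#' @inheritParams pearson_fc
#' @inheritParams fdr_threshold
#' @export
build_fc <- function(timeseries, atlas, q = 0.05) {
  rp <- pearson_fc(timeseries)
  fdr_threshold(rp$r, rp$p, atlas, q = q)
}
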