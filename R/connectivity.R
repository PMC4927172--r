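# Scale-wise association matrices between regions: wavelet correlation
# (Pearson correlation of same-scale wavelet coefficients) and an
# inverse-covariance partial correlation variant. Both operate on a
# multi-series decomposition (columns = regions).

.coef_at_scale <- function(decomp, scale, use = c("coefficients", "details")) {
  use <- match.arg(use)
  stopifnot(inherits(decomp, "wavelet_decomp"))
  if (scale < 1 || scale > decomp$n.levels) {
    stop("scale must be between 1 and the decomposition depth", call. = FALSE)
  }
  if (use == "details") {
    if (!inherits(decomp, "modwt")) {
      stop("detail-based connectivity requires a MODWT decomposition", call. = FALSE)
    }
    w <- mra(decomp)$D[[scale]]
  } else {
    w <- decomp$W[[scale]]
  }
  .as_coef_matrix(w)
}

#' Wavelet correlation matrix
#'
#' Builds the region-by-region functional connectivity matrix at one wavelet
#' scale: entry (i, j) is the Pearson correlation between the scale-`scale`
#' wavelet coefficient sequences of regions i and j. Boundary-influenced
#' coefficients are included by default; set `exclude_boundary = TRUE` to
#' drop them (MODWT only).
#'
#' A region whose coefficient sequence has zero variance cannot be
#' correlated; its entries are set to `NA` and the region indices are
#' reported in the `"degenerate_regions"` attribute with a warning (never
#' silently zeroed).
#'
#' @param decomp A [modwt()] or [dwt()] decomposition of a time-by-regions
#'   matrix.
#' @param scale Wavelet scale (1 .. depth).
#' @param use Correlate raw per-scale coefficients (default) or MRA details.
#' @param exclude_boundary Drop circularly-influenced coefficients before
#'   correlating (MODWT only).
#' @return A symmetric correlation matrix with unit diagonal and attributes
#'   `scale`, `method`, `filter`.
#' @export
wavelet_cor <- function(decomp, scale, use = c("coefficients", "details"),
                        exclude_boundary = FALSE) {
  w <- .coef_at_scale(decomp, scale, use)
  if (exclude_boundary) {
    if (!inherits(decomp, "modwt")) {
      stop("boundary exclusion is supported for MODWT decompositions", call. = FALSE)
    }
    keep <- !decomp$boundary[[scale]]
    if (sum(keep) < 3) stop("fewer than 3 interior coefficients at this scale", call. = FALSE)
    w <- w[keep, , drop = FALSE]
  }
  sds <- apply(w, 2, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  m <- suppressWarnings(stats::cor(w))
  if (length(degenerate)) {
    warning("zero-variance coefficient sequence in region(s): ",
            paste(degenerate, collapse = ", "), "; entries set to NA")
    m[degenerate, ] <- NA_real_
    m[, degenerate] <- NA_real_
  }
  diag(m) <- 1
  m <- (m + t(m)) / 2
  attr(m, "scale") <- as.integer(scale)
  attr(m, "method") <- decomp$method
  attr(m, "filter") <- decomp$filter$name
  attr(m, "degenerate_regions") <- degenerate
  m
}

#' Wavelet partial correlation matrix
#'
#' Partial correlations between regions at one wavelet scale, computed from
#' the standardized negative inverse of the coefficient covariance matrix.
#' When the number of coefficients does not exceed the number of regions the
#' covariance is singular; supply a positive `ridge` to regularize
#' (`cov + ridge * mean(diag(cov)) * I`).
#'
#' @inheritParams wavelet_cor
#' @param ridge Nonnegative ridge fraction added to the covariance diagonal.
#' @return Symmetric partial-correlation matrix with unit diagonal.
#' @export
wavelet_pcor <- function(decomp, scale, use = c("coefficients", "details"),
                         ridge = 0) {
  w <- .coef_at_scale(decomp, scale, use)
  S <- stats::cov(w)
  if (ridge > 0) S <- S + ridge * mean(diag(S)) * diag(ncol(S))
  P <- tryCatch(solve(S), error = function(e) {
    stop("coefficient covariance is singular (", conditionMessage(e),
         "); supply a ridge parameter, e.g. ridge = 0.1", call. = FALSE)
  })
  d <- sqrt(diag(P))
  m <- -P / tcrossprod(d)
  diag(m) <- 1
  m <- (m + t(m)) / 2
  attr(m, "scale") <- as.integer(scale)
  attr(m, "method") <- decomp$method
  attr(m, "filter") <- decomp$filter$name
  m
}

#' Mean and variance of the upper-triangular correlations
#'
#' The two weighted "graph metrics" of a connectivity matrix: the mean and
#' the variance of its strictly upper-triangular entries.
#'
#' @param m Symmetric connectivity matrix.
#' @return Named numeric vector `c(mean_corr, var_corr)`.
#' @export
upper_tri_stats <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  v <- m[upper.tri(m)]
  c(mean_corr = mean(v), var_corr = stats::var(v))
}
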