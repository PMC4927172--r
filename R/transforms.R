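# DWT and MODWT pyramid algorithms with periodic (circular) boundary
# handling, their inverses, additive multiresolution details, and the
# dyadic scale -> frequency-band mapping.
#
# All transforms accept either a single series (numeric vector) or a
# time-by-series matrix; internally everything is a matrix so that a whole
# subject (rows = timepoints, columns = regions) is decomposed in one pass.

.as_ts_matrix <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("input must be a numeric vector or matrix (rows = timepoints)", call. = FALSE)
  }
  if (nrow(x) < 2) stop("need at least 2 timepoints", call. = FALSE)
  if (!all(is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# width of the level-j equivalent filter
.equiv_width <- function(L, j) (2^j - 1) * (L - 1) + 1

#' Maximal overlap discrete wavelet transform (MODWT)
#'
#' Decomposes one or more time series into `n.levels` non-downsampled
#' wavelet-coefficient sequences plus a smooth, using the pyramid algorithm
#' with rescaled filters (`g/sqrt(2)`, `h/sqrt(2)`) and circular filtering.
#' Every per-scale coefficient sequence has the same length as the input,
#' the transform is invariant under circular shifts of the input, and the
#' coefficient energies sum exactly to the input energy.
#'
#' @param x Numeric vector, or matrix with rows = timepoints and columns =
#'   series (e.g. brain regions).
#' @param filter A [wavelet_filter()], or a name such as `"LA8"`.
#' @param n.levels Decomposition depth J (default 4, covering the four
#'   standard resting-state fMRI frequency bands at TR = 2 s).
#' @return An object of class `c("modwt", "wavelet_decomp")`: list with
#'   `W` (list of J coefficient matrices, each N x R), `V` (smooth, N x R),
#'   `boundary` (list of logical vectors flagging circularly-influenced
#'   coefficients per scale), `filter`, `n.levels`, `n`, `method`.
#' @seealso [imodwt()], [mra()], [dwt()]
#' @export
#' @examples
#' x <- rnorm(128)
#' d <- modwt(x, "D4", n.levels = 4)
#' sum(sapply(d$W, function(w) sum(w^2))) + sum(d$V^2) - sum(x^2)  # ~0
modwt <- function(x, filter, n.levels = 4) {
  if (is.character(filter)) filter <- wavelet_filter(filter)
  stopifnot(inherits(filter, "wavelet_filter"), n.levels >= 1)
  X <- .as_ts_matrix(x)
  N <- nrow(X); L <- filter$length
  if (.equiv_width(L, n.levels) > N) {
    warning(sprintf(
      "equivalent filter width %d at level %d exceeds series length %d; deep scales are dominated by boundary effects",
      .equiv_width(L, n.levels), n.levels, N))
  }
  gt <- filter$g / sqrt(2)
  ht <- filter$h / sqrt(2)
  W <- vector("list", n.levels)
  boundary <- vector("list", n.levels)
  V <- X
  t0 <- seq_len(N) - 1L
  for (j in seq_len(n.levels)) {
    step <- 2^(j - 1)
    Wj <- matrix(0, N, ncol(X))
    Vj <- matrix(0, N, ncol(X))
    for (l in 0:(L - 1)) {
      idx <- ((t0 - step * l) %% N) + 1L
      Wj <- Wj + ht[l + 1] * V[idx, , drop = FALSE]
      Vj <- Vj + gt[l + 1] * V[idx, , drop = FALSE]
    }
    W[[j]] <- Wj
    boundary[[j]] <- t0 < min(.equiv_width(L, j) - 1, N)
    V <- Vj
  }
  drop_vec <- is.null(dim(x))
  if (drop_vec) {
    W <- lapply(W, drop)
    V <- drop(V)
  }
  structure(list(W = W, V = V, boundary = boundary, filter = filter,
                 n.levels = n.levels, n = N, method = "modwt",
                 series = if (drop_vec) 1L else ncol(X)),
            class = c("modwt", "wavelet_decomp"))
}

#' Inverse MODWT
#'
#' Reconstructs the original series from a [modwt()] decomposition by the
#' inverse pyramid (the adjoint of the forward circular filtering).
#'
#' @param d A `"modwt"` object.
#' @return Numeric vector or matrix matching the original input shape.
#' @export
imodwt <- function(d) {
  if (!inherits(d, "modwt")) stop("imodwt() requires a MODWT decomposition", call. = FALSE)
  .modwt_inverse(lapply(d$W, .as_coef_matrix), .as_coef_matrix(d$V), d$filter,
                 d$n, drop_vec = d$series == 1L && is.null(dim(d$V)))
}

.as_coef_matrix <- function(w) if (is.matrix(w)) w else matrix(w, ncol = 1)

.modwt_inverse <- function(Wlist, V, filter, N, drop_vec = FALSE) {
  gt <- filter$g / sqrt(2)
  ht <- filter$h / sqrt(2)
  L <- filter$length
  J <- length(Wlist)
  t0 <- seq_len(N) - 1L
  for (j in rev(seq_len(J))) {
    step <- 2^(j - 1)
    Vprev <- matrix(0, N, ncol(V))
    for (l in 0:(L - 1)) {
      idx <- ((t0 + step * l) %% N) + 1L
      Vprev <- Vprev + ht[l + 1] * Wlist[[j]][idx, , drop = FALSE] +
        gt[l + 1] * V[idx, , drop = FALSE]
    }
    V <- Vprev
  }
  if (drop_vec) drop(V) else V
}

#' Multiresolution analysis details from a MODWT
#'
#' Produces the additive decomposition `x = D_1 + ... + D_J + S_J`, where
#' detail `D_j` is the inverse MODWT of the level-j coefficients alone and
#' the smooth `S_J` is the inverse of the final scaling coefficients alone.
#' Each component has the length of the input.
#'
#' @param d A `"modwt"` object.
#' @return List with elements `D` (list of J details) and `S` (smooth).
#' @export
mra <- function(d) {
  if (!inherits(d, "modwt")) {
    stop("multiresolution details are defined here for MODWT decompositions only", call. = FALSE)
  }
  J <- d$n.levels
  Wm <- lapply(d$W, .as_coef_matrix)
  Vm <- .as_coef_matrix(d$V)
  zeroW <- lapply(Wm, function(w) w * 0)
  drop_vec <- is.null(dim(d$V))
  D <- vector("list", J)
  for (j in seq_len(J)) {
    Wj <- zeroW
    Wj[[j]] <- Wm[[j]]
    D[[j]] <- .modwt_inverse(Wj, Vm * 0, d$filter, d$n, drop_vec)
  }
  S <- .modwt_inverse(zeroW, Vm, d$filter, d$n, drop_vec)
  list(D = D, S = S)
}

#' Discrete wavelet transform (DWT)
#'
#' Orthogonal, downsampled dyadic decomposition with periodic boundary
#' handling. Arbitrary lengths are supported by the odd-length carry rule:
#' when an intermediate scaling series has odd length, its last value is
#' set aside and carried (unchanged) as one extra scaling coefficient at
#' that level, so the total coefficient count always equals the input
#' length. When the input length is a multiple of `2^J` the transform is
#' orthonormal and exactly energy-preserving.
#'
#' @inheritParams modwt
#' @return An object of class `c("dwt", "wavelet_decomp")` with `W` (list
#'   of J coefficient matrices of halving length), `V` (final scaling
#'   coefficients, including any carried extras), `carry` (logical per
#'   level: was an extra coefficient carried), plus provenance fields as
#'   for [modwt()].
#' @export
dwt <- function(x, filter, n.levels = 4) {
  if (is.character(filter)) filter <- wavelet_filter(filter)
  stopifnot(inherits(filter, "wavelet_filter"), n.levels >= 1)
  X <- .as_ts_matrix(x)
  L <- filter$length
  g <- filter$g; h <- filter$h
  if (.equiv_width(L, n.levels) > nrow(X)) {
    warning(sprintf(
      "equivalent filter width %d at level %d exceeds series length %d; deep scales are dominated by boundary effects",
      .equiv_width(L, n.levels), n.levels, nrow(X)))
  }
  W <- vector("list", n.levels)
  carry <- logical(n.levels)
  extras <- vector("list", n.levels)  # carried scaling rows, re-attached at the end
  V <- X
  for (j in seq_len(n.levels)) {
    M <- nrow(V)
    if (M %% 2 == 1) {
      carry[j] <- TRUE
      extras[[j]] <- V[M, , drop = FALSE]
      V <- V[-M, , drop = FALSE]
      M <- M - 1L
    }
    if (M < 2) stop(sprintf("series too short to decompose to level %d", n.levels), call. = FALSE)
    M2 <- M %/% 2L
    Wj <- matrix(0, M2, ncol(V))
    Vj <- matrix(0, M2, ncol(V))
    for (l in 0:(L - 1)) {
      idx <- ((2 * (seq_len(M2) - 1L) + 1L - l) %% M) + 1L
      Wj <- Wj + h[l + 1] * V[idx, , drop = FALSE]
      Vj <- Vj + g[l + 1] * V[idx, , drop = FALSE]
    }
    W[[j]] <- Wj
    V <- Vj
  }
  # append carried coefficients (deepest-level first) after the final smooth
  for (j in rev(seq_len(n.levels))) {
    if (carry[j]) V <- rbind(V, extras[[j]])
  }
  drop_vec <- is.null(dim(x))
  if (drop_vec) {
    W <- lapply(W, drop)
    V <- drop(V)
  }
  structure(list(W = W, V = V, carry = carry, filter = filter,
                 n.levels = n.levels, n = nrow(X), method = "dwt",
                 series = if (drop_vec) 1L else ncol(X)),
            class = c("dwt", "wavelet_decomp"))
}

#' Inverse DWT
#'
#' Reconstructs the original series from a [dwt()] decomposition, undoing
#' the odd-length carry rule so the round trip is exact for any length.
#'
#' @param d A `"dwt"` object.
#' @return Numeric vector or matrix matching the original input shape.
#' @export
idwt <- function(d) {
  if (!inherits(d, "dwt")) stop("idwt() requires a DWT decomposition", call. = FALSE)
  g <- d$filter$g; h <- d$filter$h; L <- d$filter$length
  J <- d$n.levels
  W <- lapply(d$W, .as_coef_matrix)
  V <- .as_coef_matrix(d$V)
  # peel carried rows off the end of V (stored deepest-level first)
  extras <- vector("list", J)
  for (j in seq_len(J)) {
    if (d$carry[j]) {
      extras[[j]] <- V[nrow(V), , drop = FALSE]
      V <- V[-nrow(V), , drop = FALSE]
    }
  }
  for (j in rev(seq_len(J))) {
    M2 <- nrow(W[[j]])
    M <- 2L * M2
    Vprev <- matrix(0, M, ncol(V))
    for (l in 0:(L - 1)) {
      idx <- ((2 * (seq_len(M2) - 1L) + 1L - l) %% M) + 1L
      Vprev[idx, ] <- Vprev[idx, ] + h[l + 1] * W[[j]] + g[l + 1] * V
    }
    if (d$carry[j]) Vprev <- rbind(Vprev, extras[[j]])
    V <- Vprev
  }
  if (d$series == 1L && is.null(dim(d$W[[1]]))) drop(V) else V
}

#' @export
print.wavelet_decomp <- function(x, ...) {
  cat(sprintf("%s decomposition: %d series of length %d, %d levels, filter %s\n",
              toupper(x$method), x$series, x$n, x$n.levels, x$filter$name))
  lens <- vapply(x$W, function(w) if (is.matrix(w)) nrow(w) else length(w), 0L)
  cat("coefficients per scale:", paste(lens, collapse = ", "), "\n")
  invisible(x)
}

#' Frequency band of a wavelet scale
#'
#' Maps a dyadic wavelet scale to its nominal frequency band given the
#' sampling interval. With sampling rate `fs = 1/tr_seconds` (Nyquist
#' `fs/2`), scale `j` covers `(fs/2^(j+1), fs/2^j]`. At TR = 2 s the first
#' four scales are 0.125-0.25, 0.0625-0.125, 0.03125-0.0625 and
#' 0.015625-0.03125 Hz.
#'
#' @param tr_seconds Sampling interval (fMRI repetition time) in seconds.
#' @param scale Wavelet scale j >= 1.
#' @return A list with `scale`, `low_hz`, `high_hz`.
#' @export
#' @examples
#' scale_to_band(2, 1)  # 0.125 - 0.25 Hz
scale_to_band <- function(tr_seconds, scale) {
  stopifnot(tr_seconds > 0, scale >= 1)
  fs <- 1 / tr_seconds
  list(scale = as.integer(scale), low_hz = fs / 2^(scale + 1), high_hz = fs / 2^scale)
}
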