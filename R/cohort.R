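# Synthetic two-group cohorts of long-memory, community-structured regional
# time series: the testbed standing in for resting-state fMRI data (29 + 29
# subjects, 90 regions, 177 timepoints at TR = 2 s by default).
#
# Regional signals are correlated mixtures of fractional Gaussian noise
# (fGn) processes: a global factor, one factor per module, and idiosyncratic
# noise, mixed so the implied region-by-region correlation matrix has a
# prescribed within-module / between-module block structure. Group 2
# receives an additive perturbation of the within-module correlation
# (broadband), or a band-limited within-module component when the effect is
# restricted to one wavelet scale.

#' Simulate fractional Gaussian noise
#'
#' Exact simulation by circulant embedding (Davies-Harte) of the fGn
#' autocovariance `gamma(k) = 0.5 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})`.
#' For `H = 0.5` this degenerates to white noise; `H > 0.5` gives slowly
#' decaying positive autocorrelations (long memory). If the circulant
#' eigenvalues are not all nonnegative (which does not occur for
#' `H` in (0, 1) at these lengths) the embedding is padded until they are.
#'
#' @param n Series length.
#' @param hurst Hurst exponent in (0, 1).
#' @param n_series Number of independent series (columns).
#' @return `n` x `n_series` matrix of unit-variance fGn.
#' @export
simulate_fgn <- function(n, hurst, n_series = 1) {
  stopifnot(n >= 2, hurst > 0, hurst < 1, n_series >= 1)
  H2 <- 2 * hurst
  m <- 2 * n
  repeat {
    k <- 0:(m / 2)
    gam <- 0.5 * (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2)
    row <- c(gam, rev(gam[2:(m / 2)]))
    lam <- Re(stats::fft(row))
    if (min(lam) > -1e-10) break
    m <- 2 * m                      # pad and retry (defensive; not hit for H in (0,1))
  }
  lam <- pmax(lam, 0)
  half <- m / 2
  W <- matrix(0i, m, n_series)
  W[1, ] <- sqrt(lam[1]) * stats::rnorm(n_series)
  W[half + 1, ] <- sqrt(lam[half + 1]) * stats::rnorm(n_series)
  jj <- 2:half
  Zr <- matrix(stats::rnorm(length(jj) * n_series), length(jj), n_series)
  Zi <- matrix(stats::rnorm(length(jj) * n_series), length(jj), n_series)
  W[jj, ] <- sqrt(lam[jj] / 2) * (Zr + 1i * Zi)
  W[m + 2 - jj, ] <- Conj(W[jj, ])
  x <- Re(stats::mvfft(W)) / sqrt(m)
  x[seq_len(n), , drop = FALSE]
}

#' Specify a synthetic two-group cohort
#'
#' Collects and validates the parameters of the cohort generator. The
#' defaults reproduce the reference study's dimensions: 29 subjects per
#' group, 90 regions, 177 timepoints (180 volumes minus the first 3) at
#' TR = 2 s, with long-memory signals (H = 0.8), 6 modules of 15 regions,
#' within-module correlation 0.4 and between-module correlation 0.1, and a
#' -0.15 additive change in within-module correlation for group 2
#' (patient hypoconnectivity).
#'
#' @param n_per_group Subjects per group.
#' @param n_regions Number of regions.
#' @param n_timepoints Timepoints per series.
#' @param tr_seconds Sampling interval in seconds.
#' @param hurst Hurst exponent of all signal components, in (0.5, 1) for
#'   long memory (0.5 gives white noise).
#' @param n_modules Number of equal-size communities (must divide
#'   `n_regions`).
#' @param within_corr,between_corr Target within- and between-module
#'   correlations; the implied block matrix must be positive semi-definite,
#'   which requires `0 <= between_corr <= within_corr <= 1`.
#' @param group_effect Additive change to `within_corr` in group 2
#'   (broadband case) or the weight of the band-limited within-module
#'   component (band-restricted case).
#' @param effect_scale `NULL` for a broadband effect, or a wavelet scale
#'   (1..4) to which the group difference is confined.
#' @param seed Integer seed making the cohort reproducible.
#' @return Validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 29, n_regions = 90, n_timepoints = 177,
                        tr_seconds = 2, hurst = 0.8, n_modules = 6,
                        within_corr = 0.4, between_corr = 0.1,
                        group_effect = -0.15, effect_scale = NULL, seed = 1) {
  stopifnot(n_per_group >= 2, n_regions >= 2, n_timepoints >= 8,
            tr_seconds > 0, hurst > 0, hurst < 1, n_modules >= 1,
            n_regions %% n_modules == 0)
  w2 <- within_corr + if (is.null(effect_scale)) group_effect else 0
  for (wc in c(within_corr, w2)) {
    if (!(between_corr >= 0 && between_corr <= wc && wc <= 1)) {
      stop("implied correlation matrix is not positive semi-definite: ",
           "need 0 <= between_corr <= within_corr (after group effect) <= 1; got ",
           sprintf("between = %g, within = %g", between_corr, wc), call. = FALSE)
    }
  }
  structure(list(n_per_group = n_per_group, n_regions = n_regions,
                 n_timepoints = n_timepoints, tr_seconds = tr_seconds,
                 hurst = hurst, n_modules = n_modules,
                 within_corr = within_corr, between_corr = between_corr,
                 group_effect = group_effect, effect_scale = effect_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.block_cor_matrix <- function(n_regions, modules, within, between) {
  m <- outer(modules, modules, "==") * (within - between) + between
  diag(m) <- 1
  m
}

.simulate_subject <- function(spec, within, modules) {
  # mixture weights from the block-correlation targets
  a_glob <- sqrt(spec$between_corr)
  a_mod <- sqrt(within - spec$between_corr)
  a_idio <- sqrt(1 - within)
  n <- spec$n_timepoints
  glob <- simulate_fgn(n, spec$hurst, 1)
  mod <- simulate_fgn(n, spec$hurst, spec$n_modules)
  idio <- simulate_fgn(n, spec$hurst, spec$n_regions)
  sweep(idio, 2, rep(a_idio, spec$n_regions), "*") +
    a_mod * mod[, modules, drop = FALSE] +
    a_glob * glob[, rep(1, spec$n_regions), drop = FALSE]
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject region-by-time signal matrices according to a
#' [cohort_spec()]. Group 1 ("control") follows the baseline block
#' correlation structure; group 2 ("patient") receives the connectivity
#' perturbation. With `effect_scale = NULL` the perturbation is an exact
#' additive change of the within-module target correlation at all
#' frequencies. With `effect_scale = j`, group-2 regions additionally share
#' a within-module component band-limited to wavelet scale j (the scale-j
#' MRA detail of an extra module factor, weighted by
#' `sqrt(|group_effect|)` and signed by `group_effect`), so the group
#' difference in wavelet correlation is concentrated in that band; this
#' construction is approximate in adjacent bands due to filter leakage.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `"wbnet_cohort"`: `data` (list of timepoints x
#'   regions matrices), `manifest` (data frame with `subject`, `group`,
#'   `tr_seconds`), and `truth` (ground-truth record: target correlation
#'   matrices per group, module assignment, effect description, and the
#'   spec itself).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  modules <- rep(seq_len(spec$n_modules), each = spec$n_regions / spec$n_modules)
  broadband <- is.null(spec$effect_scale)
  within2 <- spec$within_corr + if (broadband) spec$group_effect else 0
  n_total <- 2 * spec$n_per_group
  groups <- rep(c("control", "patient"), each = spec$n_per_group)
  data <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    w <- if (groups[s] == "patient") within2 else spec$within_corr
    x <- .simulate_subject(spec, w, modules)
    if (!broadband && groups[s] == "patient") {
      extra <- simulate_fgn(spec$n_timepoints, spec$hurst, spec$n_modules)
      det <- mra(modwt(extra, wavelet_filter("LA", 8),
                       n.levels = spec$effect_scale))$D[[spec$effect_scale]]
      det <- .as_coef_matrix(det)
      x <- x + sign(spec$group_effect) * sqrt(abs(spec$group_effect)) *
        det[, modules, drop = FALSE]
    }
    colnames(x) <- sprintf("R%02d", seq_len(spec$n_regions))
    data[[s]] <- x
  }
  ids <- sprintf("S%03d", seq_len(n_total))
  names(data) <- ids
  truth <- list(
    modules = modules,
    target_cor_control = .block_cor_matrix(spec$n_regions, modules,
                                           spec$within_corr, spec$between_corr),
    target_cor_patient = if (broadband) {
      .block_cor_matrix(spec$n_regions, modules, within2, spec$between_corr)
    } else NULL,
    effect = list(type = if (broadband) "broadband" else "band-limited",
                  scale = spec$effect_scale, size = spec$group_effect,
                  direction = sign(spec$group_effect)),
    spec = spec
  )
  structure(list(data = data,
                 manifest = data.frame(subject = ids, group = groups,
                                       tr_seconds = spec$tr_seconds,
                                       stringsAsFactors = FALSE),
                 truth = truth),
            class = "wbnet_cohort")
}

#' @export
print.wbnet_cohort <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf("synthetic cohort: %d + %d subjects, %d regions x %d timepoints (TR = %gs)\n",
              s$n_per_group, s$n_per_group, s$n_regions, s$n_timepoints, s$tr_seconds))
  cat(sprintf("H = %g, %d modules, within/between corr %g/%g, %s group effect %g\n",
              s$hurst, s$n_modules, s$within_corr, s$between_corr,
              x$truth$effect$type, s$group_effect))
  invisible(x)
}

#' Wavelet-variance Hurst exponent estimator
#'
#' Estimates the Hurst exponent of a long-memory series by regressing the
#' log2 wavelet variance on scale: for fGn the per-scale (MODWT) wavelet
#' variance behaves as `2^{j (2H - 2)}` (for white noise, H = 0.5, the
#' coefficient energy halves at each level), so the regression slope `b`
#' gives `H = b/2 + 1`.
#'
#' The unbiased wavelet variance is used by default: circularly-influenced
#' (boundary) coefficients are excluded, which also makes the estimator
#' exactly immune to polynomial trends up to the filter's vanishing moments.
#'
#' @param x Numeric series, or an existing [modwt()] decomposition of one
#'   series.
#' @param filter Filter used when `x` is a series (default `"LA8"`).
#' @param n.levels Number of scales (default the deepest level whose
#'   equivalent filter fits in the series, capped at 8; at least 3).
#' @param exclude_boundary Use only interior coefficients in the per-scale
#'   variance (default `TRUE`).
#' @return Estimated Hurst exponent (scalar).
#' @export
estimate_hurst <- function(x, filter = "LA8", n.levels = NULL,
                           exclude_boundary = TRUE) {
  if (!inherits(x, "wavelet_decomp")) {
    if (is.character(filter)) filter <- wavelet_filter(filter)
    if (is.null(n.levels)) {
      n <- length(x)
      n.levels <- max(3, min(8, floor(log2(n / (filter$length - 1)))))
    }
    x <- modwt(x, filter, n.levels = n.levels)
  }
  if (!inherits(x, "modwt")) stop("Hurst estimation requires a MODWT decomposition", call. = FALSE)
  J <- x$n.levels
  nu2 <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    w <- .as_coef_matrix(x$W[[j]])[, 1]
    if (exclude_boundary) w <- w[!x$boundary[[j]]]
    if (length(w) >= 4) nu2[j] <- mean(w^2)
  }
  use <- which(is.finite(nu2))
  if (length(use) < 3) stop("need at least 3 scales to estimate the Hurst exponent", call. = FALSE)
  fit <- stats::lm(log2(nu2[use]) ~ use)
  unname(stats::coef(fit)[2]) / 2 + 1
}
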