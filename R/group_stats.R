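# The method-comparison statistics battery: the length-variation statistic,
# paired and pooled two-sample t tests, the exact sign test, Bonferroni
# family-wise correction, one-way repeated-measures ANOVA with wavelet
# length as the within-subject factor, and the -log10 p sensitivity surface.
#
# t tests and the sign test are thin wrappers over stats::t.test /
# stats::binom.test that return a uniform record and flag degenerate
# (zero-variance) inputs instead of erroring.

.test_result <- function(statistic, df, p_value, test, degenerate = FALSE) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test = test,
                 degenerate = degenerate),
            class = "wbnet_test")
}

#' @export
print.wbnet_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %s%s\n", x$test,
              format(x$statistic, digits = 4),
              paste(x$df, collapse = ","),
              format(x$p_value, digits = 4),
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Variation of a metric over consecutive filter lengths
#'
#' Total variation of a graph-metric profile across an ordered sweep of
#' wavelet filter lengths: `sum_k |v[k+1] - v[k]|`. Smaller values indicate
#' that the metric changes smoothly as the filter length grows; the
#' statistic is the basis of the DWT-vs-MODWT stability comparison.
#'
#' @param values Numeric vector of metric values ordered by ascending filter
#'   length (at least 2).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' variation_over_lengths(c(1, 3, 2))  # 3
variation_over_lengths <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need metric values at >= 2 filter lengths", call. = FALSE)
  if (any(is.na(values))) stop("metric values contain NA", call. = FALSE)
  sum(abs(diff(values)))
}

#' Paired t test
#'
#' Classical paired t test (df = n - 1, two-sided). If the differences have
#' zero variance the result is flagged degenerate with `NA` statistic
#' rather than raising an error.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @return A `"wbnet_test"` record with `statistic`, `df`, `p_value`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(.test_result(NA_real_, length(a) - 1L, NA_real_, "paired t", degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  .test_result(tt$statistic, as.integer(tt$parameter), tt$p.value, "paired t")
}

#' Two-sample t test (pooled variance)
#'
#' Classical two-sided pooled-variance t test with df = n_a + n_b - 2.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `"wbnet_test"` record.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    return(.test_result(NA_real_, length(a) + length(b) - 2L, NA_real_,
                        "two-sample t", degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  .test_result(tt$statistic, as.integer(tt$parameter), tt$p.value, "two-sample t")
}

#' Exact sign test
#'
#' Exact two-sided binomial test that the median of the paired differences
#' is zero; zero differences are dropped first. Suited to skewed metric
#' distributions where the paired t is unreliable.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A `"wbnet_test"` record; `statistic` is the count of positive
#'   differences and `df` the number of non-zero differences.
#' @export
sign_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    return(.test_result(NA_real_, 0L, NA_real_, "sign test", degenerate = TRUE))
  }
  npos <- sum(d > 0)
  bt <- stats::binom.test(npos, length(d), p = 0.5)
  .test_result(npos, length(d), bt$p.value, "sign test")
}

#' Bonferroni family-wise correction
#'
#' Marks each p value significant iff `p <= alpha / m`, the most
#' conservative standard family-wise error control.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector of significance calls.
#' @export
fwe_correct <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p_values <= alpha / length(p_values)
}

#' One-way repeated-measures ANOVA (closed form)
#'
#' Tests the within-subject factor (wavelet filter length) on a complete
#' subjects-by-lengths grid of one graph metric. The F statistic is
#' `MS_length / MS_error` with df `(k - 1, (k - 1)(n - 1))` where k is the
#' number of lengths and n the number of subjects. No sphericity correction
#' is applied by default; set `gg = TRUE` for the Greenhouse-Geisser
#' adjusted p value.
#'
#' @param Y Numeric matrix, rows = subjects, columns = factor levels
#'   (wavelet lengths in ascending order); no missing entries.
#' @param gg Apply the Greenhouse-Geisser epsilon correction to the df used
#'   for the p value.
#' @return A `"wbnet_test"` record; `df` is the integer pair
#'   `(k - 1, (k - 1)(n - 1))` (uncorrected).
#' @export
rm_anova <- function(Y, gg = FALSE) {
  stopifnot(is.matrix(Y), nrow(Y) >= 2, ncol(Y) >= 2)
  if (any(is.na(Y))) {
    bad <- which(is.na(Y), arr.ind = TRUE)
    stop("incomplete subject x length grid; missing cells at (subject, length): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "), call. = FALSE)
  }
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  f <- (ss_cond / df1) / (ss_err / df2)
  eps <- 1
  if (gg) {
    S <- stats::cov(Y)
    dbar <- mean(diag(S)); sbar <- mean(S)
    num <- (k * (dbar - sbar))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
    eps <- max(min(num / den, 1), 1 / (k - 1))
  }
  p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  .test_result(f, c(df1, df2), p, if (gg) "RM-ANOVA (GG)" else "RM-ANOVA")
}

#' Repeated-measures ANOVA for one metric from a cohort result table
#'
#' Pivots a tidy result table (one row per subject x method x family x
#' length x scale, see [run_pipeline()]) into the subjects-by-lengths grid
#' for one (metric, family, scale, method, group) cell and runs
#' [rm_anova()] with wavelet length as the within-subject factor.
#'
#' @param table Result table (data frame) from [run_pipeline()].
#' @param metric Metric column name (e.g. `"mean_corr"`).
#' @param family Filter family (`"D"`, `"LA"`, `"C"`).
#' @param scale Wavelet scale.
#' @param method `"modwt"` (default) or `"dwt"`.
#' @param group Optional subject group to restrict to (e.g. `"control"`).
#' @param gg Greenhouse-Geisser correction flag, see [rm_anova()].
#' @return A `"wbnet_test"` record.
#' @export
rm_anova_length <- function(table, metric, family, scale, method = "modwt",
                            group = NULL, gg = FALSE) {
  sub <- table[table$family == family & table$scale == scale & table$method == method, ]
  if (!is.null(group)) sub <- sub[sub$group == group, ]
  if (nrow(sub) == 0) stop("no rows match the requested cell", call. = FALSE)
  lengths <- sort(unique(sub$length))
  subjects <- unique(sub$subject)
  Y <- matrix(NA_real_, length(subjects), length(lengths),
              dimnames = list(subjects, lengths))
  for (r in seq_len(nrow(sub))) {
    Y[as.character(sub$subject[r]), as.character(sub$length[r])] <- sub[[metric]][r]
  }
  rm_anova(Y, gg = gg)
}

#' Group-difference sensitivity surface
#'
#' For every (family, length, metric) cell at one scale, runs a pooled
#' two-sample t test between the two subject groups and reports
#' `-log10(p)`: higher values indicate stronger group differences.
#'
#' @param table Result table from [run_pipeline()] containing both groups.
#' @param scale Wavelet scale to analyse (the customary choice is scale 2,
#'   0.06-0.125 Hz at TR = 2 s).
#' @param method Wavelet method to analyse (default `"modwt"`).
#' @param metrics Metric columns to test (default all eight).
#' @return Data frame with columns `family`, `length`, `metric`,
#'   `t`, `p`, `neg_log10_p`.
#' @export
sensitivity_surface <- function(table, scale = 2, method = "modwt",
                                metrics = c("mean_corr", "var_corr", "clustering",
                                            "path_length", "global_eff", "local_eff",
                                            "modularity", "n_communities")) {
  sub <- table[table$scale == scale & table$method == method, ]
  groups <- sort(unique(sub$group))
  if (length(groups) != 2) stop("need exactly two groups in the table", call. = FALSE)
  cells <- unique(sub[, c("family", "length")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cell <- sub[sub$family == cells$family[i] & sub$length == cells$length[i], ]
    do.call(rbind, lapply(metrics, function(mc) {
      tt <- two_sample_t(cell[[mc]][cell$group == groups[1]],
                         cell[[mc]][cell$group == groups[2]])
      data.frame(family = cells$family[i], length = cells$length[i], metric = mc,
                 t = tt$statistic, p = tt$p_value,
                 neg_log10_p = -log10(tt$p_value), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
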