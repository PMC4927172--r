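# Pipeline orchestration: decompose every subject under a sweep of
# (method, family, length), build scale-wise connectivity, threshold,
# compute graph metrics, and return the tidy cohort result table that the
# statistics and classification stages consume.

#' Pipeline sweep configuration
#'
#' Collects the methodological sweep: wavelet methods, filter families and
#' lengths, scales, thresholding density and mode, connectivity estimator,
#' modularity settings, and the global seed from which all per-stage
#' randomness is derived.
#'
#' @param methods Subset of `c("modwt", "dwt")`.
#' @param filters Character vector of filter names (e.g. `c("D4", "LA8")`);
#'   default the full admissible sweep (D 2-20, LA 8-20, C 6-24).
#' @param scales Wavelet scales to analyse (subset of 1..max depth).
#' @param n.levels Decomposition depth (default `max(scales)`).
#' @param density Threshold density (default 0.30).
#' @param mode Edge ranking (`"strongest"`/`"weakest"`).
#' @param estimator `"correlation"` (default) or `"partial"`.
#' @param use Correlate `"coefficients"` (default) or MRA `"details"`.
#' @param exclude_boundary Drop boundary-influenced MODWT coefficients.
#' @param binary_metrics If `FALSE`, compute only the weighted metrics
#'   (mean/variance of correlations), skipping thresholding, geodesics and
#'   modularity; useful for large sweeps of the weighted statistics.
#' @param n_restarts,reducer,n_null Modularity settings, see
#'   [graph_metrics()].
#' @param ridge Ridge fraction for the partial-correlation estimator.
#' @param seed Global integer seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(methods = c("modwt", "dwt"),
                            filters = admissible_filters()$name,
                            scales = 1:4, n.levels = max(scales),
                            density = 0.30, mode = "strongest",
                            estimator = c("correlation", "partial"),
                            use = c("coefficients", "details"),
                            exclude_boundary = FALSE,
                            binary_metrics = TRUE,
                            n_restarts = 20, reducer = "mean", n_null = 25,
                            ridge = 0, seed = 1) {
  methods <- match.arg(methods, c("modwt", "dwt"), several.ok = TRUE)
  estimator <- match.arg(estimator)
  use <- match.arg(use)
  adm <- admissible_filters()$name
  bad <- setdiff(filters, adm)
  if (length(bad)) stop("inadmissible filters in sweep: ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(density > 0, density < 1 || density == 1, all(scales >= 1),
            n.levels >= max(scales))
  structure(list(methods = methods, filters = filters, scales = scales,
                 n.levels = n.levels, density = density, mode = mode,
                 estimator = estimator, use = use,
                 exclude_boundary = exclude_boundary,
                 binary_metrics = binary_metrics,
                 n_restarts = n_restarts, reducer = reducer, n_null = n_null,
                 ridge = ridge, seed = as.integer(seed)),
            class = "pipeline_config")
}

.connectivity_matrix <- function(decomp, scale, config) {
  if (config$estimator == "partial") {
    wavelet_pcor(decomp, scale, use = config$use, ridge = config$ridge)
  } else {
    wavelet_cor(decomp, scale, use = config$use,
                exclude_boundary = config$exclude_boundary)
  }
}

#' Run the full network-construction pipeline on a cohort
#'
#' Executes decompose -> connectivity -> threshold -> graph metrics for
#' every subject and every swept (method, filter, scale) cell, returning a
#' tidy table with one row per cell and the eight metric columns. The run
#' is deterministic given the config seed: the Louvain stage of each cell
#' draws its own seed from the global one.
#'
#' @param cohort A `"wbnet_cohort"` from [generate_cohort()] or
#'   [read_cohort()], or a plain named list of timepoints x regions
#'   matrices together with a `manifest` data frame supplied via
#'   `manifest`.
#' @param config A [pipeline_config()].
#' @param manifest Manifest data frame (`subject`, `group`) when `cohort`
#'   is a plain list of matrices.
#' @return Data frame with columns `subject`, `group`, `method`, `family`,
#'   `length`, `scale`, then `mean_corr`, `var_corr`, `clustering`,
#'   `path_length`, `global_eff`, `local_eff`, `modularity`,
#'   `n_communities` (the binary metrics are `NA` when
#'   `config$binary_metrics` is `FALSE`).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), manifest = NULL) {
  if (inherits(cohort, "wbnet_cohort")) {
    manifest <- cohort$manifest
    data <- cohort$data
  } else {
    data <- cohort
    if (is.null(manifest)) stop("supply a manifest for a plain list of matrices", call. = FALSE)
  }
  stopifnot(all(manifest$subject %in% names(data)))
  metric_cols <- c("mean_corr", "var_corr", "clustering", "path_length",
                   "global_eff", "local_eff", "modularity", "n_communities")
  rows <- list()
  cell_id <- 0L
  for (si in seq_len(nrow(manifest))) {
    x <- data[[manifest$subject[si]]]
    for (method in config$methods) {
      for (fname in config$filters) {
        filt <- wavelet_filter(fname)
        decomp <- tryCatch(
          suppressWarnings(
            if (method == "modwt") modwt(x, filt, config$n.levels)
            else dwt(x, filt, config$n.levels)),
          error = function(e) {
            stop(sprintf("decomposition failed at (subject %s, %s, %s): %s",
                         manifest$subject[si], method, fname,
                         conditionMessage(e)), call. = FALSE)
          })
        for (scale in config$scales) {
          cell_id <- cell_id + 1L
          m <- .connectivity_matrix(decomp, scale, config)
          vals <- if (config$binary_metrics) {
            graph_metrics(m, density = config$density, mode = config$mode,
                          n_restarts = config$n_restarts,
                          reducer = config$reducer, n_null = config$n_null,
                          seed = (config$seed + cell_id) %% .Machine$integer.max)
          } else {
            c(upper_tri_stats(m), clustering = NA_real_, path_length = NA_real_,
              global_eff = NA_real_, local_eff = NA_real_,
              modularity = NA_real_, n_communities = NA_real_)
          }
          row <- data.frame(subject = manifest$subject[si],
                            group = manifest$group[si],
                            method = method, family = filt$family,
                            length = filt$length, scale = scale,
                            stringsAsFactors = FALSE)
          row[metric_cols] <- as.list(unname(vals[metric_cols]))
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' DWT-vs-MODWT length-variation comparison
#'
#' For each subject (optionally restricted to one group) computes the
#' total variation of one metric over ascending filter lengths within a
#' family, separately under MODWT and DWT, and runs a paired t test
#' (MODWT minus DWT). A negative t statistic means MODWT profiles vary
#' less across lengths, i.e. MODWT yields the more stable estimates.
#'
#' @param table Result table from [run_pipeline()] containing both methods.
#' @param metric Metric column to compare.
#' @param family Filter family whose lengths are swept.
#' @param scale Wavelet scale.
#' @param group Optional group restriction (e.g. `"control"`).
#' @return A `"wbnet_test"` record, with the per-subject variation values
#'   attached as attribute `"variation"` (two-column matrix).
#' @export
method_variation_test <- function(table, metric, family, scale, group = NULL) {
  sub <- table[table$family == family & table$scale == scale, ]
  if (!is.null(group)) sub <- sub[sub$group == group, ]
  subjects <- unique(sub$subject)
  v <- vapply(c("modwt", "dwt"), function(meth) {
    vapply(subjects, function(s) {
      rows <- sub[sub$subject == s & sub$method == meth, ]
      rows <- rows[order(rows$length), ]
      variation_over_lengths(rows[[metric]])
    }, 0)
  }, numeric(length(subjects)))
  res <- paired_t(v[, "modwt"], v[, "dwt"])
  attr(res, "variation") <- v
  res
}
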