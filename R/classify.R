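# AdaBoost.M1 over gain-ratio trees, stratified k-fold cross-validation
# with pooled confusion counts, and the per-(family, length) classification
# sweep over a cohort result table.

#' AdaBoost.M1 ensemble of gain-ratio trees
#'
#' Boosts [c45_tree()] base learners with the AdaBoost.M1 weight updates:
#' after each round the weights of correctly classified cases are multiplied
#' by `beta = err/(1 - err)` and renormalized, and the learner votes with
#' weight `log(1/beta)`. Boosting stops early if a learner's weighted error
#' reaches 0.5 (the learner is discarded unless it is the first) or falls to
#' 0 (the perfect learner is kept). With `n_trials = 1` the ensemble is a
#' single tree.
#'
#' @param x Numeric feature matrix.
#' @param y Binary class labels.
#' @param n_trials Number of boosting rounds (default 10).
#' @param ... Passed to [c45_tree()] (e.g. `cf`, `min_leaf`).
#' @return Object of class `"adaboost"`: list of trees with vote weights
#'   `alpha`.
#' @export
adaboost <- function(x, y, n_trials = 10, ...) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(n_trials >= 1, nrow(x) == length(y))
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- list()
  alpha <- numeric(0)
  for (m in seq_len(n_trials)) {
    tr <- c45_tree(x, y, weights = w, ...)
    pred <- predict(tr, x)
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) {
      if (length(trees) == 0) {        # keep something predictive-ish
        trees[[1]] <- tr
        alpha <- 1
      }
      break
    }
    if (err <= 0) {
      trees[[length(trees) + 1]] <- tr
      alpha <- c(alpha, log((1 - 1e-10) / 1e-10))
      break
    }
    beta <- err / (1 - err)
    trees[[length(trees) + 1]] <- tr
    alpha <- c(alpha, log(1 / beta))
    w[!miss] <- w[!miss] * beta
    w <- w / sum(w)
  }
  structure(list(trees = trees, alpha = alpha, levels = levels(y),
                 n_trials = n_trials),
            class = "adaboost")
}

#' @export
predict.adaboost <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0, nrow(newdata), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in seq_along(object$trees)) {
    pred <- predict(object$trees[[m]], newdata)
    votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] + object$alpha[m]
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.adaboost <- function(x, ...) {
  cat(sprintf("AdaBoost.M1 ensemble: %d/%d trees kept, classes: %s\n",
              length(x$trees), x$n_trials, paste(x$levels, collapse = ", ")))
  invisible(x)
}

.stratified_folds <- function(y, n_folds) {
  # round-robin within class, rotating the starting fold between classes so
  # the remainder members do not all land in the same folds (keeps overall
  # fold sizes within one of each other)
  fold <- integer(length(y))
  start <- 0L
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
    start <- (start + length(idx)) %% n_folds
  }
  fold
}

#' Cross-validated boosted-tree classification
#'
#' Stratified k-fold cross-validation (default 6 folds) of an AdaBoost.M1
#' ensemble of gain-ratio trees (default 10 boosting trials). Each subject
#' is tested exactly once; the confusion counts are pooled cumulatively
#' across folds. Sensitivity is TP/(TP + FN) with the `positive` class (the
#' patient group by default) as positive.
#'
#' @param x Numeric feature matrix (rows = subjects).
#' @param y Binary class labels.
#' @param n_folds Number of folds (default 6).
#' @param n_trials Boosting rounds per fold (default 10).
#' @param seed Optional integer seed controlling the fold assignment (and
#'   hence the whole run, since the learners are deterministic).
#' @param positive Positive class label; defaults to `"patient"` when
#'   present, otherwise the second factor level.
#' @param ... Passed to [c45_tree()].
#' @return List of class `"classification_report"`: `accuracy`,
#'   `sensitivity`, `specificity`, `confusion` (2x2 matrix with TP, FN, FP,
#'   TN), `positive`, `n`.
#' @export
crossval_classify <- function(x, y, n_folds = 6, n_trials = 10, seed = NULL,
                              positive = NULL, ...) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2, nrow(x) == length(y))
  if (min(table(y)) < n_folds) {
    stop("each class must have at least n_folds members for stratified folds", call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if ("patient" %in% levels(y)) "patient" else levels(y)[2]
  }
  negative <- setdiff(levels(y), positive)
  if (!is.null(seed)) set.seed(seed)
  fold <- .stratified_folds(y, n_folds)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    model <- adaboost(x[!test, , drop = FALSE], y[!test], n_trials = n_trials, ...)
    pred[test] <- predict(model, x[test, , drop = FALSE])
  }
  tp <- sum(pred == positive & y == positive)
  fn <- sum(pred == negative & y == positive)
  fp <- sum(pred == positive & y == negative)
  tn <- sum(pred == negative & y == negative)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(predicted = c(positive, negative),
                                      actual = c(positive, negative)))
  structure(list(accuracy = (tp + tn) / length(y),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 confusion = confusion, positive = positive, n = length(y)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("cross-validated classification (positive = %s, n = %d)\n",
              x$positive, x$n))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  print(x$confusion)
  invisible(x)
}

#' Classification sweep over filter families and lengths
#'
#' For every (family, length) present in a cohort result table at one
#' wavelet scale, gathers the eight graph metrics as features and runs
#' [crossval_classify()] to distinguish the two subject groups, mirroring
#' the accuracy / sensitivity / specificity-versus-length comparison.
#'
#' @param table Result table from [run_pipeline()] containing both groups.
#' @param scale Wavelet scale whose metrics are used as features (default 2).
#' @param method Wavelet method (default `"modwt"`).
#' @param metrics Feature columns (default the eight graph metrics).
#' @param seed Integer seed; fold randomization for cell i uses `seed + i`.
#' @param ... Passed to [crossval_classify()].
#' @return Data frame with one row per (family, length): accuracy,
#'   sensitivity, specificity and the confusion counts TP, FN, FP, TN.
#' @export
classification_sweep <- function(table, scale = 2, method = "modwt",
                                 metrics = c("mean_corr", "var_corr", "clustering",
                                             "path_length", "global_eff", "local_eff",
                                             "modularity", "n_communities"),
                                 seed = 1, ...) {
  sub <- table[table$scale == scale & table$method == method, ]
  if (length(unique(sub$group)) != 2) stop("need exactly two groups", call. = FALSE)
  cells <- unique(sub[, c("family", "length")])
  cells <- cells[order(cells$family, cells$length), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cell <- sub[sub$family == cells$family[i] & sub$length == cells$length[i], ]
    cell <- cell[order(cell$subject), ]
    rep <- crossval_classify(as.matrix(cell[, metrics]), cell$group,
                             seed = seed + i, ...)
    data.frame(family = cells$family[i], length = cells$length[i], scale = scale,
               accuracy = rep$accuracy, sensitivity = rep$sensitivity,
               specificity = rep$specificity,
               TP = rep$confusion[1, 1], FN = rep$confusion[2, 1],
               FP = rep$confusion[1, 2], TN = rep$confusion[2, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
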