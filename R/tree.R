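# A C4.5-style decision-tree learner for continuous features: axis-aligned
# binary splits chosen by gain ratio, with pessimistic-error (confidence
# bound) pruning. Instance weights are supported throughout so the tree can
# serve as the AdaBoost.M1 base learner.

.weighted_entropy <- function(w_by_class) {
  tot <- sum(w_by_class)
  if (tot <= 0) return(0)
  p <- w_by_class[w_by_class > 0] / tot
  -sum(p * log2(p))
}

.class_weights <- function(y, w, levels) {
  vapply(levels, function(cl) sum(w[y == cl]), 0)
}

# C4.5 pessimistic error: upper confidence limit of the binomial error rate
# for E (possibly fractional, weighted) errors out of N cases.
.ucf <- function(E, N, cf = 0.25) {
  if (N <= 0) return(0)
  if (E >= N) return(1)
  stats::qbeta(1 - cf, E + 1, N - E)
}

.best_split <- function(x, y, w, levels, min_leaf) {
  n <- length(y)
  parent_w <- .class_weights(y, w, levels)
  H <- .weighted_entropy(parent_w)
  tot <- sum(w)
  best <- NULL
  cand <- list()
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]; ys <- y[ord]; ws <- w[ord]
    # cumulative weighted class counts left of each cut
    cum <- sapply(levels, function(cl) cumsum(ws * (ys == cl)))
    if (!is.matrix(cum)) cum <- matrix(cum, nrow = n)
    cuts <- which(diff(xs) > 0)                      # split between distinct values
    cuts <- cuts[cuts >= min_leaf & (n - cuts) >= min_leaf]
    if (!length(cuts)) next
    # C4.5 (release 8) MDL correction: penalize the gain used for *ranking*
    # by log2(T)/n so near-zero slices of single points cannot win on a
    # deflated split-info denominator
    penalty <- log2(length(cuts)) / n
    for (ci in cuts) {
      lw <- cum[ci, ]; rw <- parent_w - lw
      wl <- sum(lw); wr <- sum(rw)
      gain <- H - (wl / tot) * .weighted_entropy(lw) - (wr / tot) * .weighted_entropy(rw)
      pl <- wl / tot
      split_info <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
      if (split_info <= 0) next
      cand[[length(cand) + 1]] <- list(
        feature = j, threshold = (xs[ci] + xs[ci + 1]) / 2,
        gain = gain, gain_ratio = (gain - penalty) / split_info)
    }
  }
  if (!length(cand)) return(NULL)
  gains <- vapply(cand, `[[`, 0, "gain")
  # C4.5 heuristic: maximize (penalized) gain ratio among splits with at
  # least average raw gain
  ok <- gains >= mean(gains) - 1e-12
  cand <- cand[ok]
  gr <- vapply(cand, `[[`, 0, "gain_ratio")
  best <- cand[[which.max(gr)]]
  if (best$gain <= 1e-12) return(NULL)
  best
}

.grow_tree <- function(x, y, w, levels, min_leaf, max_depth, depth = 0) {
  cw <- .class_weights(y, w, levels)
  cls <- levels[which.max(cw)]
  leaf <- list(leaf = TRUE, class = cls, class_w = cw, n = length(y))
  if (length(unique(y)) == 1 || length(y) < 2 * min_leaf || depth >= max_depth) {
    return(leaf)
  }
  sp <- .best_split(x, y, w, levels, min_leaf)
  if (is.null(sp)) return(leaf)
  left <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       class = cls, class_w = cw, n = length(y),
       left = .grow_tree(x[left, , drop = FALSE], y[left], w[left], levels,
                         min_leaf, max_depth, depth + 1),
       right = .grow_tree(x[!left, , drop = FALSE], y[!left], w[!left], levels,
                          min_leaf, max_depth, depth + 1))
}

# bottom-up pessimistic pruning: replace a subtree by a leaf when the
# leaf's estimated error bound does not exceed the subtree's
.prune_node <- function(node, cf) {
  if (node$leaf) return(node)
  node$left <- .prune_node(node$left, cf)
  node$right <- .prune_node(node$right, cf)
  N <- sum(node$class_w)
  E_leaf <- N - max(node$class_w)
  err_leaf <- N * .ucf(E_leaf, N, cf)
  err_sub <- .subtree_error(node$left, cf) + .subtree_error(node$right, cf)
  if (err_leaf <= err_sub + 1e-12) {
    return(list(leaf = TRUE, class = node$class, class_w = node$class_w, n = node$n))
  }
  node
}

.subtree_error <- function(node, cf) {
  if (node$leaf) {
    N <- sum(node$class_w)
    return(N * .ucf(N - max(node$class_w), N, cf))
  }
  .subtree_error(node$left, cf) + .subtree_error(node$right, cf)
}

#' Fit a gain-ratio decision tree
#'
#' Grows a binary decision tree on continuous features using C4.5-style
#' gain-ratio split selection (the best gain ratio among candidate
#' thresholds whose information gain is at least the average candidate
#' gain), then applies pessimistic-error pruning with confidence `cf`.
#' Instance weights are honoured in the split criterion and leaf votes,
#' which makes the tree usable as a boosting base learner. Degenerate
#' single-class input yields a constant classifier.
#'
#' @param x Numeric feature matrix (rows = cases).
#' @param y Class labels (coerced to factor; two or more classes).
#' @param weights Optional nonnegative case weights (default uniform).
#' @param min_leaf Minimum cases per side of a split (default 2).
#' @param max_depth Depth cap (default 12).
#' @param cf Pruning confidence (default 0.25, the C4.5 default); `cf = 1`
#'   disables pruning.
#' @return Object of class `"c45_tree"`.
#' @export
c45_tree <- function(x, y, weights = NULL, min_leaf = 2, max_depth = 12, cf = 0.25) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  stopifnot(nrow(x) == length(y), all(is.finite(x)))
  if (is.null(weights)) weights <- rep(1 / nrow(x), nrow(x))
  stopifnot(length(weights) == length(y), all(weights >= 0))
  levels <- levels(y)
  root <- .grow_tree(x, as.character(y), weights, levels, min_leaf, max_depth)
  if (cf < 1) root <- .prune_node(root, cf)
  structure(list(root = root, levels = levels, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "c45_tree")
}

.tree_predict_one <- function(node, xi) {
  while (!node$leaf) {
    node <- if (xi[node$feature] <= node$threshold) node$left else node$right
  }
  node$class
}

#' @export
predict.c45_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$n_features)
  factor(apply(newdata, 1, function(xi) .tree_predict_one(object$root, xi)),
         levels = object$levels)
}

.tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(.tree_depth(node$left), .tree_depth(node$right))
}

.tree_size <- function(node) {
  if (node$leaf) return(1L)
  1L + .tree_size(node$left) + .tree_size(node$right)
}

#' @export
print.c45_tree <- function(x, ...) {
  cat(sprintf("gain-ratio decision tree: %d nodes, depth %d, classes: %s\n",
              .tree_size(x$root), .tree_depth(x$root),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}
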