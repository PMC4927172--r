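# Density thresholding and the eight per-network summaries: mean/variance of
# correlations (weighted), clustering coefficient, characteristic path
# length, global and local efficiency, Louvain modularity (restart mean) and
# number of communities from a consensus partition.
#
# Geodesics and Louvain optimization are delegated to igraph; the metric
# formulas themselves follow the standard binary-network definitions.

.check_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A != t(A))) stop("adjacency matrix must be symmetric", call. = FALSE)
  if (any(diag(A) != 0)) stop("adjacency matrix must have zero diagonal", call. = FALSE)
  A
}

.graph_from_adjacency <- function(A, weighted = FALSE) {
  igraph::graph_from_adjacency_matrix(
    A, mode = "undirected", weighted = if (weighted) TRUE else NULL, diag = FALSE)
}

#' Threshold a connectivity matrix to fixed edge density
#'
#' Keeps the `round(density * M)` strongest (most positive) or weakest
#' (least positive) of the `M = n(n-1)/2` edge weights, giving a binary
#' undirected graph. Rounding is half away from zero; ties among equal
#' weights are broken deterministically by lexicographic (row, column)
#' order, so repeated calls always return the same edge set. Signed values
#' are ranked as-is (no absolute value).
#'
#' @param m Symmetric weighted connectivity matrix (e.g. from
#'   [wavelet_cor()]).
#' @param density Target edge density in (0, 1]; the conventional choice for
#'   functional brain networks is 0.30.
#' @param mode `"strongest"` (default) or `"weakest"`.
#' @return Binary 0/1 adjacency matrix with attribute `density` (the
#'   realized edge density).
#' @export
threshold_density <- function(m, density = 0.30, mode = c("strongest", "weakest")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]", call. = FALSE)
  if (any(is.na(m[upper.tri(m)]))) {
    stop("connectivity matrix contains NA entries (degenerate regions); cannot threshold", call. = FALSE)
  }
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  M <- length(w)
  k <- floor(density * M + 0.5)
  if (k < 1) stop("requested density yields zero edges", call. = FALSE)
  ord <- if (mode == "strongest") {
    order(-w, ut[, 1], ut[, 2])
  } else {
    order(w, ut[, 1], ut[, 2])
  }
  keep <- ord[seq_len(k)]
  A <- matrix(0L, n, n, dimnames = dimnames(m))
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  attr(A, "density") <- k / M
  A
}

#' Clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' `C_i = sum_{j != h} A_ij A_ih A_jh / (k_i (k_i - 1))`, the fraction of a
#' node's neighbour pairs that are themselves connected. Nodes with degree
#' below 2 contribute 0.
#'
#' @param A Binary symmetric adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coef <- function(A) {
  A <- .check_adjacency(A)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)      # 2 x number of triangles through each node
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean geodesic distance over all ordered pairs of distinct vertices that
#' lie in the same connected component, pooled across components
#' (denominator `sum_m n_m (n_m - 1)`). If the graph has no connected pair
#' the value is undefined and `NA` is returned with a warning.
#'
#' @param A Binary symmetric adjacency matrix.
#' @return Scalar `>= 1`, or `NA` if no two vertices are connected.
#' @export
char_path_length <- function(A) {
  A <- .check_adjacency(A)
  D <- igraph::distances(.graph_from_adjacency(A))
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  if (!any(fin)) {
    warning("no connected vertex pairs; characteristic path length undefined")
    return(NA_real_)
  }
  mean(off[fin])
}

#' Global efficiency
#'
#' `E = 1/(n(n-1)) sum_{i != j} 1/d_ij`, with `1/Inf = 0` for disconnected
#' pairs; a measure of how effectively information can be exchanged across
#' the whole network.
#'
#' @param A Binary symmetric adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  A <- .check_adjacency(A)
  n <- nrow(A)
  if (n < 2) return(0)
  D <- igraph::distances(.graph_from_adjacency(A))
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours, with geodesics computed within that subgraph. Nodes
#' with degree below 2 contribute 0.
#'
#' @param A Binary symmetric adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  A <- .check_adjacency(A)
  n <- nrow(A)
  k <- rowSums(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] > 0)
    e[i] <- global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(e)
}

#' Louvain modularity over seeded restarts
#'
#' Runs the Louvain heuristic `n_restarts` times, each restart visiting the
#' nodes in a freshly drawn random order (a seeded vertex permutation), and
#' scores every partition with the normalized Newman-Girvan modularity
#' `Q = 1/(2l) sum_ij (A_ij - k_i k_j / (2l)) delta(c_i, c_j)`. Because the
#' modularity landscape is nearly degenerate, the reported `q` is the mean
#' over restarts by default (set `reducer = "max"` for the best solution).
#'
#' @param A Symmetric adjacency matrix; nonnegative weights are honoured
#'   (used when re-clustering consensus allegiance matrices).
#' @param n_restarts Number of seeded Louvain restarts (default 20).
#' @param seed Optional integer seed making the restart set reproducible.
#' @param reducer `"mean"` (default) or `"max"` over restart Q values.
#' @return List with `q` (reduced modularity), `q_all` (per restart),
#'   `partitions` (list of integer membership vectors, labels contiguous
#'   from 1), and `best` (partition achieving the maximum Q).
#' @export
louvain_q <- function(A, n_restarts = 20, seed = NULL, reducer = c("mean", "max")) {
  reducer <- match.arg(reducer)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (all(A[upper.tri(A)] == 0)) stop("graph has no edges; modularity undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  weighted <- any(A[upper.tri(A)] != 0 & A[upper.tri(A)] != 1)
  g <- .graph_from_adjacency(A, weighted = weighted)
  wts <- if (weighted) igraph::E(g)$weight else NULL
  n <- nrow(A)
  qs <- numeric(n_restarts)
  parts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    memb <- igraph::membership(igraph::cluster_louvain(gp))[perm]
    memb <- .canonical_labels(as.integer(memb))
    qs[r] <- igraph::modularity(g, memb, weights = wts)
    parts[[r]] <- memb
  }
  list(q = if (reducer == "mean") mean(qs) else max(qs),
       q_all = qs, partitions = parts, best = parts[[which.max(qs)]])
}

# relabel communities 1, 2, ... in order of first appearance
.canonical_labels <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

#' Consensus partition over degenerate modularity optima
#'
#' Builds the module-allegiance matrix (fraction of input partitions that
#' place each node pair in the same community), zeroes entries at or below
#' the expectation under a permutation null (community labels of each
#' partition randomly reassigned to nodes), re-clusters the thresholded
#' allegiance matrix with Louvain, and iterates until every restart returns
#' the same partition or the iteration cap is reached.
#'
#' @param partitions List of integer membership vectors over the same nodes
#'   (e.g. `louvain_q(...)$partitions`).
#' @param n_null Number of label permutations used for the null expectation.
#' @param seed Optional integer seed.
#' @param max_iter Iteration cap; if reached without convergence the last
#'   iterate is returned with attribute `converged = FALSE` and a warning.
#' @return Integer membership vector (labels contiguous from 1) with
#'   attributes `converged` and `iterations`.
#' @export
consensus_partition <- function(partitions, n_null = 100, seed = NULL, max_iter = 20) {
  stopifnot(is.list(partitions), length(partitions) >= 2)
  P <- do.call(cbind, lapply(partitions, as.integer))
  n <- nrow(P)
  if (!is.null(seed)) set.seed(seed)
  nrest <- length(partitions)
  for (it in seq_len(max_iter)) {
    if (.all_partitions_identical(P)) {
      out <- .canonical_labels(P[, 1])
      attr(out, "converged") <- TRUE
      attr(out, "iterations") <- it - 1L
      return(out)
    }
    Ag <- .allegiance(P)
    # null expectation of off-diagonal allegiance under label permutation
    mu <- mean(vapply(seq_len(n_null), function(b) {
      Pb <- apply(P, 2, sample)
      mean(.allegiance(Pb)[upper.tri(Ag)])
    }, 0))
    Ag[Ag <= mu] <- 0
    diag(Ag) <- 0
    if (all(Ag[upper.tri(Ag)] == 0)) {
      # no above-chance co-assignment structure: every node its own community
      out <- seq_len(n)
      attr(out, "converged") <- TRUE
      attr(out, "iterations") <- it
      return(out)
    }
    lv <- louvain_q(Ag, n_restarts = nrest)
    P <- do.call(cbind, lv$partitions)
  }
  warning("consensus partition did not converge within ", max_iter, " iterations")
  out <- .canonical_labels(P[, 1])
  attr(out, "converged") <- FALSE
  attr(out, "iterations") <- max_iter
  out
}

.allegiance <- function(P) {
  n <- nrow(P)
  Ag <- matrix(0, n, n)
  for (r in seq_len(ncol(P))) {
    Ag <- Ag + outer(P[, r], P[, r], "==")
  }
  Ag / ncol(P)
}

.all_partitions_identical <- function(P) {
  ref <- .canonical_labels(P[, 1])
  all(apply(P, 2, function(col) identical(.canonical_labels(col), ref)))
}

#' All eight graph metrics of one connectivity matrix
#'
#' Thresholds the matrix to the target density and assembles the standard
#' record: mean and variance of the upper-triangular correlations (weighted
#' metrics of the unthresholded matrix), clustering coefficient,
#' characteristic path length, global and local efficiency, Louvain
#' modularity (restart mean by default) and the number of communities in
#' the consensus partition.
#'
#' @param m Symmetric weighted connectivity matrix.
#' @param density Edge density for thresholding (default 0.30).
#' @param mode Edge ranking mode, see [threshold_density()].
#' @param n_restarts Louvain restarts (default 20).
#' @param reducer Modularity reducer over restarts (`"mean"` or `"max"`).
#' @param n_null Permutations for the consensus null (default 25).
#' @param seed Optional integer seed for the modularity stage.
#' @return Named numeric vector with elements `mean_corr`, `var_corr`,
#'   `clustering`, `path_length`, `global_eff`, `local_eff`, `modularity`,
#'   `n_communities`.
#' @export
graph_metrics <- function(m, density = 0.30, mode = "strongest",
                          n_restarts = 20, reducer = "mean", n_null = 25,
                          seed = NULL) {
  ws <- upper_tri_stats(m)
  A <- threshold_density(m, density, mode)
  lv <- louvain_q(A, n_restarts = n_restarts, seed = seed, reducer = reducer)
  cons <- consensus_partition(lv$partitions, n_null = n_null)
  c(ws,
    clustering = clustering_coef(A),
    path_length = char_path_length(A),
    global_eff = global_efficiency(A),
    local_eff = local_efficiency(A),
    modularity = lv$q,
    n_communities = length(unique(cons)))
}
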