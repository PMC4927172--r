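# Independent oracles used by the tests. These deliberately take different
# computational routes from the package implementation: explicit loops,
# exhaustive enumeration, and equivalent-filter (non-pyramid) transforms.

circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

# ---- direct (non-pyramid) MODWT via explicit level-j equivalent filters ----

.upsample <- function(f, by) {
  if (by == 1) return(f)
  out <- numeric((length(f) - 1) * by + 1)
  out[seq(1, length(out), by = by)] <- f
  out
}

.conv_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

# level-j equivalent MODWT filters: h_j = up(h~, 2^{j-1}) * g_{j-1},
# g_j = up(g~, 2^{j-1}) * g_{j-1}, with g_0 = 1 and tilde = /sqrt(2)
modwt_equiv_filters <- function(filter, J) {
  gt <- filter$g / sqrt(2)
  ht <- filter$h / sqrt(2)
  gj <- 1
  H <- vector("list", J)
  for (j in seq_len(J)) {
    H[[j]] <- .conv_full(.upsample(ht, 2^(j - 1)), gj)
    gj <- .conv_full(.upsample(gt, 2^(j - 1)), gj)
  }
  list(H = H, G = gj)
}

# definition-based circular filtering: W_j[t] = sum_l f[l] x[(t - l) mod N]
modwt_direct <- function(x, filter, J) {
  N <- length(x)
  eq <- modwt_equiv_filters(filter, J)
  apply_filt <- function(f) {
    vapply(seq_len(N) - 1L, function(t) {
      sum(f * x[((t - (seq_along(f) - 1L)) %% N) + 1L])
    }, 0)
  }
  list(W = lapply(eq$H, apply_filt), V = apply_filt(eq$G))
}

# ---- brute-force graph metric oracles (explicit loops over tuples) ----

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {            # BFS from each source
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(A[v, ] > 0)) {
          if (dist[u] > dist[v] + 1) {
            dist[u] <- dist[v] + 1
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

bf_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    cnt <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != h) cnt <- cnt + A[i, j] * A[i, h] * A[j, h]
    }
    ci[i] <- cnt / (k * (k - 1))
  }
  mean(ci)
}

bf_path_length <- function(A) {
  D <- bf_distances(A)
  v <- D[row(D) != col(D)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

bf_global_eff <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (n * (n - 1))
}

bf_local_eff <- function(A) {
  n <- nrow(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    e[i] <- bf_global_eff(A[nb, nb, drop = FALSE])
  }
  mean(e)
}

# ---- exhaustive modularity oracle -----------------------------------------

# all set partitions of n elements as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  recur <- function(memb, kmax) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (c in seq_len(kmax + 1L)) recur(c(memb, c), max(kmax, c))
  }
  recur(integer(0), 0L)
  out
}

# Newman-Girvan modularity by the definition formula
modularity_formula <- function(A, memb) {
  k <- rowSums(A)
  twol <- sum(k)
  same <- outer(memb, memb, "==")
  sum((A - outer(k, k) / twol) * same) / twol
}

max_modularity_exhaustive <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) modularity_formula(A, p), 0))
}

random_graph <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A + t(A)
}

# random graph guaranteed to have at least one edge
random_graph_nonempty <- function(n, p) {
  repeat {
    A <- random_graph(n, p)
    if (sum(A) > 0) return(A)
  }
}
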