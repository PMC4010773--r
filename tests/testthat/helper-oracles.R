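# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# weighted clustering coefficient by explicit triple sum over ordered pairs
oracle_clustering <- function(W) {
  n <- nrow(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(n)) for (l in seq_len(n)) {
      if (k == i || l == i || k == l) next
      num <- num + W[i, k] * W[i, l] * W[k, l]
      den <- den + W[i, k] * W[i, l]
    }
    ci[i] <- if (den > 0) num / den else 0
  }
  ci
}

# all-pairs shortest paths on reciprocal weights by Floyd-Warshall
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# maximum spanning tree weight by exhaustive enumeration (n <= 7)
oracle_max_tree_weight <- function(W) {
  n <- nrow(W)
  stopifnot(n <= 7)
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  best <- -Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    w <- W[e]
    if (any(w <= 0)) next
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < n) next
    if (igraph::is_connected(g) && igraph::ecount(g) == n - 1)
      best <- max(best, sum(w))
  }
  best
}

# random labelled tree on n nodes from a uniform Pruefer sequence
oracle_random_tree <- function(n) {
  stopifnot(n >= 3)
  prf <- sample.int(n, n - 2, replace = TRUE)
  degree <- rep(1L, n)
  for (v in prf) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0L
  for (v in prf) {
    leaf <- min(which(degree == 1L))
    k <- k + 1L
    edges[k, ] <- c(leaf, v)
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# symmetric random weight matrix with positive weights (connected)
random_weight_matrix <- function(n, min_w = 0.05, max_w = 1) {
  W <- matrix(stats::runif(n * n, min_w, max_w), n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# tiny two-group, two-condition record table for the stats layer
make_records <- function(n1 = 8, n2 = 8, effect1 = 0, effect2 = 0, sd = 1) {
  ids <- c(sprintf("P%02d", 1:n1), sprintf("C%02d", 1:n2))
  grp <- rep(c("patient", "control"), c(n1, n2))
  base <- stats::rnorm(n1 + n2, 10, sd)
  shift <- c(rep(effect1, n1), rep(effect2, n2)) + stats::rnorm(n1 + n2, 0, sd)
  rbind(
    data.frame(subject_id = ids, group = grp, condition = "routine",
               value = base, stringsAsFactors = FALSE),
    data.frame(subject_id = ids, group = grp, condition = "sleep_deprived",
               value = base + shift, stringsAsFactors = FALSE)
  )
}
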