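# Maximum spanning tree of the PLI network via Kruskal's algorithm, and the
# tree-shape measures leaf number and diameter.

#' Maximum-weight spanning tree (Kruskal)
#'
#' Edges are sorted by descending weight (strong PLI = important connection)
#' with deterministic lexicographic label-pair tie-breaking, and added
#' greedily, skipping any edge that would close a cycle, until all N nodes
#' are connected by N - 1 edges. Equivalent to the minimum spanning tree
#' under reciprocal-weight edge lengths, and invariant under any monotone
#' increasing transform of the weights.
#'
#' @param W A [pli_matrix()] result or symmetric zero-diagonal weight matrix;
#'   the positive-weight graph must be connected.
#' @return An object of class `spanning_tree`: `labels`, `edges` (data.frame
#'   `a`, `b`, `weight`, N - 1 rows), `degree` (named integer vector).
#' @export
maximum_spanning_tree <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes")
  labels <- rownames(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("graph has no positive-weight edges")
  ord <- order(-W[idx], labels[idx[, 1L]], labels[idx[, 2L]])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ea <- integer(n - 1L); eb <- integer(n - 1L); ew <- numeric(n - 1L)
  m <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {                      # otherwise the edge closes a cycle
      parent[ri] <- rj
      m <- m + 1L
      ea[m] <- i; eb[m] <- j; ew[m] <- W[i, j]
      if (m == n - 1L) break
    }
  }
  if (m < n - 1L)
    stop("graph is disconnected: spanning tree has only ", m, " of ",
         n - 1L, " edges")
  deg <- tabulate(c(ea, eb), nbins = n)
  names(deg) <- labels
  structure(list(labels = labels,
                 edges = data.frame(a = labels[ea], b = labels[eb],
                                    weight = ew, stringsAsFactors = FALSE),
                 degree = deg),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges, %d leaves\n",
              length(x$labels), nrow(x$edges), sum(x$degree == 1L)))
  invisible(x)
}

# adjacency list of a spanning tree, by node index
tree_adjacency <- function(tree) {
  n <- length(tree$labels)
  ai <- match(tree$edges$a, tree$labels)
  bi <- match(tree$edges$b, tree$labels)
  adj <- vector("list", n)
  for (k in seq_along(ai)) {
    adj[[ai[k]]] <- c(adj[[ai[k]]], bi[k])
    adj[[bi[k]]] <- c(adj[[bi[k]]], ai[k])
  }
  adj
}

# hop distances from one node by breadth-first search
bfs_hops <- function(adj, start) {
  n <- length(adj)
  dist <- rep.int(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) if (is.na(dist[u])) {
      dist[u] <- dist[v] + 1L
      queue <- c(queue, u)
    }
  }
  dist
}

#' Leaf number and diameter of a spanning tree
#'
#' The leaf number is the count of degree-1 nodes (bounds: 2 for a path, up
#' to m = N - 1 for a star). The diameter is the largest hop distance between
#' any node pair, found by a double breadth-first sweep (exact on trees); it
#' is bounded above by `m - leaf_number + 2`. Both are normalized by m to
#' `(0, 1]`.
#'
#' @param tree A [maximum_spanning_tree()] result.
#' @return An object of class `tree_measures`: `leaf_number`, `diameter`,
#'   `leaf_norm`, `diameter_norm`, `m`.
#' @examples
#' tree_measures(maximum_spanning_tree(chain_coupling(5, 0.9)))
#' @export
tree_measures <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- length(tree$labels)
  m <- n - 1L
  leaf <- sum(tree$degree == 1L)
  adj <- tree_adjacency(tree)
  d1 <- bfs_hops(adj, 1L)
  far <- which.max(d1)
  d2 <- bfs_hops(adj, far)
  diameter <- max(d2)
  structure(list(leaf_number = leaf, diameter = diameter,
                 leaf_norm = leaf / m, diameter_norm = diameter / m, m = m),
            class = "tree_measures")
}

#' @export
print.tree_measures <- function(x, ...) {
  cat(sprintf("<tree_measures> leaves %d/%d (%.3f), diameter %d/%d (%.3f)\n",
              x$leaf_number, x$m, x$leaf_norm, x$diameter, x$m,
              x$diameter_norm))
  invisible(x)
}

#' Edge-list serialization of a spanning tree
#'
#' @param tree A [maximum_spanning_tree()] result.
#' @param path Destination CSV (`node_a`, `node_b`, `weight`).
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "spanning_tree"))
  out <- tree$edges
  names(out) <- c("node_a", "node_b", "weight")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
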