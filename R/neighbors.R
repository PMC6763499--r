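# Weighted K-nearest-neighbour graphs: the shared structure both latent
# spaces and trajectories reduce to before autocorrelation is computed.

new_neighbor_graph <- function(index, distance, weight, K, cell_ids,
                               bandwidth = "squared") {
  structure(
    list(index = index, distance = distance, weight = weight, K = K,
         W = sum(weight), cell_ids = cell_ids, bandwidth = bandwidth),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, K = %d, total weight W = %.4g\n",
              nrow(x$index), x$K, x$W))
  invisible(x)
}

# Default neighbourhood size: ceiling(sqrt(N)).
default_k <- function(n) as.integer(ceiling(sqrt(n)))

# Exact blocked KNN from a dense distance computation.  Ties at the K
# boundary are broken by cell index so runs are deterministic.
knn_from_coords <- function(coords, K) {
  n <- nrow(coords)
  idx <- matrix(0L, n, K)
  dst <- matrix(0, n, K)
  sq <- rowSums(coords^2)
  block <- max(1L, min(n, as.integer(2e7 / n)))
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    rows <- s:min(s + block - 1L, n)
    # squared Euclidean distances of this block against all cells
    d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    d2 <- pmax(d2, 0)
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- d2[r, ]
      d[i] <- Inf  # self excluded from its own neighbourhood
      ord <- order(d, seq_len(n))[seq_len(K)]
      idx[i, ] <- ord
      dst[i, ] <- sqrt(d[ord])
    }
  }
  list(index = idx, distance = dst)
}

#' K-nearest-neighbour graph from a latent space
#'
#' Euclidean KNN in the supplied latent coordinates, with Gaussian
#' distance-decay weights ([weights_from_distances()]).  The default
#' neighbourhood size scales as the square root of the number of cells,
#' `K = ceiling(sqrt(N))`.
#'
#' @param latent Cells x dims numeric matrix with cell rownames.
#' @param K Number of neighbours, or `NULL` for the square-root default.
#' @param bandwidth Kernel dialect, see [weights_from_distances()].
#' @return A `neighbor_graph`.
#' @export
knn_from_latent <- function(latent, K = NULL, bandwidth = c("squared", "literal")) {
  bandwidth <- match.arg(bandwidth)
  if (is.null(rownames(latent))) abort("Latent matrix needs cell rownames.")
  if (!all(is.finite(latent))) abort("Latent coordinates must be finite.")
  n <- nrow(latent)
  K <- if (is.null(K)) default_k(n) else as.integer(K)
  if (K >= n) abort(sprintf("K = %d must be smaller than the number of cells (%d).", K, n))
  if (K < 1L) abort("K must be at least 1.")
  nn <- knn_from_coords(as.matrix(latent), K)
  g <- new_neighbor_graph(nn$index, nn$distance,
                          weight = matrix(1, n, K), K = K,
                          cell_ids = rownames(latent), bandwidth = bandwidth)
  weights_from_distances(g, bandwidth)
}

#' Gaussian kernel weights from neighbour distances
#'
#' For cell i and neighbour j, `w_ij = exp(-d_ij^2 / sigma_i^2)` with a
#' per-cell bandwidth set from the distance to the K-th nearest neighbour.
#' With `bandwidth = "squared"` (default) `sigma_i = d_iK`, so the kernel
#' argument is dimensionless and the K-th neighbour always receives weight
#' `exp(-1)`; `"literal"` instead uses `sigma_i^2 = d_iK` as printed in some
#' descriptions of this kernel.  Rows whose K-th neighbour sits at distance
#' 0 (duplicated points) fall back to uniform weight 1 with a warning.
#'
#' @param graph A `neighbor_graph` with distances filled in.
#' @param bandwidth `"squared"` or `"literal"`.
#' @return The graph with `weight` and total weight `W` updated.
#' @export
weights_from_distances <- function(graph, bandwidth = c("squared", "literal")) {
  bandwidth <- match.arg(bandwidth)
  dk <- graph$distance[, graph$K]
  sigma2 <- if (bandwidth == "squared") dk^2 else dk
  flat <- sigma2 == 0
  sigma2[flat] <- 1
  w <- exp(-graph$distance^2 / sigma2)
  if (any(flat)) {
    w[flat, ] <- 1
    warn(sprintf("%d cells have duplicate-point neighbourhoods; uniform weights used.",
                 sum(flat)))
  }
  graph$weight <- w
  graph$W <- sum(w)
  graph$bandwidth <- bandwidth
  graph
}

#' K-nearest-neighbour graph from a precomputed distance matrix
#'
#' Used for trajectory geodesic distances; selection and weighting follow
#' [knn_from_latent()].
#'
#' @param d Symmetric cells x cells distance matrix with cell dimnames.
#' @param K Neighbourhood size or `NULL` for `ceiling(sqrt(N))`.
#' @param bandwidth See [weights_from_distances()].
#' @return A `neighbor_graph`.
#' @export
knn_from_distances <- function(d, K = NULL, bandwidth = c("squared", "literal")) {
  bandwidth <- match.arg(bandwidth)
  n <- nrow(d)
  K <- if (is.null(K)) default_k(n) else as.integer(K)
  if (K >= n) abort(sprintf("K = %d must be smaller than the number of cells (%d).", K, n))
  idx <- matrix(0L, n, K)
  dst <- matrix(0, n, K)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    ord <- order(di, seq_len(n))[seq_len(K)]
    idx[i, ] <- ord
    dst[i, ] <- di[ord]
  }
  g <- new_neighbor_graph(idx, dst, weight = matrix(1, n, K), K = K,
                          cell_ids = rownames(d) %||% as.character(seq_len(n)),
                          bandwidth = bandwidth)
  weights_from_distances(g, bandwidth)
}

#' Export a neighbour graph as an edge table
#'
#' @param graph A `neighbor_graph`.
#' @return Tibble with columns `from`, `to` (cell ids), `distance`, `weight`.
#' @export
graph_edges <- function(graph) {
  n <- nrow(graph$index)
  tibble(
    from = rep(graph$cell_ids, graph$K),
    to = graph$cell_ids[as.vector(graph$index)],
    distance = as.vector(graph$distance),
    weight = as.vector(graph$weight)
  )
}
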