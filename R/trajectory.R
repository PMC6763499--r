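# Trajectory models: a milestone network (edges with lengths) plus cells
# placed fractionally along edges.  Cell-cell similarity is the geodesic
# path length through the network, after which the analysis proceeds on
# the same weighted KNN graph used for latent spaces.

#' Construct a trajectory model
#'
#' @param milestones Character vector of milestone names.
#' @param edges Data frame with columns `from`, `to`, `length` (positive).
#' @param cells Data frame with columns `cell_id`, `from`, `to`,
#'   `progress` (fraction in `[0, 1]` from `from` towards `to`; the edge
#'   must exist in `edges`).
#' @return A `trajectory_model`.
#' @export
trajectory_model <- function(milestones, edges, cells) {
  edges <- as_tibble(edges)
  cells <- as_tibble(cells)
  stopifnot(all(c("from", "to", "length") %in% names(edges)),
            all(c("cell_id", "from", "to", "progress") %in% names(cells)))
  if (any(edges$length <= 0)) abort("Edge lengths must be positive.")
  if (any(cells$progress < 0 | cells$progress > 1)) {
    abort("Cell progress values must lie in [0, 1].")
  }
  bad <- !(cells$from %in% milestones) | !(cells$to %in% milestones)
  if (any(bad)) abort("Cells reference unknown milestones.")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (!all(key(cells$from, cells$to) %in% key(edges$from, edges$to))) {
    abort("Cells are assigned to edges absent from the milestone network.")
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = milestones))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    abort(sprintf("Milestone network is disconnected (%d components: %s).",
                  comp$no,
                  paste(tapply(names(comp$membership), comp$membership,
                               function(x) paste(x, collapse = "+")),
                        collapse = " | ")))
  }
  structure(list(milestones = milestones, edges = edges, cells = cells),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("<trajectory_model> %d milestones, %d edges, %d cells\n",
              length(x$milestones), nrow(x$edges), nrow(x$cells)))
  invisible(x)
}

#' Read a trajectory model from JSON
#'
#' Schema: `{"milestones": [...], "edges": [{"from","to","length"}],
#' "cells": [{"id","edge_from","edge_to","progress"}]}` — the common
#' abstraction trajectory-inference wrappers rectify their output to.
#'
#' @param path JSON file path.
#' @return A [trajectory_model()].
#' @export
read_trajectory <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as_tibble(j$cells)
  names(cells)[names(cells) == "id"] <- "cell_id"
  names(cells)[names(cells) == "edge_from"] <- "from"
  names(cells)[names(cells) == "edge_to"] <- "to"
  trajectory_model(j$milestones, as_tibble(j$edges), cells)
}

#' Write a trajectory model to JSON
#' @param traj A [trajectory_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cells <- traj$cells
  out <- list(
    milestones = traj$milestones,
    edges = traj$edges,
    cells = data.frame(id = cells$cell_id, edge_from = cells$from,
                       edge_to = cells$to, progress = cells$progress)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Geodesic cell-cell distances along a trajectory
#'
#' The distance between two cells is the shortest path length through the
#' milestone network between their positions; cells sharing an edge may
#' also connect directly along that edge.
#'
#' @param traj A [trajectory_model()].
#' @return Symmetric cells x cells distance matrix with cell-id dimnames.
#' @export
geodesic_distances <- function(traj) {
  cells <- traj$cells
  n <- nrow(cells)
  g <- igraph::graph_from_data_frame(traj$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = traj$milestones))
  D <- igraph::distances(g, weights = traj$edges$length)
  D <- D[traj$milestones, traj$milestones]

  len <- cells$progress * 0
  ekey <- paste(traj$edges$from, traj$edges$to)
  ekey2 <- paste(traj$edges$to, traj$edges$from)
  li <- match(paste(cells$from, cells$to), ekey)
  li2 <- match(paste(cells$from, cells$to), ekey2)
  len <- ifelse(is.na(li), traj$edges$length[li2], traj$edges$length[li])

  d_from <- cells$progress * len        # distance back to the `from` milestone
  d_to <- (1 - cells$progress) * len    # distance on to the `to` milestone

  # cell -> every milestone, exiting through either endpoint
  c2m <- pmin(d_from + D[cells$from, , drop = FALSE],
              d_to + D[cells$to, , drop = FALSE])

  # cell-cell: exit cell i through either endpoint, then geodesic to cell j
  t1 <- sweep(t(c2m[, cells$from, drop = FALSE]), 1L, d_from, `+`)
  t2 <- sweep(t(c2m[, cells$to, drop = FALSE]), 1L, d_to, `+`)
  # entry [i, j] of t(c2m[, cells$from]) is c2m[j, from_i]; result is d(i, j)
  out <- pmin(t1, t2)

  # cells on the same (undirected) edge can connect directly along it
  ukey <- paste(pmin(cells$from, cells$to), pmax(cells$from, cells$to))
  same <- outer(ukey, ukey, `==`)
  # signed position along the undirected edge (progress measured from the
  # lexicographically smaller endpoint)
  pos <- ifelse(cells$from <= cells$to, d_from, d_to)
  direct <- abs(outer(pos, pos, `-`))
  out[same] <- pmin(out[same], direct[same])

  out <- pmin(out, t(out))
  diag(out) <- 0
  dimnames(out) <- list(cells$cell_id, cells$cell_id)
  out
}

#' KNN graph from trajectory geodesic distances
#'
#' @param traj A [trajectory_model()].
#' @param K Neighbourhood size, `NULL` for `ceiling(sqrt(N))`.
#' @param bandwidth See [weights_from_distances()].
#' @return A `neighbor_graph` over the trajectory's cells.
#' @export
knn_from_trajectory <- function(traj, K = NULL,
                                bandwidth = c("squared", "literal")) {
  bandwidth <- match.arg(bandwidth)
  knn_from_distances(geodesic_distances(traj), K = K, bandwidth = bandwidth)
}
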