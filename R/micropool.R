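# Micro-pooling: merge transcriptionally similar cells into small pools
# whose averaged profiles stand in for single cells, reducing N for the
# graph and null computations.  Procedure: detection + variable-gene
# filters, 20-dim PCA, square-root-K KNN, Louvain community detection,
# then K-means splitting of oversized communities until every pool holds
# at most P cells; pooled expression is the per-gene mean over members.

#' Detection and variable-gene filters
#'
#' Keeps genes detected (nonzero) in at least `min_detection` of cells,
#' then selects over-dispersed genes by the Fano factor (variance / mean):
#' genes are binned into `n_bins` mean-expression quantile bins and kept
#' when their Fano factor exceeds the bin median by more than `n_mads`
#' MADs.  If the dispersion filter degenerates (e.g. near-identical genes),
#' the detection-filtered matrix is returned with a warning.
#'
#' @param expr Genes x cells matrix.
#' @param min_detection Minimum detected fraction (default 0.1).
#' @param n_bins Mean-expression bins for the Fano filter (default 30).
#' @param n_mads MAD threshold above the bin median (default 2).
#' @return The filtered matrix.
#' @export
filter_genes <- function(expr, min_detection = 0.1, n_bins = 30, n_mads = 2) {
  check_expression(expr)
  detected <- rowMeans(expr != 0) >= min_detection
  expr <- expr[detected, , drop = FALSE]
  if (nrow(expr) < 2L) abort("Fewer than 2 genes pass the detection filter.")
  mu <- rowMeans(expr)
  v <- apply(expr, 1L, stats::var)
  fano <- ifelse(mu > 0, v / mu, 0)
  if (all(fano == fano[1L]) || all(v == 0)) {
    warn("Dispersion filter degenerate; returning detection-filtered genes only.")
    return(expr)
  }
  n_bins <- min(n_bins, max(1L, floor(nrow(expr) / 2L)))
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  keep <- logical(nrow(expr))
  for (b in unique(bins)) {
    i <- bins == b
    thr <- median(fano[i]) + n_mads * stats::mad(fano[i])
    keep[i] <- fano[i] > thr
  }
  if (sum(keep) < 2L) {
    warn("Dispersion filter kept < 2 genes; returning detection-filtered genes only.")
    return(expr)
  }
  expr[keep, , drop = FALSE]
}

# Split any cluster larger than P into ceiling(S / P) K-means pieces on the
# latent coordinates, recursively until the bound holds.
split_to_size <- function(membership, coords, P) {
  repeat {
    sizes <- table(membership)
    big <- names(sizes)[sizes > P]
    if (length(big) == 0L) break
    nxt <- max(as.integer(factor(membership)))
    for (cl in big) {
      i <- which(membership == cl)
      k <- ceiling(length(i) / P)
      pieces <- if (k >= length(i)) {
        seq_along(i)
      } else {
        kmeans(coords[i, , drop = FALSE], centers = k, nstart = 5,
               iter.max = 50)$cluster
      }
      membership[i] <- paste0(cl, ".", pieces)
    }
  }
  membership
}

#' Micro-pool an expression matrix
#'
#' @param expr Genes x cells matrix (normalized, log scale).
#' @param P Maximum cells per pool (default 20).
#' @param seed Seed for PCA-downstream clustering.
#' @param n_dims PCA dimensionality for the pooling space (default 20).
#' @param K Neighbourhood size for the Louvain graph; default
#'   `ceiling(sqrt(N))`.
#' @param latent Optional precomputed cells x dims coordinates; when given,
#'   gene filtering and PCA are skipped.
#' @return A `micropool` object: list with `assignment` (tibble `cell_id`,
#'   `pool`), `pooled` (genes x pools matrix of member means over all genes
#'   of `expr`), `sizes`, and `P`.
#' @export
micropool <- function(expr, P = 20, seed = 1, n_dims = 20, K = NULL,
                      latent = NULL) {
  check_expression(expr)
  n <- ncol(expr)
  if (P >= n) {
    assignment <- tibble(cell_id = colnames(expr), pool = "pool1")
    pooled <- matrix(rowMeans(expr), ncol = 1L,
                     dimnames = list(rownames(expr), "pool1"))
    return(structure(list(assignment = assignment, pooled = pooled,
                          sizes = stats::setNames(n, "pool1"), P = P),
                     class = "micropool"))
  }
  if (is.null(latent)) {
    filtered <- filter_genes(expr)
    latent <- pca_latent(filtered, n_dims = n_dims)
  }
  K <- K %||% default_k(n)
  membership <- with_seed(seed, {
    graph <- knn_from_latent(latent, K = K)
    edges <- graph_edges(graph)
    ig <- igraph::graph_from_data_frame(edges[, c("from", "to", "weight")],
                                        directed = FALSE,
                                        vertices = data.frame(name = graph$cell_ids))
    comm <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight)
    mem <- igraph::membership(comm)[graph$cell_ids]
    if (all(table(mem) == 1L)) {
      warn("Louvain produced only singletons; falling back to K-means pooling.")
      mem <- kmeans(latent, centers = ceiling(n / P), nstart = 5,
                    iter.max = 50)$cluster
    }
    split_to_size(as.character(mem), latent, P)
  })
  pool_ids <- paste0("pool", as.integer(factor(membership, levels = unique(membership))))
  assignment <- tibble(cell_id = colnames(expr), pool = pool_ids)
  pools <- unique(pool_ids)
  pooled <- vapply(pools, function(p) {
    rowMeans(expr[, pool_ids == p, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(pooled) <- list(rownames(expr), pools)
  structure(list(assignment = assignment, pooled = pooled,
                 sizes = stats::setNames(as.integer(table(pool_ids)[pools]), pools),
                 P = P),
            class = "micropool")
}

#' @export
print.micropool <- function(x, ...) {
  cat(sprintf("<micropool> %d cells -> %d pools (max size %d, bound P = %d)\n",
              nrow(x$assignment), length(x$sizes), max(x$sizes), x$P))
  invisible(x)
}

#' Pool a meta-data table to match a micro-pool assignment
#'
#' Numeric columns are averaged within pools; categorical columns take the
#' modal label (ties broken by level order).
#'
#' @param meta Tibble with `cell_id` plus annotation columns.
#' @param pools A `micropool` object.
#' @return Tibble with one row per pool, `cell_id` holding the pool id.
#' @export
pool_metadata <- function(meta, pools) {
  j <- dplyr::inner_join(meta, pools$assignment, by = "cell_id")
  j |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(dplyr::across(
      -dplyr::any_of("cell_id"),
      function(x) {
        if (is.numeric(x)) mean(x) else names(sort(table(x), decreasing = TRUE))[1L]
      }
    ), .groups = "drop") |>
    dplyr::rename(cell_id = "pool")
}

#' Within-pool coherence ratios
#'
#' For an independent per-cell feature matrix (e.g. protein abundances in a
#' joint protein/RNA assay), quantifies how homogeneous pools are: the
#' ratio `r = sigma_pool / sigma_population` of the within-pool standard
#' deviation to the population standard deviation of each feature, using
#' population (1/n) variances.  Ratios near 0 mean pools are internally
#' coherent; random pools give ratios near 1.  Singleton pools have zero
#' within-variance and are flagged.
#'
#' @param features Features x cells matrix with cell colnames.
#' @param pools A `micropool` object (or a tibble `cell_id`, `pool`).
#' @return Tibble `feature`, `pool`, `size`, `ratio`, `singleton`.
#' @export
coherence_ratios <- function(features, pools) {
  assignment <- if (inherits(pools, "micropool")) pools$assignment else pools
  idx <- match(assignment$cell_id, colnames(features))
  if (anyNA(idx)) abort("Pool assignment references cells absent from `features`.")
  pop_sd <- apply(features[, idx, drop = FALSE], 1L, function(x) sqrt(pop_var(x)))
  if (any(pop_sd == 0)) {
    abort(sprintf("Features with zero population variance: %s",
                  paste(rownames(features)[pop_sd == 0], collapse = ", ")))
  }
  res <- purrr::map(unique(assignment$pool), function(p) {
    cells <- assignment$cell_id[assignment$pool == p]
    sub <- features[, match(cells, colnames(features)), drop = FALSE]
    within_sd <- apply(sub, 1L, function(x) sqrt(pop_var(x)))
    tibble(feature = rownames(features), pool = p, size = length(cells),
           ratio = unname(within_sd / pop_sd), singleton = length(cells) == 1L)
  })
  dplyr::bind_rows(res)
}
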