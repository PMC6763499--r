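# End-to-end orchestration: normalize -> (optional micro-pooling) ->
# score -> graph -> autocorrelation (+ meta-data tests) -> optional
# label-based differential tests and latent-component annotation.

#' Run the full signature-annotation pipeline
#'
#' @param expr Genes x cells expression matrix.  Raw counts when
#'   `normalize` is `"median_umi"` or `"cpm"`; already-normalized log-scale
#'   values with `normalize = "none"`.
#' @param signatures List of [gene_signature()] objects (e.g. [read_gmt()]).
#' @param latent Optional cells x dims latent space; defaults to a PCA of
#'   the normalized matrix ([pca_latent()]).  Ignored when `trajectory` is
#'   given.
#' @param trajectory Optional [trajectory_model()]; the graph is then built
#'   from geodesic distances instead of the latent space.
#' @param meta Optional tibble (`cell_id` + columns).  Numeric columns are
#'   tested with the permutation autocorrelation test, categorical columns
#'   with the chi-squared/Cramer's V test and as 1-vs-all differential
#'   stratifications.
#' @param normalize Normalization mode, see [normalize_expression()].
#' @param K Neighbourhood size (`NULL` = `ceiling(sqrt(N))`).
#' @param bandwidth Kernel dialect, see [weights_from_distances()].
#' @param n_backgrounds Random signatures per background group.
#' @param n_permutations Permutations for numeric meta-data tests.
#' @param pool_size Optional micro-pooling bound `P`; when set, the
#'   analysis runs on pooled profiles ([micropool()]) and pooled meta-data.
#' @param n_latent_dims PCA dimensionality when `latent` is computed here.
#' @param seed One seed governing backgrounds, permutations and pooling.
#' @return A `sigscape_result` with tibble components `autocorrelation`,
#'   `meta_numeric`, `meta_categorical`, `differential`, `components`, the
#'   `scores` object, the `graph`, and the run `config`.
#' @export
sigscape <- function(expr, signatures, latent = NULL, trajectory = NULL,
                     meta = NULL, normalize = c("none", "median_umi", "cpm"),
                     K = NULL, bandwidth = c("squared", "literal"),
                     n_backgrounds = 500, n_permutations = 1000,
                     pool_size = NULL, n_latent_dims = 20, seed = 1) {
  normalize <- match.arg(normalize)
  bandwidth <- match.arg(bandwidth)
  config <- list(normalize = normalize, K = K, bandwidth = bandwidth,
                 n_backgrounds = n_backgrounds,
                 n_permutations = n_permutations, pool_size = pool_size,
                 n_latent_dims = n_latent_dims, seed = seed,
                 mode = if (!is.null(trajectory)) "trajectory" else "latent")
  if (normalize != "none") {
    expr <- normalize_expression(expr, mode = normalize, log1p = TRUE)
  }
  pools <- NULL
  if (!is.null(pool_size)) {
    if (!is.null(trajectory)) abort("Micro-pooling is not defined for trajectory inputs.")
    pools <- micropool(expr, P = pool_size, seed = seed)
    expr <- pools$pooled
    if (!is.null(meta)) meta <- pool_metadata(meta, pools)
    latent <- NULL  # recomputed on pooled profiles
  }
  if (!is.null(meta)) {
    meta <- meta[match(colnames(expr), meta$cell_id), , drop = FALSE]
    if (anyNA(meta$cell_id)) abort("Meta-data is missing some cells of the matrix.")
  }
  if (is.null(trajectory)) {
    if (is.null(latent)) latent <- pca_latent(expr, n_dims = n_latent_dims)
    latent <- latent[colnames(expr), , drop = FALSE]
    graph <- knn_from_latent(latent, K = K, bandwidth = bandwidth)
  } else {
    graph <- knn_from_trajectory(trajectory, K = K, bandwidth = bandwidth)
    if (!identical(graph$cell_ids, colnames(expr))) {
      ord <- match(colnames(expr), graph$cell_ids)
      if (anyNA(ord)) abort("Trajectory cells do not match the expression matrix.")
      graph <- knn_from_distances(
        geodesic_distances(trajectory)[colnames(expr), colnames(expr)],
        K = K, bandwidth = bandwidth)
    }
    latent <- NULL
  }
  scores <- score_signatures(expr, signatures, correct = TRUE)
  kept <- rownames(scores$scores)
  sig_kept <- signatures[vapply(signatures, `[[`, character(1), "name") %in% kept]
  observed <- autocorrelation_cprime(scores, graph)
  bg <- build_backgrounds(sig_kept, rownames(expr),
                          n_per_group = n_backgrounds, seed = seed)
  bg <- background_null_cprime(bg, expr, graph)
  autocorr <- empirical_pvalues(observed, bg)

  meta_numeric <- NULL
  meta_categorical <- NULL
  differential <- NULL
  if (!is.null(meta)) {
    num_cols <- setdiff(names(meta)[vapply(meta, is.numeric, logical(1))], "cell_id")
    cat_cols <- setdiff(names(meta)[!vapply(meta, is.numeric, logical(1))], "cell_id")
    if (length(num_cols) > 0L) {
      ok <- stats::complete.cases(meta[num_cols])
      if (all(ok)) {
        meta_numeric <- metadata_autocorrelation(meta, graph, n_perm = n_permutations,
                                                 seed = seed, columns = num_cols)
      }
    }
    cat_cols <- cat_cols[vapply(cat_cols, function(cl)
      nlevels(as.factor(meta[[cl]])) >= 2L, logical(1))]
    if (length(cat_cols) > 0L) {
      meta_categorical <- categorical_autocorrelation(meta, graph, columns = cat_cols)
      differential <- purrr::map(cat_cols, function(cl) {
        dplyr::mutate(one_vs_all(scores, meta[[cl]]), stratification = cl,
                      .before = 1L)
      }) |> dplyr::bind_rows()
    }
  }
  components <- if (!is.null(latent)) {
    annotate_components(latent, scores, meta)
  }
  structure(
    list(autocorrelation = autocorr, meta_numeric = meta_numeric,
         meta_categorical = meta_categorical, differential = differential,
         components = components, scores = scores, graph = graph,
         latent = latent, pools = pools, config = config),
    class = "sigscape_result"
  )
}

#' @export
print.sigscape_result <- function(x, ...) {
  cat("<sigscape_result>\n")
  cat(sprintf("  %d signatures x %d cells, K = %d (%s graph)\n",
              nrow(x$scores$scores), ncol(x$scores$scores), x$graph$K,
              x$config$mode))
  top <- dplyr::arrange(x$autocorrelation, dplyr::desc(.data$c_prime))
  cat(sprintf("  top autocorrelated signature: %s (C' = %.3f, FDR = %.3g)\n",
              top$signature[1L], top$c_prime[1L], top$fdr[1L]))
  if (!is.null(x$pools)) {
    cat(sprintf("  micro-pooled to %d pools (P = %d)\n",
                length(x$pools$sizes), x$pools$P))
  }
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x A `sigscape_result`.
#' @param type Which table: `"autocorrelation"` (default), `"differential"`,
#'   `"meta_numeric"`, `"meta_categorical"` or `"components"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.sigscape_result <- function(x, type = c("autocorrelation", "differential",
                                             "meta_numeric", "meta_categorical",
                                             "components"), ...) {
  type <- match.arg(type)
  out <- x[[type]]
  if (is.null(out)) abort(sprintf("No '%s' results in this run.", type))
  out
}

#' One-row summary of a pipeline result
#'
#' @param x A `sigscape_result`.
#' @param ... Unused.
#' @return Tibble with run dimensions and hit counts at FDR < 0.05.
#' @export
glance.sigscape_result <- function(x, ...) {
  tibble(
    n_signatures = nrow(x$scores$scores),
    n_cells = ncol(x$scores$scores),
    K = x$graph$K,
    mode = x$config$mode,
    n_autocorrelated = sum(x$autocorrelation$fdr < 0.05, na.rm = TRUE),
    n_differential = if (is.null(x$differential)) NA_integer_ else
      sum(x$differential$fdr < 0.05, na.rm = TRUE),
    max_c_prime = max(x$autocorrelation$c_prime, na.rm = TRUE)
  )
}

#' Plot a pipeline result
#'
#' `"autocorrelation"`: per-signature C' against -log10 FDR;
#' `"differential"`: AUROC per (signature, group); `"categorical"`:
#' Cramer's V per variable.
#'
#' @param object A `sigscape_result`.
#' @param type Panel to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigscape_result <- function(object,
                                     type = c("autocorrelation",
                                              "differential", "categorical"),
                                     ...) {
  type <- match.arg(type)
  if (type == "autocorrelation") {
    d <- object$autocorrelation
    ggplot2::ggplot(d, ggplot2::aes(x = .data$c_prime,
                                    y = -log10(.data$fdr),
                                    label = .data$signature)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
      ggplot2::labs(x = "C' (local autocorrelation)", y = "-log10 FDR") +
      ggplot2::theme_minimal()
  } else if (type == "differential") {
    d <- tidy(object, "differential")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$auroc,
                                    colour = .data$fdr < 0.05)) +
      ggplot2::geom_jitter(width = 0.15, height = 0) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
      ggplot2::labs(x = NULL, y = "AUROC", colour = "FDR < 0.05") +
      ggplot2::theme_minimal()
  } else {
    d <- tidy(object, "meta_categorical")
    ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$variable,
                                                       .data$cramers_v),
                                    y = .data$cramers_v)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "Cramer's V") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-cell signature scores on a 2-D embedding
#'
#' @param result A `sigscape_result` (run in latent mode).
#' @param signature Signature name to colour by.
#' @param embedding Optional cells x 2 matrix; defaults to the first two
#'   latent dimensions of the run.
#' @return A ggplot object.
#' @export
plot_signature_scores <- function(result, signature, embedding = NULL) {
  emb <- embedding %||% result$latent[, 1:2, drop = FALSE]
  if (is.null(emb)) abort("No embedding available; supply one.")
  s <- result$scores$scores[signature, rownames(emb)]
  d <- tibble(dim1 = emb[, 1L], dim2 = emb[, 2L], score = s)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                  colour = .data$score)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(title = signature, x = "dim 1", y = "dim 2",
                  colour = "score") +
    ggplot2::theme_minimal()
}

#' Cluster signatures by score similarity
#'
#' Groups signatures whose per-cell scores are strongly correlated in
#' absolute value: average-linkage hierarchical clustering on the
#' `1 - |r|` distance, cut at `h`.
#'
#' @param scores A `signature_scores` object or matrix.
#' @param h Cut height on the `1 - |r|` scale (default 0.5).
#' @return Tibble `signature`, `score_cluster`.
#' @export
cluster_signatures <- function(scores, h = 0.5) {
  m <- if (inherits(scores, "signature_scores")) scores$scores else as.matrix(scores)
  if (nrow(m) < 2L) return(tibble(signature = rownames(m), score_cluster = 1L))
  r <- suppressWarnings(stats::cor(t(m)))
  r[!is.finite(r)] <- 0
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = "average")
  tibble(signature = rownames(m),
         score_cluster = as.integer(stats::cutree(hc, h = h)))
}
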