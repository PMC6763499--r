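# Local-structure test for discrete meta-data (batch, donor, cluster).
# Geary's C needs numeric values, so categorical variables are handled by
# aggregating each cell's weighted neighbour label distribution into a
# square contingency table and testing it against independence.

#' Weighted local label proportions
#'
#' For each cell i and level m, the kernel-weighted count of level-m
#' neighbours: `c_im = sum_j w_ij * I(label_j == m)`.  Rows are left
#' unnormalized, so each row sums to the cell's total neighbour weight.
#'
#' @param labels Per-cell label vector (factor or character), ordered like
#'   the graph's cells; every cell must be labelled.
#' @param graph A `neighbor_graph`.
#' @return Cells x levels numeric matrix.
#' @export
local_proportions <- function(labels, graph) {
  n <- nrow(graph$index)
  if (length(labels) != n) abort("`labels` length does not match the graph.")
  if (anyNA(labels)) {
    abort(sprintf("Unlabelled cells: %s",
                  paste(graph$cell_ids[is.na(labels)], collapse = ", ")))
  }
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) abort("Need at least 2 label levels.")
  props <- matrix(0, n, nlevels(labels),
                  dimnames = list(graph$cell_ids, levels(labels)))
  li <- as.integer(labels)
  for (k in seq_len(graph$K)) {
    lv <- li[graph$index[, k]]
    w <- graph$weight[, k]
    for (m in seq_len(nlevels(labels))) {
      sel <- lv == m
      props[sel, m] <- props[sel, m] + w[sel]
    }
  }
  props
}

#' Aggregate local proportions into a square contingency table
#'
#' Row `l` of the table is the summed local label distribution over the
#' cells carrying label `l`: `X_lm = sum_i c_im * I(label_i == l)`.
#'
#' @param props Cells x levels matrix from [local_proportions()].
#' @param labels The same per-cell labels.
#' @return Levels x levels numeric matrix.
#' @export
contingency_from_proportions <- function(props, labels) {
  labels <- as.factor(labels)
  if (!all(levels(labels) %in% colnames(props))) {
    abort("Label level missing from the proportion matrix columns.")
  }
  X <- rowsum(props, labels)
  X <- X[levels(labels), levels(labels), drop = FALSE]
  X
}

#' Chi-squared test and Cramer's V of a local-label contingency table
#'
#' Pearson chi-squared against independence on the (fractional, weighted)
#' table, with `dof = (L - 1)^2` for `L` levels, and effect size
#' `V = sqrt(chi2 / (T * (L - 1)))` where `T` is the table total.  V ranges
#' from 0 (labels mixed randomly on the graph) to 1 (neighbourhoods purely
#' of one label).  Empty levels are dropped with a warning.
#'
#' @param X Square contingency table (levels x levels).
#' @return One-row tibble `cramers_v`, `chi2`, `dof`, `p_value`.
#' @export
categorical_test <- function(X) {
  X <- as.matrix(X)
  empty <- rowSums(X) == 0 & colSums(X) == 0
  if (any(empty)) {
    warn(sprintf("Dropping %d empty levels from the contingency table.", sum(empty)))
    X <- X[!empty, !empty, drop = FALSE]
  }
  L <- nrow(X)
  if (L < 2L) abort("Contingency table must have at least 2 levels.")
  total <- sum(X)
  expected <- outer(rowSums(X), colSums(X)) / total
  chi2 <- sum((X - expected)^2 / expected)
  dof <- (L - 1)^2
  v <- sqrt(chi2 / (total * (L - 1)))
  tibble(cramers_v = v, chi2 = chi2, dof = dof,
         p_value = stats::pchisq(chi2, dof, lower.tail = FALSE))
}

#' Autocorrelation of categorical meta-data columns
#'
#' Runs [local_proportions()] -> [contingency_from_proportions()] ->
#' [categorical_test()] per column, with BH correction across the tested
#' columns.  Because the sample sizes of single-cell data make even weak
#' localization significant, results should be ranked by the effect size
#' `cramers_v`, with `p_value` secondary.
#'
#' @param meta Tibble with `cell_id` plus categorical columns, ordered like
#'   the graph.
#' @param graph A `neighbor_graph`.
#' @param columns Columns to test; defaults to all non-numeric columns.
#' @return Tibble `variable`, `cramers_v`, `chi2`, `dof`, `p_value`, `fdr`.
#' @export
categorical_autocorrelation <- function(meta, graph, columns = NULL) {
  if (nrow(meta) != nrow(graph$index)) abort("Meta-data rows do not match the graph.")
  if (is.null(columns)) {
    columns <- names(meta)[!vapply(meta, is.numeric, logical(1))]
    columns <- setdiff(columns, "cell_id")
  }
  if (length(columns) == 0L) abort("No categorical meta-data columns to test.")
  res <- purrr::map(columns, function(cl) {
    labels <- as.factor(meta[[cl]])
    if (nlevels(labels) < 2L) {
      return(tibble(variable = cl, cramers_v = NA_real_, chi2 = NA_real_,
                    dof = NA_real_, p_value = NA_real_))
    }
    props <- local_proportions(labels, graph)
    X <- contingency_from_proportions(props, labels)
    dplyr::bind_cols(tibble(variable = cl), categorical_test(X))
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- bh_adjust(out$p_value)
  out
}
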