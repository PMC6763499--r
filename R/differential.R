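# Label-based mode: which signatures are differential for each group of a
# categorical stratification?  Every (signature, level) pair is tested
# 1-vs-all with the Wilcoxon rank-sum test; the effect size is the
# equivalent AUROC, U / (n1 * n2), computed from average-tie ranks so ties
# contribute half a win.

# AUROC of `x` (in-group) against `y` (out-group) via the Mann-Whitney U.
auroc_from_ranks <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' One-vs-all differential signature tests
#'
#' For every signature and every level of `labels`, compares in-group
#' versus out-group scores with a two-sided Wilcoxon rank-sum test and
#' reports the AUROC effect size.  BH correction is applied across all
#' (signature, level) pairs of the stratification.
#'
#' @param scores A `signature_scores` object or signatures x cells matrix.
#' @param labels Per-cell labels (factor or character) aligned to columns.
#' @return Tibble `signature`, `group`, `auroc`, `p_value`, `fdr`,
#'   `direction` (`"up"` if AUROC > 0.5).  Levels with fewer than 2 cells
#'   are skipped with a warning.
#' @export
one_vs_all <- function(scores, labels) {
  m <- if (inherits(scores, "signature_scores")) scores$scores else as.matrix(scores)
  labels <- as.factor(labels)
  if (length(labels) != ncol(m)) abort("`labels` length does not match the score columns.")
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warn(sprintf("Skipping levels with < 2 cells: %s", paste(small, collapse = ", ")))
  }
  levels_use <- setdiff(levels(labels), small)
  if (length(levels_use) == 0L) abort("No levels with at least 2 cells.")
  res <- purrr::map(levels_use, function(lv) {
    ing <- labels == lv
    purrr::map(seq_len(nrow(m)), function(i) {
      x <- m[i, ing]
      y <- m[i, !ing]
      a <- auroc_from_ranks(x, y)
      p <- if (length(unique(c(x, y))) == 1L) {
        1  # all ties: no evidence either way
      } else {
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
      }
      tibble(signature = rownames(m)[i], group = lv, auroc = a, p_value = p,
             direction = if (a > 0.5) "up" else "down")
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  res$fdr <- bh_adjust(res$p_value)
  res[, c("signature", "group", "auroc", "p_value", "fdr", "direction")]
}

#' One-vs-all differential expression for individual genes
#'
#' The same rank-sum/AUROC machinery applied to single-gene expression
#' rows, BH-corrected within the requested gene family.
#'
#' @param expr Genes x cells matrix.
#' @param labels Per-cell labels aligned to columns.
#' @param genes Genes to test (case-insensitive match); unknown genes are
#'   listed in a warning and skipped.
#' @return Tibble as in [one_vs_all()], with `signature` holding the gene.
#' @export
differential_genes <- function(expr, labels, genes) {
  check_expression(expr)
  idx <- match(toupper(genes), toupper(rownames(expr)))
  if (anyNA(idx)) {
    warn(sprintf("Unknown genes skipped: %s",
                 paste(genes[is.na(idx)], collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0L) abort("None of the requested genes are in the matrix.")
  one_vs_all(expr[idx, , drop = FALSE], labels)
}
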