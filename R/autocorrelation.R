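# Local autocorrelation of signature scores on the cell-cell graph.
#
# The statistic is Geary's C evaluated over the directed stored
# neighbour pairs,
#   C = (N - 1) * sum_i sum_j w_ij (x_i - x_j)^2 / (2 W sum_i (x_i - xbar)^2)
# with x the within-signature average-tie ranks of the corrected scores,
# and C' = 1 - C reported as the effect size (0 = no local autocorrelation,
# 1 = maximal).  Significance comes from an empirical null of random
# signatures matched in size and sign balance, pushed through the identical
# score -> rank -> C' path.

# Geary C for many value vectors at once; x is a (vectors x cells) matrix.
geary_c_many <- function(x, graph) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  stopifnot(n == nrow(graph$index))
  num <- numeric(nrow(x))
  for (k in seq_len(graph$K)) {
    d <- x - x[, graph$index[, k], drop = FALSE]
    num <- num + as.numeric((d * d) %*% graph$weight[, k])
  }
  ss <- rowSums((x - rowMeans(x))^2)
  out <- (n - 1) * num / (2 * graph$W * ss)
  out[ss == 0] <- NA_real_
  unname(out)
}

#' Geary's C of a value vector on a neighbour graph
#'
#' @param values Per-cell numeric vector (length = number of cells in the
#'   graph).  Typically ranks of a corrected signature score.
#' @param graph A `neighbor_graph`.
#' @return The scalar C.  Callers report `C' = 1 - C`.  A constant vector
#'   has no defined autocorrelation and errors.
#' @export
geary_c <- function(values, graph) {
  if (length(values) != nrow(graph$index)) {
    abort("`values` length does not match the graph.")
  }
  if (length(values) < 3L) abort("Need at least 3 cells.")
  if (length(unique(values)) == 1L) {
    abort("Geary's C is undefined for a constant value vector.")
  }
  as.numeric(geary_c_many(matrix(values, nrow = 1L), graph))
}

#' Per-signature autocorrelation effect sizes
#'
#' Rank-transforms each signature's corrected scores (average ranks for
#' ties) and evaluates `C' = 1 - C` on the graph.  Constant score vectors
#' yield `NA` with a reason.
#'
#' @param scores A `signature_scores` object or a signatures x cells matrix.
#' @param graph A `neighbor_graph` over the same cells.
#' @return Tibble with columns `signature`, `c_prime`.
#' @export
autocorrelation_cprime <- function(scores, graph) {
  m <- if (inherits(scores, "signature_scores")) scores$scores else as.matrix(scores)
  if (ncol(m) != nrow(graph$index)) {
    abort("Scores and graph cover different numbers of cells.")
  }
  ranks <- rank_rows(m)
  cc <- geary_c_many(ranks, graph)
  tibble(signature = rownames(m) %||% paste0("s", seq_len(nrow(m))),
         c_prime = 1 - cc)
}

#' Build grouped random-signature backgrounds
#'
#' Input signatures are clustered by `log10(size)` and balance
#' (`n_pos / size`) with seeded k-means into at most `n_groups` groups
#' (default 5).  Each group receives `n_per_group` random signatures drawn
#' uniformly without replacement from the gene universe at the group's
#' centre size and balance; the first `ceiling(balance * size)` sampled
#' genes form the positive set.
#'
#' @param signatures List of [gene_signature()] objects under test.
#' @param gene_universe Character vector of candidate genes (typically
#'   `rownames(expr)`).
#' @param n_per_group Random signatures per group (default 500).
#' @param n_groups Number of background groups (default 5; reduced when
#'   there are fewer distinct signature profiles).
#' @param seed Integer seed governing k-means and sampling.
#' @return A `background_set`: list of groups (centre size/balance and
#'   random signatures) plus the input-signature -> group assignment.
#' @export
build_backgrounds <- function(signatures, gene_universe, n_per_group = 500,
                              n_groups = 5, seed = 1) {
  sizes <- vapply(signatures, sig_size, numeric(1))
  balance <- vapply(signatures, sig_balance, numeric(1))
  feats <- cbind(log10(sizes), balance)
  uniq <- unique(feats)
  k <- min(n_groups, nrow(uniq), length(signatures))
  with_seed(seed, {
    if (nrow(uniq) <= k) {
      # one group per distinct (size, balance) profile; no clustering needed
      centers <- uniq
      assignment <- match(paste(feats[, 1L], feats[, 2L]),
                          paste(uniq[, 1L], uniq[, 2L]))
      k <- nrow(uniq)
    } else {
      km <- kmeans(feats, centers = k, nstart = 10)
      centers <- km$centers
      assignment <- km$cluster
    }
    groups <- lapply(seq_len(k), function(g) {
      size <- round(10^centers[g, 1L])
      size <- max(1L, min(size, length(gene_universe)))
      if (size > length(gene_universe)) {
        warn("Background signature size capped at the universe size.")
      }
      bal <- min(1, max(0, centers[g, 2L]))
      n_pos <- as.integer(ceiling(bal * size))
      sigs <- lapply(seq_len(n_per_group), function(b) {
        genes <- sample(gene_universe, size, replace = FALSE)
        gene_signature(sprintf("bg%d_%d", g, b),
                       positive = genes[seq_len(n_pos)],
                       negative = if (n_pos < size) genes[(n_pos + 1L):size] else character())
      })
      list(center_log10_size = centers[g, 1L], center_balance = bal,
           size = size, n_pos = n_pos, signatures = sigs,
           c_prime_null = NULL)
    })
  })
  structure(list(groups = groups, assignment = assignment,
                 signature_names = vapply(signatures, `[[`, character(1), "name")),
            class = "background_set")
}

#' Compute the null autocorrelation distribution of each background group
#'
#' Background signatures go through the same pipeline as real ones:
#' corrected scoring against `expr`, rank transform, `C'` on `graph`.
#'
#' @param backgrounds A `background_set` from [build_backgrounds()].
#' @param expr Genes x cells matrix the real signatures were scored on.
#' @param graph The `neighbor_graph` used for the observed statistics.
#' @return The `background_set` with `c_prime_null` vectors filled in.
#' @export
background_null_cprime <- function(backgrounds, expr, graph) {
  backgrounds$groups <- lapply(backgrounds$groups, function(g) {
    sc <- score_many(expr, g$signatures, correct = TRUE)
    g$c_prime_null <- autocorrelation_cprime(sc$scores, graph)$c_prime
    g
  })
  backgrounds
}

#' Empirical p-values against the background null
#'
#' For each signature, `p = (x + 1) / (n + 1)` where `x` counts background
#' signatures in its assigned group with an autocorrelation score at least
#' as high (one-sided: only high autocorrelation is of interest), and `n`
#' is the group's null size.  Benjamini-Hochberg correction is applied
#' jointly across the tested signatures.
#'
#' @param observed Tibble from [autocorrelation_cprime()] for the real
#'   signatures (same order as the background assignment).
#' @param backgrounds A `background_set` with nulls filled in
#'   ([background_null_cprime()]).
#' @return Tibble `signature`, `c_prime`, `p_value`, `fdr`,
#'   `background_group`.
#' @export
empirical_pvalues <- function(observed, backgrounds) {
  grp <- backgrounds$assignment
  if (nrow(observed) != length(grp)) {
    abort("Observed results and background assignment differ in length.")
  }
  p <- vapply(seq_len(nrow(observed)), function(i) {
    null <- backgrounds$groups[[grp[i]]]$c_prime_null
    if (is.null(null) || length(null) == 0L) abort("Empty background null; run background_null_cprime() first.")
    if (is.na(observed$c_prime[i])) return(NA_real_)
    (sum(null >= observed$c_prime[i]) + 1) / (length(null) + 1)
  }, numeric(1))
  tibble(signature = observed$signature,
         c_prime = observed$c_prime,
         p_value = p,
         fdr = bh_adjust(p),
         background_group = grp)
}

#' Signature autocorrelation analysis
#'
#' One-stop wrapper: corrected scores -> ranks -> `C'` for every signature,
#' empirical p-values from grouped random-signature backgrounds, and BH
#' FDR across signatures.
#'
#' @param expr Genes x cells matrix (normalized, log scale).
#' @param signatures List of [gene_signature()] objects, or a
#'   `signature_scores` object already computed on `expr`.
#' @param graph A `neighbor_graph` over the cells of `expr`.
#' @param n_backgrounds Random signatures per background group.
#' @param n_groups Number of background groups (default 5).
#' @param seed Seed for background generation.
#' @return Tibble `signature`, `c_prime`, `p_value`, `fdr`,
#'   `background_group`.
#' @export
signature_autocorrelation <- function(expr, signatures, graph,
                                      n_backgrounds = 500, n_groups = 5,
                                      seed = 1) {
  if (inherits(signatures, "signature_scores")) {
    abort("Pass the signature list; scores are recomputed for the null path.")
  }
  sc <- score_signatures(expr, signatures, correct = TRUE)
  kept <- rownames(sc$scores)
  signatures <- signatures[vapply(signatures, `[[`, character(1), "name") %in% kept]
  observed <- autocorrelation_cprime(sc, graph)
  bg <- build_backgrounds(signatures, rownames(expr),
                          n_per_group = n_backgrounds, n_groups = n_groups,
                          seed = seed)
  bg <- background_null_cprime(bg, expr, graph)
  empirical_pvalues(observed, bg)
}

#' Autocorrelation of numeric meta-data columns
#'
#' Numeric per-cell covariates (library size, detection ratio, externally
#' computed scores) are rank-transformed and tested with the same `C'`
#' statistic; significance comes from a per-column permutation test:
#' `p = (x + 1) / (n_perm + 1)` with `x` the number of label permutations
#' reaching an equal or higher `C'`.  Optionally permutes only within the
#' strata of a grouping column, which removes between-stratum signal (a
#' negative-control design for e.g. donor effects).
#'
#' @param meta Tibble with a `cell_id` column (ordered like the graph) and
#'   numeric columns to test.
#' @param graph A `neighbor_graph`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @param columns Columns to test; default all numeric columns.
#' @param within Optional name of a categorical column; permutations are
#'   then performed within its levels.
#' @return Tibble `variable`, `c_prime`, `p_value`, `fdr` (BH within this
#'   family).
#' @export
metadata_autocorrelation <- function(meta, graph, n_perm = 1000, seed = 1,
                                     columns = NULL, within = NULL) {
  n <- nrow(graph$index)
  if (nrow(meta) != n) abort("Meta-data rows do not match the graph cells.")
  if (is.null(columns)) {
    columns <- names(meta)[vapply(meta, is.numeric, logical(1))]
    columns <- setdiff(columns, "cell_id")
  }
  if (length(columns) == 0L) abort("No numeric meta-data columns to test.")
  strata <- if (!is.null(within)) as.factor(meta[[within]]) else NULL
  res <- purrr::map(columns, function(cl) {
    x <- meta[[cl]]
    if (length(unique(x)) == 1L) {
      return(tibble(variable = cl, c_prime = NA_real_, p_value = NA_real_))
    }
    r <- rank(x, ties.method = "average")
    obs <- 1 - geary_c_many(matrix(r, nrow = 1L), graph)
    perm <- with_seed(seed, {
      pm <- matrix(0, n_perm, n)
      for (b in seq_len(n_perm)) {
        pm[b, ] <- if (is.null(strata)) sample(r) else permute_within(r, strata)
      }
      pm
    })
    null <- 1 - geary_c_many(perm, graph)
    p <- (sum(null >= as.numeric(obs)) + 1) / (n_perm + 1)
    tibble(variable = cl, c_prime = as.numeric(obs), p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$fdr <- bh_adjust(out$p_value)
  out
}

permute_within <- function(x, strata) {
  out <- x
  for (lv in levels(strata)) {
    i <- which(strata == lv)
    out[i] <- x[i][sample.int(length(i))]
  }
  out
}
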