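# Per-cell signature scores and the random-signature correction.
#
# The raw score of signature s in cell j is
#   s_j = (sum_{g in G_pos} e_gj - sum_{g in G_neg} e_gj) / (n + m)
# with n = |G_pos|, m = |G_neg| counted over the genes actually present in
# the matrix.  Scores are then z-normalized against the analytic moments of
# a random signature of the same size and balance drawn from the matrix's
# gene universe:
#   E[R_j]   = ((n - m) / (n + m)) * ebar_j
#   var(R_j) = sigma2_j / (n + m)
# where ebar_j and sigma2_j are the mean and population variance of cell
# j's expression values over ALL genes.

# Mean and population variance of each cell's expression over genes.
cell_moments <- function(expr) {
  ebar <- colMeans(expr)
  sigma2 <- colMeans(expr^2) - ebar^2
  sigma2 <- pmax(sigma2, 0)
  list(ebar = ebar, sigma2 = sigma2)
}

#' Raw signature score per cell
#'
#' Mean expression of the positive genes minus mean of the negative genes,
#' jointly normalized by the total number of signature genes found in the
#' matrix (case-insensitive matching; absent genes shrink the denominator).
#'
#' @param expr Genes x cells matrix, normalized log-scale expression.
#' @param sig A [gene_signature()].
#' @return Named per-cell vector with attributes `n_pos` and `n_neg`, the
#'   counts of genes actually used.
#' @export
raw_score <- function(expr, sig) {
  check_expression(expr)
  ip <- match_genes(sig$positive, rownames(expr))
  im <- match_genes(sig$negative, rownames(expr))
  n <- length(ip)
  m <- length(im)
  if (n + m == 0L) {
    abort(sprintf("Signature '%s' shares no genes with the expression matrix.",
                  sig$name))
  }
  pos <- if (n > 0L) colSums(expr[ip, , drop = FALSE]) else 0
  neg <- if (m > 0L) colSums(expr[im, , drop = FALSE]) else 0
  s <- (pos - neg) / (n + m)
  names(s) <- colnames(expr)
  attr(s, "n_pos") <- n
  attr(s, "n_neg") <- m
  s
}

#' Correct a raw score against the random-signature moments
#'
#' Subtracts the expected score of a random signature with the same gene
#' counts and divides by its standard deviation, cell by cell.  Cells whose
#' expression is constant across genes (zero variance) cannot be corrected;
#' their score is set to 0 with a warning.
#'
#' @param raw Per-cell raw score vector, aligned to `expr` columns.
#' @param expr The expression matrix the score was computed from.
#' @param n_pos,n_neg Counts of positive/negative genes used.  Default to
#'   the attributes set by [raw_score()].
#' @return Per-cell corrected score vector.
#' @export
corrected_score <- function(raw, expr, n_pos = attr(raw, "n_pos"),
                            n_neg = attr(raw, "n_neg")) {
  if (is.null(n_pos) || is.null(n_neg)) {
    abort("Supply n_pos/n_neg (or a vector produced by raw_score()).")
  }
  mom <- cell_moments(expr)
  total <- n_pos + n_neg
  e_r <- ((n_pos - n_neg) / total) * mom$ebar
  v_r <- mom$sigma2 / total
  out <- (as.numeric(raw) - e_r) / sqrt(v_r)
  flat <- mom$sigma2 == 0
  if (any(flat)) {
    warn(sprintf("%d cells have constant expression; corrected score set to 0.",
                 sum(flat)))
    out[flat] <- 0
  }
  names(out) <- colnames(expr)
  out
}

# Vectorized scorer: all signatures at once through a sparse +/-1
# coefficient matrix.  Returns the signatures x cells score matrix plus the
# per-signature used counts; signatures with no usable genes come back in
# `dropped`.
score_many <- function(expr, signatures, correct = TRUE) {
  gene_up <- toupper(rownames(expr))
  n_cells <- ncol(expr)
  used <- lapply(signatures, function(s) {
    list(pos = match(toupper(s$positive), gene_up),
         neg = match(toupper(s$negative), gene_up))
  })
  n_pos <- vapply(used, function(u) sum(!is.na(u$pos)), integer(1))
  n_neg <- vapply(used, function(u) sum(!is.na(u$neg)), integer(1))
  keep <- n_pos + n_neg > 0L
  dropped <- tibble(
    signature = vapply(signatures, `[[`, character(1), "name")[!keep],
    reason = rep("no signature genes present in matrix", sum(!keep))
  )
  signatures <- signatures[keep]
  used <- used[keep]
  n_pos <- n_pos[keep]
  n_neg <- n_neg[keep]
  if (length(signatures) == 0L) {
    return(list(scores = matrix(0, 0, n_cells), n_pos = integer(), n_neg = integer(),
                names = character(), dropped = dropped))
  }
  ii <- rep(seq_along(used), vapply(used, function(u)
    sum(!is.na(u$pos)) + sum(!is.na(u$neg)), integer(1)))
  jj <- unlist(lapply(used, function(u) c(u$pos[!is.na(u$pos)], u$neg[!is.na(u$neg)])))
  xx <- unlist(lapply(used, function(u)
    c(rep(1, sum(!is.na(u$pos))), rep(-1, sum(!is.na(u$neg))))))
  coef <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                               dims = c(length(used), nrow(expr)))
  raw <- as.matrix(coef %*% expr) / (n_pos + n_neg)
  if (correct) {
    mom <- cell_moments(expr)
    total <- n_pos + n_neg
    e_r <- outer((n_pos - n_neg) / total, mom$ebar)
    sd_r <- sqrt(outer(1 / total, mom$sigma2))
    raw <- (raw - e_r) / sd_r
    flat <- mom$sigma2 == 0
    if (any(flat)) raw[, flat] <- 0
  }
  rownames(raw) <- vapply(signatures, `[[`, character(1), "name")
  colnames(raw) <- colnames(expr)
  list(scores = raw, n_pos = n_pos, n_neg = n_neg,
       names = rownames(raw), dropped = dropped)
}

#' Score a set of signatures across all cells
#'
#' Batch interface: computes raw and (by default) corrected scores for every
#' signature.  Signatures sharing no genes with the matrix are dropped and
#' reported rather than erroring.
#'
#' @param expr Genes x cells matrix, normalized log-scale expression.
#' @param signatures List of [gene_signature()] objects (e.g. from
#'   [read_gmt()]).
#' @param correct Apply the random-signature correction? Default `TRUE`.
#' @return A `signature_scores` object: list with `scores` (signatures x
#'   cells matrix), `n_pos`/`n_neg` used-gene counts, `corrected` flag and a
#'   `dropped` tibble with reason codes.
#' @export
score_signatures <- function(expr, signatures, correct = TRUE) {
  check_expression(expr)
  if (length(signatures) == 0L) abort("Empty signature list.")
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  nms <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort(sprintf("Duplicate signature names: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  res <- score_many(expr, signatures, correct = correct)
  if (nrow(res$dropped) > 0L) {
    warn(sprintf("Dropped %d signatures with no genes in the matrix: %s",
                 nrow(res$dropped), paste(res$dropped$signature, collapse = ", ")))
  }
  if (nrow(res$scores) == 0L) abort("All signatures were dropped.")
  structure(
    list(scores = res$scores, n_pos = res$n_pos, n_neg = res$n_neg,
         corrected = correct, dropped = res$dropped),
    class = "signature_scores"
  )
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("<signature_scores> %d signatures x %d cells (%s)\n",
              nrow(x$scores), ncol(x$scores),
              if (x$corrected) "corrected" else "raw"))
  if (nrow(x$dropped) > 0L) cat(sprintf("  %d signatures dropped\n", nrow(x$dropped)))
  invisible(x)
}

#' @export
as_tibble.signature_scores <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "signature") |>
    tidyr::pivot_longer(-"signature", names_to = "cell_id", values_to = "score")
}

#' Covariance between signature genes and the signature score
#'
#' For each gene in the signature, the covariance across cells between that
#' gene's expression and the per-cell score — used to rank which genes drive
#' a signature's behaviour in this dataset.
#'
#' @param expr Genes x cells matrix.
#' @param scores Per-cell score vector aligned to `expr` columns.
#' @param sig The [gene_signature()] the scores belong to.
#' @return Tibble with columns `gene`, `set` (`"positive"`/`"negative"`) and
#'   `covariance`, sorted by decreasing absolute covariance.
#' @export
gene_signature_covariance <- function(expr, scores, sig) {
  check_expression(expr)
  if (ncol(expr) < 2L) abort("Need at least 2 cells for a covariance.")
  genes <- c(sig$positive, sig$negative)
  set <- rep(c("positive", "negative"),
             c(length(sig$positive), length(sig$negative)))
  idx <- match(toupper(genes), toupper(rownames(expr)))
  present <- !is.na(idx)
  e <- expr[idx[present], , drop = FALSE]
  s <- as.numeric(scores)
  # cov(x, y) = sum(x * (y - ybar)) / (n - 1); centring x is redundant.
  cv <- as.numeric((e %*% (s - mean(s))) / (ncol(expr) - 1L))
  out <- tibble(gene = genes[present], set = set[present], covariance = cv)
  out[order(-abs(out$covariance)), ]
}
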