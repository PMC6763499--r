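#' Read a genes x cells expression matrix
#'
#' Reads normalized (or raw count) expression data from either a
#' tab/comma-separated table or a MatrixMarket sparse triplet file with
#' sidecar gene and cell name files.  Values are returned untouched;
#' normalization is a separate step ([normalize_expression()]).
#'
#' Duplicate gene symbols are resolved by keeping, for each symbol, the row
#' with the highest total signal (a warning reports how many rows were
#' dropped).  Duplicate cell identifiers are an error.
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (by extension), `"mtx"`, `"tsv"` or `"csv"`.
#' @param gene_file,cell_file For MTX input, the one-name-per-line sidecar
#'   files with row (gene) and column (cell) identifiers.  Default to
#'   `<stem>.genes.txt` and `<stem>.cells.txt` next to `path`.
#' @return A dense numeric matrix (genes x cells) with gene rownames and
#'   cell colnames.
#' @seealso [write_expression()], [normalize_expression()]
#' @export
read_expression <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                            gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
      abort(sprintf("Cannot guess format from extension '.%s'; pass `format`.", ext))
    )
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    gene_file <- gene_file %||% paste0(stem, ".genes.txt")
    cell_file <- cell_file %||% paste0(stem, ".cells.txt")
    for (f in c(gene_file, cell_file)) {
      if (!file.exists(f)) abort(sprintf("MTX sidecar file not found: %s", f))
    }
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      abort(sprintf("Malformed MatrixMarket file %s: %s", path, conditionMessage(e)))
    })
    m <- as.matrix(m)
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      abort("Sidecar gene/cell name files do not match the matrix dimensions.")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    delim <- if (format == "csv") "," else "\t"
    # base parser: correctly-rounded strtod (exact double round-trip) and no
    # silent renaming of duplicate column names
    tab <- utils::read.delim(path, sep = delim, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) abort("Expression table needs a gene column plus >=1 cell column.")
    genes <- as.character(tab[[1L]])
    cell_ids <- colnames(tab)[-1L]
    if (anyDuplicated(cell_ids)) abort("Duplicate cell identifiers in expression input.")
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) abort("Non-numeric entries in expression table.")
    dimnames(m) <- list(genes, cell_ids)
  }
  if (anyDuplicated(colnames(m))) abort("Duplicate cell identifiers in expression input.")
  m <- resolve_duplicate_genes(m)
  check_expression(m)
  m
}

# Keep, per duplicated symbol, the row with the largest total count.
resolve_duplicate_genes <- function(m) {
  dup <- duplicated(rownames(m)) | duplicated(rownames(m), fromLast = TRUE)
  if (!any(dup)) return(m)
  totals <- rowSums(m)
  keep <- !logical(nrow(m))
  for (g in unique(rownames(m)[dup])) {
    rows <- which(rownames(m) == g)
    keep[setdiff(rows, rows[which.max(totals[rows])])] <- FALSE
  }
  warn(sprintf("Dropped %d duplicate gene rows (kept highest-total row per symbol).",
               sum(!keep)))
  m[keep, , drop = FALSE]
}

#' Write an expression matrix
#'
#' TSV output round-trips doubles exactly; MTX output writes a sparse
#' triplet file plus `<stem>.genes.txt` / `<stem>.cells.txt` sidecars.
#'
#' @param expr Genes x cells matrix with dimnames.
#' @param path Output path (`.tsv` or `.mtx`).
#' @param format `"auto"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  check_expression(expr)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "mtx") "mtx" else "tsv"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(as.matrix(expr), sparse = TRUE), path)
    writeLines(rownames(expr), paste0(stem, ".genes.txt"))
    writeLines(colnames(expr), paste0(stem, ".cells.txt"))
  } else {
    m <- as.matrix(expr)
    # %.17g guarantees exact double round-trip through strtod
    txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    out <- cbind(gene = rownames(m), txt)
    colnames(out) <- c("gene", colnames(m))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Normalize an expression matrix
#'
#' Library-size normalization of raw counts.  `"median_umi"` scales every
#' cell's total to the median total across cells (the convention used for
#' UMI data); `"cpm"` scales to one million; `"none"` leaves values as-is.
#' Optionally applies `log(x + 1)` afterwards, the scale on which signature
#' scores are defined.
#'
#' Cells with zero total counts cannot be scaled (and break the per-cell
#' variance used by score correction), so they are dropped with a warning.
#'
#' @param expr Genes x cells matrix of non-negative counts (unless
#'   `mode = "none"`).
#' @param mode `"median_umi"`, `"cpm"` or `"none"`.
#' @param log1p Apply `log(x + 1)` after scaling?  Default `TRUE`.
#' @return Normalized matrix, possibly with all-zero cells removed.
#' @export
normalize_expression <- function(expr, mode = c("median_umi", "cpm", "none"),
                                 log1p = TRUE) {
  mode <- match.arg(mode)
  check_expression(expr)
  expr <- as.matrix(expr)
  if (mode != "none") {
    if (any(expr < 0)) abort("Negative values: normalization expects raw counts.")
    totals <- colSums(expr)
    zero <- totals == 0
    if (any(zero)) {
      warn(sprintf("Dropping %d all-zero cells prior to scaling.", sum(zero)))
      expr <- expr[, !zero, drop = FALSE]
      totals <- totals[!zero]
    }
    target <- if (mode == "median_umi") median(totals) else 1e6
    expr <- sweep(expr, 2L, target / totals, `*`)
  }
  if (log1p) expr <- log1p(expr)
  expr
}

#' Read a cell meta-data table
#'
#' Tab-separated table whose first column holds cell identifiers; remaining
#' columns are numeric or categorical per-cell annotations.
#'
#' @param path TSV path.
#' @return A tibble with first column `cell_id`; character columns are kept
#'   as categorical variables, numeric columns as numeric.
#' @export
read_metadata <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) abort("Meta-data table needs a cell-id column plus >=1 variable.")
  names(tab)[1L] <- "cell_id"
  tab$cell_id <- as.character(tab$cell_id)
  if (anyDuplicated(tab$cell_id)) abort("Duplicate cell ids in meta-data.")
  tab
}

#' Read a latent-space table
#'
#' @param path TSV with first column = cell id, remaining columns = latent
#'   dimensions.
#' @return Numeric matrix (cells x dims) with cell rownames.
#' @export
read_latent <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  if (!all(is.finite(m))) abort("Latent coordinates must be finite.")
  m
}

#' Principal-component latent space from expression
#'
#' Convenience pre-step when no external latent space is supplied: PCA of
#' the cells over standardized genes.  Zero-variance genes are dropped
#' before scaling.
#'
#' @param expr Genes x cells matrix (normalized, log scale).
#' @param n_dims Number of components to keep (default 20, capped at the
#'   available rank).
#' @param scale. Standardize genes to unit variance first?  Default `TRUE`.
#' @return Cells x dims matrix of scores with cell rownames.
#' @export
pca_latent <- function(expr, n_dims = 20, scale. = TRUE) {
  check_expression(expr)
  v <- apply(expr, 1L, stats::var)
  keep <- v > 0
  if (!any(keep)) abort("All genes have zero variance; cannot compute PCA.")
  x <- t(expr[keep, , drop = FALSE])      # cells x genes
  x <- scale(x, center = TRUE, scale = scale.)
  n <- nrow(x)
  p <- ncol(x)
  n_dims <- min(n_dims, n - 1L, p)
  # eigendecompose the smaller of the two Gram matrices; scores are
  # identical (up to sign) to the SVD-based principal components
  if (p <= n) {
    ev <- eigen(crossprod(x), symmetric = TRUE)
    coords <- x %*% ev$vectors[, seq_len(n_dims), drop = FALSE]
  } else {
    ev <- eigen(tcrossprod(x), symmetric = TRUE)
    lam <- sqrt(pmax(ev$values[seq_len(n_dims)], 0))
    coords <- sweep(ev$vectors[, seq_len(n_dims), drop = FALSE], 2L, lam, `*`)
  }
  dimnames(coords) <- list(colnames(expr), paste0("PC", seq_len(n_dims)))
  coords
}
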