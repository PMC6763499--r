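#' Construct a gene signature
#'
#' A signature is a named gene set, optionally *signed*: a positive set of
#' genes expected to go up and a negative set expected to go down under the
#' process the signature represents.  Unsigned signatures have an empty
#' negative set.
#'
#' @param name Signature name.
#' @param positive Character vector of positive-set genes.
#' @param negative Character vector of negative-set genes (default none).
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, positive, negative = character()) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(intersect(toupper(positive), toupper(negative))) > 0L) {
    abort(sprintf("Signature '%s': positive and negative sets overlap.", name))
  }
  if (length(positive) + length(negative) < 1L) {
    abort(sprintf("Signature '%s' is empty.", name))
  }
  structure(
    list(name = as.character(name), positive = positive, negative = negative),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d positive / %d negative genes\n",
              x$name, length(x$positive), length(x$negative)))
  invisible(x)
}

sig_size <- function(sig) length(sig$positive) + length(sig$negative)
sig_balance <- function(sig) length(sig$positive) / sig_size(sig)

#' Read gene signatures from a GMT file
#'
#' Standard tab-separated GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Two dialects encode signed signatures:
#' \itemize{
#'   \item a name pair `X_PLUS` / `X_MINUS`, merged into one signed
#'     signature `X`;
#'   \item an inline per-gene suffix `gene,-1` (or `gene,1`) marking
#'     negative (positive) membership.
#' }
#' Lines with fewer than three fields are skipped with a warning.  Gene
#' case is preserved here; matching against an expression matrix is done
#' case-insensitively at scoring time.
#'
#' @param path GMT file path.
#' @return Named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("Empty GMT file: %s", path))
  raw <- list()
  n_skipped <- 0L
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      n_skipped <- n_skipped + 1L
      next
    }
    raw[[fields[1L]]] <- fields[-(1:2)]
  }
  if (n_skipped > 0L) {
    warn(sprintf("Skipped %d GMT lines with fewer than 3 fields.", n_skipped))
  }
  if (length(raw) == 0L) abort(sprintf("No usable signature lines in %s", path))

  sigs <- list()
  done <- character()
  for (nm in names(raw)) {
    if (nm %in% done) next
    base <- sub("_(PLUS|MINUS)$", "", nm)
    plus_nm <- paste0(base, "_PLUS")
    minus_nm <- paste0(base, "_MINUS")
    if (grepl("_(PLUS|MINUS)$", nm) &&
        (plus_nm %in% names(raw) || minus_nm %in% names(raw))) {
      pos <- if (plus_nm %in% names(raw)) strip_suffix(raw[[plus_nm]])$gene else character()
      neg <- if (minus_nm %in% names(raw)) strip_suffix(raw[[minus_nm]])$gene else character()
      sigs[[base]] <- gene_signature(base, pos, neg)
      done <- c(done, plus_nm, minus_nm)
    } else {
      parsed <- strip_suffix(raw[[nm]])
      sigs[[nm]] <- gene_signature(nm,
                                   positive = parsed$gene[parsed$sign >= 0],
                                   negative = parsed$gene[parsed$sign < 0])
      done <- c(done, nm)
    }
  }
  sigs
}

# Parse the "gene,-1" / "gene,1" inline-sign dialect.
strip_suffix <- function(genes) {
  has <- grepl(",-?1$", genes)
  sign <- ifelse(has & grepl(",-1$", genes), -1, 1)
  gene <- sub(",-?1$", "", genes)
  list(gene = gene, sign = sign)
}

#' Write gene signatures to a GMT file
#'
#' Signed signatures are serialized with the inline `gene,-1` suffix
#' dialect so a single line per signature round-trips through [read_gmt()].
#'
#' @param signatures List of [gene_signature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    genes <- c(s$positive, if (length(s$negative)) paste0(s$negative, ",-1"))
    paste(c(s$name, "na", genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
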