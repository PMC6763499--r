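# Latent-component annotation: rather than testing signatures on the whole
# graph, correlate each individual latent dimension with signature scores
# and meta-data, to label what each axis of the embedding captures.

#' Annotate latent components with signatures and meta-data
#'
#' Spearman correlation of every latent dimension against every corrected
#' signature score and numeric meta-data column (rank-based, consistent
#' with the autocorrelation machinery); categorical meta-data columns are
#' related to components with a Kruskal-Wallis test.  BH correction is
#' applied within each mode (signatures, numeric, categorical).
#'
#' @param latent Cells x dims matrix.
#' @param scores A `signature_scores` object or signatures x cells matrix
#'   (optional).
#' @param meta Optional tibble with `cell_id` plus meta-data columns,
#'   ordered like the latent rows.
#' @return Tibble `component`, `feature`, `type`, `correlation` (NA for
#'   categorical), `statistic`, `p_value`, `fdr`.  Constant components give
#'   NA rows.
#' @export
annotate_components <- function(latent, scores = NULL, meta = NULL) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  comp_names <- colnames(latent) %||% paste0("component_", seq_len(ncol(latent)))
  features <- list()
  if (!is.null(scores)) {
    m <- if (inherits(scores, "signature_scores")) scores$scores else as.matrix(scores)
    for (i in seq_len(nrow(m))) {
      features[[length(features) + 1L]] <-
        list(name = rownames(m)[i], type = "signature", values = m[i, ])
    }
  }
  if (!is.null(meta)) {
    for (cl in setdiff(names(meta), "cell_id")) {
      features[[length(features) + 1L]] <- list(
        name = cl,
        type = if (is.numeric(meta[[cl]])) "numeric_meta" else "categorical_meta",
        values = meta[[cl]]
      )
    }
  }
  if (length(features) == 0L) abort("Nothing to annotate: supply scores and/or meta.")
  res <- purrr::map(seq_len(ncol(latent)), function(d) {
    comp <- latent[, d]
    constant <- length(unique(comp)) == 1L
    purrr::map(features, function(f) {
      if (constant) {
        return(tibble(component = comp_names[d], feature = f$name, type = f$type,
                      correlation = NA_real_, statistic = NA_real_,
                      p_value = NA_real_))
      }
      if (f$type == "categorical_meta") {
        kt <- stats::kruskal.test(comp, as.factor(f$values))
        tibble(component = comp_names[d], feature = f$name, type = f$type,
               correlation = NA_real_, statistic = unname(kt$statistic),
               p_value = kt$p.value)
      } else {
        ct <- suppressWarnings(
          stats::cor.test(comp, as.numeric(f$values), method = "spearman",
                          exact = FALSE)
        )
        tibble(component = comp_names[d], feature = f$name, type = f$type,
               correlation = unname(ct$estimate), statistic = unname(ct$statistic),
               p_value = ct$p.value)
      }
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  res |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(fdr = bh_adjust(.data$p_value)) |>
    dplyr::ungroup()
}
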