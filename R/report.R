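# Results bundle on disk: one TSV per analysis table, a JSON index, and a
# static HTML report rendered by string templating (self-contained, no
# external assets).

#' Write a results bundle
#'
#' @param result A `sigscape_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.  Writes `autocorrelation.tsv`, `scores.tsv`,
#'   optional `differential.tsv` / `meta_numeric.tsv` /
#'   `meta_categorical.tsv` / `components.tsv` / `pools.tsv` /
#'   `dropped_signatures.tsv`, plus `index.json` and `config.yaml`.
#' @export
write_results_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(tab, name) {
    path <- file.path(dir, name)
    readr::write_tsv(tab, path, progress = FALSE)
    files <<- c(files, name)
  }
  put(result$autocorrelation, "autocorrelation.tsv")
  put(tibble::as_tibble(result$scores$scores, rownames = "signature"), "scores.tsv")
  if (nrow(result$scores$dropped) > 0L) put(result$scores$dropped, "dropped_signatures.tsv")
  for (nm in c("differential", "meta_numeric", "meta_categorical", "components")) {
    if (!is.null(result[[nm]])) put(result[[nm]], paste0(nm, ".tsv"))
  }
  if (!is.null(result$pools)) put(result$pools$assignment, "pools.tsv")
  yaml::write_yaml(result$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(files = files, config = result$config,
         n_signatures = nrow(result$scores$scores),
         n_cells = ncol(result$scores$scores)),
    file.path(dir, "index.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline configuration file
#'
#' YAML mirror of the [sigscape()] arguments plus input paths
#' (`expression`, `signatures`, and optional `latent`, `trajectory`,
#' `meta`).
#'
#' @param path YAML file path.
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$expression) || is.null(cfg$signatures)) {
    abort("Config must name `expression` and `signatures` inputs.")
  }
  cfg
}

#' Run the pipeline from a configuration file
#'
#' Reads all inputs named in the config, calls [sigscape()], and writes the
#' results bundle to `cfg$output` (if set).
#'
#' @param config Path to a YAML config, or the list from
#'   [read_run_config()].
#' @return The `sigscape_result`, invisibly.
#' @export
run_from_config <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  expr <- read_expression(cfg$expression)
  sigs <- read_gmt(cfg$signatures)
  latent <- if (!is.null(cfg$latent)) read_latent(cfg$latent)
  traj <- if (!is.null(cfg$trajectory)) read_trajectory(cfg$trajectory)
  meta <- if (!is.null(cfg$meta)) read_metadata(cfg$meta)
  res <- sigscape(
    expr, sigs, latent = latent, trajectory = traj, meta = meta,
    normalize = cfg$normalize %||% "none",
    K = cfg$K, bandwidth = cfg$bandwidth %||% "squared",
    n_backgrounds = cfg$n_backgrounds %||% 500,
    n_permutations = cfg$n_permutations %||% 1000,
    pool_size = cfg$pool_size, seed = cfg$seed %||% 1
  )
  if (!is.null(cfg$output)) write_results_bundle(res, cfg$output)
  invisible(res)
}

html_table <- function(tab, max_rows = 500) {
  tab <- utils::head(tab, max_rows)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 4)
  header <- paste0("<tr>", paste0("<th>", names(tab), "</th>", collapse = ""), "</tr>")
  rows <- apply(tab, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table>", header, paste(rows, collapse = "\n"), "</table>")
}

#' Render a static HTML report from a results bundle
#'
#' Single self-contained page with one sortable-by-eye table per analysis
#' mode.  Missing bundle files are listed rather than failing.
#'
#' @param dir Bundle directory from [write_results_bundle()].
#' @param file Output HTML path (default `report.html` inside `dir`).
#' @return `file`, invisibly.
#' @export
render_report <- function(dir, file = file.path(dir, "report.html")) {
  index_path <- file.path(dir, "index.json")
  if (!file.exists(index_path)) abort(sprintf("No index.json in %s", dir))
  index <- jsonlite::read_json(index_path, simplifyVector = TRUE)
  sections <- character()
  missing <- character()
  titles <- c(autocorrelation.tsv = "Signature autocorrelation",
              differential.tsv = "Differential signatures (1-vs-all)",
              meta_numeric.tsv = "Numeric meta-data autocorrelation",
              meta_categorical.tsv = "Categorical meta-data localization",
              components.tsv = "Latent component annotation",
              dropped_signatures.tsv = "Dropped signatures")
  for (f in names(titles)) {
    if (!(f %in% index$files)) next
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      missing <- c(missing, f)
      next
    }
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    sections <- c(sections, sprintf("<h2>%s</h2>\n%s", titles[[f]], html_table(tab)))
  }
  if (length(missing) > 0L) {
    sections <- c(sections,
                  sprintf("<h2>Missing files</h2><p>%s</p>",
                          paste(missing, collapse = ", ")))
  }
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>sigscape report</title>",
    "<style>body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:2px 8px;text-align:right}",
    "th{background:#eee}</style></head><body>",
    sprintf("<h1>sigscape results (%d signatures, %d cells)</h1>",
            index$n_signatures, index$n_cells),
    paste(sections, collapse = "\n"),
    "</body></html>"
  )
  writeLines(html, file)
  invisible(file)
}
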