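# Seeded synthetic datasets with known structure.  These generators stand
# in for real droplet data in every test: negative-binomial (or lognormal)
# counts, lognormal library-size variation, and signals planted either as
# cluster-restricted shifts of a gene set, as smooth within-cluster
# gradients, or as markers ramping along a trajectory branch.

#' Describe a planted signature for the clustered simulator
#'
#' @param name Signature name.
#' @param n_genes Number of (disjointly sampled) genes carrying the effect.
#' @param clusters Integer cluster indices whose cells receive the shift.
#' @param effect Shift in natural-log units: affected cells' expected
#'   expression of the signature genes is multiplied by `exp(effect)`.
#' @param gradient If `TRUE`, the shift is scaled per cell by a uniform
#'   gradient in `[0, 1]`, planting smooth within-cluster variation rather
#'   than a step.
#' @return A `planted_signature` description.
#' @export
planted_signature <- function(name, n_genes = 50, clusters = 1, effect = 1,
                              gradient = FALSE) {
  structure(list(name = name, n_genes = n_genes, clusters = clusters,
                 effect = effect, gradient = gradient),
            class = "planted_signature")
}

#' Simulate a clustered single-cell counts dataset
#'
#' Gene base means are lognormal across genes; counts are negative binomial
#' (dispersion `dispersion`, i.e. `size = 1/dispersion`) or rounded
#' lognormal, with per-cell lognormal library-size factors of coefficient
#' of variation `libsize_cv`.  Cells are split evenly across clusters and
#' assigned donors at random; each [planted_signature()] multiplies the
#' expected expression of its genes by `exp(effect)` (optionally ramped by
#' a per-cell gradient) in the affected clusters.
#'
#' @param n_cells,n_genes,n_clusters Dataset dimensions.
#' @param planted List of [planted_signature()] descriptions (gene sets are
#'   sampled disjointly from the universe).
#' @param n_donors Number of donor labels (assigned independently of
#'   cluster).
#' @param noise `"nb"` (default) or `"lognormal"` count noise.
#' @param dispersion NB dispersion (default 0.5).
#' @param libsize_cv Library-size coefficient of variation (default 0.3).
#' @param seed Integer seed; fixed seed gives bit-identical counts.
#' @return List with `counts` (genes x cells raw counts), `meta` (tibble
#'   `cell_id`, `cluster`, `donor`, plus one numeric `<name>_gradient`
#'   column per gradient signature), `signatures` (the planted gene sets as
#'   [gene_signature()] objects) and `truth` (a tibble of the planted
#'   effects).
#' @export
simulate_clustered_dataset <- function(n_cells = 1000, n_genes = 2000,
                                       n_clusters = 2, planted = list(),
                                       n_donors = 2,
                                       noise = c("nb", "lognormal"),
                                       dispersion = 0.5, libsize_cv = 0.3,
                                       seed = 1) {
  noise <- match.arg(noise)
  total_planted <- sum(vapply(planted, `[[`, numeric(1), "n_genes"))
  if (total_planted > n_genes) abort("Planted signatures need more genes than the universe holds.")
  bad <- vapply(planted, function(p) any(p$clusters < 1 | p$clusters > n_clusters), logical(1))
  if (any(bad)) abort("Planted signature references a cluster outside 1..n_clusters.")
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    cells <- sprintf("cell%04d", seq_len(n_cells))
    cluster <- rep_len(seq_len(n_clusters), n_cells)
    donor <- sample(sprintf("donor%d", seq_len(n_donors)), n_cells, replace = TRUE)
    base_mu <- exp(rnorm(n_genes, mean = 0, sd = 1))

    mu <- matrix(base_mu, n_genes, n_cells)
    meta <- tibble(cell_id = cells, cluster = sprintf("cluster%d", cluster),
                   donor = donor)
    avail <- sample(genes)  # disjoint gene sets per planted signature
    sigs <- list()
    truth <- list()
    for (p in planted) {
      gset <- avail[seq_len(p$n_genes)]
      avail <- avail[-seq_len(p$n_genes)]
      affected <- cluster %in% p$clusters
      g <- if (p$gradient) runif(n_cells) else rep(1, n_cells)
      fac <- ifelse(affected, exp(p$effect * g), 1)
      mu[match(gset, genes), ] <- mu[match(gset, genes), ] *
        rep(fac, each = p$n_genes)
      if (p$gradient) meta[[paste0(p$name, "_gradient")]] <- ifelse(affected, g, NA)
      sigs[[p$name]] <- gene_signature(p$name, positive = gset)
      truth[[p$name]] <- tibble(signature = p$name, effect = p$effect,
                                gradient = p$gradient,
                                clusters = paste(p$clusters, collapse = ","))
    }
    lib <- exp(rnorm(n_cells, sd = sqrt(log(1 + libsize_cv^2))))
    mu <- sweep(mu, 2L, lib, `*`)
    counts <- if (noise == "nb") {
      matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
             n_genes, n_cells)
    } else {
      matrix(round(mu * exp(rnorm(n_genes * n_cells,
                                  sd = sqrt(log(1 + dispersion))))),
             n_genes, n_cells)
    }
    dimnames(counts) <- list(genes, cells)
    list(counts = counts, meta = meta, signatures = sigs,
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulate a trajectory-shaped dataset
#'
#' Builds a random milestone tree (random attachment, edge lengths uniform
#' on `edge_length_range`), places cells uniformly along edges (edge chosen
#' with probability proportional to length), and plants per-branch marker
#' genes whose expected expression ramps as `exp(effect * progress)` along
#' their branch.  A housekeeping signature of flat genes is included as a
#' negative control.
#'
#' @param n_milestones Number of milestones (default 7).
#' @param n_cells Number of cells (default 200).
#' @param n_genes Gene universe size (default 500).
#' @param markers_per_branch Marker genes planted on each edge (default 20).
#' @param effect Ramp steepness in natural-log units (default 2).
#' @param edge_length_range Uniform range for edge lengths.
#' @param dispersion,libsize_cv Noise parameters as in
#'   [simulate_clustered_dataset()].
#' @param seed Integer seed.
#' @return List with `trajectory` ([trajectory_model()]), `counts`,
#'   `meta` (tibble `cell_id`, `branch`, `progress`), and `signatures`
#'   (per-branch markers plus `housekeeping`).
#' @export
simulate_tree_dataset <- function(n_milestones = 7, n_cells = 200,
                                  n_genes = 500, markers_per_branch = 20,
                                  effect = 2, edge_length_range = c(1, 3),
                                  dispersion = 0.5, libsize_cv = 0.3,
                                  seed = 1) {
  if (n_milestones < 2L) abort("Need at least 2 milestones.")
  n_edges <- n_milestones - 1L
  if (markers_per_branch * n_edges > n_genes) {
    abort("Not enough genes for the requested branch markers.")
  }
  with_seed(seed, {
    ms <- sprintf("M%d", seq_len(n_milestones))
    to <- ms[-1L]
    from <- vapply(seq_len(n_edges), function(i) ms[sample.int(i, 1L)], character(1))
    edges <- tibble(from = from, to = to,
                    length = runif(n_edges, edge_length_range[1L], edge_length_range[2L]))
    cells <- sprintf("cell%04d", seq_len(n_cells))
    ei <- sample.int(n_edges, n_cells, replace = TRUE, prob = edges$length)
    progress <- runif(n_cells)
    traj <- trajectory_model(ms, edges,
                             tibble(cell_id = cells, from = edges$from[ei],
                                    to = edges$to[ei], progress = progress))

    genes <- sprintf("gene%04d", seq_len(n_genes))
    base_mu <- exp(rnorm(n_genes, mean = 0, sd = 0.5))
    mu <- matrix(base_mu, n_genes, n_cells)
    marker_pool <- sample(genes, markers_per_branch * n_edges)
    sigs <- list()
    for (e in seq_len(n_edges)) {
      gset <- marker_pool[((e - 1L) * markers_per_branch + 1L):(e * markers_per_branch)]
      ramp <- ifelse(ei == e, exp(effect * progress), 1)
      mu[match(gset, genes), ] <- mu[match(gset, genes), ] *
        rep(ramp, each = markers_per_branch)
      nm <- sprintf("branch_%s_%s", edges$from[e], edges$to[e])
      sigs[[nm]] <- gene_signature(nm, positive = gset)
    }
    flat <- setdiff(genes, marker_pool)
    sigs[["housekeeping"]] <- gene_signature(
      "housekeeping", positive = sample(flat, min(30L, length(flat))))

    lib <- exp(rnorm(n_cells, sd = sqrt(log(1 + libsize_cv^2))))
    mu <- sweep(mu, 2L, lib, `*`)
    counts <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
                     n_genes, n_cells)
    dimnames(counts) <- list(genes, cells)
    meta <- tibble(cell_id = cells,
                   branch = sprintf("%s_%s", edges$from[ei], edges$to[ei]),
                   progress = progress)
    list(trajectory = traj, counts = counts, meta = meta, signatures = sigs)
  })
}
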