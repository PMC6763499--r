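test_that("detection filter removes rarely expressed genes", {
  expr <- random_expr(20, 100, seed = 97)
  expr["g001", ] <- 0
  expr["g001", 1:5] <- 1  # detected in 5% of cells
  out <- filter_genes(expr, min_detection = 0.1, n_mads = -Inf)  # keep all variable
  expect_false("g001" %in% rownames(out))
  expect_true("g002" %in% rownames(out))
})

test_that("dispersion filter keeps the planted high-variance gene per bin", {
  # genes with identical means, one per 'bin' wildly overdispersed
  withr::with_seed(101, {
    n_genes <- 60
    expr <- matrix(rpois(n_genes * 200, lambda = 5), n_genes, 200,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%03d", 1:200)))
    loud <- c("g010", "g030", "g050")
    for (g in loud) expr[g, ] <- rpois(200, 5) * sample(c(0, 4), 200, replace = TRUE)
  })
  out <- filter_genes(expr, min_detection = 0.05, n_bins = 3, n_mads = 2)
  expect_true(all(loud %in% rownames(out)))
  expect_lt(nrow(out), 20)
})

test_that("degenerate dispersion falls back to detection-only with a warning", {
  expr <- matrix(rep(1:10, times = 6), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  # all-identical columns: zero variance everywhere
  expect_warning(out <- filter_genes(expr, min_detection = 0), "degenerate")
  expect_equal(nrow(out), 10)
})

test_that("P >= N collapses to a single pool holding the global mean", {
  expr <- random_expr(15, 8, seed = 103)
  mp <- micropool(expr, P = 10, seed = 1)
  expect_equal(ncol(mp$pooled), 1L)
  expect_equal(unname(mp$pooled[, 1]), unname(rowMeans(expr)), tolerance = 1e-12)
})

test_that("pooled columns are exact member means and conserve total mass", {
  sim <- simulate_clustered_dataset(n_cells = 300, n_genes = 300, n_clusters = 3,
                                    planted = list(planted_signature("p", 30, 1, 1.5)),
                                    seed = 107)
  expr <- normalize_expression(sim$counts, "median_umi")
  mp <- micropool(expr, P = 15, seed = 5)
  expect_true(all(mp$sizes <= 15))
  expect_true(all(table(mp$assignment$pool) == mp$sizes[names(table(mp$assignment$pool))]))
  # hand-average a few pools
  for (p in head(unique(mp$assignment$pool), 3)) {
    cells <- mp$assignment$cell_id[mp$assignment$pool == p]
    expect_equal(unname(mp$pooled[, p]),
                 unname(rowMeans(expr[, cells, drop = FALSE])), tolerance = 1e-12)
  }
  # size-weighted mean of pooled columns equals the global mean vector
  wmean <- as.numeric(mp$pooled %*% mp$sizes[colnames(mp$pooled)]) / ncol(expr)
  expect_equal(wmean, unname(rowMeans(expr)), tolerance = 1e-10)
})

test_that("micro-pooling is deterministic under a fixed seed", {
  sim <- simulate_clustered_dataset(n_cells = 200, n_genes = 200, seed = 109)
  expr <- normalize_expression(sim$counts, "median_umi")
  a <- micropool(expr, P = 10, seed = 42)
  b <- micropool(expr, P = 10, seed = 42)
  expect_identical(a$assignment, b$assignment)
  expect_equal(a$pooled, b$pooled)
})

test_that("pools never span well-separated blobs", {
  lat <- blob_latent(60, sep = 60, seed = 113)
  expr <- random_expr(40, 120, seed = 113)
  colnames(expr) <- rownames(lat)
  mp <- micropool(expr, P = 20, seed = 7, latent = lat)
  blob <- rep(c("b1", "b2"), each = 60)
  purity <- tapply(blob[match(mp$assignment$cell_id, colnames(expr))],
                   mp$assignment$pool,
                   function(x) max(table(x)) / length(x))
  expect_true(all(purity == 1))
})

test_that("coherence ratios behave at the identities and under random pooling", {
  withr::with_seed(127, {
    features <- matrix(rnorm(3 * 2000), 3, 2000,
                       dimnames = list(paste0("f", 1:3), sprintf("c%04d", 1:2000)))
  })
  # a single pool holding all cells gives r = 1 exactly
  all_one <- tibble::tibble(cell_id = colnames(features), pool = "p1")
  r1 <- coherence_ratios(features, all_one)
  expect_equal(r1$ratio, rep(1, 3), tolerance = 1e-12)
  # random pools of i.i.d. data give median r near 1
  withr::with_seed(131, {
    rand_pools <- tibble::tibble(cell_id = colnames(features),
                                 pool = sample(rep(sprintf("p%03d", 1:100), each = 20)))
  })
  rr <- coherence_ratios(features, rand_pools)
  expect_gt(median(rr$ratio), 0.9)
  expect_lt(median(rr$ratio), 1.1)
  # pools aligned with a two-level feature have near-zero within-pool spread
  lv <- rep(c(0, 10), each = 1000)
  features2 <- rbind(step = lv + rnorm(2000, sd = 0.01))
  colnames(features2) <- colnames(features)
  aligned <- tibble::tibble(cell_id = colnames(features),
                            pool = rep(c("lo", "hi"), each = 1000))
  ra <- coherence_ratios(features2, aligned)
  expect_lt(max(ra$ratio), 0.05)
  # singleton pools are flagged with ratio 0
  single <- tibble::tibble(cell_id = colnames(features)[1:3],
                           pool = c("s1", "s2", "s2"))
  rs <- coherence_ratios(features[, 1:3], single)
  expect_true(all(rs$ratio[rs$pool == "s1"] == 0))
  expect_true(all(rs$singleton[rs$pool == "s1"]))
})
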