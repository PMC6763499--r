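test_that("Geary's C matches the dense double-loop oracle", {
  withr::with_seed(61, {
    for (rep in 1:5) {
      n <- sample(30:120, 1)
      lat <- matrix(rnorm(n * 3), n, 3, dimnames = list(sprintf("c%03d", 1:n), NULL))
      g <- knn_from_latent(lat, K = sample(3:8, 1))
      x <- rnorm(n)
      expect_equal(geary_c(x, g), geary_oracle(x, g), tolerance = 1e-12)
    }
  })
})

test_that("hand-built 6-cell graph matches brute force", {
  g <- structure(list(
    index = matrix(c(2L, 1L, 4L, 3L, 6L, 5L,
                     3L, 3L, 1L, 5L, 4L, 4L), 6, 2),
    distance = matrix(c(rep(1, 6), rep(2, 6)), 6, 2),
    weight = matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4,
                      0.3, 0.2, 0.1, 0.15, 0.25, 0.35), 6, 2),
    K = 2L, cell_ids = paste0("c", 1:6)), class = "neighbor_graph")
  g$W <- sum(g$weight)
  x <- c(0.3, -1.2, 2.2, 0.0, 1.7, -0.4)
  expect_equal(geary_c(x, g), geary_oracle(x, g), tolerance = 1e-12)
})

test_that("perfectly smooth values give C = 0, C' = 1", {
  # two far-separated blobs, constant value within each, K small enough
  # that no edges cross blobs
  lat <- blob_latent(20, sep = 100, seed = 3)
  g <- knn_from_latent(lat, K = 5)
  x <- rep(c(0, 1), each = 20)
  expect_equal(geary_c(x, g), 0, tolerance = 1e-12)
  res <- autocorrelation_cprime(matrix(x, 1, dimnames = list("blob", NULL)), g)
  expect_equal(res$c_prime, 1, tolerance = 1e-12)
})

test_that("randomly permuted values have mean C' near zero", {
  withr::with_seed(17, {
    lat <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(sprintf("c%02d", 1:80), NULL))
    g <- knn_from_latent(lat, K = 8)
    x <- rnorm(80)
    cp <- vapply(1:200, function(i) 1 - geary_c(sample(x), g), numeric(1))
  })
  expect_lt(abs(mean(cp)), 3 * sd(cp) / sqrt(200))
})

test_that("constant vectors are rejected, NA propagated in batch mode", {
  lat <- chain_latent(10)
  g <- knn_from_latent(lat, K = 2)
  expect_error(geary_c(rep(1, 10), g), "constant")
  m <- rbind(flat = rep(2, 10), ok = rnorm(10))
  res <- autocorrelation_cprime(m, g)
  expect_true(is.na(res$c_prime[res$signature == "flat"]))
  expect_false(is.na(res$c_prime[res$signature == "ok"]))
})

test_that("monotone scores along a chain are strongly autocorrelated; noise is not", {
  g <- knn_from_latent(chain_latent(100), K = 5)
  mono <- autocorrelation_cprime(matrix(1:100, 1, dimnames = list("m", NULL)), g)
  expect_gt(mono$c_prime, 0.8)
  withr::with_seed(23, {
    noise <- replicate(50, 1 - geary_c(rnorm(100), g))
  })
  expect_lt(abs(mean(noise)), 3 * sd(noise))
})

test_that("C' is invariant to strictly monotone transforms of the scores", {
  withr::with_seed(29, {
    lat <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(sprintf("c%02d", 1:60), NULL))
    x <- rnorm(60)
  })
  g <- knn_from_latent(lat, K = 6)
  m1 <- matrix(x, 1, dimnames = list("s", NULL))
  m2 <- matrix(exp(3 * x) + 5, 1, dimnames = list("s", NULL))
  expect_equal(autocorrelation_cprime(m1, g)$c_prime,
               autocorrelation_cprime(m2, g)$c_prime, tolerance = 1e-12)
})

test_that("empirical p-values hit the closed-form extremes", {
  obs <- tibble::tibble(signature = c("hi", "lo"), c_prime = c(10, -10))
  bg <- structure(list(
    groups = list(list(c_prime_null = rnorm(100))),
    assignment = c(1L, 1L),
    signature_names = c("hi", "lo")), class = "background_set")
  res <- empirical_pvalues(obs, bg)
  expect_equal(res$p_value[1], 1 / 101)
  expect_equal(res$p_value[2], 1)
})

test_that("reported FDR equals the textbook step-up procedure", {
  # craft background nulls so the empirical p-values land on a hand case:
  # p = (x+1)/1000 for x nulls >= observed
  null <- seq(0.001, 0.999, by = 0.001)  # 999 null C' values
  bg <- structure(list(groups = list(list(c_prime_null = null)),
                       assignment = rep(1L, 4),
                       signature_names = paste0("s", 1:4)),
                  class = "background_set")
  # observed C' placed to leave x = 0, 9, 19, 799 nulls above
  obs <- tibble::tibble(signature = paste0("s", 1:4),
                        c_prime = c(1, 0.9905, 0.9805, 0.2005))
  res <- empirical_pvalues(obs, bg)
  expect_equal(res$p_value, c(0.001, 0.01, 0.02, 0.8), tolerance = 1e-12)
  expect_equal(res$fdr, c(0.004, 0.02, 4 / 150, 0.8), tolerance = 1e-12)
  expect_equal(res$fdr, bh_oracle(res$p_value), tolerance = 1e-14)
  expect_true(all(res$fdr >= res$p_value))
})

test_that("background groups separate signatures of very different sizes", {
  universe <- sprintf("g%04d", 1:2000)
  sigs <- c(
    lapply(1:6, function(i) gene_signature(paste0("small", i), universe[i * 10 + 1:10])),
    lapply(1:6, function(i) gene_signature(paste0("big", i), universe[1000 + i * 80 + 1:80]))
  )
  bg <- build_backgrounds(sigs, universe, n_per_group = 5, n_groups = 2, seed = 4)
  for (i in seq_along(sigs)) {
    center_size <- bg$groups[[bg$assignment[i]]]$size
    sz <- length(sigs[[i]]$positive)
    expect_lt(abs(log2(center_size / sz)), 1)
  }
})

test_that("background generation is deterministic under a fixed seed", {
  universe <- sprintf("g%03d", 1:500)
  sigs <- lapply(1:5, function(i) gene_signature(paste0("s", i), universe[i * 20 + 1:20]))
  b1 <- build_backgrounds(sigs, universe, n_per_group = 10, seed = 99)
  b2 <- build_backgrounds(sigs, universe, n_per_group = 10, seed = 99)
  expect_identical(
    lapply(b1$groups, function(g) lapply(g$signatures, `[[`, "positive")),
    lapply(b2$groups, function(g) lapply(g$signatures, `[[`, "positive"))
  )
  expect_identical(b1$assignment, b2$assignment)
  # matched size and balance: signed inputs beget signed backgrounds
  signed <- lapply(1:5, function(i)
    gene_signature(paste0("sg", i), universe[1:10], universe[11:20]))
  bs <- build_backgrounds(signed, universe, n_per_group = 3, seed = 1)
  one <- bs$groups[[1]]$signatures[[1]]
  expect_equal(length(one$positive), 10)
  expect_equal(length(one$negative), 10)
})

test_that("planted smooth gradients reach the minimal permutation p-value", {
  n <- 120
  g <- knn_from_latent(chain_latent(n), K = 8)
  meta <- tibble::tibble(cell_id = sprintf("c%03d", 1:n),
                         gradient = seq_len(n) + rnorm(n, sd = 0.01),
                         flat = rep(1, n))
  res <- metadata_autocorrelation(meta, g, n_perm = 99, seed = 11,
                                  columns = c("gradient", "flat"))
  expect_equal(res$p_value[res$variable == "gradient"], 1 / 100)
  expect_true(is.na(res$p_value[res$variable == "flat"]))
})

test_that("within-stratum permutations remove between-stratum signal", {
  # two 'donors' occupying separate regions; the donor-level signal is a
  # step function, significant under free permutation but not within-donor
  n <- 100
  lat <- blob_latent(n / 2, sep = 40, seed = 19)
  g <- knn_from_latent(lat, K = 6)
  donor <- rep(c("d1", "d2"), each = n / 2)
  withr::with_seed(7, {
    meta <- tibble::tibble(cell_id = rownames(lat),
                           signal = ifelse(donor == "d1", 0, 1) + rnorm(n, sd = 0.05),
                           donor = donor)
  })
  free <- metadata_autocorrelation(meta, g, n_perm = 199, seed = 3,
                                   columns = "signal")
  strat <- metadata_autocorrelation(meta, g, n_perm = 199, seed = 3,
                                    columns = "signal", within = "donor")
  expect_lt(free$p_value, 0.01)
  expect_gt(strat$p_value, 0.05)
})
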