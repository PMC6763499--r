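test_that("local proportions saturate when all neighbours share a label", {
  lat <- blob_latent(10, sep = 100, seed = 2)
  g <- knn_from_latent(lat, K = 3)
  labels <- rep(c("a", "b"), each = 10)
  props <- local_proportions(labels, g)
  # neighbourhoods never cross the blobs, so all mass is on the own label
  expect_equal(unname(props[1:10, "b"]), rep(0, 10))
  expect_equal(unname(props[11:20, "a"]), rep(0, 10))
  # row sums equal row weight sums
  expect_equal(unname(rowSums(props)), unname(rowSums(g$weight)), tolerance = 1e-12)
})

test_that("local proportions equal the dense indicator-product oracle", {
  withr::with_seed(43, {
    lat <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(sprintf("c%02d", 1:50), NULL))
    labels <- sample(c("x", "y", "z"), 50, replace = TRUE)
  })
  g <- knn_from_latent(lat, K = 6)
  props <- local_proportions(labels, g)
  # oracle: dense weight matrix times one-hot indicator
  W <- matrix(0, 50, 50)
  for (i in 1:50) W[i, g$index[i, ]] <- g$weight[i, ]
  ind <- sapply(sort(unique(labels)), function(l) as.numeric(labels == l))
  expect_equal(unname(props), unname(W %*% ind), tolerance = 1e-12)
})

test_that("contingency aggregation sums local rows by own label", {
  # 4-cell toy, K = 1, uniform weights: hand-computable 2x2 table
  g <- structure(list(
    index = matrix(c(2L, 1L, 4L, 3L), 4, 1),
    distance = matrix(0, 4, 1),
    weight = matrix(1, 4, 1),
    K = 1L, W = 4, cell_ids = paste0("c", 1:4)), class = "neighbor_graph")
  labels <- c("a", "b", "a", "b")  # c1<->c2 cross-label, c3<->c4 cross-label
  props <- local_proportions(labels, g)
  X <- contingency_from_proportions(props, labels)
  expect_equal(unname(X), matrix(c(0, 2, 2, 0), 2), tolerance = 1e-12)
  expect_error(contingency_from_proportions(props[, 1, drop = FALSE], labels),
               "missing")
})

test_that("chi-squared test and Cramer's V on printed-style tables", {
  # perfect association
  res1 <- categorical_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res1$cramers_v, 1)
  # exact independence
  res2 <- categorical_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res2$chi2, 0)
  expect_equal(res2$cramers_v, 0)
  # textbook worked case: all expected counts 20, chi2 = 4 * 100/20 = 20,
  # V = sqrt(20 / 80) = 0.5
  res3 <- categorical_test(matrix(c(30, 10, 10, 30), 2))
  expect_equal(res3$chi2, 20, tolerance = 1e-12)
  expect_equal(res3$cramers_v, sqrt(20 / 80), tolerance = 1e-12)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(30, 10, 10, 30), 2), correct = FALSE))
  expect_equal(res3$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res3$dof, 1)
  expect_error(categorical_test(matrix(5)), "2 levels")
})

test_that("V is invariant to relabeling the levels", {
  withr::with_seed(47, {
    lat <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(sprintf("c%02d", 1:60), NULL))
    labels <- sample(c("a", "b", "c"), 60, replace = TRUE)
  })
  g <- knn_from_latent(lat, K = 5)
  v1 <- categorical_test(contingency_from_proportions(local_proportions(labels, g), labels))
  relab <- c(a = "z", b = "q", c = "m")[labels]
  v2 <- categorical_test(contingency_from_proportions(local_proportions(relab, g), relab))
  expect_equal(v1$cramers_v, v2$cramers_v, tolerance = 1e-12)
  expect_equal(v1$chi2, v2$chi2, tolerance = 1e-12)
})

test_that("separated blobs give V near 1; permuted labels give V near 0", {
  lat <- blob_latent(50, sep = 80, seed = 53)
  g <- knn_from_latent(lat, K = 7)
  labels <- rep(c("batch1", "batch2"), each = 50)
  v_sep <- categorical_test(
    contingency_from_proportions(local_proportions(labels, g), labels))$cramers_v
  expect_gt(v_sep, 0.9)
  withr::with_seed(59, {
    v_null <- replicate(200, {
      lp <- sample(labels)
      categorical_test(
        contingency_from_proportions(local_proportions(lp, g), lp))$cramers_v
    })
  })
  # shuffled labels are essentially unlocalized
  expect_lt(mean(v_null), mean(v_null) + 3 * sd(v_null))  # sanity on spread
  expect_lt(mean(v_null), 0.15)
})

test_that("categorical_autocorrelation wraps columns with BH across the family", {
  lat <- blob_latent(30, sep = 60, seed = 61)
  g <- knn_from_latent(lat, K = 5)
  withr::with_seed(67, {
    meta <- tibble::tibble(cell_id = rownames(lat),
                           blob = rep(c("p", "q"), each = 30),
                           noise = sample(c("u", "v"), 60, replace = TRUE))
  })
  res <- categorical_autocorrelation(meta, g)
  expect_setequal(res$variable, c("blob", "noise"))
  expect_gt(res$cramers_v[res$variable == "blob"],
            res$cramers_v[res$variable == "noise"])
  expect_equal(res$fdr, bh_oracle(res$p_value))
})
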