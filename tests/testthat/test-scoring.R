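test_that("raw score matches the signed-mean formula on small cases", {
  expr <- matrix(c(2, 3, 1, 0.5), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("c1", "c2")))
  # single positive gene: score is that gene's expression
  s1 <- raw_score(expr, gene_signature("s", "A"))
  expect_equal(unname(s1["c1"]), 2)
  # one positive, one negative: (e_A - e_B) / 2
  s2 <- raw_score(expr, gene_signature("s", "A", "B"))
  expect_equal(unname(s2["c1"]), (2 - 1) / 2)
  expect_equal(unname(s2["c2"]), (3 - 0.5) / 2)
})

test_that("raw and batch scores match a brute-force summation oracle", {
  expr <- random_expr(100, 40, seed = 11)
  withr::with_seed(3, {
    pos <- sample(rownames(expr), 10)
    neg <- sample(setdiff(rownames(expr), pos), 5)
  })
  sig <- gene_signature("s", pos, neg)
  got <- raw_score(expr, sig)
  want <- vapply(seq_len(ncol(expr)), function(j) {
    (sum(expr[pos, j]) - sum(expr[neg, j])) / 15
  }, numeric(1))
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
  # batch path agrees with the per-signature loop
  sigs <- list(sig, gene_signature("t", pos[1:3]))
  batch <- score_signatures(expr, sigs, correct = TRUE)
  loop <- t(vapply(sigs, function(sg) {
    corrected_score(raw_score(expr, sg), expr)
  }, numeric(ncol(expr))))
  expect_equal(unname(batch$scores), unname(loop), tolerance = 1e-12)
})

test_that("correction uses the random-signature moments", {
  expr <- random_expr(60, 25, seed = 5)
  # balanced signed signature: expected value term vanishes
  sig <- gene_signature("bal", rownames(expr)[1:5], rownames(expr)[6:10])
  raw <- raw_score(expr, sig)
  cs <- corrected_score(raw, expr)
  ebar <- colMeans(expr)
  sigma2 <- colMeans(expr^2) - ebar^2
  expect_equal(as.numeric(cs), as.numeric(raw) / sqrt(unname(sigma2) / 10), tolerance = 1e-12)
  # a "signature" whose raw score equals ebar in every cell corrects to 0
  cs0 <- corrected_score(ebar, expr, n_pos = 1, n_neg = 0)
  expect_equal(unname(cs0), rep(0, ncol(expr)), tolerance = 1e-12)
})

test_that("corrected scores of random signatures have mean ~0 and variance ~1", {
  # log-scale fixture (the scale scores are defined on); signatures small
  # relative to the universe so without-replacement sampling stays close to
  # the independence the analytic variance assumes
  expr <- log1p(random_expr(1000, 50, seed = 9))
  n_draws <- 400
  sigs <- withr::with_seed(21, {
    lapply(seq_len(n_draws), function(i) {
      gene_signature(paste0("r", i), sample(rownames(expr), 15))
    })
  })
  sc <- score_signatures(expr, sigs)$scores
  per_cell_mean <- colMeans(sc)
  per_cell_var <- apply(sc, 2, var)
  expect_lt(max(abs(per_cell_mean)), 0.15)
  expect_true(all(per_cell_var > 0.75 & per_cell_var < 1.25))
})

test_that("missing genes shrink the denominator consistently", {
  expr <- random_expr(20, 10, seed = 2)
  sig <- gene_signature("s", c(rownames(expr)[1:3], "ABSENT1", "ABSENT2"))
  s <- raw_score(expr, sig)
  expect_identical(attr(s, "n_pos"), 3L)
  expect_equal(as.numeric(s), unname(colSums(expr[1:3, ]) / 3), tolerance = 1e-12)
  # gene matching is case-insensitive
  sig2 <- gene_signature("s2", tolower(rownames(expr)[1:3]))
  expect_equal(as.numeric(raw_score(expr, sig2)), unname(colSums(expr[1:3, ]) / 3))
})

test_that("signatures without any matrix genes are dropped with a report", {
  expr <- random_expr(20, 10, seed = 2)
  sigs <- list(gene_signature("ok", rownames(expr)[1:4]),
               gene_signature("gone", c("NOPE1", "NOPE2")))
  expect_warning(sc <- score_signatures(expr, sigs), "gone")
  expect_equal(rownames(sc$scores), "ok")
  expect_equal(sc$dropped$signature, "gone")
  expect_error(score_signatures(expr, list()), "Empty")
  expect_error(
    score_signatures(expr, list(gene_signature("d", "g001"),
                                gene_signature("d", "g002"))),
    "Duplicate")
})

test_that("raw score is linear over disjoint unsigned signatures", {
  expr <- random_expr(80, 15, seed = 13)
  a <- gene_signature("a", rownames(expr)[1:10])
  b <- gene_signature("b", rownames(expr)[11:25])
  u <- gene_signature("u", rownames(expr)[1:25])
  s <- (10 * as.numeric(raw_score(expr, a)) + 15 * as.numeric(raw_score(expr, b))) / 25
  expect_equal(as.numeric(raw_score(expr, u)), s, tolerance = 1e-12)
})

test_that("corrected scores are invariant to duplicating cells", {
  expr <- random_expr(50, 12, seed = 17)
  dup <- cbind(expr, expr[, 1:3])
  colnames(dup) <- c(colnames(expr), paste0("dup", 1:3))
  sig <- gene_signature("s", rownames(expr)[1:8])
  a <- corrected_score(raw_score(expr, sig), expr)
  b <- corrected_score(raw_score(dup, sig), dup)
  expect_equal(unname(b[1:12]), unname(a), tolerance = 1e-12)
  expect_equal(unname(b[13:15]), unname(a[1:3]), tolerance = 1e-12)
})

test_that("gene-signature covariance matches direct computation", {
  expr <- random_expr(30, 20, seed = 23)
  sig <- gene_signature("s", rownames(expr)[1:5])
  sc <- corrected_score(raw_score(expr, sig), expr)
  tab <- gene_signature_covariance(expr, sc, sig)
  for (g in sig$positive) {
    expect_equal(tab$covariance[tab$gene == g],
                 cov(expr[g, ], as.numeric(sc)), tolerance = 1e-12)
  }
  # constant gene has zero covariance
  expr2 <- rbind(expr, const = rep(1, 20))
  sig2 <- gene_signature("s2", c("const", rownames(expr)[1]))
  sc2 <- corrected_score(raw_score(expr2, sig2), expr2)
  tab2 <- gene_signature_covariance(expr2, sc2, sig2)
  expect_equal(tab2$covariance[tab2$gene == "const"], 0, tolerance = 1e-12)
})

test_that("anti-correlated negative-set genes get negative covariance", {
  up <- seq(1, 5, length.out = 20)
  expr <- rbind(A = up, B = rev(up))
  colnames(expr) <- sprintf("c%02d", 1:20)
  sig <- gene_signature("s", "A", "B")
  sc <- raw_score(expr, sig)
  tab <- gene_signature_covariance(expr, sc, sig)
  expect_lt(tab$covariance[tab$gene == "B"], 0)
  expect_gt(tab$covariance[tab$gene == "A"], 0)
})
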