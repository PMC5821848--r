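test_that("perfectly correlated variables collapse onto one axis", {
  set.seed(50)
  x <- rnorm(40)
  tab <- data.frame(v1 = x, v2 = 3 * x + 2)
  p <- group_pca(tab, n_axes = 2)
  expect_equal(p$variance_fraction[1], 1)
  expect_equal(abs(p$loadings[1, 1]), abs(p$loadings[2, 1]))
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)  # sign rule
})

test_that("full-rank scores reconstruct the standardized data", {
  set.seed(51)
  tab <- as.data.frame(matrix(rnorm(30 * 4), 30, 4))
  p <- group_pca(tab, n_axes = 4)
  z <- scale(as.matrix(tab))
  recon <- p$scores %*% t(p$loadings)
  expect_equal(unname(recon), unname(z[, ]), tolerance = 1e-10)
  expect_equal(unname(colMeans(p$scores)), rep(0, 4))
})

test_that("near-independent variables spread variance evenly (eigenvalues near 1)", {
  set.seed(52)
  tab <- as.data.frame(matrix(rnorm(4000 * 3), ncol = 3))
  p <- group_pca(tab, n_axes = 3)
  # eigenvalues of a 3-var identity correlation: all 1/3 of total
  expect_true(all(abs(p$variance_fraction - 1 / 3) < 3 / sqrt(4000)))
})

test_that("constant columns are dropped with a warning; n_axes is bounded", {
  tab <- data.frame(a = rnorm(10), b = rnorm(10), c = rep(1, 10))
  expect_warning(p <- group_pca(tab, 2), "constant")
  expect_equal(p$dropped, "c")
  expect_error(group_pca(data.frame(a = rnorm(10), b = rnorm(10)), 3),
               "n_axes")
})

test_that("PC-variable correlations match textbook Pearson arithmetic", {
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 3, 5, 4, 9)
  scores <- cbind(PC1 = y)
  out <- pc_variable_correlations(scores, data.frame(v = x))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand)
  expect_equal(out$p, stats::cor.test(x, y)$p.value)
  # identical variable: r = 1; orthogonal contrast: r = 0
  out2 <- pc_variable_correlations(cbind(PC1 = x), data.frame(v = x))
  expect_equal(out2$r, 1)
  z <- c(1, -1, 1, -1)
  out3 <- pc_variable_correlations(cbind(PC1 = z),
                                   data.frame(v = c(1, 1, -1, -1)))
  expect_equal(out3$r, 0)
  out4 <- pc_variable_correlations(cbind(PC1 = z),
                                   data.frame(v = rep(2, 4)))
  expect_true(is.na(out4$r))
})

test_that("historical differences average the circulation models first", {
  cur <- c(a = 10, b = 20, c = 30)
  lgm_same <- cbind(cur)
  expect_equal(unname(historical_difference(cur, lgm_same)), c(0, 0, 0))
  lgm_pm <- cbind(cur - 1, cur + 1)
  expect_equal(unname(historical_difference(cur, lgm_pm)), c(0, 0, 0))
  set.seed(53)
  f <- replicate(3, cur + rnorm(3))
  expect_equal(historical_difference(cur, f),
               cur - (f[, 1] + f[, 2] + f[, 3]) / 3)
  expect_error(historical_difference(cur, cbind(1:2)), "different cell sets")
})

test_that("the assembled predictor table carries the nine driver terms", {
  land <- demo_landscape(seed = 54)
  pred <- build_predictor_table(land$env, land$lat)
  expect_setequal(setdiff(names(pred), "cell_id"),
                  c("CURE.PC1", "CURE.PC2", "TOPO.PC1", "TOPO.PC2",
                    "VEGE.PC1", "VEGE.PC2", "HDT", "HDP", "RIVERS"))
  pcs <- c("CURE.PC1", "CURE.PC2", "TOPO.PC1", "TOPO.PC2", "VEGE.PC1",
           "VEGE.PC2")
  expect_true(all(abs(colMeans(pred[pcs])) < 1e-10))
  expect_true(is.factor(pred$RIVERS))
  expect_gte(nlevels(pred$RIVERS), 2)
})
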