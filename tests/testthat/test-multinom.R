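test_that("the intercept-only model recovers class frequencies and closed-form deviance", {
  y <- factor(rep(c("a", "b", "c"), times = c(10, 6, 4)))
  fit <- fit_multinomial(NULL, y)
  freq <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(colMeans(fit$fitted)[names(freq)], freq, tolerance = 1e-5)
  d_expected <- -2 * sum(c(10, 6, 4) * log(c(10, 6, 4) / 20))
  expect_equal(fit$deviance, d_expected, tolerance = 1e-5)
  expect_equal(fit$n_params, 2L)
})

test_that("the two-class case matches the binomial GLM maximum likelihood", {
  set.seed(60)
  X <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  eta <- 0.5 + 1.2 * X$x1 - 0.8 * X$x2
  y <- factor(ifelse(runif(60) < plogis(eta), "pos", "neg"))
  fit <- fit_multinomial(X, y, reference = "neg", standardize = FALSE)
  glm_fit <- stats::glm(y ~ x1 + x2, data = cbind(X, y = y),
                        family = stats::binomial())
  expect_equal(unname(fit$coefficients[, "pos"]),
               unname(stats::coef(glm_fit)), tolerance = 1e-4)
  expect_equal(fit$deviance, glm_fit$deviance, tolerance = 1e-6)
})

test_that("deviance agrees with the nnet reference implementation on 3 classes", {
  set.seed(61)
  n <- 150
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- factor(sample(c("r1", "r2", "r3"), n, TRUE,
                     prob = c(0.5, 0.3, 0.2)))
  fit <- fit_multinomial(X, y, standardize = FALSE)
  nn <- nnet::multinom(y ~ x1 + x2, data = cbind(X, y = y), trace = FALSE,
                       reltol = 1e-12)
  expect_equal(fit$deviance, nn$deviance, tolerance = 1e-5)
})

test_that("predicted probabilities sum to one per cell", {
  set.seed(62)
  X <- data.frame(x = rnorm(80), g = factor(sample(letters[1:3], 80, TRUE)))
  y <- factor(sample(1:4, 80, TRUE))
  fit <- fit_multinomial(X, y)
  expect_equal(unname(rowSums(fit$fitted)), rep(1, 80), tolerance = 1e-9)
})

test_that("parameter counting handles dummy-coded categoricals (7 classes, 96 params)", {
  set.seed(63)
  n <- 400
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  X$RIVERS <- factor(sample(paste0("bank", 1:10), n, TRUE))
  y <- factor(sample(paste0("BR", 1:7), n, TRUE))
  fit <- fit_multinomial(X, y, ridge_lambda = 1e-6, maxit = 5)
  expect_equal(fit$n_params, 6L * (1L + 6L + 9L))
  expect_equal(fit$n_params, 96L)
})

test_that("ridge keeps estimates finite under perfect separation", {
  set.seed(64)
  g <- factor(rep(c("L", "R"), each = 25))
  y <- factor(rep(c("north", "south"), each = 25))   # g predicts y exactly
  fit <- fit_multinomial(data.frame(g = g), y, ridge_lambda = 1e-4)
  expect_true(all(is.finite(fit$coefficients)))
  expect_lt(fit$deviance, 1)   # near-perfect classification
})

test_that("known coefficients are recovered within 3 SE at large n", {
  set.seed(65)
  n <- 2000
  hits <- 0; total <- 0
  for (rep in 1:5) {
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    B <- cbind(c(-0.3, 0.8, -0.5), c(0.2, -0.6, 1.0))  # classes 2,3 vs ref
    eta <- cbind(0, as.matrix(cbind(1, X)) %*% B)
    P <- exp(eta) / rowSums(exp(eta))
    y <- factor(apply(P, 1, function(p) sample(1:3, 1, prob = p)))
    fit <- fit_multinomial(X, y, reference = "1", standardize = FALSE,
                           hessian = TRUE)
    se <- matrix(sqrt(diag(fit$vcov)), nrow = 3)
    hits <- hits + sum(abs(fit$coefficients - B) <= 3 * se)
    total <- total + length(B)
  }
  expect_gte(hits / total, 0.95)
})

test_that("AICc follows its closed form and limits", {
  fit <- list(deviance = 200, n_params = 5)
  expect_equal(aicc(fit, 50), 210 + 60 / 44)
  expect_lt(abs(aicc(fit, 1e6) - 210), 1e-3)      # AICc -> AIC
  richer <- list(deviance = 200, n_params = 8)
  expect_gt(aicc(richer, 50), aicc(fit, 50))      # monotone penalty
  expect_error(aicc(list(deviance = 1, n_params = 49), 50), "AICc undefined")
})

test_that("Akaike weights normalize, shift-invariantly, over the candidate set", {
  w <- akaike_weights(c(100, 100))
  expect_equal(w, c(0.5, 0.5))
  expect_equal(akaike_weights(42), 1)
  set.seed(66)
  a <- runif(8, 100, 140)
  expect_equal(sum(akaike_weights(a)), 1)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3))
})

test_that("percent deviance explained spans its closed-form anchors", {
  null_fit <- list(deviance = 200)
  expect_equal(percent_deviance_explained(list(deviance = 200), null_fit), 0)
  expect_equal(percent_deviance_explained(list(deviance = 40), null_fit), 80)
  expect_equal(percent_deviance_explained(list(deviance = 0), null_fit), 100)
  expect_error(percent_deviance_explained(list(deviance = 0),
                                          list(deviance = 0)), "zero")
})
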