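#' Multinomial logistic regression by direct likelihood maximization
#'
#' Fits a softmax-link multinomial model: one linear predictor per
#' non-reference class, class probabilities
#' \deqn{P(y_i = k) = \exp(x_i^\top \beta_k) / \sum_l \exp(x_i^\top \beta_l)}
#' with the reference class's coefficients fixed at zero. The log-likelihood
#' is maximized by BFGS with analytic gradients. An optional L2 (ridge)
#' penalty `ridge_lambda * sum(beta^2)` on non-intercept coefficients keeps
#' estimates finite under (quasi-)separation — e.g. when a categorical
#' predictor perfectly predicts the regions; the reported log-likelihood and
#' deviance are always the *unpenalized* values at the optimum, so AICc
#' comparisons across models remain on one scale.
#'
#' @param X Data frame of predictor terms (numeric and/or factor), or
#'   `NULL` for an intercept-only model. Factors are dummy-coded with
#'   treatment contrasts against their most frequent level.
#' @param y Region labels (coerced to factor).
#' @param ridge_lambda Non-negative ridge penalty (default 0).
#' @param reference Reference class; default the most frequent class.
#' @param standardize Standardize numeric terms to mean 0 / SD 1 before
#'   fitting (default `TRUE`; coefficients are reported on the transformed
#'   scale — deviance, AICc and %DE are unaffected).
#' @param maxit Maximum BFGS iterations.
#' @param hessian Also return the numerically-differentiated Hessian of the
#'   negative log-likelihood at the optimum (for standard errors).
#' @return A `multinom_fit`: list with `coefficients` (p x (K-1) matrix,
#'   columns the non-reference classes), `class_labels`, `reference`,
#'   `log_likelihood` (unpenalized), `deviance` (= -2 log_likelihood),
#'   `n_params` = (K-1) * p, `converged`, `ridge_lambda`, `fitted` (n x K
#'   probabilities, columns in `class_labels` order), `n`, and optionally
#'   `vcov`.
#' @export
fit_multinomial <- function(X, y, ridge_lambda = 0, reference = NULL,
                            standardize = TRUE, maxit = 1000L,
                            hessian = FALSE) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes present", call. = FALSE)
  n <- length(y)
  if (is.null(reference)) reference <- names(which.max(table(y)))
  lev <- c(reference, setdiff(levels(y), reference))
  y <- factor(y, levels = lev)

  if (is.null(X) || (is.data.frame(X) && ncol(X) == 0L)) {
    Xd <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == n)
    for (nm in names(X)) {
      if (is.character(X[[nm]])) X[[nm]] <- factor(X[[nm]])
      if (is.factor(X[[nm]])) {
        tb <- table(X[[nm]])
        X[[nm]] <- stats::relevel(droplevels(X[[nm]]),
                                  ref = names(which.max(tb)))
      } else if (standardize) {
        s <- stats::sd(X[[nm]])
        X[[nm]] <- (X[[nm]] - mean(X[[nm]])) / if (s > 0) s else 1
      }
    }
    Xd <- stats::model.matrix(~ ., data = X)
  }
  p <- ncol(Xd)
  K <- nlevels(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  pen_mask <- rep(1, p); pen_mask[colnames(Xd) == "(Intercept)"] <- 0

  probs_of <- function(B) {
    eta <- cbind(0, Xd %*% B)              # reference column first
    eta <- eta - apply(eta, 1L, max)
    ex <- exp(eta)
    ex / rowSums(ex)
  }
  negll <- function(theta) {
    B <- matrix(theta, p, K - 1L)
    P <- probs_of(B)
    ll <- sum(Y * log(pmax(P, 1e-300)))
    -ll + ridge_lambda * sum((pen_mask * B)^2)
  }
  grad <- function(theta) {
    B <- matrix(theta, p, K - 1L)
    P <- probs_of(B)
    G <- crossprod(Xd, P[, -1L, drop = FALSE] - Y[, -1L, drop = FALSE])
    as.vector(G + 2 * ridge_lambda * (pen_mask * B))
  }

  opt <- stats::optim(rep(0, p * (K - 1L)), negll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10),
                      hessian = hessian)
  B <- matrix(opt$par, p, K - 1L,
              dimnames = list(colnames(Xd), lev[-1L]))
  P <- probs_of(B)
  colnames(P) <- lev
  ll <- sum(Y * log(pmax(P, 1e-300)))      # unpenalized
  # optim's code 1 only says maxit was hit; on the near-flat plateau that a
  # ridge penalty creates under separation, the gradient is the honest test
  converged <- opt$convergence == 0L ||
    max(abs(grad(opt$par))) < 1e-4 * max(1, n / 100)
  if (!converged && ridge_lambda == 0)
    warning("multinomial fit did not converge (possible separation); ",
            "consider ridge_lambda > 0", call. = FALSE)

  out <- list(coefficients = B, class_labels = lev, reference = reference,
              log_likelihood = ll, deviance = -2 * ll,
              n_params = (K - 1L) * p, converged = converged,
              ridge_lambda = ridge_lambda, fitted = P, n = n,
              terms = if (is.null(X)) character(0) else names(X))
  if (hessian) out$vcov <- tryCatch(solve(opt$hessian),
                                    error = function(e) NULL)
  class(out) <- "multinom_fit"
  out
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf(
    "multinomial fit: %d classes (ref '%s'), %d params, deviance %.2f%s\n",
    length(x$class_labels), x$reference, x$n_params, x$deviance,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' AIC = deviance + 2 q and AICc = AIC + 2 q (q + 1) / (n - q - 1), with q
#' the parameter count. The correction requires n - q - 1 > 0.
#'
#' @param fit A `multinom_fit`, or any list with `deviance` and `n_params`.
#' @param n Sample size (number of grid cells).
#' @return AICc value.
#' @export
aicc <- function(fit, n) {
  q <- fit$n_params
  if (n - q - 1 <= 0)
    stop(sprintf("AICc undefined: n - q - 1 = %d <= 0 (model too rich)",
                 n - q - 1), call. = FALSE)
  fit$deviance + 2 * q + 2 * q * (q + 1) / (n - q - 1)
}

#' Akaike weights
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2) with Delta_i the AICc
#' difference to the best model; the relative likelihood of each candidate
#' model given the data and the candidate set. Invariant to adding a
#' constant to every AICc.
#'
#' @param aicc_values Finite numeric vector of AICc (or Delta-AICc) values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1L, all(is.finite(aicc_values)))
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Percent deviance explained
#'
#' 100 (D0 - D) / D0, with D0 the deviance of the intercept-only model on
#' the same data — the categorical-response analogue of R-squared.
#'
#' @param fit Model fit (`deviance` element).
#' @param null_fit Intercept-only fit on the same data.
#' @return %DE in `[0, 100]` for converged nested fits.
#' @export
percent_deviance_explained <- function(fit, null_fit) {
  d0 <- null_fit$deviance
  if (d0 <= 0) stop("null deviance is zero", call. = FALSE)
  100 * (d0 - fit$deviance) / d0
}
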