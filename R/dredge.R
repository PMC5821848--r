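#' All-subsets multinomial model ranking by AICc
#'
#' Fits every subset of the candidate terms (including the intercept-only
#' model, so 2^t fits), ranks by AICc, and attaches Delta-AICc, Akaike
#' weights (normalized over all converged fits) and percent deviance
#' explained. Ordering is deterministic: AICc ascending, ties broken by
#' fewer terms, then by the lexicographic term string.
#'
#' @param terms_df Data frame of candidate predictor terms (columns =
#'   terms; numeric or factor).
#' @param y Region labels.
#' @param n Sample size for AICc (default: number of cells).
#' @param ridge_lambda Ridge penalty passed to [fit_multinomial()].
#' @param ... Further arguments to [fit_multinomial()].
#' @return A `model_ranking`: list with `table` (data frame: `terms`,
#'   `n_terms`, `df`, `deviance`, `AICc`, `delta_AICc`, `wAICc`, `pct_DE`,
#'   `converged`), `best_terms` (character vector), `null_deviance`, `n`.
#'   Non-converged fits keep their row with `AICc = NA` and weight 0.
#' @export
dredge_models <- function(terms_df, y, n = nrow(terms_df), ridge_lambda = 0,
                          ...) {
  terms_df <- as.data.frame(terms_df)
  term_names <- names(terms_df)
  t <- length(term_names)
  null_fit <- fit_multinomial(NULL, y, ridge_lambda = ridge_lambda, ...)

  subsets <- lapply(0:(2^t - 1L), function(mask)
    term_names[bitwAnd(mask, bitwShiftL(1L, seq_len(t) - 1L)) != 0L])

  rows <- lapply(subsets, function(terms) {
    fit <- if (length(terms) == 0L) null_fit else
      fit_multinomial(terms_df[terms], y, ridge_lambda = ridge_lambda, ...)
    ok <- fit$converged
    ai <- if (ok) tryCatch(aicc(fit, n), error = function(e) NA_real_)
          else NA_real_
    data.frame(
      terms = if (length(terms)) paste(sort(terms), collapse = " + ")
              else "(intercept only)",
      n_terms = length(terms),
      df = fit$n_params,
      deviance = fit$deviance,
      AICc = ai,
      pct_DE = percent_deviance_explained(fit, null_fit),
      converged = ok,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (any(!tab$converged | is.na(tab$AICc)))
    warning(sum(!tab$converged | is.na(tab$AICc)),
            " model(s) excluded from AICc weights (non-converged or AICc ",
            "undefined)", call. = FALSE)

  ok <- is.finite(tab$AICc)
  tab$delta_AICc <- tab$AICc - min(tab$AICc[ok])
  tab$wAICc <- 0
  tab$wAICc[ok] <- akaike_weights(tab$AICc[ok])
  ord <- order(ifelse(ok, tab$AICc, Inf), tab$n_terms, tab$terms)
  tab <- tab[ord, c("terms", "n_terms", "df", "deviance", "AICc",
                    "delta_AICc", "wAICc", "pct_DE", "converged")]
  rownames(tab) <- NULL
  best_terms <- if (tab$terms[1L] == "(intercept only)") character(0)
                else strsplit(tab$terms[1L], " \\+ ")[[1L]]
  structure(list(table = tab, best_terms = best_terms,
                 null_deviance = null_fit$deviance, n = n,
                 ridge_lambda = ridge_lambda),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat(sprintf("model ranking: %d candidate models, n = %d\n",
              nrow(x$table), x$n))
  print(utils::head(x$table[, c("terms", "df", "delta_AICc", "wAICc",
                                "pct_DE")], 6), row.names = FALSE)
  invisible(x)
}

subset_masks <- function(groups) {
  g <- length(groups)
  lapply(1:(2^g - 1L), function(mask)
    groups[bitwAnd(mask, bitwShiftL(1L, seq_len(g) - 1L)) != 0L])
}

#' Deviance partitioning across predictor groups
#'
#' Partitions the percent deviance explained by the full model into unique
#' and shared fractions of the predictor groups — by convention C (current
#' plus historical climate), T (topography), R (rivers), V (vegetation) —
#' by fitting the models on all non-empty unions of groups and applying
#' inclusion-exclusion. Shared fractions may be negative, as usual for
#' variation partitioning. The fractions sum exactly to the full model's
#' %DE; `unexplained` is its complement to 100.
#'
#' @param terms_df Data frame holding the terms of (typically) the best
#'   model.
#' @param groups Named character vector mapping each column of `terms_df`
#'   to a group code (e.g. `c(CURE.PC1 = "C", ..., RIVERS = "R")`). Groups
#'   with no terms contribute zero fractions.
#' @param y Region labels.
#' @param n Sample size (unused by the partition itself; kept for the
#'   record).
#' @param ridge_lambda Ridge penalty passed to the component fits.
#' @param ... Further arguments to [fit_multinomial()].
#' @return A `deviance_partition`: list with `fractions` (data frame:
#'   `component` such as `"R"` or `"C:T"`, `fraction` in %DE points),
#'   `pct_DE` (per group-union %DE), `full_pct_DE`, `unexplained`,
#'   `groups`.
#' @export
partition_deviance <- function(terms_df, groups, y, n = nrow(terms_df),
                               ridge_lambda = 0, ...) {
  terms_df <- as.data.frame(terms_df)
  groups <- groups[names(groups) %in% names(terms_df)]
  present <- sort(unique(unname(groups)))
  if (length(present) < 2L)
    stop("deviance partitioning needs >= 2 non-empty predictor groups",
         call. = FALSE)
  null_fit <- fit_multinomial(NULL, y, ridge_lambda = ridge_lambda, ...)

  de_of_union <- function(gs) {
    if (!length(gs)) return(0)
    terms <- names(groups)[groups %in% gs]
    fit <- fit_multinomial(terms_df[terms], y, ridge_lambda = ridge_lambda,
                           ...)
    percent_deviance_explained(fit, null_fit)
  }
  unions <- subset_masks(present)
  R <- vapply(unions, de_of_union, numeric(1))
  names(R) <- vapply(unions, paste, character(1), collapse = ":")
  R_of <- function(gs) if (!length(gs)) 0 else
    R[[paste(sort(gs), collapse = ":")]]
  full <- R_of(present)

  # h(B) = %DE(all) - %DE(all \ B); Moebius inversion over subsets of B
  # gives the fraction attributable exactly to the groups in S
  h_of <- function(gs) full - R_of(setdiff(present, gs))
  fractions <- vapply(unions, function(S) {
    Ts <- subset_masks(S)
    val <- sum(vapply(Ts, function(T)
      (-1)^(length(S) - length(T)) * h_of(T), numeric(1)))
    val
  }, numeric(1))
  frac_df <- data.frame(
    component = vapply(unions, paste, character(1), collapse = ":"),
    fraction = fractions, stringsAsFactors = FALSE)

  structure(list(fractions = frac_df, pct_DE = R, full_pct_DE = full,
                 unexplained = 100 - full, groups = groups),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat(sprintf("deviance partition: full model %%DE = %.1f\n", x$full_pct_DE))
  df <- x$fractions[order(-abs(x$fractions$fraction)), ]
  print(utils::head(df, 8), row.names = FALSE)
  cat(sprintf("unexplained: %.1f\n", x$unexplained))
  invisible(x)
}
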