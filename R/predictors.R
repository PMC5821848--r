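#' Group-wise principal components of standardized variables
#'
#' Standardizes each variable to mean 0 / unit SD (constant columns are
#' dropped with a warning), performs PCA on the correlation structure, and
#' returns the first `n_axes` score columns. Axis signs are fixed so the
#' loading of largest magnitude on each axis is positive, making score
#' orientation reproducible across platforms.
#'
#' @param tab Data frame or matrix of raw variables for one predictor group
#'   (>= 2 variables, >= 3 cells, no missing values).
#' @param n_axes Number of axes to return (default 2).
#' @return List with `scores` (cells x n_axes, columns `PC1`, `PC2`, ...),
#'   `loadings` (variables x axes), `variance_fraction` (per retained axis),
#'   `dropped` (names of constant columns removed).
#' @export
group_pca <- function(tab, n_axes = 2L) {
  tab <- as.data.frame(tab)
  num <- vapply(tab, is.numeric, logical(1))
  tab <- tab[num]
  if (ncol(tab) < 2L) stop("group_pca needs at least 2 numeric variables",
                           call. = FALSE)
  if (nrow(tab) < 3L) stop("group_pca needs at least 3 cells", call. = FALSE)
  if (anyNA(tab)) stop("missing values in PCA input", call. = FALSE)
  sds <- vapply(tab, stats::sd, numeric(1))
  dropped <- names(tab)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    tab <- tab[sds > 0]
  }
  if (n_axes > ncol(tab))
    stop("n_axes exceeds the number of (non-constant) variables", call. = FALSE)
  pc <- stats::prcomp(tab, center = TRUE, scale. = TRUE)
  keep <- seq_len(n_axes)
  rot <- pc$rotation[, keep, drop = FALSE]
  sc <- pc$x[, keep, drop = FALSE]
  for (j in keep) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  varfrac <- (pc$sdev^2 / sum(pc$sdev^2))[keep]
  list(scores = sc, loadings = rot, variance_fraction = varfrac,
       dropped = dropped)
}

#' Pearson correlations between raw variables and PC axes
#'
#' For every (variable, axis) pair, the Pearson correlation coefficient and
#' its two-sided t-test p-value — the standard check of which raw
#' environmental variables each retained axis represents. No multiplicity
#' correction is applied.
#'
#' @param scores Cells x axes score matrix (e.g. from [group_pca()]).
#' @param raw Data frame of the raw variables (same cells, same order).
#' @return Data frame with `variable`, `axis`, `r`, `p` (`NA` for
#'   zero-variance variables).
#' @export
pc_variable_correlations <- function(scores, raw) {
  scores <- as.matrix(scores)
  raw <- as.data.frame(raw)
  if (nrow(scores) != nrow(raw))
    stop("scores and raw table must cover the same cells", call. = FALSE)
  out <- expand.grid(variable = names(raw), axis = colnames(scores),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- raw[[out$variable[i]]]
    y <- scores[, out$axis[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- stats::cor.test(x, y)
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' Historical climate difference (current minus LGM mean)
#'
#' Averages the Last Glacial Maximum fields across circulation models
#' first, then subtracts from the current field, yielding per-cell
#' historical differences (HDT for temperature, HDP for precipitation).
#'
#' @param current Named numeric vector (names = cell ids) or plain vector.
#' @param lgm_fields Matrix/data frame with one column per circulation
#'   model, or list of vectors, aligned to the same cells.
#' @return Numeric vector, current - mean(LGM).
#' @export
historical_difference <- function(current, lgm_fields) {
  if (is.list(lgm_fields) && !is.data.frame(lgm_fields))
    lgm_fields <- do.call(cbind, lgm_fields)
  lgm_fields <- as.matrix(lgm_fields)
  if (nrow(lgm_fields) != length(current))
    stop("current and LGM fields cover different cell sets", call. = FALSE)
  if (!is.null(names(current)) && !is.null(rownames(lgm_fields)) &&
      !identical(names(current), rownames(lgm_fields)))
    stop("current and LGM fields cover different cell sets", call. = FALSE)
  current - rowMeans(lgm_fields)
}

#' Assemble the reduced per-cell predictor table
#'
#' Applies the three group-wise PCAs (current climate, topography,
#' vegetation percentages), computes the historical-difference variables
#' HDT and HDP, and attaches the river-bank category, yielding the nine
#' predictors used by the driver models: CURE.PC1, CURE.PC2, TOPO.PC1,
#' TOPO.PC2, VEGE.PC1, VEGE.PC2, HDT, HDP, RIVERS.
#'
#' @param env Environment table from [sample_environment()] (or any table
#'   with the same columns and attributes).
#' @param lat Lattice providing the per-cell river-bank category.
#' @param cell_ids Optional subset/order of cells to keep.
#' @return Data frame keyed by `cell_id` with the nine predictors; PC score
#'   columns have mean 0. Attribute `pca` holds the three [group_pca()]
#'   fits, `groups` the term-to-group map used by deviance partitioning.
#' @export
build_predictor_table <- function(env, lat, cell_ids = NULL) {
  if (!is.null(cell_ids)) {
    env <- env[match(cell_ids, env$cell_id), , drop = FALSE]
    stopifnot(!anyNA(env$cell_id))
  }
  clim_cols <- c("AMAXTE", "AMINTE", "TESE", "APRE", "PRER", "PRSE")
  topo_cols <- c("TOPOMAX", "TOPOMIN", "TOPOSTD", "SLOPERAN", "SLOPESTD",
                 "ASPECTSTD")
  veg_cols <- attr(env, "veg_cols")
  if (is.null(veg_cols)) veg_cols <- grep("^VEG_", names(env), value = TRUE)

  cure <- group_pca(env[clim_cols], 2L)
  topo <- group_pca(env[topo_cols], 2L)
  vege <- group_pca(env[veg_cols], 2L)

  prec_cols <- attr(env, "lgm_prec_cols")
  temp_cols <- attr(env, "lgm_temp_cols")
  if (is.null(prec_cols)) prec_cols <- grep("^LGM_PREC_", names(env), value = TRUE)
  if (is.null(temp_cols)) temp_cols <- grep("^LGM_TEMP_", names(env), value = TRUE)
  hdp <- historical_difference(env$APRE, env[prec_cols])
  hdt <- historical_difference(env$AMTE, env[temp_cols])

  rb <- lat$cells$river_bank[match(env$cell_id, lat$cells$cell_id)]
  out <- data.frame(
    cell_id = env$cell_id,
    CURE.PC1 = cure$scores[, 1], CURE.PC2 = cure$scores[, 2],
    TOPO.PC1 = topo$scores[, 1], TOPO.PC2 = topo$scores[, 2],
    VEGE.PC1 = vege$scores[, 1], VEGE.PC2 = vege$scores[, 2],
    HDT = hdt, HDP = hdp,
    RIVERS = factor(rb),
    stringsAsFactors = FALSE
  )
  attr(out, "pca") <- list(CURE = cure, TOPO = topo, VEGE = vege)
  attr(out, "groups") <- c(
    CURE.PC1 = "C", CURE.PC2 = "C", HDT = "C", HDP = "C",
    TOPO.PC1 = "T", TOPO.PC2 = "T",
    RIVERS = "R",
    VEGE.PC1 = "V", VEGE.PC2 = "V"
  )
  out
}
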