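#' Default environmental gradient specification
#'
#' One entry per field: `direction` ("row", "col" or "radial"), `range`
#' (value at the start and end of the gradient) and `noise` (standard
#' deviation of i.i.d. Gaussian noise added per cell). Units follow the
#' conventions of gridded climatologies: temperatures in degrees C,
#' precipitation in mm/year, elevations in m.
#'
#' Fields cover the six current-climate variables (AMAXTE, AMINTE, TESE,
#' APRE, PRER, PRSE), annual mean temperature (AMTE, used with APRE to form
#' the historical-difference variables), and six topographic-heterogeneity
#' measures (TOPOMAX is derived from TOPOMIN plus a non-negative relief
#' field so that TOPOMAX >= TOPOMIN holds cell-wise).
#'
#' @return Named list of per-field gradient specs.
#' @export
default_gradients <- function() {
  g <- function(direction, range, noise)
    list(direction = direction, range = range, noise = noise)
  list(
    AMAXTE    = g("row",    c(30, 34),      0.4),
    AMINTE    = g("row",    c(18, 23),      0.4),
    TESE      = g("radial", c(0.4, 1.6),    0.08),
    APRE      = g("col",    c(1200, 3200),  90),
    PRER      = g("col",    c(80, 260),     12),
    PRSE      = g("radial", c(20, 70),      4),
    AMTE      = g("row",    c(24, 28),      0.3),
    TOPOMIN   = g("radial", c(20, 450),     25),
    RELIEF    = g("col",    c(40, 700),     40),   # TOPOMAX = TOPOMIN + RELIEF
    TOPOSTD   = g("col",    c(10, 170),     12),
    SLOPERAN  = g("col",    c(2, 25),       1.5),
    SLOPESTD  = g("col",    c(0.5, 6),      0.4),
    ASPECTSTD = g("radial", c(30, 110),     8)
  )
}

gradient_field <- function(lat, direction, range, noise) {
  r <- lat$cells$row; c <- lat$cells$col
  t <- switch(direction,
    row = if (lat$n_rows > 1L) (r - 1) / (lat$n_rows - 1) else rep(0, length(r)),
    col = if (lat$n_cols > 1L) (c - 1) / (lat$n_cols - 1) else rep(0, length(c)),
    radial = {
      d <- sqrt(((r - (lat$n_rows + 1) / 2))^2 + ((c - (lat$n_cols + 1) / 2))^2)
      if (max(d) > 0) d / max(d) else d
    },
    stop("unknown gradient direction: ", direction, call. = FALSE))
  base <- range[1] + t * (range[2] - range[1])
  if (noise > 0) base + stats::rnorm(length(base), 0, noise) else base
}

#' Sample environmental fields over a lattice
#'
#' Generates smooth climate and topography gradients with seeded noise,
#' per-circulation-model Last Glacial Maximum (LGM) analogues of annual
#' precipitation and annual mean temperature, and vegetation-type
#' percentages, emulating the structure of gridded climatological and
#' elevation data extracted per grid cell.
#'
#' LGM fields are the corresponding current field shifted by `lgm_offset`
#' (LGM = current - offset; a cooler, drier glacial climate has positive
#' offsets) plus model-specific noise of standard deviation `lgm_noise`,
#' one replicate field per circulation model. Vegetation percentages are
#' softmax-normalized positive mixtures of gradients, so each cell's
#' percentages are non-negative and sum to 100.
#'
#' @param lat A [make_lattice()] object.
#' @param gradient_spec Per-field gradient specification; see
#'   [default_gradients()].
#' @param n_lgm_models Number of LGM circulation models to emulate (>= 1).
#' @param lgm_offset Named numeric, current-minus-LGM offsets for `APRE`
#'   (mm) and `AMTE` (deg C).
#' @param lgm_noise Standard deviation of per-model LGM noise (same units
#'   as the field).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Data frame with `cell_id`, one column per field, LGM columns
#'   `LGM_PREC_<i>` / `LGM_TEMP_<i>`, and vegetation percentage columns
#'   `VEG_*`. Attributes `veg_cols`, `lgm_prec_cols`, `lgm_temp_cols` name
#'   the column groups.
#' @export
sample_environment <- function(lat, gradient_spec = default_gradients(),
                               n_lgm_models = 3L,
                               lgm_offset = c(APRE = 300, AMTE = 4),
                               lgm_noise = c(APRE = 60, AMTE = 0.6),
                               seed = 1L) {
  stopifnot(inherits(lat, "lattice"), n_lgm_models >= 1L)
  bad <- vapply(gradient_spec, function(g) g$noise < 0, logical(1))
  if (any(bad)) stop("noise level must be >= 0", call. = FALSE)
  set.seed(seed)

  env <- data.frame(cell_id = lat$cells$cell_id, stringsAsFactors = FALSE)
  for (nm in names(gradient_spec)) {
    g <- gradient_spec[[nm]]
    env[[nm]] <- gradient_field(lat, g$direction, g$range, g$noise)
  }
  if (all(c("TOPOMIN", "RELIEF") %in% names(env))) {
    env$TOPOMAX <- env$TOPOMIN + pmax(env$RELIEF, 0)
    env$RELIEF <- NULL
  }

  lgm_prec_cols <- character(0); lgm_temp_cols <- character(0)
  for (i in seq_len(n_lgm_models)) {
    pc <- sprintf("LGM_PREC_%d", i); tc <- sprintf("LGM_TEMP_%d", i)
    env[[pc]] <- env$APRE - lgm_offset[["APRE"]] +
      stats::rnorm(nrow(env), 0, lgm_noise[["APRE"]])
    env[[tc]] <- env$AMTE - lgm_offset[["AMTE"]] +
      stats::rnorm(nrow(env), 0, lgm_noise[["AMTE"]])
    lgm_prec_cols <- c(lgm_prec_cols, pc); lgm_temp_cols <- c(lgm_temp_cols, tc)
  }

  # vegetation mixture: moist forest follows precipitation, dry forest the
  # reverse, varzea tracks river proximity crudely via rows, montane follows
  # relief, mangrove is rare and edge-bound
  veg_types <- c("VEG_MOIST", "VEG_DRY", "VEG_VARZEA", "VEG_MANGROVE",
                 "VEG_MONTANE")
  p01 <- function(x) (x - min(x)) / max(max(x) - min(x), 1e-12)
  raw <- cbind(
    2.0 + 2.0 * p01(env$APRE),
    1.5 - 1.2 * p01(env$APRE),
    0.2 + 0.8 * p01(-abs(lat$cells$row - (lat$n_rows + 1) / 2)),
    -1.5 + 1.0 * p01(lat$cells$col),
    -0.5 + 2.0 * p01(env$TOPOMAX)
  ) + matrix(stats::rnorm(nrow(env) * 5, 0, 0.3), ncol = 5)
  ex <- exp(raw)
  pct <- 100 * ex / rowSums(ex)
  colnames(pct) <- veg_types
  env <- cbind(env, as.data.frame(pct))

  attr(env, "veg_cols") <- veg_types
  attr(env, "lgm_prec_cols") <- lgm_prec_cols
  attr(env, "lgm_temp_cols") <- lgm_temp_cols
  env
}
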