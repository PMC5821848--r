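#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end analysis. Exactly one of
#' `input` (paths to an existing incidence/cell/environment CSV triple) or
#' `simulation` (a synthetic-landscape spec) must be given; `seed` is
#' mandatory when simulating.
#'
#' Defaults mirror the regionalization settings of the motivating analysis:
#' `k_max = 50`, `n_reorder = 50`, explained-dissimilarity threshold 0.90,
#' Ward variant `"ward.D"`, ridge penalty `1e-6`.
#'
#' @param input List with `incidence`, `cells`, `environment` CSV paths, or
#'   `NULL`.
#' @param simulation List with `n_rows`, `n_cols`, `rivers` (list of
#'   [river_h()]/[river_v()]), `n_species`, `crossing_prob`, `range_size`,
#'   `niche_breadth`, `n_lgm_models`; or `NULL`.
#' @param filter_threshold Small-range cutoff passed to
#'   [filter_small_ranges()] (default 0).
#' @param k_max,n_reorder,threshold,ward_variant Regionalization settings,
#'   see [scan_regions()] / [select_k()].
#' @param ridge_lambda Ridge penalty for driver models.
#' @param dredge Run the all-subsets model ranking (default `TRUE`).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            filter_threshold = 0L,
                            k_max = 50L, n_reorder = 50L, threshold = 0.90,
                            ward_variant = "ward.D", ridge_lambda = 1e-6,
                            dredge = TRUE, seed = NULL, out_dir = NULL) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of `input` and `simulation` must be supplied",
         call. = FALSE)
  if (!is.null(simulation) && is.null(seed))
    stop("`seed` is mandatory when simulating", call. = FALSE)
  cfg <- list(input = input, simulation = simulation,
              filter_threshold = as.integer(filter_threshold),
              k_max = as.integer(k_max), n_reorder = as.integer(n_reorder),
              threshold = threshold, ward_variant = ward_variant,
              ridge_lambda = ridge_lambda, dredge = isTRUE(dredge),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file whose keys match the arguments
#'   of [pipeline_config()]. River entries are lists with `orientation`
#'   ("h"/"v"), `position`, and optional `from`/`to`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation$rivers))
    raw$simulation$rivers <- lapply(raw$simulation$rivers, function(rv) {
      f <- if (identical(rv$orientation, "h")) river_h else river_v
      f(rv$position, rv$from %||% 1L, rv$to %||% NA_integer_)
    })
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# short stable content hash (polynomial rolling hash over the deparsed object)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_table <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the end-to-end regionalization pipeline
#'
#' Simulate (or ingest) an incidence matrix, filter small-ranged species
#' and empty cells, compute pairwise Simpson turnover, scan cluster counts
#' over randomized-order Ward replicates, select the number of regions,
#' build the consensus region map, summarize cells, and attribute regions
#' to predictors (group PCAs, HDT/HDP, rivers) via AICc model ranking and
#' four-group deviance partitioning. All tabular outputs are written as CSV
#' under `cfg$out_dir`; a JSON manifest records the configuration, seed,
#' per-stage dimensions and headline results.
#'
#' @param cfg A [pipeline_config()].
#' @return The run manifest (list), invisibly; its `results` element holds
#'   the in-memory stage outputs (`scan`, `regions`, `ranking`,
#'   `partition`, ...).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir %||% tempfile("betaregion_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    log[[name]] <<- list(seconds = as.numeric(Sys.time() - t0, units = "secs"))
    message(sprintf("[%s] done (%.1fs)", name, log[[name]]$seconds))
    res
  }

  sim <- NULL; lat <- NULL; env <- NULL
  if (!is.null(cfg$simulation)) {
    sp <- cfg$simulation
    lat <- stage("lattice", make_lattice(sp$n_rows, sp$n_cols,
                                         sp$rivers %||% list()))
    env <- stage("environment",
                 sample_environment(lat,
                                    n_lgm_models = sp$n_lgm_models %||% 3L,
                                    seed = cfg$seed))
    sim <- stage("species",
                 simulate_species(lat, env,
                                  n_species = sp$n_species,
                                  range_size = sp$range_size %||%
                                    list(dist = "uniform", min = 5, max = 30),
                                  crossing_prob = sp$crossing_prob %||% 0,
                                  niche_breadth = sp$niche_breadth %||% Inf,
                                  seed = cfg$seed + 1L))
    inc <- sim$incidence
    write_table(lat$cells, out_dir, "cell_table.csv")
    write_table(env, out_dir, "environment.csv")
    write_incidence(inc, file.path(out_dir, "incidence.csv"))
  } else {
    inc <- stage("ingest", read_incidence(cfg$input$incidence))
    lat_cells <- utils::read.csv(cfg$input$cells, stringsAsFactors = FALSE)
    env <- utils::read.csv(cfg$input$environment, check.names = FALSE,
                           stringsAsFactors = FALSE)
    lat <- list(cells = lat_cells)   # minimal lattice view: river_bank column
    class(lat) <- "lattice"
  }
  n_species_in <- ncol(inc)

  inc <- stage("filter", {
    f <- filter_small_ranges(inc, cfg$filter_threshold)
    drop_empty_cells(f)$incidence
  })
  summ <- stage("summaries", summarize_cells(inc))
  write_table(summ, out_dir, "cell_summary.csv")

  d <- stage("turnover", pairwise_turnover(inc))
  scan <- stage("region_scan",
                scan_regions(d, k_max = min(cfg$k_max, nrow(d) - 1L),
                             n_reorder = cfg$n_reorder, seed = cfg$seed,
                             variant = cfg$ward_variant))
  write_table(scan$summary, out_dir, "region_scan.csv")
  k <- stage("select_k", select_k(scan, cfg$threshold))
  regions <- stage("consensus", {
    ki <- match(k, scan$k_values)
    sols <- matrix(scan$labels[, ki, ], nrow = length(scan$cell_ids),
                   dimnames = list(scan$cell_ids, NULL))
    consensus_partition(sols, d)
  })
  write_table(data.frame(cell_id = names(regions), region = regions),
              out_dir, "region_labels.csv")

  pred <- stage("predictors",
                build_predictor_table(env, lat, cell_ids = rownames(inc)))
  y <- factor(regions[pred$cell_id])
  groups <- attr(pred, "groups")
  terms_df <- pred[names(groups)]

  ranking <- NULL
  if (cfg$dredge) {
    ranking <- stage("dredge",
                     dredge_models(terms_df, y, n = nrow(terms_df),
                                   ridge_lambda = cfg$ridge_lambda))
    write_table(ranking$table, out_dir, "model_ranking.csv")
    best <- ranking$best_terms
  } else best <- names(groups)
  part <- stage("partition", {
    bt <- if (length(best)) best else names(groups)
    # partitioning needs >= 2 predictor groups; widen to the full term set
    # if the best model collapsed onto a single group
    if (length(unique(groups[bt])) < 2L) bt <- names(groups)
    partition_deviance(terms_df[bt], groups[bt], y,
                       ridge_lambda = cfg$ridge_lambda)
  })
  write_table(part$fractions, out_dir, "deviance_partition.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("betaregion")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    dimensions = list(cells = nrow(inc), species_in = n_species_in,
                      species_kept = ncol(inc)),
    chosen_k = k,
    best_model_terms = best,
    full_pct_DE = part$full_pct_DE,
    stages = log
  )
  jsonlite::write_json(manifest[setdiff(names(manifest), "config")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$results <- list(lattice = lat, environment = env, sim = sim,
                           incidence = inc, turnover = d, scan = scan,
                           regions = regions, summary = summ,
                           predictors = pred, ranking = ranking,
                           partition = part, out_dir = out_dir)
  invisible(manifest)
}

#' Small-range exclusion sensitivity sweep
#'
#' Reruns the regionalization for each range-size cutoff and reports the
#' chosen number of regions plus the adjusted Rand agreement of each
#' filtered partition with the unfiltered one — the robustness check that
#' regions are not artefacts of narrow-ranged, poorly-sampled species.
#'
#' @param cfg A [pipeline_config()] (its own `filter_threshold` is
#'   ignored).
#' @param thresholds Non-negative increasing integer cutoffs; the first is
#'   the baseline (typically 0).
#' @return Data frame with `threshold`, `n_species`, `n_cells`, `chosen_k`,
#'   `adjusted_rand` (vs the first threshold; 1 for the baseline itself).
#' @export
sensitivity_sweep <- function(cfg, thresholds = c(0L, 1L, 2L, 3L)) {
  stopifnot(all(thresholds >= 0), !is.unsorted(thresholds, strictly = TRUE))
  runs <- lapply(thresholds, function(th) {
    c2 <- cfg; c2$filter_threshold <- as.integer(th); c2$dredge <- FALSE
    c2$out_dir <- tempfile("sweep_")
    man <- suppressMessages(run_pipeline(c2))
    if (man$dimensions$species_kept == 0L)
      stop("threshold ", th, " empties the matrix", call. = FALSE)
    man
  })
  base <- runs[[1L]]$results$regions
  out <- data.frame(
    threshold = thresholds,
    n_species = vapply(runs, function(m) m$dimensions$species_kept, integer(1)),
    n_cells = vapply(runs, function(m) m$dimensions$cells, integer(1)),
    chosen_k = vapply(runs, function(m) m$chosen_k, integer(1)),
    adjusted_rand = vapply(runs, function(m) {
      common <- intersect(names(base), names(m$results$regions))
      adjusted_rand(base[common], m$results$regions[common])
    }, numeric(1))
  )
  out
}
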