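#' Simulate species ranges by spreading dye over a lattice
#'
#' Each species starts from a seed cell and grows a contiguous range by the
#' spreading-dye process: at every step one unoccupied 4-neighbour of the
#' current range is chosen uniformly at random and occupied, until the drawn
#' range size is reached or no admissible neighbour remains. A step whose
#' every connecting edge crosses a river is accepted with probability
#' `crossing_prob` (with `crossing_prob = 0` rivers are absolute barriers
#' and no range spans two blocks). A candidate cell whose climate lies
#' outside the species' niche (`|climate - niche_center| > niche_breadth`,
#' measured on one designated environment field) is never occupied.
#'
#' By default species origins are assigned round-robin across lattice
#' blocks, so every block receives (near-)equal numbers of potential
#' endemics; set `balance_blocks = FALSE` to draw origins uniformly over
#' the lattice.
#'
#' @param lat A [make_lattice()] lattice.
#' @param env Environment table from [sample_environment()] (only needed
#'   when `niche_breadth` is finite).
#' @param n_species Number of species (>= 1).
#' @param range_size Either a numeric vector of per-species target sizes, or
#'   a list such as `list(dist = "uniform", min = 5, max = 30)` or
#'   `list(dist = "lognormal", meanlog = 2.3, sdlog = 0.6)`. Draws are
#'   rounded to integers and floored at 1; sizes larger than the lattice are
#'   capped with a warning.
#' @param crossing_prob Probability in `[0, 1]` that a river-crossing growth
#'   step is accepted.
#' @param niche_field Environment column used for niche filtering.
#' @param niche_breadth Half-width of the climatic niche, in the units of
#'   `niche_field`; `Inf` disables filtering. Either a scalar or a
#'   per-species vector.
#' @param niche_centers Optional per-species niche centres; default is the
#'   `niche_field` value at the species' seed cell.
#' @param balance_blocks Assign species origins round-robin over blocks.
#' @param max_attempts Cap on consecutive rejected river-crossing draws per
#'   growth step before growth stops early (guards against near-zero
#'   `crossing_prob` loops).
#' @param seed Integer seed. Per-species random substreams are derived from
#'   it, so output is byte-identical across runs with the same arguments.
#' @return List with `incidence` (cells x species 0/1 integer matrix, row
#'   names are cell ids) and `ground_truth`, a list holding `species`
#'   (per-species origin cell/block, niche centre and breadth, target and
#'   realized range size), `true_region` (per-cell block label),
#'   `crossing_prob`.
#' @export
simulate_species <- function(lat, env = NULL, n_species,
                             range_size = list(dist = "uniform", min = 5, max = 30),
                             crossing_prob = 0,
                             niche_field = "APRE", niche_breadth = Inf,
                             niche_centers = NULL,
                             balance_blocks = TRUE,
                             max_attempts = 100L,
                             seed = 1L) {
  stopifnot(inherits(lat, "lattice"), n_species >= 1L,
            crossing_prob >= 0, crossing_prob <= 1)
  cells <- lat$cells
  n <- nrow(cells)

  niche_breadth <- rep_len(niche_breadth, n_species)
  use_niche <- any(is.finite(niche_breadth))
  if (use_niche) {
    if (is.null(env) || !niche_field %in% names(env))
      stop("finite niche_breadth requires `env` with column ", niche_field,
           call. = FALSE)
    clim <- env[[niche_field]][match(cells$cell_id, env$cell_id)]
  } else clim <- rep(0, n)

  set.seed(seed)
  species_seed <- sample.int(.Machine$integer.max - 1L, n_species)

  # draw target range sizes from the master stream
  sizes <- if (is.numeric(range_size)) {
    rep_len(as.numeric(range_size), n_species)
  } else {
    switch(range_size$dist,
      uniform   = stats::runif(n_species, range_size$min, range_size$max + 1),
      lognormal = stats::rlnorm(n_species, range_size$meanlog, range_size$sdlog),
      poisson   = 1 + stats::rpois(n_species, range_size$lambda),
      stop("unknown range_size dist: ", range_size$dist, call. = FALSE))
  }
  sizes <- pmax(1L, as.integer(floor(sizes)))
  if (any(sizes > n)) {
    warning(sprintf("%d range-size draw(s) exceed the lattice (%d cells); capped",
                    sum(sizes > n), n))
    sizes <- pmin(sizes, n)
  }

  blocks <- sort(unique(cells$block))
  origin_block <- if (balance_blocks)
    blocks[((seq_len(n_species) - 1L) %% length(blocks)) + 1L]
  else rep(NA_integer_, n_species)

  # 4-neighbour table and river-crossing flags, precomputed once
  nbr <- matrix(NA_integer_, n, 4L)
  nbr_cross <- matrix(FALSE, n, 4L)
  for (i in seq_len(n)) {
    r <- cells$row[i]; c <- cells$col[i]; j <- 0L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1L || r2 > lat$n_rows || c2 < 1L || c2 > lat$n_cols) next
      j <- j + 1L
      nbr[i, j] <- (r2 - 1L) * lat$n_cols + c2
      nbr_cross[i, j] <- crosses_river(lat, r, c, r2, c2)
    }
  }

  inc <- matrix(0L, n, n_species,
                dimnames = list(cells$cell_id, sprintf("sp%04d", seq_len(n_species))))
  origin_cell <- integer(n_species)
  center_out <- numeric(n_species)
  realized <- integer(n_species)

  for (s in seq_len(n_species)) {
    set.seed(species_seed[s])
    pool <- if (balance_blocks) which(cells$block == origin_block[s]) else seq_len(n)
    ctr <- if (!is.null(niche_centers)) niche_centers[s] else NA_real_
    if (is.finite(niche_breadth[s])) {
      adm <- abs(clim - (if (is.na(ctr)) clim else ctr)) <= niche_breadth[s]
      if (!is.na(ctr)) pool <- pool[adm[pool]]
      if (!length(pool)) stop("no admissible seed cell for species ", s,
                              call. = FALSE)
    }
    start <- pool[sample.int(length(pool), 1L)]
    if (is.na(ctr)) ctr <- clim[start]
    in_niche <- !is.finite(niche_breadth[s]) |
      abs(clim - ctr) <= niche_breadth[s]

    occ <- logical(n); occ[start] <- TRUE; size <- 1L
    while (size < sizes[s]) {
      fr <- which(occ)
      cand_to <- as.vector(nbr[fr, , drop = FALSE])
      cand_cr <- as.vector(nbr_cross[fr, , drop = FALSE])
      keep <- !is.na(cand_to) & !occ[ifelse(is.na(cand_to), 1L, cand_to)] &
        in_niche[ifelse(is.na(cand_to), 1L, cand_to)]
      cand_to <- cand_to[keep]; cand_cr <- cand_cr[keep]
      if (!length(cand_to)) break
      # a cell reachable through any non-crossing edge is free to enter
      free_entry <- tapply(!cand_cr, cand_to, any)
      ids <- as.integer(names(free_entry))
      if (crossing_prob == 0) {
        ids <- ids[free_entry]
        if (!length(ids)) break
        nxt <- ids[sample.int(length(ids), 1L)]
      } else {
        accepted <- FALSE
        for (att in seq_len(max_attempts)) {
          pick <- ids[sample.int(length(ids), 1L)]
          if (free_entry[as.character(pick)] ||
              stats::runif(1) < crossing_prob) {
            nxt <- pick; accepted <- TRUE; break
          }
        }
        if (!accepted) break
      }
      occ[nxt] <- TRUE; size <- size + 1L
    }
    inc[occ, s] <- 1L
    origin_cell[s] <- start
    center_out[s] <- ctr
    realized[s] <- size
  }

  species <- data.frame(
    species_id = colnames(inc),
    origin_cell = cells$cell_id[origin_cell],
    origin_block = cells$block[origin_cell],
    niche_center = center_out,
    niche_breadth = niche_breadth,
    target_range = sizes,
    realized_range = realized,
    stringsAsFactors = FALSE
  )
  list(incidence = inc,
       ground_truth = list(species = species,
                           true_region = stats::setNames(cells$block, cells$cell_id),
                           crossing_prob = crossing_prob))
}
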