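test_that("rivers are absolute barriers at crossing probability zero", {
  land <- demo_landscape(seed = 3, crossing_prob = 0)
  inc <- land$sim$incidence
  blocks <- land$lat$cells$block
  spans <- apply(inc, 2, function(s) length(unique(blocks[s == 1])))
  expect_true(all(spans == 1))
  # the composition partition refines the block partition
  expect_true(all(rowSums(inc) >= 0))
})

test_that("saturated ranges cover the lattice and have zero turnover", {
  lat <- make_lattice(5, 5, rivers = list(river_h(2)))
  sim <- simulate_species(lat, NULL, n_species = 6,
                          range_size = rep(25, 6), crossing_prob = 1,
                          niche_breadth = Inf, seed = 2)
  expect_true(all(sim$incidence == 1L))
  d <- pairwise_turnover(sim$incidence)
  expect_true(all(d == 0))
})

test_that("block-endemic faunas give cross-block turnover of exactly 1", {
  lat <- make_lattice(6, 6, rivers = list(river_h(3)))
  sim <- simulate_species(lat, NULL, n_species = 100,
                          range_size = list(dist = "uniform", min = 3, max = 12),
                          crossing_prob = 0, seed = 4)
  inc <- drop_empty_cells(sim$incidence)$incidence
  d <- pairwise_turnover(inc)
  blocks <- lat$cells$block[match(rownames(inc), lat$cells$cell_id)]
  cross <- outer(blocks, blocks, "!=")
  expect_true(all(d[cross] == 1))
  expect_true(any(d[!cross & upper.tri(d)] < 1))
})

test_that("incidence is binary, ranges are non-empty and contiguous sizes honoured", {
  land <- demo_landscape(seed = 6)
  inc <- land$sim$incidence
  expect_true(all(inc %in% c(0L, 1L)))
  expect_true(all(colSums(inc) >= 1))
  gt <- land$sim$ground_truth$species
  expect_equal(unname(colSums(inc)), gt$realized_range)
  expect_true(all(gt$realized_range <= gt$target_range))
})

test_that("range-size draws match the requested distribution mean within 3 SE", {
  lat <- make_lattice(40, 40)
  n_sp <- 600
  sim <- simulate_species(lat, NULL, n_species = n_sp,
                          range_size = list(dist = "uniform", min = 10, max = 60),
                          crossing_prob = 1, niche_breadth = Inf, seed = 8)
  targets <- sim$ground_truth$species$target_range
  mu <- (10 + 60) / 2
  se <- sqrt((60 - 10 + 1)^2 / 12) / sqrt(n_sp)
  expect_lt(abs(mean(targets) - mu), 3 * se)
})

test_that("identical seeds reproduce the simulation byte for byte", {
  a <- demo_landscape(seed = 12)
  b <- demo_landscape(seed = 12)
  expect_identical(a$sim, b$sim)
})

test_that("range sizes beyond the lattice are capped with a warning", {
  lat <- make_lattice(3, 3)
  expect_warning(
    sim <- simulate_species(lat, NULL, n_species = 2, range_size = c(50, 4),
                            crossing_prob = 1, seed = 1),
    "capped")
  expect_equal(max(sim$ground_truth$species$target_range), 9)
})

test_that("niche filtering confines ranges to admissible climate", {
  lat <- make_lattice(6, 10)
  gs <- default_gradients(); gs$APRE$noise <- 0
  env <- sample_environment(lat, gradient_spec = gs, seed = 3)
  sim <- simulate_species(lat, env, n_species = 30,
                          range_size = rep(30, 30), crossing_prob = 1,
                          niche_field = "APRE", niche_breadth = 300, seed = 9)
  gt <- sim$ground_truth$species
  for (s in seq_len(30)) {
    occ <- which(sim$incidence[, s] == 1)
    expect_true(all(abs(env$APRE[occ] - gt$niche_center[s]) <= 300))
  }
})
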