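# Independent brute-force oracles and fixture builders. These deliberately
# use naive set/loop arithmetic, not the vectorized package code paths.

random_incidence <- function(n_cells, n_species, p = 0.4, min_rich = 1L) {
  m <- matrix(rbinom(n_cells * n_species, 1L, p), n_cells, n_species,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("s%03d", seq_len(n_species))))
  # guarantee non-empty cells so beta-sim is defined everywhere
  for (i in which(rowSums(m) < min_rich))
    m[i, sample.int(n_species, min_rich)] <- 1L
  m
}

random_dissimilarity <- function(n, values = NULL) {
  d <- matrix(0, n, n)
  ut <- upper.tri(d)
  d[ut] <- if (is.null(values)) runif(sum(ut)) else
    sample(values, sum(ut), replace = TRUE)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- sprintf("c%03d", seq_len(n))
  d
}

# beta-sim by explicit set arithmetic
oracle_beta_sim <- function(x, y) {
  a <- length(intersect(x, y))
  m <- min(length(setdiff(y, x)), length(setdiff(x, y)))
  m / (a + m)
}

oracle_pairwise <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = dimnames(m)[c(1, 1)])
  sets <- lapply(seq_len(n), function(i) colnames(m)[m[i, ] == 1])
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out[i, j] <- out[j, i] <- oracle_beta_sim(sets[[i]], sets[[j]])
  out
}

# per-point silhouette by explicit loops
oracle_mean_silhouette <- function(d, labels) {
  labels <- as.integer(factor(labels))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == g]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

oracle_explained_dissimilarity <- function(d, labels) {
  labels <- as.integer(factor(labels))
  between <- 0; total <- 0
  n <- nrow(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + d[i, j]
    if (labels[i] != labels[j]) between <- between + d[i, j]
  }
  between / total
}

# naive Ward agglomeration: cluster member lists, Lance-Williams recomputed
# pairwise from a distance lookup, same min/tie rule as specified
oracle_ward <- function(d, ord = seq_len(nrow(d))) {
  d <- d[ord, ord, drop = FALSE]
  n <- nrow(d)
  clusters <- as.list(seq_len(n))        # members in permuted index space
  dist <- d
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  merges <- list()
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in which(alive)) for (j in which(alive)) {
      if (j <= i) next
      if (is.null(best) || dist[i, j] < best$h) best <- list(i = i, j = j, h = dist[i, j])
    }
    i <- best$i; j <- best$j
    for (w in which(alive)) {
      if (w == i || w == j) next
      dist[i, w] <- dist[w, i] <-
        ((sizes[i] + sizes[w]) * dist[i, w] +
         (sizes[j] + sizes[w]) * dist[j, w] -
         sizes[w] * best$h) / (sizes[i] + sizes[j] + sizes[w])
    }
    alive[j] <- FALSE
    sizes[i] <- sizes[i] + sizes[j]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    merges[[step]] <- list(height = best$h,
                           members = sort(ord[clusters[[i]]]))
  }
  merges
}

# cluster membership implied by a ward_tree at every merge step, in original
# cell indices, for comparison with oracle_ward
tree_merge_members <- function(tree) {
  collect <- function(cd) if (cd < 0) -cd else
    unlist(lapply(tree$merge[cd, ], collect))
  lapply(seq_len(nrow(tree$merge)), function(s)
    sort(unlist(lapply(tree$merge[s, ], collect))))
}

# 4-block demo landscape used across tests
demo_landscape <- function(seed, n_rows = 10, n_cols = 10,
                           n_species = 128, crossing_prob = 0.02,
                           range_size = list(dist = "uniform",
                                             min = 10, max = 25)) {
  lat <- make_lattice(n_rows, n_cols,
                      rivers = list(river_h(n_rows %/% 2),
                                    river_v(n_cols %/% 2)))
  env <- sample_environment(lat, seed = seed)
  sim <- simulate_species(lat, env, n_species = n_species,
                          range_size = range_size,
                          crossing_prob = crossing_prob, seed = seed + 1)
  list(lat = lat, env = env, sim = sim)
}
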