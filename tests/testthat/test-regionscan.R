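test_that("tie-free matrices make every replicate identical", {
  set.seed(40)
  d <- random_dissimilarity(12)
  scan <- scan_regions(d, k_max = 6, n_reorder = 8, seed = 1)
  expect_equal(apply(scan$silhouette, 1, stats::sd), rep(0, 5))
  expect_equal(apply(scan$explained, 1, stats::sd), rep(0, 5))
})

test_that("a single reordering equals one linkage-and-cut sweep", {
  set.seed(41)
  d <- random_dissimilarity(10)
  scan <- scan_regions(d, k_max = 5, n_reorder = 1, seed = 7)
  set.seed(7)
  perm <- sample.int(10)
  tree <- ward_linkage(d, order = perm)
  for (k in 2:5) {
    expect_equal(scan$summary$mean_silhouette[k - 1],
                 mean_silhouette(d, cut_k(tree, k)))
    expect_equal(scan$summary$mean_explained_dissimilarity[k - 1],
                 explained_dissimilarity(d, cut_k(tree, k)))
  }
})

test_that("scans are reproducible bit for bit given the seed", {
  set.seed(42)
  d <- random_dissimilarity(12, values = c(0.25, 0.5, 0.75, 1))
  s1 <- scan_regions(d, k_max = 6, n_reorder = 5, seed = 99)
  s2 <- scan_regions(d, k_max = 6, n_reorder = 5, seed = 99)
  expect_identical(s1, s2)
})

test_that("the dual-criterion rule selects seven regions on the reference series", {
  ref <- reference_region_scan()
  expect_equal(select_k(ref, threshold = 0.90), 7)
})

test_that("selection stops immediately when the silhouette never rises", {
  tab <- data.frame(k = 2:8,
                    silhouette = c(0.5, 0.45, 0.44, 0.40, 0.35, 0.30, 0.25),
                    explained_dissimilarity = c(0.5, 0.7, 0.92, 0.95, 0.96,
                                                0.97, 0.98))
  expect_equal(select_k(tab), 4)
})

test_that("a silhouette increasing to the scan edge returns K_max with a warning", {
  tab <- data.frame(k = 2:6,
                    silhouette = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    explained_dissimilarity = c(0.91, 0.92, 0.93, 0.94, 0.95))
  expect_warning(k <- select_k(tab), "largest scanned k")
  expect_equal(k, 6)
})

test_that("an unreachable threshold errors with the best value achieved", {
  tab <- data.frame(k = 2:4, silhouette = c(0.3, 0.4, 0.5),
                    explained_dissimilarity = c(0.5, 0.6, 0.7))
  expect_error(select_k(tab), "0.7000")
})

test_that("consensus returns the unanimous partition up to relabeling", {
  sols <- cbind(c(1, 1, 2, 2), c(2, 2, 1, 1), c(1, 1, 2, 2))
  rownames(sols) <- paste0("c", 1:4)
  got <- consensus_partition(sols)
  expect_equal(unname(got), c(1L, 1L, 2L, 2L))
})

test_that("consensus follows the majority co-classification", {
  # {AB|C} three times, {A|BC} once: co(A,B) = 0.75, co(B,C) = 0.25
  sols <- cbind(c(1, 1, 2), c(1, 1, 2), c(1, 1, 2), c(1, 2, 2))
  rownames(sols) <- c("A", "B", "C")
  got <- consensus_partition(sols)
  expect_equal(unname(got), c(1L, 1L, 2L))
})

test_that("consensus is invariant to relabeling any replicate", {
  set.seed(43)
  sols <- replicate(6, sample(rep(1:3, each = 3)))  # 3 clusters per replicate
  rownames(sols) <- paste0("c", 1:9)
  base <- consensus_partition(sols)
  perm <- sols
  perm[, 2] <- c(3, 1, 2)[perm[, 2]]   # relabel one replicate
  expect_equal(consensus_partition(perm), base)
})

test_that("replicates with differing cluster counts are rejected", {
  sols <- cbind(c(1, 1, 2), c(1, 2, 3))
  expect_error(consensus_partition(sols), "same number of clusters")
})
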