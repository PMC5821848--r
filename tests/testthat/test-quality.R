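make_two_pair_d <- function(within = 0.1, between = 0.9) {
  d <- matrix(between, 4, 4)
  d[1, 2] <- d[2, 1] <- within
  d[3, 4] <- d[4, 3] <- within
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("c", 1:4)
  d
}

test_that("silhouette reproduces the two-pair hand computation", {
  d <- make_two_pair_d()
  s <- mean_silhouette(d, c(1, 1, 2, 2))
  expect_equal(s, (0.9 - 0.1) / 0.9)
})

test_that("all-singleton partitions score zero by convention", {
  d <- make_two_pair_d()
  expect_equal(mean_silhouette(d, 1:4), 0)
  expect_error(mean_silhouette(d, rep(1, 4)), "at least 2")
})

test_that("silhouette equals the loop oracle and cluster::silhouette on random inputs", {
  set.seed(30)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    d <- random_dissimilarity(n)
    k <- sample(2:4, 1)
    labels <- sample(rep_len(seq_len(k), n))
    expect_equal(mean_silhouette(d, labels), oracle_mean_silhouette(d, labels))
    sil <- cluster::silhouette(labels, dmatrix = d)
    expect_equal(mean_silhouette(d, labels), mean(sil[, "sil_width"]))
  }
})

test_that("silhouette stays within [-1, 1] and hits 1 for perfect separation", {
  set.seed(31)
  for (rep in 1:20) {
    d <- random_dissimilarity(sample(5:15, 1))
    labels <- sample(1:3, nrow(d), replace = TRUE)
    if (length(unique(labels)) < 2) next
    s <- mean_silhouette(d, labels)
    expect_gte(s, -1); expect_lte(s, 1)
  }
  d0 <- make_two_pair_d(within = 0, between = 0.7)
  expect_equal(mean_silhouette(d0, c(1, 1, 2, 2)), 1)
})

test_that("explained dissimilarity covers its closed-form cases", {
  d <- make_two_pair_d()
  expect_equal(explained_dissimilarity(d, rep(1, 4)), 0)       # k = 1
  expect_equal(explained_dissimilarity(d, 1:4), 1)             # singletons
  expect_equal(explained_dissimilarity(d, c(1, 1, 2, 2)), 3.6 / 3.8)
  expect_error(explained_dissimilarity(matrix(0, 3, 3), c(1, 1, 2)),
               "zero")
})

test_that("explained dissimilarity equals the pair-loop oracle on random inputs", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    d <- random_dissimilarity(n)
    labels <- sample(1:4, n, replace = TRUE)
    expect_equal(explained_dissimilarity(d, labels),
                 oracle_explained_dissimilarity(d, labels))
  }
})

test_that("explained dissimilarity is non-decreasing over nested cuts of one tree", {
  set.seed(33)
  d <- random_dissimilarity(18)
  tree <- ward_linkage(d)
  ed <- vapply(2:17, function(k) explained_dissimilarity(d, cut_k(tree, k)),
               numeric(1))
  expect_true(all(diff(ed) >= -1e-12))
})
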