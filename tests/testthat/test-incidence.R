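test_that("CSV round-trip preserves the matrix and its ordering", {
  set.seed(1)
  m <- random_incidence(8, 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_incidence(m, path)
  m2 <- read_incidence(path)
  expect_identical(m2, m)
})

test_that("validation names the offending entry and duplicate ids", {
  m <- matrix(c(0, 1, 1, 2), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(validate_incidence(m), "cell 'b', species 's2'")
  m2 <- matrix(0:1, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(validate_incidence(m2), "duplicated cell")
  m3 <- matrix(0:1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s1")))
  expect_error(validate_incidence(m3), "duplicated species")
})

test_that("empty species columns are accepted with a warning naming them", {
  m <- cbind(s1 = c(1L, 0L), s2 = c(0L, 0L))
  rownames(m) <- c("a", "b")
  expect_warning(out <- validate_incidence(m), "s2")
  expect_equal(ncol(out), 2)
})

test_that("small-range filtering matches the column-sum oracle and is idempotent", {
  set.seed(2)
  m <- random_incidence(20, 30, p = 0.12)
  for (th in 0:3) {
    f <- filter_small_ranges(m, th)
    expect_identical(colnames(f), colnames(m)[colSums(m) > th])
    expect_identical(filter_small_ranges(f, th), f)   # idempotent
    expect_identical(rownames(f), rownames(m))        # cells untouched
  }
  expect_identical(filter_small_ranges(m, 0), m)      # threshold 0 is identity
})

test_that("empty cells are dropped (only) after filtering empties them", {
  m <- rbind(c1 = c(1L, 1L, 0L), c2 = c(0L, 0L, 1L), c3 = c(1L, 0L, 0L))
  colnames(m) <- c("wide1", "wide2", "rare")   # rare occupies 1 cell
  expect_identical(drop_empty_cells(m)$incidence, m)
  f <- filter_small_ranges(m, 1)
  expect_message(res <- drop_empty_cells(f), "c2")
  expect_equal(rownames(res$incidence), c("c1", "c3"))
  expect_equal(res$removed, "c2")
  expect_true(all(rowSums(res$incidence) >= 1))
  expect_error(drop_empty_cells(m * 0L), "all cells are empty")
})

test_that("cell summaries equal a per-cell loop oracle", {
  set.seed(3)
  m <- random_incidence(10, 15, p = 0.3, min_rich = 0L)
  m[4, ] <- 0L   # force an empty cell
  s <- summarize_cells(m)
  rs <- colSums(m)
  for (i in seq_len(nrow(m))) {
    present <- which(m[i, ] == 1)
    expect_equal(s$richness[i], length(present))
    if (length(present)) expect_equal(s$mean_range_size[i], mean(rs[present]))
    else expect_true(is.na(s$mean_range_size[i]))
  }
  expect_equal(sum(s$richness), sum(m))
})

test_that("a cell holding species with ranges 2 and 4 averages to 3", {
  m <- rbind(c1 = c(1L, 1L), c2 = c(1L, 1L), c3 = c(0L, 1L), c4 = c(0L, 1L))
  colnames(m) <- c("spA", "spB")   # ranges 2 and 4
  s <- summarize_cells(m)
  expect_equal(s$mean_range_size[s$cell_id == "c1"], 3)
})
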