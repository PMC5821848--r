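#' Scan cluster counts over randomized-order Ward replicates
#'
#' Builds `n_reorder` Ward dendrograms, each from a random permutation of
#' the cells (turnover matrices carry many ties, so the input order can
#' change the topology), cuts every tree at each k in `2..min(k_max, n-1)`,
#' and records mean silhouette width and explained dissimilarity per
#' solution. Per-k means over replicates summarize the scan.
#'
#' @param d Symmetric turnover dissimilarity matrix.
#' @param k_max Largest cluster count scanned (default 50).
#' @param n_reorder Number of random cell reorderings (default 50).
#' @param seed Integer seed driving the permutations.
#' @param variant Ward variant, see [ward_linkage()].
#' @return A `region_scan`: list with `summary` (data frame `k`,
#'   `mean_silhouette`, `mean_explained_dissimilarity`), `silhouette` and
#'   `explained` (k x replicate matrices), `labels` (array cells x k x
#'   replicate of cluster labels), `k_values`, `n_reorder`, `seed`,
#'   `cell_ids`, `variant`.
#' @export
scan_regions <- function(d, k_max = 50L, n_reorder = 50L, seed = 1L,
                         variant = "ward.D") {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(k_max >= 2L, n_reorder >= 1L, n >= 3L)
  ks <- 2L:min(k_max, n - 1L)
  set.seed(seed)
  perms <- replicate(n_reorder, sample.int(n), simplify = FALSE)

  silh <- matrix(NA_real_, length(ks), n_reorder)
  exdi <- matrix(NA_real_, length(ks), n_reorder)
  labs <- array(NA_integer_, c(n, length(ks), n_reorder),
                dimnames = list(rownames(d), paste0("k", ks), NULL))
  for (r in seq_len(n_reorder)) {
    tree <- ward_linkage(d, order = perms[[r]], variant = variant)
    for (ki in seq_along(ks)) {
      lb <- cut_k(tree, ks[ki])
      labs[, ki, r] <- lb
      silh[ki, r] <- mean_silhouette(d, lb)
      exdi[ki, r] <- explained_dissimilarity(d, lb)
    }
  }
  summary <- data.frame(
    k = ks,
    mean_silhouette = rowMeans(silh),
    mean_explained_dissimilarity = rowMeans(exdi)
  )
  structure(list(summary = summary, silhouette = silh, explained = exdi,
                 labels = labs, k_values = ks, n_reorder = n_reorder,
                 seed = seed, cell_ids = rownames(d), variant = variant),
            class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  cat(sprintf("region scan: k = %d..%d, %d reorderings, seed %d\n",
              min(x$k_values), max(x$k_values), x$n_reorder, x$seed))
  print(utils::head(x$summary, 10), row.names = FALSE)
  if (nrow(x$summary) > 10) cat("...\n")
  invisible(x)
}

#' Select the number of regions by the dual criterion
#'
#' First finds the smallest k whose mean explained dissimilarity reaches
#' `threshold` (90% by default), then advances k while the mean silhouette
#' width strictly increases, returning the k at which the silhouette stops
#' increasing. If the silhouette still increases at the largest scanned k,
#' that k is returned with a warning.
#'
#' @param scan A [scan_regions()] object, or a data frame with columns `k`,
#'   a silhouette column (`mean_silhouette` or `silhouette`) and an
#'   explained-dissimilarity column (`mean_explained_dissimilarity` or
#'   `explained_dissimilarity`), covering contiguous k from 2.
#' @param threshold Explained-dissimilarity threshold (default 0.90).
#' @return Selected number of regions (integer).
#' @export
select_k <- function(scan, threshold = 0.90) {
  tab <- if (inherits(scan, "region_scan")) scan$summary else as.data.frame(scan)
  sil_col <- intersect(c("mean_silhouette", "silhouette"), names(tab))[1]
  ed_col <- intersect(c("mean_explained_dissimilarity",
                        "explained_dissimilarity", "ex.diss"), names(tab))[1]
  if (is.na(sil_col) || is.na(ed_col))
    stop("scan must provide silhouette and explained-dissimilarity columns",
         call. = FALSE)
  tab <- tab[order(tab$k), ]
  if (any(diff(tab$k) != 1L))
    stop("scan must cover contiguous k values", call. = FALSE)
  ed <- tab[[ed_col]]; sil <- tab[[sil_col]]; ks <- tab$k
  hit <- which(ed >= threshold)
  if (!length(hit))
    stop(sprintf(
      "no k reaches explained dissimilarity %.2f (maximum achieved: %.4f)",
      threshold, max(ed)), call. = FALSE)
  i <- hit[1L]
  while (i < length(ks) && sil[i + 1L] > sil[i]) i <- i + 1L
  if (i == length(ks) && length(ks) > hit[1L] && sil[i] > sil[i - 1L])
    warning("silhouette still increasing at the largest scanned k; returning it")
  ks[i]
}

#' Consensus partition from replicate clusterings
#'
#' Aggregates replicate label vectors (all at the same k) through the
#' co-classification matrix: the fraction of replicates placing each cell
#' pair in the same cluster. Ward clustering of 1 minus this matrix, with
#' the identity input order, cut at k, gives the consensus labels. The
#' result is invariant to relabeling of any replicate's cluster ids.
#'
#' @param solutions Cells x replicates matrix (or list) of cluster labels,
#'   each column a replicate partition with the same number of clusters.
#' @param d Optional dissimilarity matrix (unused by the aggregation;
#'   accepted so callers can pass the scan context through).
#' @return Named integer labels, canonicalized by first occurrence.
#' @export
consensus_partition <- function(solutions, d = NULL) {
  if (is.list(solutions) && !is.data.frame(solutions))
    solutions <- do.call(cbind, solutions)
  solutions <- as.matrix(solutions)
  kk <- apply(solutions, 2L, function(col) length(unique(col)))
  if (length(unique(kk)) != 1L)
    stop("all replicate partitions must have the same number of clusters",
         call. = FALSE)
  k <- kk[1L]
  n <- nrow(solutions)
  co <- matrix(0, n, n)
  for (r in seq_len(ncol(solutions))) {
    oh <- outer(solutions[, r], solutions[, r], "==")
    co <- co + oh
  }
  co <- co / ncol(solutions)
  dd <- 1 - co
  diag(dd) <- 0
  rownames(dd) <- colnames(dd) <- rownames(solutions)
  if (k == 1L) {
    lb <- rep(1L, n); names(lb) <- rownames(solutions); return(lb)
  }
  tree <- ward_linkage(dd, order = seq_len(n))
  cut_k(tree, k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells; 1 for
#' identical partitions (up to relabeling), approximately 0 for independent
#' ones. Wraps the standard implementation.
#'
#' @param a,b Label vectors of equal length.
#' @return Adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
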