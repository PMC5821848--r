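#' Mean silhouette width of a partition
#'
#' For each cell i with own-cluster mean dissimilarity a(i) and smallest
#' other-cluster mean dissimilarity b(i), the silhouette is
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)); cells in singleton clusters get
#' s(i) = 0 by convention. The mean over cells lies in `[-1, 1]`; values
#' near 1 indicate cells firmly inside well-separated clusters, negative
#' values cells probably assigned to the wrong cluster.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param labels Cluster labels per cell (>= 2 distinct values).
#' @return Mean silhouette width.
#' @export
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette requires at least 2 clusters", call. = FALSE)
  n <- nrow(d)
  ind <- matrix(0, n, k); ind[cbind(seq_len(n), labels)] <- 1
  sizes <- colSums(ind)
  sums <- d %*% ind                      # per-cell sums of d to each cluster
  own <- sizes[labels]
  a <- ifelse(own > 1, sums[cbind(seq_len(n), labels)] / (own - 1), 0)
  means <- sweep(sums, 2L, sizes, "/")
  means[cbind(seq_len(n), labels)] <- Inf
  b <- apply(means, 1L, min)
  s <- ifelse(own == 1, 0, {
    den <- pmax(a, b)
    ifelse(den > 0, (b - a) / den, 0)
  })
  mean(s)
}

#' Explained dissimilarity of a partition
#'
#' The fraction of the total pairwise dissimilarity that falls between
#' clusters: the sum of d(i, j) over unordered pairs in different clusters,
#' divided by the sum over all unordered pairs. Equals 0 for a single
#' cluster and 1 when every pair is between-cluster (all singletons). A
#' partition that captures the compositional structure places most
#' dissimilarity between regions, so values near 1 indicate well-separated
#' regions.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param labels Cluster labels per cell.
#' @return Explained dissimilarity in `[0, 1]`.
#' @export
explained_dissimilarity <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.integer(factor(labels))
  tot <- sum(d[upper.tri(d)])
  if (tot <= 0) stop("total dissimilarity is zero (degenerate landscape)",
                     call. = FALSE)
  if (max(labels) == 1L) return(0)
  within <- 0
  for (g in seq_len(max(labels))) {
    idx <- which(labels == g)
    if (length(idx) > 1L) {
      dg <- d[idx, idx, drop = FALSE]
      within <- within + sum(dg[upper.tri(dg)])
    }
  }
  (tot - within) / tot
}
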