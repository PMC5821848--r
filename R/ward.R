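#' Ward agglomerative clustering with explicit input-order tie-breaking
#'
#' Agglomerates cells under the Lance-Williams Ward update
#' \deqn{d(uv,w) = \frac{(n_u+n_w)\,d(u,w) + (n_v+n_w)\,d(v,w) - n_w\,d(u,v)}
#'                     {n_u+n_v+n_w}}
#' merging at each step the pair of minimum current dissimilarity. Ties are
#' broken by the lexicographically smallest pair of positions in the
#' supplied ordering, so a different `order` can yield a different tree —
#' beta-diversity turnover matrices are rich in ties and zeros, and this
#' order sensitivity is exactly what the randomized-reordering consensus
#' procedure exploits (and controls for).
#'
#' `variant = "ward.D"` applies the update to the dissimilarities as given
#' (the legacy default of hierarchical-clustering software in this field);
#' `"ward.D2"` applies it to squared dissimilarities and reports
#' square-rooted merge heights.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param order Permutation of `1:n` (or of the cell ids) giving the cell
#'   ordering used for tie-breaking. Default: identity.
#' @param variant `"ward.D"` (default) or `"ward.D2"`.
#' @return A `ward_tree`: list with `merge` (n-1 x 2, hclust convention —
#'   negative entries are leaves indexed in the *original* cell order,
#'   positive entries earlier merge steps), `height`, `order` (the
#'   permutation used), `labels`, `n`, `variant`.
#' @export
ward_linkage <- function(d, order = seq_len(nrow(d)),
                         variant = c("ward.D", "ward.D2")) {
  variant <- match.arg(variant)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 cells to cluster", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (is.character(order)) order <- match(order, labels)
  order <- as.integer(order)
  if (length(order) != n || anyNA(order) || !setequal(order, seq_len(n)))
    stop("`order` must be a permutation of the cells", call. = FALSE)

  # work in permuted slot space; slot i holds original cell order[i]
  cur <- d[order, order, drop = FALSE]
  if (variant == "ward.D2") cur <- cur^2
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -order            # hclust codes: leaf = -original index
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  big <- Inf
  diag(cur) <- big

  for (s in seq_len(n - 1L)) {
    act <- which(active)
    sub <- cur[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- big
    h <- min(sub)
    # ties: smallest row slot, then smallest column slot
    hits <- which(sub == h, arr.ind = TRUE)
    hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    i <- act[hit[1L]]; j <- act[hit[2L]]   # i < j in slot order

    hd <- cur[i, j]
    w <- act[act != i & act != j]
    if (length(w)) {
      cur[i, w] <- ((size[i] + size[w]) * cur[i, w] +
                    (size[j] + size[w]) * cur[j, w] -
                    size[w] * hd) / (size[i] + size[j] + size[w])
      cur[w, i] <- cur[i, w]
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    merge[s, ] <- c(code[i], code[j])
    height[s] <- if (variant == "ward.D2") sqrt(h) else h
    code[i] <- s
  }

  structure(list(merge = merge, height = height, order = order,
                 labels = labels, n = n, variant = variant),
            class = "ward_tree")
}

#' Cut a Ward tree into k clusters
#'
#' Undoes the last `k - 1` merges: cells joined by the first `n - k` merges
#' form the clusters. Labels are canonicalized to `1..k` by first occurrence
#' in the original cell order.
#'
#' @param tree A [ward_linkage()] tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster labels per cell.
#' @export
cut_k <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  n <- tree$n
  if (k < 1L || k > n) stop("k must be in 1..", n, call. = FALSE)
  grp <- seq_len(n)
  if (n - k >= 1L) {
    # membership of each merge step, built incrementally
    step_members <- vector("list", n - k)
    for (s in seq_len(n - k)) {
      mem <- integer(0)
      for (cd in tree$merge[s, ]) {
        mem <- c(mem, if (cd < 0L) -cd else step_members[[cd]])
      }
      step_members[[s]] <- mem
      grp[mem] <- n + s   # distinct id per step
    }
  }
  canon <- match(grp, unique(grp))
  names(canon) <- tree$labels
  canon
}

#' Convert a ward_tree to an hclust object
#'
#' Useful for plotting with the standard dendrogram machinery.
#'
#' @param x A `ward_tree`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.ward_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = order_leaves(x), labels = x$labels,
                 method = x$variant, call = match.call(),
                 dist.method = "beta_sim"),
            class = "hclust")
}

order_leaves <- function(tree) {
  rec <- function(cd) {
    if (cd < 0L) return(-cd)
    c(rec(tree$merge[cd, 1L]), rec(tree$merge[cd, 2L]))
  }
  rec_last <- rec(nrow(tree$merge))
  rec_last
}
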