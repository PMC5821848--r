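#' Simpson turnover dissimilarity between two assemblages
#'
#' For species sets x (focal) and y (neighbour), with a = |x intersect y|
#' shared species, b = |y \ x| and c = |x \ y|,
#' \deqn{\beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}
#'                   = 1 - \frac{a}{a + \min(b, c)}}
#' The index measures species replacement only: it is 0 for identical or
#' nested assemblages (insensitive to richness differences) and 1 for
#' disjoint ones.
#'
#' @param x,y Non-empty vectors of species identifiers.
#' @return Numeric in `[0, 1]`.
#' @examples
#' beta_sim(c("s1", "s2", "s3"), c("s2", "s3", "s4"))  # 1 - 1/3
#' @export
beta_sim <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (!length(x) || !length(y))
    stop("beta_sim is undefined for empty assemblages", call. = FALSE)
  a <- length(intersect(x, y))
  b <- length(setdiff(y, x))
  cc <- length(setdiff(x, y))
  m <- min(b, cc)
  m / (a + m)
}

#' Pairwise Simpson turnover matrix
#'
#' Computes [beta_sim()] between every unordered pair of cells of an
#' incidence matrix, vectorized through the shared-species cross-product.
#'
#' @param m Incidence matrix (cells x species, 0/1); every cell must be
#'   non-empty (see [drop_empty_cells()]).
#' @param components If `TRUE`, attach the per-pair `a`, `b`, `c` count
#'   matrices as attributes (diagnostics, test oracles).
#' @return Symmetric numeric matrix with zero diagonal, dimnames the cell
#'   ids.
#' @export
pairwise_turnover <- function(m, components = FALSE) {
  if (any(rowSums(m) == 0))
    stop("empty cell(s) present; run drop_empty_cells() first", call. = FALSE)
  m <- as.matrix(m); storage.mode(m) <- "numeric"
  a <- tcrossprod(m)                      # shared species
  rich <- rowSums(m)
  b <- matrix(rich, nrow(m), nrow(m), byrow = TRUE) - a  # only in neighbour
  cc <- matrix(rich, nrow(m), nrow(m)) - a               # only in focal
  mn <- pmin(b, cc)
  d <- mn / (a + mn)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  if (components) {
    attr(d, "a") <- a; attr(d, "b") <- b; attr(d, "c") <- cc
  }
  d
}
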