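#' River segments on a lattice edge grid
#'
#' Rivers are axis-aligned polylines lying on the edges between grid cells.
#' `river_h()` describes a river running along the horizontal gap below row
#' `position` (i.e. between rows `position` and `position + 1`), spanning
#' columns `from` to `to`; `river_v()` the vertical gap right of column
#' `position`, spanning rows `from` to `to`.
#'
#' @param position Index of the row (or column) immediately above (left of)
#'   the river. Must lie strictly inside the lattice: `1 <= position <=
#'   n_rows - 1` for horizontal rivers.
#' @param from,to First and last column (row) whose boundary edge the river
#'   crosses. Defaults span the whole lattice when resolved by
#'   [make_lattice()].
#' @return A `river` object (list with `orientation`, `position`, `from`,
#'   `to`).
#' @examples
#' river_h(2)           # full-width river between rows 2 and 3
#' river_v(3, 1, 4)     # vertical river segment along rows 1..4
#' @export
river_h <- function(position, from = 1L, to = NA_integer_) {
  structure(list(orientation = "h", position = as.integer(position),
                 from = as.integer(from), to = as.integer(to)),
            class = "river")
}

#' @rdname river_h
#' @export
river_v <- function(position, from = 1L, to = NA_integer_) {
  structure(list(orientation = "v", position = as.integer(position),
                 from = as.integer(from), to = as.integer(to)),
            class = "river")
}

resolve_river <- function(rv, n_rows, n_cols) {
  if (!inherits(rv, "river"))
    stop("each element of `rivers` must be created by river_h() or river_v()",
         call. = FALSE)
  span_max <- if (rv$orientation == "h") n_cols else n_rows
  pos_max <- if (rv$orientation == "h") n_rows - 1L else n_cols - 1L
  if (is.na(rv$to)) rv$to <- span_max
  if (rv$position < 1L || rv$position > pos_max)
    stop(sprintf("river position %d is off the edge grid (must be in 1..%d)",
                 rv$position, pos_max), call. = FALSE)
  if (rv$from < 1L || rv$to > span_max || rv$from > rv$to)
    stop(sprintf("river span %d..%d is off the edge grid (must lie in 1..%d)",
                 rv$from, rv$to, span_max), call. = FALSE)
  rv
}

#' Build a rectangular lattice partitioned into blocks by rivers
#'
#' Cells are unit squares on an `n_rows` x `n_cols` grid, identified in
#' row-major order. Rivers remove the 4-adjacency edges they cross; the
#' connected components of the remaining adjacency graph are the lattice
#' *blocks*. The per-cell river-bank category (the RIVERS predictor used in
#' driver models) defaults to the block label: cells on opposite banks of a
#' river that fully separates them fall in different categories.
#'
#' @param n_rows,n_cols Lattice dimensions (positive integers).
#' @param rivers List of [river_h()] / [river_v()] segments. A segment that
#'   does not span the lattice leaves the two sides connected around its end.
#' @return A `lattice` object: list with `n_rows`, `n_cols`, `rivers`
#'   (resolved), and `cells`, a data frame with columns `cell_id`, `row`,
#'   `col`, `block`, `river_bank` (block labels are integers numbered by
#'   first occurrence in row-major order).
#' @examples
#' lat <- make_lattice(4, 4, rivers = list(river_h(2)))
#' table(lat$cells$block)   # two blocks of 8 cells
#' @export
make_lattice <- function(n_rows, n_cols, rivers = list()) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  rivers <- lapply(rivers, resolve_river, n_rows = n_rows, n_cols = n_cols)

  n <- n_rows * n_cols
  idx <- function(r, c) (r - 1L) * n_cols + c   # row-major

  # horizontal-cut matrix: cut_h[r, c] TRUE means edge (r,c)-(r+1,c) removed
  cut_h <- matrix(FALSE, max(n_rows - 1L, 1L), n_cols)
  cut_v <- matrix(FALSE, n_rows, max(n_cols - 1L, 1L))
  for (rv in rivers) {
    if (rv$orientation == "h") cut_h[rv$position, rv$from:rv$to] <- TRUE
    else cut_v[rv$from:rv$to, rv$position] <- TRUE
  }

  # adjacency list under the cut edge set
  nbrs <- vector("list", n)
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    i <- idx(r, c); out <- integer(0)
    if (r > 1L     && !cut_h[r - 1L, c]) out <- c(out, idx(r - 1L, c))
    if (r < n_rows && !cut_h[r, c])      out <- c(out, idx(r + 1L, c))
    if (c > 1L     && !cut_v[r, c - 1L]) out <- c(out, idx(r, c - 1L))
    if (c < n_cols && !cut_v[r, c])      out <- c(out, idx(r, c + 1L))
    nbrs[[i]] <- out
  }

  # connected components by iterative flood fill, labels in row-major order
  block <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (block[s] > 0L) next
    lab <- lab + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (block[i] > 0L) next
      block[i] <- lab
      un <- nbrs[[i]][block[nbrs[[i]]] == 0L]
      if (length(un)) stack <- c(stack, un)
    }
  }

  rc <- arrayInd(seq_len(n), c(n_cols, n_rows))  # col varies fastest
  cells <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    row = rep(seq_len(n_rows), each = n_cols),
    col = rep(seq_len(n_cols), times = n_rows),
    block = block,
    river_bank = block,
    stringsAsFactors = FALSE
  )
  structure(list(n_rows = n_rows, n_cols = n_cols, rivers = rivers,
                 cells = cells, cut_h = cut_h, cut_v = cut_v),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("lattice: %d x %d cells, %d river segment(s), %d block(s)\n",
              x$n_rows, x$n_cols, length(x$rivers),
              length(unique(x$cells$block))))
  invisible(x)
}

# TRUE iff the step between two 4-adjacent cells (given as row/col pairs)
# crosses a river edge of the lattice
crosses_river <- function(lat, r1, c1, r2, c2) {
  if (r1 == r2) lat$cut_v[r1, min(c1, c2)] else lat$cut_h[min(r1, r2), c1]
}
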