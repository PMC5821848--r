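#' Read a cells x species incidence matrix from CSV
#'
#' Expects a header row, a first column of cell identifiers, and one column
#' per species containing only 0 or 1. Cell and species order are preserved
#' from the file.
#'
#' @param path Path to a CSV file.
#' @return Integer 0/1 matrix, row names cell ids, column names species ids.
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("incidence CSV needs a cell_id column plus >= 1 species",
                           call. = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(raw[[1]])
  validate_incidence(m)
}

#' Validate an incidence matrix
#'
#' Checks identifiers are unique and values are strictly 0/1; warns about
#' all-zero (empty) species columns, naming them.
#'
#' @param m Matrix-like, cells in rows, species in columns.
#' @return The validated matrix with integer storage.
#' @export
validate_incidence <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sp%04d", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m)))
    stop("duplicated cell identifier(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicated species identifier(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf("non-binary value %s at cell '%s', species '%s'",
                 format(m[b[1], b[2]]), rownames(m)[b[1]], colnames(m)[b[2]]),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  empty <- colnames(m)[colSums(m) == 0L]
  if (length(empty))
    warning("species with no occurrences: ", paste(empty, collapse = ", "),
            call. = FALSE)
  m
}

#' Remove small-ranged species
#'
#' Drops every species occupying at most `max_cells_excluded` cells — the
#' sensitivity design used to probe whether poorly-sampled narrow endemics
#' drive the regionalization. Cells are untouched. Idempotent at a fixed
#' threshold; `max_cells_excluded = 0` is the identity.
#'
#' @param m Incidence matrix.
#' @param max_cells_excluded Non-negative integer range-size cutoff.
#' @return Filtered incidence matrix.
#' @export
filter_small_ranges <- function(m, max_cells_excluded) {
  stopifnot(max_cells_excluded >= 0)
  m[, colSums(m) > max_cells_excluded, drop = FALSE]
}

#' Drop cells with no species
#'
#' Simpson turnover is undefined for empty assemblages, so empty cells must
#' be removed before dissimilarity computation (typically after range-size
#' filtering).
#'
#' @param m Incidence matrix.
#' @return List with `incidence` (all remaining cells have richness >= 1)
#'   and `removed` (character vector of dropped cell ids).
#' @export
drop_empty_cells <- function(m) {
  rich <- rowSums(m)
  if (all(rich == 0L)) stop("all cells are empty", call. = FALSE)
  removed <- rownames(m)[rich == 0L]
  if (length(removed))
    message("dropping ", length(removed), " empty cell(s): ",
            paste(removed, collapse = ", "))
  list(incidence = m[rich > 0L, , drop = FALSE], removed = removed)
}

#' Per-cell richness and mean range size
#'
#' Richness is the number of species in the cell; mean range size is the
#' mean, over the species present, of each species' total occupied-cell
#' count in the supplied matrix (the grid-native analogue of range area).
#' Empty cells get `NA` mean range size.
#'
#' @param m Incidence matrix.
#' @return Data frame with `cell_id`, `richness`, `mean_range_size`.
#' @export
summarize_cells <- function(m) {
  rich <- rowSums(m)
  rs <- colSums(m)
  mrs <- as.vector(m %*% rs) / ifelse(rich > 0, rich, NA_real_)
  data.frame(cell_id = rownames(m), richness = as.integer(rich),
             mean_range_size = mrs, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write an incidence matrix to CSV
#'
#' First column `cell_id`, one column per species, values 0/1 — the format
#' [read_incidence()] reads back.
#'
#' @param m Incidence matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(m, path) {
  out <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
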