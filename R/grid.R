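#' Cell geometry for a regular grid
#'
#' Row-major grid with the origin at the north-west corner and 0-based row
#' and column indices in the cell ids (`r<row>_c<col>`). Coordinates are cell
#' centers in the same units as `cell_size` (default 1000 m, i.e. a 1 km
#' grid).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge length (m).
#' @return a tibble with columns `cell`, `row`, `col`, `x`, `y`.
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size = 1000) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  g <- tidyr::expand_grid(row = seq_len(n_rows) - 1L, col = seq_len(n_cols) - 1L)
  dplyr::mutate(g,
    cell = cell_id(.data$row, .data$col),
    x = (.data$col + 0.5) * cell_size,
    y = (n_rows - .data$row - 0.5) * cell_size,
    .before = 1
  )
}

cell_id <- function(row, col) sprintf("r%d_c%d", row, col)

geometry_cols <- c("cell", "row", "col", "x", "y")

#' Species columns of an occurrence grid
#'
#' An occurrence grid is a tibble with the [grid_geometry()] columns followed
#' by one 0/1 column per species.
#'
#' @param grid an occurrence tibble.
#' @return character vector of species ids.
#' @export
occ_species <- function(grid) setdiff(names(grid), geometry_cols)

#' Extract the cells-by-species presence matrix
#'
#' @param grid an occurrence tibble.
#' @return an integer 0/1 matrix with cell ids as row names.
#' @export
occ_matrix <- function(grid) {
  sp <- occ_species(grid)
  m <- as.matrix(grid[, sp, drop = FALSE])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) abort("occurrence matrix entries must be 0/1")
  rownames(m) <- grid$cell
  m
}

#' Rebuild an occurrence tibble from a presence matrix
#'
#' @param m a 0/1 matrix with cell ids as row names.
#' @param geometry a [grid_geometry()] tibble covering the same cells.
#' @return an occurrence tibble.
#' @export
as_occurrence_grid <- function(m, geometry) {
  if (!setequal(rownames(m), geometry$cell)) abort("matrix rows do not match geometry cells")
  m <- m[geometry$cell, , drop = FALSE]
  dplyr::bind_cols(geometry, tibble::as_tibble(m))
}

#' Read / write occurrence grids as TSV
#'
#' Rows are cells (first column `cell`, ids `r<row>_c<col>`), remaining
#' columns are species presences (0/1). Geometry is reconstructed from the
#' ids.
#'
#' @param grid an occurrence tibble.
#' @param path file path.
#' @param cell_size cell edge length used to rebuild coordinates on read.
#' @return `write_occurrences()` returns `path` invisibly; `read_occurrences()`
#'   returns an occurrence tibble.
#' @export
write_occurrences <- function(grid, path) {
  out <- dplyr::select(grid, "cell", dplyr::all_of(occ_species(grid)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path, cell_size = 1000) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(d)[1] != "cell") abort("first column must be 'cell'")
  rc <- parse_cell_ids(d$cell)
  geom <- grid_geometry(max(rc$row) + 1L, max(rc$col) + 1L, cell_size)
  geom <- geom[match(d$cell, geom$cell), ]
  dplyr::bind_cols(geom, d[, -1, drop = FALSE])
}

parse_cell_ids <- function(ids) {
  m <- regmatches(ids, regexec("^r([0-9]+)_c([0-9]+)$", ids))
  if (any(lengths(m) != 3)) abort("cell ids must look like r<row>_c<col>")
  tibble::tibble(
    row = as.integer(vapply(m, `[`, "", 2)),
    col = as.integer(vapply(m, `[`, "", 3))
  )
}

assert_same_cells <- function(a, b, what = "inputs") {
  if (!identical(a$cell, b$cell)) {
    if (setequal(a$cell, b$cell)) {
      abort(paste0(what, " have the same cells in different order; reorder first"))
    }
    abort(paste0(what, " are not on the same grid (cell sets differ)"))
  }
  invisible(TRUE)
}
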