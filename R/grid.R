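#' Define a raster grid
#'
#' All layers of one landscape share a single grid: `n_rows` x `n_cols`
#' square cells of side `cell_size` metres in a planar equal-area system,
#' origin at the upper-left corner (raster convention, row 1 = top).
#' The default 500 m cell reproduces the resolution at which land-use
#' decisions and services are assessed (a 5 km analysis buffer is then ten
#' cells).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell side length in metres (> 0).
#' @param origin Numeric length-2, planar coordinates of the upper-left
#'   corner (x, y).
#' @param crs_label Free-text label for the coordinate system.
#' @return A `grid_spec` object.
#' @export
#' @examples
#' grid_spec(20, 30)
grid_spec <- function(n_rows, n_cols, cell_size = 500,
                      origin = c(0, 0), crs_label = "local equal-area") {
  assert_number(n_rows, "n_rows", lower = 1)
  assert_number(n_cols, "n_cols", lower = 1)
  assert_number(cell_size, "cell_size", lower = 0, strict = TRUE)
  if (!is.numeric(origin) || length(origin) != 2L) {
    abort("`origin` must be a numeric vector of length 2.")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size), origin = as.numeric(origin),
      crs_label = as.character(crs_label)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g m (%s)\n",
    x$n_rows, x$n_cols, x$cell_size, x$crs_label
  ))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell area of a grid in hectares
#'
#' @param grid A [grid_spec()].
#' @return Area of one cell in ha.
#' @export
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

# pixel table in column-major order so vectors align with as.vector(matrix);
# x, y are cell-centre coordinates, y decreasing with row (origin upper-left)
grid_coords <- function(grid) {
  rows <- rep(seq_len(grid$n_rows), grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  tibble(
    pixel_id = seq_len(n_cells(grid)),
    row = rows,
    col = cols,
    x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
    y = grid$origin[2] - (rows - 0.5) * grid$cell_size
  )
}

# reshape a column-major pixel vector into the grid matrix
as_grid_matrix <- function(values, grid) {
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols)
}
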