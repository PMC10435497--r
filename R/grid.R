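#' 2-D simulation grid
#'
#' A regular isotropic 2-D grid of cell centers.  Cell (1,1) sits at
#' `origin`; lengths are in millimetres throughout the package.
#'
#' @param nx,ny number of cells along x and y (>= 8).
#' @param dx isotropic cell spacing in mm (> 0).
#' @param origin physical coordinate (mm) of the center of cell (1,1).
#' @return an object of class `grid2d`.
#' @export
grid2d <- function(nx, ny, dx, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("grid must be at least 8x8 cells")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) stop("dx must be a positive scalar (mm)")
  structure(list(nx = nx, ny = ny, dx = dx, origin = as.numeric(origin)),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d cells, dx = %g mm (%.1f x %.1f mm)\n",
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a [grid2d()] object.
#' @return list with vectors `x` (length nx), `y` (length ny) and matrices
#'   `X`, `Y` (nx x ny) of cell-center coordinates in mm.
#' @export
grid_coords <- function(grid) {
  x <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx
  y <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dx
  list(x = x, y = y,
       X = matrix(x, grid$nx, grid$ny),
       Y = matrix(y, grid$nx, grid$ny, byrow = TRUE))
}

#' Area of one grid cell in mm^2
#' @param grid a [grid2d()] object.
#' @export
cell_area <- function(grid) grid$dx^2

n_cells <- function(grid) grid$nx * grid$ny

# linear index <-> (i, j) cell index, column-major to match R matrices
cell_index <- function(grid, i, j) (as.integer(j) - 1L) * grid$nx + as.integer(i)

# nearest cell index for a physical coordinate (mm)
nearest_cell <- function(grid, xy) {
  i <- round((xy[1] - grid$origin[1]) / grid$dx) + 1
  j <- round((xy[2] - grid$origin[2]) / grid$dx) + 1
  c(min(max(i, 1), grid$nx), min(max(j, 1), grid$ny))
}

# physical center of the grid (mm)
grid_center <- function(grid) {
  c(grid$origin[1] + (grid$nx - 1) / 2 * grid$dx,
    grid$origin[2] + (grid$ny - 1) / 2 * grid$dx)
}
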