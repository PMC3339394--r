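#' Pixel grid geometry
#'
#' A `pixel_grid` ties the columns of a movie matrix to positions on a 2D or
#' 3D image raster and defines the neighbour structure used for covariation
#' sampling. Pixel indices are 1-based; flattening is row-major over
#' (z, y, x), i.e. x varies fastest, so pixel `j` sits at
#' `x = (j-1) %% width + 1`, `y = ((j-1) %/% width) %% height + 1`, and (in
#' 3D) `z = (j-1) %/% (width*height) + 1`.
#'
#' @param dims integer vector `c(width, height)` or `c(width, height, depth)`,
#'   all entries positive.
#' @return An object of class `pixel_grid` with elements `dims`, `ndim` and
#'   `n` (total pixel count).
#' @examples
#' g <- pixel_grid(c(3, 3))
#' neighbours(g, 5)  # centre pixel of a 3x3 grid: all 8 others
#' @export
pixel_grid <- function(dims) {
  dims <- as.integer(dims)
  if (!length(dims) %in% c(2L, 3L) || anyNA(dims) || any(dims < 1L))
    stop("dims must be 2 or 3 positive integers (width, height[, depth])")
  structure(list(dims = dims, ndim = length(dims), n = prod(dims)),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat("pixel_grid:", paste(x$dims, collapse = " x "),
      sprintf("(%d pixels, %dD)\n", x$n, x$ndim))
  invisible(x)
}

#' Grid coordinates of flattened pixel indices
#'
#' @param grid a [pixel_grid()].
#' @param j vector of 1-based pixel indices.
#' @return Integer matrix with one row per index and columns x, y (and z in
#'   3D).
#' @export
grid_coords <- function(grid, j) {
  stopifnot(inherits(grid, "pixel_grid"))
  j <- as.integer(j)
  if (any(j < 1L | j > grid$n)) stop("pixel index out of range")
  w <- grid$dims[1]; h <- grid$dims[2]
  x <- (j - 1L) %% w + 1L
  y <- ((j - 1L) %/% w) %% h + 1L
  if (grid$ndim == 2L) cbind(x = x, y = y)
  else cbind(x = x, y = y, z = (j - 1L) %/% (w * h) + 1L)
}

#' Flattened index of grid coordinates
#'
#' Inverse of [grid_coords()].
#'
#' @param grid a [pixel_grid()].
#' @param coords matrix (or vector) of x, y (, z) coordinates.
#' @return Integer vector of 1-based pixel indices.
#' @export
grid_index <- function(grid, coords) {
  stopifnot(inherits(grid, "pixel_grid"))
  coords <- matrix(as.integer(coords), ncol = grid$ndim)
  if (any(coords < 1L) ||
      any(sweep(coords, 2, grid$dims, `>`)))
    stop("coordinates out of range")
  w <- grid$dims[1]; h <- grid$dims[2]
  idx <- (coords[, 1] - 1L) + w * (coords[, 2] - 1L)
  if (grid$ndim == 3L) idx <- idx + w * h * (coords[, 3] - 1L)
  idx + 1L
}

# All nonzero offsets of the Moore neighbourhood: 8 in 2D, 26 in 3D.
moore_offsets <- function(ndim) {
  d <- if (ndim == 2L) expand.grid(dx = -1:1, dy = -1:1)
       else expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(d[rowSums(d != 0) > 0, , drop = FALSE])
}

#' Moore neighbourhood of a pixel
#'
#' Returns the immediately adjacent pixels (8-connected in 2D, 26-connected
#' in 3D). Border pixels get truncated neighbourhoods; no padding is applied,
#' so edges never pick up artificial neighbours.
#'
#' @param grid a [pixel_grid()].
#' @param j a single 1-based pixel index.
#' @return Integer vector of neighbour indices (possibly fewer than 8/26 at
#'   borders), in increasing order.
#' @export
neighbours <- function(grid, j) {
  stopifnot(inherits(grid, "pixel_grid"), length(j) == 1L)
  xy <- grid_coords(grid, j)
  off <- moore_offsets(grid$ndim)
  cand <- sweep(off, 2, as.integer(xy), `+`)
  ok <- rep(TRUE, nrow(cand))
  for (d in seq_len(grid$ndim))
    ok <- ok & cand[, d] >= 1L & cand[, d] <= grid$dims[d]
  sort(grid_index(grid, cand[ok, , drop = FALSE]))
}

# For each Moore offset, the vectorised pairs (j, neighbour of j) that stay
# on the grid. Used to accumulate neighbour inner products over all pixels
# at once without building the n x n local covariance matrix.
neighbour_shift_pairs <- function(grid) {
  off <- moore_offsets(grid$ndim)
  co <- grid_coords(grid, seq_len(grid$n))
  lapply(seq_len(nrow(off)), function(r) {
    cand <- sweep(co, 2, off[r, ], `+`)
    ok <- rep(TRUE, nrow(cand))
    for (d in seq_len(grid$ndim))
      ok <- ok & cand[, d] >= 1L & cand[, d] <= grid$dims[d]
    list(j = which(ok), r = grid_index(grid, cand[ok, , drop = FALSE]))
  })
}
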