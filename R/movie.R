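#' Calcium-imaging movie matrix
#'
#' Container tying an m timepoints x n pixels fluorescence matrix to its
#' pixel-grid geometry. Each column is the timeseries of one pixel; columns
#' are ordered by the grid's flattening rule (see [pixel_grid()]).
#'
#' @param data numeric matrix, m timepoints x n pixels, all entries finite,
#'   with m >= 2 and n >= 2.
#' @param dims grid dimensions `c(width, height[, depth])`, or a
#'   [pixel_grid()]; the pixel count must equal `ncol(data)`.
#' @param centered logical; `TRUE` asserts every column has (numerically)
#'   zero mean.
#' @return An object of class `ca_movie` with elements `data`, `grid`,
#'   `centered`.
#' @seealso [center_movie()], [read_movie()], [synthetic_movie()]
#' @export
movie_matrix <- function(data, dims, centered = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("movie contains non-finite values")
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("movie must have at least 2 timepoints and 2 pixels")
  grid <- if (inherits(dims, "pixel_grid")) dims else pixel_grid(dims)
  if (grid$n != ncol(data))
    stop(sprintf("grid has %d pixels but movie has %d columns",
                 grid$n, ncol(data)))
  if (centered && max(abs(colMeans(data))) > 1e-8 * max(1, max(abs(data))))
    stop("centered = TRUE but column means are not zero")
  structure(list(data = data, grid = grid, centered = isTRUE(centered)),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  cat(sprintf("ca_movie: %d timepoints x %d pixels (%s grid), %s\n",
              nrow(x$data), ncol(x$data), paste(x$grid$dims, collapse = "x"),
              if (x$centered) "centered" else "raw"))
  invisible(x)
}

#' @export
dim.ca_movie <- function(x) dim(x$data)

#' Remove per-pixel temporal means
#'
#' Subtracts each pixel's mean over time, the one-pass centering that makes
#' the right singular vectors of the movie the principal components of the
#' pixel covariance. Idempotent.
#'
#' @param A a [movie_matrix()].
#' @return A centered `ca_movie` on the same grid.
#' @export
center_movie <- function(A) {
  stopifnot(inherits(A, "ca_movie"))
  out <- A
  out$data <- sweep(A$data, 2, colMeans(A$data), `-`)
  out$centered <- TRUE
  out
}

#' Read a movie from a TIFF stack or dense text matrix
#'
#' TIFF stacks are read one frame per timepoint (multi-page); each frame is
#' flattened row-major with x fastest, matching [pixel_grid()]. Plain-text
#' files (any extension other than .tif/.tiff) hold the dense matrix with
#' one whitespace-separated row per timepoint.
#'
#' @param path file path.
#' @param dims grid dimensions; the per-frame pixel count must match.
#' @return A raw (uncentered) `ca_movie`.
#' @export
read_movie <- function(path, dims) {
  if (!file.exists(path)) stop("file not found: ", path)
  grid <- if (inherits(dims, "pixel_grid")) dims else pixel_grid(dims)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    dat <- t(vapply(frames, function(fr) {
      if (length(dim(fr)) == 3L) fr <- fr[, , 1]  # greyscale stored as RGB
      if (length(fr) != grid$n)
        stop(sprintf("frame has %d pixels but grid expects %d",
                     length(fr), grid$n))
      # readTIFF returns height x width matrices; row-major x-fastest flatten
      as.vector(t(fr))
    }, numeric(grid$n)))
    if (!all(is.finite(dat))) stop("movie contains non-finite values")
  } else {
    dat <- as.matrix(utils::read.table(path))
    dimnames(dat) <- NULL
    if (ncol(dat) != grid$n)
      stop(sprintf("matrix has %d columns but grid expects %d",
                   ncol(dat), grid$n))
  }
  movie_matrix(dat, grid, centered = FALSE)
}

#' Write a movie to a TIFF stack or dense text matrix
#'
#' The inverse of [read_movie()]. TIFF output is a 16-bit greyscale stack,
#' one page per timepoint — bit-exact for integer fluorescence counts in
#' [0, 65535], quantised (with a warning) otherwise. Text output is a
#' whitespace-separated dense matrix, lossless on round trip.
#'
#' @param A a `ca_movie`.
#' @param path output path; `.tif`/`.tiff` selects TIFF.
#' @return `path`, invisibly.
#' @export
write_movie <- function(A, path) {
  stopifnot(inherits(A, "ca_movie"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    w <- A$grid$dims[1]
    h <- prod(A$grid$dims[-1])  # stack z-planes vertically in 3D
    dat <- A$data
    if (any(dat != round(dat)) || min(dat) < 0 || max(dat) > 65535) {
      warning("non-integer or out-of-range data quantised to 16-bit TIFF; ",
              "use the text matrix format for a lossless round trip")
      rng <- range(dat)
      dat <- round((dat - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
                   * 65535)
    }
    frames <- lapply(seq_len(nrow(dat)), function(i)
      matrix(dat[i, ] / 65535, nrow = h, ncol = w, byrow = TRUE))
    tiff::writeTIFF(frames, path, bits.per.sample = 16L, reduce = FALSE)
  } else {
    utils::write.table(A$data, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Frobenius norm.
fnorm <- function(X) sqrt(sum(X * X))

# Run expr with a reproducible, caller-isolated RNG stream. NULL seed uses
# (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}
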