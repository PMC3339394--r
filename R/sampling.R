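#' Pixel sampling probabilities
#'
#' Constructor for a probability vector over the pixels of a movie, carrying
#' the strategy it was derived from. Norm probabilities weight pixel j by its
#' squared column norm relative to the squared Frobenius norm of the movie;
#' covariation probabilities do the same on the local covariance matrix L
#' (pixel covariance with all non-neighbour entries zeroed), so that pixels
#' inside spatially coherent sources — glomeruli — are preferred.
#'
#' @param p nonnegative numeric vector summing to 1.
#' @param strategy one of `"uniform"`, `"norm"`, `"covariation"`.
#' @param local_norms for the covariation strategy, the vector of local
#'   covariation norms |L_j| (retained for energy computations).
#' @param total_norm for the covariation strategy, the Frobenius norm of L.
#' @return An object of class `sampling_prob`.
#' @seealso [norm_probabilities()], [covariation_probabilities()],
#'   [uniform_probabilities()]
#' @export
sampling_prob <- function(p, strategy = c("uniform", "norm", "covariation"),
                          local_norms = NULL, total_norm = NULL) {
  strategy <- match.arg(strategy)
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("probabilities must be nonnegative and sum to 1")
  if (strategy == "covariation" && (is.null(local_norms) ||
                                    is.null(total_norm)))
    stop("covariation probabilities require local_norms and total_norm")
  structure(list(p = p, strategy = strategy, local_norms = local_norms,
                 total_norm = total_norm),
            class = "sampling_prob")
}

#' @export
print.sampling_prob <- function(x, ...) {
  cat(sprintf("sampling_prob (%s): %d pixels, %d with positive mass\n",
              x$strategy, length(x$p), sum(x$p > 0)))
  invisible(x)
}

#' @rdname sampling_prob
#' @param A a centered [movie_matrix()].
#' @export
uniform_probabilities <- function(A) {
  stopifnot(inherits(A, "ca_movie"))
  n <- ncol(A$data)
  sampling_prob(rep(1 / n, n), "uniform")
}

#' Norm-based sampling probabilities
#'
#' p_j = |A_j|^2 / ||A||_Fr^2: each pixel is weighted by the share of the
#' movie's total energy carried by its (centered) timeseries. These are the
#' probabilities under which the Monte-Carlo error bounds hold.
#'
#' @param A a centered [movie_matrix()].
#' @return A `sampling_prob` with strategy `"norm"`.
#' @export
norm_probabilities <- function(A) {
  stopifnot(inherits(A, "ca_movie"))
  if (!A$centered) stop("center the movie first (center_movie)")
  cn2 <- colSums(A$data^2)
  tot <- sum(cn2)
  if (tot == 0) stop("all-zero movie: norm probabilities undefined")
  sampling_prob(cn2 / tot, "norm")
}

#' Local covariation norms
#'
#' Column norms of the local covariance matrix L = f(A'A), where f zeroes
#' every entry whose pixel pair are not grid neighbours:
#' |L_j| = sqrt( sum_r (A_j . A_r)^2 ) over the Moore neighbours r of j.
#' Computed directly from the movie, offset by offset, without materialising
#' the n x n matrix; ||L||_Fr accumulates on the fly.
#'
#' @param A a centered [movie_matrix()].
#' @return Numeric vector of length n with attribute `total_norm` = ||L||_Fr.
#' @export
local_covariation_norms <- function(A) {
  stopifnot(inherits(A, "ca_movie"))
  if (!A$centered) stop("center the movie first (center_movie)")
  X <- A$data
  acc <- numeric(ncol(X))
  for (sh in neighbour_shift_pairs(A$grid)) {
    ip <- colSums(X[, sh$j, drop = FALSE] * X[, sh$r, drop = FALSE])
    acc[sh$j] <- acc[sh$j] + ip^2
  }
  structure(sqrt(acc), total_norm = sqrt(sum(acc)))
}

#' Covariation-based sampling probabilities
#'
#' p_j = |L_j|^2 / ||L||_Fr^2 with |L_j| from [local_covariation_norms()].
#' Equivalent to norm sampling applied to the local covariance matrix L, and
#' the biologically informed strategy: probability mass concentrates on
#' pixels whose neighbours covary, i.e. inside glomeruli.
#'
#' @param A a centered [movie_matrix()].
#' @return A `sampling_prob` with strategy `"covariation"`, retaining the
#'   local norms and ||L||_Fr for [covariation_energy()].
#' @export
covariation_probabilities <- function(A) {
  ln <- local_covariation_norms(A)
  tot <- attr(ln, "total_norm")
  if (tot == 0)
    stop("no neighbourhood covariation in the movie: ",
         "covariation probabilities undefined")
  sampling_prob(as.numeric(ln)^2 / tot^2, "covariation",
                local_norms = as.numeric(ln), total_norm = tot)
}

#' Draw a pixel sample from a movie
#'
#' With replacement (the Monte-Carlo scheme): c independent draws with
#' probabilities `p`, each selected column rescaled by `1/sqrt(c * p_j)` so
#' that C C' is an unbiased estimate of A A'. Without replacement (the
#' parsimonious scheme paired with covariation probabilities): c distinct
#' pixels drawn sequentially, each draw proportional to `p` renormalised
#' over the not-yet-selected pixels, columns copied unscaled.
#'
#' @param A a centered [movie_matrix()].
#' @param c number of pixels to draw.
#' @param prob a [sampling_prob()].
#' @param replace draw with replacement (and rescale)?
#' @param seed optional integer; fixes the draw exactly.
#' @return An object of class `pixel_sample`: list with the m x c sample
#'   matrix `C`, the drawn `indices` (with multiplicity under replacement),
#'   `with_replacement`, `rescaled`, and the probability `strategy`.
#' @export
sample_pixels <- function(A, c, prob, replace = FALSE, seed = NULL) {
  stopifnot(inherits(A, "ca_movie"), inherits(prob, "sampling_prob"))
  n <- ncol(A$data)
  if (length(prob$p) != n) stop("probability vector does not match movie")
  c <- as.integer(c)
  if (is.na(c) || c < 1L) stop("c must be a positive integer")
  if (replace && prob$strategy != "norm")
    warning("Monte-Carlo error guarantees assume norm probabilities ",
            "when sampling with replacement")
  npos <- sum(prob$p > 0)
  if (!replace && c > npos)
    stop(sprintf("c = %d exceeds the %d pixels with positive probability",
                 c, npos))
  idx <- with_seed(seed,
    sample.int(n, size = c, replace = replace, prob = prob$p))
  C <- A$data[, idx, drop = FALSE]
  if (replace)
    C <- sweep(C, 2, sqrt(c * prob$p[idx]), `/`)
  structure(list(C = C, indices = idx, with_replacement = replace,
                 rescaled = replace, strategy = prob$strategy),
            class = "pixel_sample")
}

#' @export
print.pixel_sample <- function(x, ...) {
  cat(sprintf("pixel_sample: %d columns (%d unique), %s replacement%s, %s probabilities\n",
              length(x$indices), length(unique(x$indices)),
              if (x$with_replacement) "with" else "without",
              if (x$rescaled) " (rescaled)" else "", x$strategy))
  invisible(x)
}

#' Covariation energy of a pixel sample
#'
#' The fraction of the local covariance norm accounted for by the sample:
#' sum of |L_j|^2 over the *unique* sampled indices, divided by ||L||_Fr^2.
#' An a-priori quality measure: energy near 1 means the sample covers
#' essentially all neighbourhood-covarying (glomerular) structure.
#'
#' @param indices sampled pixel indices (duplicates are ignored), or a
#'   `pixel_sample`.
#' @param local_norms local covariation norms |L_j| of the movie the sample
#'   was drawn from (see [local_covariation_norms()]).
#' @param total_norm ||L||_Fr of the same movie.
#' @return A number in \[0, 1\].
#' @export
covariation_energy <- function(indices, local_norms,
                               total_norm = attr(local_norms, "total_norm")) {
  if (inherits(indices, "pixel_sample")) indices <- indices$indices
  if (is.null(total_norm)) stop("total_norm missing")
  if (total_norm == 0) stop("||L||_Fr is zero: energy undefined")
  idx <- unique(as.integer(indices))
  if (length(idx) && (min(idx) < 1L || max(idx) > length(local_norms)))
    stop("index out of range")
  sum(local_norms[idx]^2) / total_norm^2
}

#' Adaptive covariation sampling
#'
#' Draws pixels without replacement under covariation probabilities until
#' the accumulated covariation energy reaches `threshold` (e.g. 0.95) — the
#' "safe" strategy: the sample size adapts to how concentrated the movie's
#' local covariation is. If every positive-probability pixel is exhausted
#' first, all of them are returned.
#'
#' @param A a centered [movie_matrix()].
#' @param threshold target energy in (0, 1].
#' @param seed optional integer seed.
#' @param prob optionally, precomputed covariation [sampling_prob()].
#' @return A `pixel_sample` with attribute `energy`, the energy attained.
#' @export
adaptive_sample <- function(A, threshold = 0.95, seed = NULL, prob = NULL) {
  stopifnot(inherits(A, "ca_movie"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (is.null(prob)) prob <- covariation_probabilities(A)
  if (prob$strategy != "covariation")
    stop("adaptive sampling requires covariation probabilities")
  npos <- sum(prob$p > 0)
  # Draw a full permutation of the positive-mass pixels once (sequentially
  # renormalised, as in the one-by-one loop), then cut at the first index
  # where the running energy crosses the threshold.
  idx <- with_seed(seed,
    sample.int(length(prob$p), size = npos, replace = FALSE, prob = prob$p))
  energy <- cumsum(prob$local_norms[idx]^2) / prob$total_norm^2
  cstop <- which(energy >= threshold)[1]
  if (is.na(cstop)) cstop <- npos  # threshold unreachable: take all
  idx <- idx[seq_len(cstop)]
  structure(list(C = A$data[, idx, drop = FALSE], indices = idx,
                 with_replacement = FALSE, rescaled = FALSE,
                 strategy = "covariation"),
            class = "pixel_sample", energy = energy[cstop])
}

#' Probabilities as a table or image
#'
#' Export helpers for probability maps: a two-column table (pixel index,
#' value) or the vector reshaped to the grid for image display.
#'
#' @param prob a [sampling_prob()] (or any numeric vector for
#'   `probability_image`).
#' @param grid the movie's [pixel_grid()].
#' @return `probability_table`: a data.frame with columns `pixel`, `p`.
#'   `probability_image`: an array with the grid's dimensions ordered
#'   (width, height\[, depth\]).
#' @export
probability_table <- function(prob) {
  stopifnot(inherits(prob, "sampling_prob"))
  data.frame(pixel = seq_along(prob$p), p = prob$p)
}

#' @rdname probability_table
#' @export
probability_image <- function(prob, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  p <- if (inherits(prob, "sampling_prob")) prob$p else as.numeric(prob)
  if (length(p) != grid$n) stop("length mismatch with grid")
  array(p, dim = grid$dims)
}
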