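#' NIPALS extraction of top principal components
#'
#' Sequential power-iteration extraction of the top-k score vectors of a
#' (centered) matrix, with rank-1 deflation between components. Each
#' component is initialised from the column of the current residual with
#' the largest norm (ties broken by lowest index) and iterated via
#' `s = C't/(t't); t = Cs/(s's)` until the relative Euclidean change of t
#' falls below `tol` or `max_iter` is reached. Converged components are
#' sign-fixed so the largest-magnitude entry of t is positive.
#'
#' @param C numeric matrix (m x c), all entries finite.
#' @param k number of components, `k <= min(dim(C))`.
#' @param tol relative convergence tolerance on successive t.
#' @param max_iter iteration cap per component.
#' @return List with `T` (m x k_eff score matrix, columns pairwise
#'   orthogonal), `iterations` (per component), `converged` (per component)
#'   and `rank_deficient` (`TRUE` if the residual vanished before k
#'   components, in which case fewer columns are returned with a warning).
#' @export
nipals <- function(C, k, tol = 1e-9, max_iter = 500L) {
  C <- as.matrix(C)
  if (!all(is.finite(C))) stop("matrix contains non-finite values")
  if (k < 1L || k > min(dim(C))) stop("k must be in [1, min(dim(C))]")
  if (tol <= 0 || max_iter < 1L) stop("invalid tol or max_iter")
  m <- nrow(C)
  Tm <- matrix(0, m, k)
  iters <- integer(k); conv <- logical(k)
  scale0 <- fnorm(C)
  l <- 0L
  while (l < k) {
    cn <- colSums(C^2)
    j0 <- which.max(cn)  # which.max takes the first maximum: lowest index
    if (sqrt(cn[j0]) <= 1e-12 * max(scale0, 1)) break  # residual exhausted
    t <- C[, j0]
    for (it in seq_len(max_iter)) {
      s <- drop(crossprod(C, t)) / sum(t * t)
      t_new <- drop(C %*% s) / sum(s * s)
      delta <- sqrt(sum((t_new - t)^2)) / sqrt(sum(t_new^2))
      t <- t_new
      if (delta < tol) break
    }
    l <- l + 1L
    iters[l] <- it
    conv[l] <- delta < tol
    s <- drop(crossprod(C, t)) / sum(t * t)
    C <- C - tcrossprod(t, s)  # deflate the rank-1 fit
    if (t[which.max(abs(t))] < 0) t <- -t
    Tm[, l] <- t
  }
  rank_def <- l < k
  if (rank_def) {
    warning(sprintf("residual exhausted after %d of %d components", l, k))
    Tm <- Tm[, seq_len(l), drop = FALSE]
    iters <- iters[seq_len(l)]; conv <- conv[seq_len(l)]
  }
  list(T = Tm, iterations = iters, converged = conv,
       rank_deficient = rank_def)
}

#' Fast (approximate) PCA of a calcium-imaging movie
#'
#' Fits the rank-k decomposition `A ~ T S` (T: m x k temporal loadings,
#' S: k x n spatial component images). For `strategy = "exact"` NIPALS runs
#' on the full movie. Otherwise a pixel sample C is drawn — uniformly, with
#' norm probabilities (with replacement and Monte-Carlo rescaling), or with
#' covariation probabilities (without replacement) — NIPALS runs on the
#' small m x c matrix, and the full-size spatial components are recovered
#' as `S = T^+ A` with the Moore-Penrose pseudoinverse of T.
#'
#' @param movie a [movie_matrix()]; centered automatically if raw.
#' @param k target rank (number of components).
#' @param strategy pixel-selection strategy: `"covariation"` (default),
#'   `"norm"`, `"uniform"`, `"adaptive"` (covariation draws until the energy
#'   threshold is met), or `"exact"` (no sampling).
#' @param c_frac sample size as a fraction of the pixel count (ignored when
#'   `c`, `sample` or an adaptive threshold applies).
#' @param c absolute sample size, overrides `c_frac`.
#' @param sample a precomputed [sample_pixels()] result to reuse.
#' @param energy_threshold covariation-energy stop level for
#'   `strategy = "adaptive"`.
#' @param replace override the strategy's default replacement rule
#'   (norm: with replacement; uniform/covariation: without).
#' @param seed optional integer; fixes the pixel draw.
#' @param tol,max_iter NIPALS convergence controls (see [nipals()]).
#' @param keep_movie store the centered movie in the fit (needed by
#'   [residuals.fastpca()] and [frobenius_error()] without re-supplying it).
#' @return An object of class `fastpca`: list with `T`, `S`, `k` (effective
#'   rank), `strategy`, `sample`, `energy` (covariation energy of the
#'   sample, `NA` if local norms were not computed, 1 for exact), `sv`
#'   (component scales ||t_l|| * ||s_l||), `frobenius_error`, `iterations`,
#'   `converged`, `grid`, and (if kept) the centered `movie`.
#' @examples
#' sim <- synthetic_movie(synthetic_movie_spec(dims = c(16, 16),
#'   n_measurements = 2, frames_per_measurement = 20, seed = 1))
#' fit <- fastpca(sim$movie, k = 4, strategy = "covariation",
#'                c_frac = 0.15, seed = 1)
#' fit
#' @export
fastpca <- function(movie, k = 30,
                    strategy = c("covariation", "norm", "uniform",
                                 "adaptive", "exact"),
                    c_frac = 0.15, c = NULL, sample = NULL,
                    energy_threshold = 0.95, replace = NULL, seed = NULL,
                    tol = 1e-9, max_iter = 500L, keep_movie = TRUE) {
  stopifnot(inherits(movie, "ca_movie"))
  strategy <- match.arg(strategy)
  cl <- match.call()
  if (!movie$centered) movie <- center_movie(movie)
  A <- movie$data
  n <- ncol(A)

  energy <- NA_real_
  if (!is.null(sample)) {
    stopifnot(inherits(sample, "pixel_sample"))
    strategy <- sample$strategy
    if (!is.null(attr(sample, "energy"))) energy <- attr(sample, "energy")
  } else if (strategy == "exact") {
    sample <- NULL
    energy <- 1
  } else if (strategy == "adaptive") {
    sample <- adaptive_sample(movie, threshold = energy_threshold,
                              seed = seed)
    energy <- attr(sample, "energy")
  } else {
    prob <- switch(strategy,
                   uniform = uniform_probabilities(movie),
                   norm = norm_probabilities(movie),
                   covariation = covariation_probabilities(movie))
    if (is.null(replace)) replace <- strategy == "norm"
    if (is.null(c)) c <- max(1L, round(c_frac * n))
    sample <- suppressWarnings(
      sample_pixels(movie, c, prob, replace = replace, seed = seed))
    if (strategy == "covariation")
      energy <- covariation_energy(sample, prob$local_norms,
                                   prob$total_norm)
  }

  C <- if (is.null(sample)) A else sample$C
  k_use <- min(k, dim(C))
  if (k_use < k)
    warning(sprintf("k reduced from %d to %d (sample has %d columns)",
                    k, k_use, ncol(C)))
  np <- nipals(C, k_use, tol = tol, max_iter = max_iter)
  Tm <- np$T
  S <- MASS::ginv(Tm) %*% A
  sv <- sqrt(colSums(Tm^2) * rowSums(S^2))
  err <- fnorm(A - Tm %*% S)

  structure(list(T = Tm, S = S, k = ncol(Tm), k_requested = k,
                 strategy = strategy, sample = sample, energy = energy,
                 sv = sv, frobenius_error = err,
                 iterations = np$iterations, converged = np$converged,
                 rank_deficient = np$rank_deficient, grid = movie$grid,
                 movie = if (keep_movie) movie else NULL, call = cl),
            class = "fastpca")
}

#' Frobenius reconstruction error of a decomposition
#'
#' ||A - T S||_Fr, the standard low-rank approximation error.
#'
#' @param A a centered [movie_matrix()] (or plain matrix); defaults to the
#'   movie stored in the fit.
#' @param fit a [fastpca()] (or [fastica()]) decomposition.
#' @return Nonnegative number.
#' @export
frobenius_error <- function(fit, A = NULL) {
  X <- if (is.null(A)) {
    if (is.null(fit$movie)) stop("fit carries no movie; supply A")
    fit$movie$data
  } else if (inherits(A, "ca_movie")) A$data else as.matrix(A)
  Tm <- if (!is.null(fit$T_ica)) fit$T_ica else fit$T
  S <- if (!is.null(fit$S_ica)) fit$S_ica else fit$S
  if (nrow(X) != nrow(Tm) || ncol(X) != ncol(S)) stop("shape mismatch")
  fnorm(X - Tm %*% S)
}

#' @export
print.fastpca <- function(x, ...) {
  cat(sprintf("fastpca decomposition: rank %d, strategy '%s'\n",
              x$k, x$strategy))
  if (!is.null(x$sample))
    cat(sprintf("  pixel sample: c = %d (%.1f%% of %d pixels)%s\n",
                length(x$sample$indices),
                100 * length(x$sample$indices) / ncol(x$S), ncol(x$S),
                if (!is.na(x$energy))
                  sprintf(", covariation energy %.3f", x$energy) else ""))
  cat(sprintf("  Frobenius error ||A - TS||: %.4f\n", x$frobenius_error))
  invisible(x)
}

#' @export
summary.fastpca <- function(object, ...) {
  comp_en <- object$sv^2
  out <- list(k = object$k, strategy = object$strategy,
              energy = object$energy,
              frobenius_error = object$frobenius_error,
              component_scale = object$sv,
              scale_share = comp_en / sum(comp_en),
              iterations = object$iterations,
              c = if (!is.null(object$sample))
                length(object$sample$indices) else ncol(object$S))
  class(out) <- "summary.fastpca"
  out
}

#' @export
print.summary.fastpca <- function(x, ...) {
  cat(sprintf("fastpca: rank %d, strategy '%s', c = %d\n",
              x$k, x$strategy, x$c))
  if (!is.na(x$energy))
    cat(sprintf("covariation energy: %.4f\n", x$energy))
  cat(sprintf("Frobenius error: %.4f\n", x$frobenius_error))
  tab <- data.frame(component = seq_len(x$k),
                    scale = signif(x$component_scale, 4),
                    share = signif(x$scale_share, 3),
                    iterations = x$iterations)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fastpca <- function(object, ...) object$S

#' @export
fitted.fastpca <- function(object, ...) object$T %*% object$S

#' @export
residuals.fastpca <- function(object, A = NULL, ...) {
  X <- if (is.null(A)) {
    if (is.null(object$movie)) stop("fit carries no movie; supply A")
    object$movie$data
  } else if (inherits(A, "ca_movie")) A$data else as.matrix(A)
  X - fitted(object)
}

#' Project new frames onto the fitted spatial components
#'
#' Temporal loadings of new image frames: `T_new = X S^+`.
#'
#' @param object a `fastpca` fit.
#' @param newdata matrix of frames (rows) x pixels, or a `ca_movie`;
#'   defaults to the stored movie (returning `T` up to numerical error).
#' @param ... unused.
#' @export
predict.fastpca <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) {
    if (is.null(object$movie)) return(object$T)
    object$movie$data
  } else if (inherits(newdata, "ca_movie")) newdata$data
  else as.matrix(newdata)
  if (ncol(X) != ncol(object$S)) stop("newdata pixel count mismatch")
  X %*% MASS::ginv(object$S)
}

#' Display spatial components as images
#'
#' @param x a `fastpca` (or `fastica`) fit.
#' @param components which components to draw.
#' @param slice z-plane to draw for 3D grids.
#' @param ... passed to [graphics::image()].
#' @export
plot.fastpca <- function(x, components = seq_len(min(4, x$k)), slice = 1L,
                         ...) {
  S <- if (!is.null(x$S_ica)) x$S_ica else x$S
  grid <- x$grid
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(components)),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (l in components) {
    img <- probability_image(S[l, ], grid)
    if (grid$ndim == 3L) img <- img[, , slice]
    graphics::image(img, axes = FALSE, main = paste("component", l),
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
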