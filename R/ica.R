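# E[log cosh(y)] for standard normal y; baseline of the log-cosh contrast.
.logcosh_gauss <- 0.3745672

# Symmetric (orthogonal) decorrelation: W <- (W W')^{-1/2} W.
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

#' Source separation of a reduced movie with fastICA
#'
#' Runs the symmetric fixed-point fastICA iteration (log-cosh contrast) on
#' the rank-k PCA representation of a movie. In spatial mode the k principal
#' component images (rows of S) are unmixed into statistically independent
#' images; in temporal mode the k component timeseries (columns of T) are
#' unmixed into independent timecourses. Either way the result is a rotation
#' of the reduced space: `T_ica S_ica` reproduces `T S` up to numerical
#' error, so reconstruction quality is inherited from the PCA step.
#'
#' The input is whitened internally (the centered k-variable covariance is
#' sphered exactly); the unmixing matrix starts from a seeded random
#' orthogonal matrix and is symmetrically re-orthogonalised every step.
#' Components are ordered by decreasing log-cosh non-Gaussianity and
#' sign-fixed so each source's largest-magnitude entry is positive.
#'
#' @param fit a [fastpca()] decomposition with `k >= 2`.
#' @param mode `"spatial"` (independent images, the glomerulus-map use
#'   case) or `"temporal"` (independent timecourses, the artifact-removal
#'   use case).
#' @param seed integer; fixes the random initial unmixing matrix.
#' @param tol convergence tolerance on the unmixing rotation.
#' @param max_iter iteration cap; on hitting it the last iterate is
#'   returned with `converged = FALSE`.
#' @return An object of class `fastica`: list with `T_ica` (m x k), `S_ica`
#'   (k x n), `mode`, `converged`, `iterations`, `contrast`
#'   (non-Gaussianity per component), `unmixing` (k x k, applied to the
#'   PCA-space variables), `grid`, `k`.
#' @export
fastica <- function(fit, mode = c("spatial", "temporal"), seed = NULL,
                    tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(fit, "fastpca"))
  mode <- match.arg(mode)
  k <- fit$k
  if (k < 2L) stop("ICA needs at least 2 components")
  X <- if (mode == "spatial") fit$S else t(fit$T)  # k variables x N samples
  N <- ncol(X)

  xbar <- rowMeans(X)
  Xc <- X - xbar
  eg <- eigen(tcrossprod(Xc) / N, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    stop("reduced space is rank deficient; lower k")
  K <- diag(1 / sqrt(eg$values), k) %*% t(eg$vectors)   # whitening
  Kinv <- eg$vectors %*% diag(sqrt(eg$values), k)
  Z <- K %*% Xc

  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    G <- tanh(Y)
    W1 <- G %*% t(Z) / N - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fastICA did not converge within max_iter; returning last iterate")

  # Non-Gaussianity (log-cosh negentropy proxy) of each whitened source.
  Y <- W %*% Z
  contrast <- (rowMeans(log(cosh(Y))) - .logcosh_gauss)^2
  ord <- order(contrast, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  contrast <- contrast[ord]

  # Sources with the removed means folded back in: U X = W K X gives exact
  # X = (K^-1 W') (W K X), so T_ica S_ica == T S.
  U <- W %*% K
  sources <- U %*% X
  flip <- apply(sources, 1, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sources <- sources * flip
  Minv <- sweep(Kinv %*% t(W), 2, flip, `*`)  # columns flipped with sources

  if (mode == "spatial") {
    S_ica <- sources
    T_ica <- fit$T %*% Minv
  } else {
    T_ica <- t(sources)
    S_ica <- t(Minv) %*% fit$S
  }
  structure(list(T_ica = T_ica, S_ica = S_ica, mode = mode,
                 converged = converged, iterations = it,
                 contrast = contrast, unmixing = sweep(U, 1, flip, `*`),
                 grid = fit$grid, k = k),
            class = "fastica")
}

#' @export
print.fastica <- function(x, ...) {
  cat(sprintf("fastica decomposition: %s mode, k = %d, %s after %d iterations\n",
              x$mode, x$k,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  non-Gaussianity:", paste(signif(x$contrast, 3), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.fastica <- function(x, components = seq_len(min(4, x$k)), slice = 1L,
                         ...) {
  plot.fastpca(x, components = components, slice = slice, ...)
}

# Component matrix in a common orientation: one row per component.
component_rows <- function(x, what) {
  if (is.matrix(x)) return(if (what == "temporal") t(x) else x)
  if (inherits(x, "fastica"))
    return(if (what == "spatial") x$S_ica else t(x$T_ica))
  if (inherits(x, "fastpca"))
    return(if (what == "spatial") x$S else t(x$T))
  stop("cannot extract components from this object")
}

#' Greedy matching of decomposition components
#'
#' Pairs the components of two decompositions by absolute Pearson
#' correlation, greedily: the globally best pair is matched first, then the
#' best among the remainder, and so on up to the smaller rank. Used to
#' compare exact-PCA ICA against approximate-PCA ICA, or recovered sources
#' against planted ground truth (sign and order of ICA/PCA components are
#' arbitrary, so matching is on |r|).
#'
#' @param x,y `fastpca`/`fastica` fits, or plain matrices of components
#'   (spatial: components x pixels; temporal: timepoints x components).
#' @param what compare `"spatial"` component images or `"temporal"`
#'   timecourses.
#' @return data.frame with columns `x`, `y` (component indices) and
#'   `abs_r`, one row per matched pair, in matching order.
#' @export
match_components <- function(x, y, what = c("spatial", "temporal")) {
  what <- match.arg(what)
  Xr <- component_rows(x, what)
  Yr <- component_rows(y, what)
  if (ncol(Xr) != ncol(Yr)) stop("components have different lengths")
  R <- abs(stats::cor(t(Xr), t(Yr)))
  R[!is.finite(R)] <- 0  # constant components have undefined correlation
  nmatch <- min(nrow(Xr), nrow(Yr))
  out <- data.frame(x = integer(nmatch), y = integer(nmatch),
                    abs_r = numeric(nmatch))
  for (i in seq_len(nmatch)) {
    best <- arrayInd(which.max(R), dim(R))
    out$x[i] <- best[1]; out$y[i] <- best[2]
    out$abs_r[i] <- R[best[1], best[2]]
    R[best[1], ] <- -1
    R[, best[2]] <- -1
  }
  out
}

#' Pixels carried by an ICA component image
#'
#' Thresholds the absolute coefficients of a spatial component at a
#' quantile, returning the supra-threshold pixel indices — the simple
#' glomerulus-position readout from an independent component image.
#'
#' @param ica a [fastica()] (or [fastpca()]) fit.
#' @param component component number.
#' @param quantile threshold quantile of |coefficient| (default 0.99: the
#'   top 1% of pixels).
#' @return Integer vector of pixel indices.
#' @export
component_pixels <- function(ica, component, quantile = 0.99) {
  S <- if (!is.null(ica$S_ica)) ica$S_ica else ica$S
  v <- abs(S[component, ])
  which(v > stats::quantile(v, quantile))
}
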