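# Shared fixtures and independent oracles, all built in code.

fnorm_oracle <- function(X) sqrt(sum(X^2))

# Random centered movie on a grid.
random_movie <- function(m, dims, seed = 1, sd = 1) {
  set.seed(seed)
  A <- matrix(rnorm(m * prod(dims), sd = sd), m, prod(dims))
  center_movie(movie_matrix(A, dims))
}

# Independent neighbour relation: Chebyshev distance 1 on the raster,
# computed from coordinates alone (no package neighbour code).
oracle_neighbour_matrix <- function(dims) {
  n <- prod(dims)
  co <- arrayInd(seq_len(n), .dim = dims)  # x fastest, like the package
  N <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- abs(sweep(co, 2, co[i, ], `-`))
    N[i, ] <- apply(d, 1, max) == 1L & apply(d, 1, max) >= 1L
  }
  diag(N) <- FALSE
  N
}

# Explicit local covariance matrix L = f(A'A): materialise the full n x n
# Gram matrix and zero every non-neighbour entry; return its column norms
# and Frobenius norm.
oracle_local_norms <- function(A, dims) {
  X <- if (inherits(A, "ca_movie")) A$data else A
  G <- crossprod(X)
  G[!oracle_neighbour_matrix(dims)] <- 0
  list(norms = sqrt(colSums(G^2)), total = sqrt(sum(G^2)))
}

# Random matrix with a prescribed, well-separated singular spectrum.
spectrum_matrix <- function(m, n, d, seed = 1) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  V <- qr.Q(qr(matrix(rnorm(n * m), n, m)))
  U %*% diag(d, m) %*% t(V)
}

# Largest principal angle (radians) between the column spaces of X and Y.
max_principal_angle <- function(X, Y) {
  qx <- qr.Q(qr(X)); qy <- qr.Q(qr(Y))
  s <- svd(crossprod(qx, qy))$d
  acos(min(1, max(-1, min(s))))
}

# Small two-glomerulus spec used across tests.
two_glom_spec <- function(dims = c(24, 24), noise_sd = 0.1, bleach = 0.3,
                          seed = 5, n_meas = 4, fpm = 30) {
  synthetic_movie_spec(
    dims = dims, n_measurements = n_meas, frames_per_measurement = fpm,
    glomeruli = list(
      list(centre = round(dims * 0.3), radius = 3,
           amplitudes = rep_len(c(2, 0.3, 1.5, 0.4), n_meas)),
      list(centre = round(dims * 0.7), radius = 3,
           amplitudes = rep_len(c(0.4, 1.8, 0.3, 1.4), n_meas))),
    bleach = list(amplitude = bleach, tau = 0.75 * fpm),
    noise_sd = noise_sd, seed = seed)
}
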