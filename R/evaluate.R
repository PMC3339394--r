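#' Strategy evaluation sweep
#'
#' Runs exact PCA once and each (strategy, sample fraction) combination for
#' a number of seeded repetitions, recording the Frobenius reconstruction
#' error and the covariation energy of every sample — the standard
#' accuracy protocol for comparing uniform, norm and covariation pixel
#' sampling against the exact baseline.
#'
#' @param movie a [movie_matrix()]; centered automatically.
#' @param strategies subset of `c("uniform", "norm", "covariation")`.
#' @param c_fractions sample sizes as fractions of the pixel count.
#' @param k rank of every decomposition.
#' @param repetitions independent repetitions per cell.
#' @param seed master seed; derives one sub-seed per (strategy, fraction,
#'   repetition) cell so the table is fully reproducible.
#' @param include_exact prepend the exact-PCA baseline row (covariation
#'   energy 1 by convention: the full pixel set).
#' @return An object of class `fastpca_eval`: data.frame with columns
#'   `strategy`, `c_fraction`, `c`, `repetition`, `seed`,
#'   `frobenius_error`, `covariation_energy`, `elapsed` (seconds, logged
#'   but hardware-dependent).
#' @export
evaluate_sampling <- function(movie,
                              strategies = c("uniform", "norm",
                                             "covariation"),
                              c_fractions = c(0.01, 0.05, 0.10, 0.15),
                              k = 30, repetitions = 10, seed = 1L,
                              include_exact = TRUE) {
  stopifnot(inherits(movie, "ca_movie"))
  if (length(strategies))
    strategies <- match.arg(strategies, several.ok = TRUE)
  if (!movie$centered) movie <- center_movie(movie)
  n <- ncol(movie$data)
  ln <- local_covariation_norms(movie)
  probs <- list(uniform = uniform_probabilities(movie),
                norm = norm_probabilities(movie),
                covariation = covariation_probabilities(movie))

  rows <- list()
  if (include_exact) {
    t0 <- proc.time()[3]
    fit <- fastpca(movie, k = k, strategy = "exact", keep_movie = FALSE)
    rows[[1]] <- data.frame(strategy = "exact", c_fraction = 1, c = n,
                            repetition = 1L, seed = NA_integer_,
                            frobenius_error = fit$frobenius_error,
                            covariation_energy = 1,
                            elapsed = proc.time()[3] - t0)
  }
  cell <- 0L
  for (strat in strategies) for (fr in c_fractions) {
    c_abs <- max(1L, round(fr * n))
    for (rep in seq_len(repetitions)) {
      cell <- cell + 1L
      # sub-seed per cell, kept below 2^31
      sd <- (as.integer(seed) * 10007L + cell) %% .Machine$integer.max
      t0 <- proc.time()[3]
      smp <- suppressWarnings(
        sample_pixels(movie, c_abs, probs[[strat]],
                      replace = strat == "norm", seed = sd))
      fit <- fastpca(movie, k = k, sample = smp, keep_movie = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = strat, c_fraction = fr, c = c_abs,
                   repetition = rep, seed = sd,
                   frobenius_error = fit$frobenius_error,
                   covariation_energy =
                     covariation_energy(smp, ln),
                   elapsed = proc.time()[3] - t0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fastpca_eval", "data.frame")
  out
}

#' @export
summary.fastpca_eval <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- stats::aggregate(
    cbind(frobenius_error, covariation_energy) ~ strategy + c_fraction,
    data = df, FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(strategy = agg$strategy, c_fraction = agg$c_fraction,
                    error_mean = agg$frobenius_error[, "mean"],
                    error_sd = agg$frobenius_error[, "sd"],
                    energy_mean = agg$covariation_energy[, "mean"],
                    energy_sd = agg$covariation_energy[, "sd"])
  out[order(out$strategy, out$c_fraction), ]
}

#' @export
print.fastpca_eval <- function(x, ...) {
  cat(sprintf("fastpca_eval: %d runs\n", nrow(x)))
  print(summary(x), row.names = FALSE)
  invisible(x)
}
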