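#' Monte-Carlo sample size for a target expected error
#'
#' The expected-error guarantee of norm-probability column sampling holds
#' when at least `4k / epsilon^2` columns are drawn with replacement: the
#' smallest such integer is returned. A small relative fuzz keeps
#' analytically integer values (e.g. k = 20, epsilon = 0.05 giving 32000)
#' from being bumped up by floating point.
#'
#' @param k target rank.
#' @param epsilon target error as a fraction of ||A||_Fr^2.
#' @return The smallest integer c with c >= 4k / epsilon^2.
#' @examples
#' required_sample_size(20, 0.05)  # 32000
#' @export
required_sample_size <- function(k, epsilon) {
  if (length(k) != 1L || length(epsilon) != 1L || k < 1 || epsilon <= 0)
    stop("k must be a positive integer and epsilon > 0")
  val <- 4 * k / epsilon^2
  as.integer(ceiling(val * (1 - 1e-12) - 1e-12))
}

#' Covariance approximation error of a pixel sample
#'
#' ||A A' - C C'||_Fr over the m x m time-covariance matrices: the quantity
#' through which column sampling enters the deterministic error bound. With
#' Algorithm-1 rescaling, C C' is an unbiased estimator of A A' and this
#' error shrinks as c grows.
#'
#' @param A a centered [movie_matrix()] (or plain matrix).
#' @param C a [sample_pixels()] result (or plain m x c matrix).
#' @return Nonnegative number.
#' @export
covariance_error <- function(A, C) {
  X <- if (inherits(A, "ca_movie")) A$data else as.matrix(A)
  Cm <- if (inherits(C, "pixel_sample")) C$C else as.matrix(C)
  if (nrow(X) != nrow(Cm)) stop("A and C must share the timepoint dimension")
  fnorm(tcrossprod(X) - tcrossprod(Cm))
}

#' Empirical verification of the sampling error bounds
#'
#' For each repetition, draws a with-replacement norm-probability sample of
#' size `c = required_sample_size(k, epsilon)` (or `c` if given), extracts
#' the top-k NIPALS basis of the sample, orthonormalises it into H_k, and
#' checks the deterministic bound
#' `||A - H_k H_k' A||^2 <= ||A - A_k||^2 + 2 sqrt(k) ||AA' - CC'||_Fr`
#' run by run. The expectation bound
#' `E ||A - H_k H_k' A||^2 <= ||A - A_k||^2 + epsilon ||A||^2`
#' is checked on the empirical mean across repetitions. The optimal rank-k
#' error `||A - A_k||` comes from a dense SVD of A. Both bound sides are
#' reported so the (known) slack of the bound is visible, not just
#' pass/fail.
#'
#' @param A a [movie_matrix()]; centered automatically if raw.
#' @param k rank of the approximation.
#' @param epsilon target expected-error fraction.
#' @param repetitions number of independent samples.
#' @param seed integer seed governing all draws.
#' @param c optional explicit sample size overriding the 4k/epsilon^2 rule.
#' @param c_cap guard against accidental huge draws; raise it explicitly
#'   when a large c is intended.
#' @param tol,max_iter NIPALS controls.
#' @return An object of class `bound_report`: a data.frame with one row per
#'   repetition (columns `c`, `approx_error_sq`, `exact_error_sq`,
#'   `cov_error`, `bound_rhs`, `satisfied`) plus attributes
#'   `expectation_lhs` (mean approx error squared), `expectation_rhs`
#'   (exact^2 + epsilon ||A||^2) and `expectation_satisfied`.
#' @export
verify_bounds <- function(A, k, epsilon, repetitions = 30L, seed = NULL,
                          c = NULL, c_cap = 100000L, tol = 1e-9,
                          max_iter = 500L) {
  stopifnot(inherits(A, "ca_movie"))
  if (!A$centered) A <- center_movie(A)
  if (is.null(c)) c <- required_sample_size(k, epsilon)
  if (c > c_cap)
    stop(sprintf("required c = %d exceeds c_cap = %d; raise c_cap to force",
                 c, c_cap))
  X <- A$data
  prob <- norm_probabilities(A)
  sv <- svd(X, nu = 0, nv = 0)$d
  exact_sq <- sum(sv[-seq_len(min(k, length(sv)))]^2)  # ||A - A_k||^2
  a_fr_sq <- sum(sv^2)

  rows <- with_seed(seed, lapply(seq_len(repetitions), function(r) {
    smp <- sample_pixels(A, c, prob, replace = TRUE, seed = NULL)
    np <- nipals(smp$C, min(k, min(dim(smp$C))), tol = tol,
                 max_iter = max_iter)
    Hk <- qr.Q(qr(np$T))  # orthonormal basis of the sample score space
    lhs <- a_fr_sq - sum(crossprod(Hk, X)^2)  # ||A - Hk Hk' A||^2
    cov_err <- covariance_error(X, smp$C)
    rhs <- exact_sq + 2 * sqrt(k) * cov_err
    data.frame(c = c, approx_error_sq = lhs, exact_error_sq = exact_sq,
               cov_error = cov_err, bound_rhs = rhs,
               satisfied = lhs <= rhs * (1 + 1e-10))
  }))
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  attr(out, "epsilon") <- epsilon
  attr(out, "expectation_lhs") <- mean(out$approx_error_sq)
  attr(out, "expectation_rhs") <- exact_sq + epsilon * a_fr_sq
  attr(out, "expectation_satisfied") <-
    attr(out, "expectation_lhs") <= attr(out, "expectation_rhs")
  class(out) <- c("bound_report", "data.frame")
  out
}

#' @export
print.bound_report <- function(x, ...) {
  cat(sprintf("bound_report: k = %d, epsilon = %g, c = %d, %d repetitions\n",
              attr(x, "k"), attr(x, "epsilon"), x$c[1], nrow(x)))
  cat(sprintf("  deterministic bound satisfied in %d/%d runs\n",
              sum(x$satisfied), nrow(x)))
  cat(sprintf("  expectation bound: mean %.6g <= %.6g (%s)\n",
              attr(x, "expectation_lhs"), attr(x, "expectation_rhs"),
              if (attr(x, "expectation_satisfied")) "holds" else "VIOLATED"))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5))
  invisible(x)
}
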