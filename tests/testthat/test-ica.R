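# Build a fastpca-like fit from a known T S decomposition so ICA can be
# tested against controlled mixtures.
fake_fit <- function(T, S, dims) {
  structure(list(T = T, S = S, k = ncol(T), strategy = "exact",
                 grid = pixel_grid(dims), movie = NULL),
            class = "fastpca")
}

test_that("spatial fastICA unmixes two disjoint non-Gaussian sources", {
  set.seed(61)
  n <- 400; m <- 40
  s1 <- numeric(n); s2 <- numeric(n)
  s1[1:60] <- rexp(60)              # disjoint supports, heavy tails
  s2[201:280] <- rexp(80)
  Strue <- rbind(s1, s2)
  M <- matrix(c(1, 0.8, -0.6, 1), 2, 2)        # mixing
  Tload <- qr.Q(qr(matrix(rnorm(m * 2), m, 2))) # orthogonal loadings
  fit <- fake_fit(Tload, M %*% Strue, c(20, 20))
  ic <- fastica(fit, mode = "spatial", seed = 5)
  mt <- match_components(ic$S_ica, Strue, what = "spatial")
  expect_true(all(mt$abs_r >= 0.95))
  expect_true(ic$converged)
})

test_that("already independent input yields a signed-permutation unmixing", {
  set.seed(62)
  n <- 500
  Strue <- rbind(c(rexp(100), numeric(n - 100)),
                 c(numeric(n - 120), rexp(120)))
  Tload <- qr.Q(qr(matrix(rnorm(30 * 2), 30, 2)))
  fit <- fake_fit(Tload, Strue, c(25, 20))
  ic <- fastica(fit, mode = "spatial", seed = 3)
  mt <- match_components(ic$S_ica, Strue, what = "spatial")
  expect_true(all(mt$abs_r >= 0.99))
  expect_setequal(mt$y, 1:2)
})

test_that("source sign flips do not change matching quality", {
  sim <- synthetic_movie(two_glom_spec())
  fit <- fastpca(sim$movie, k = 3, strategy = "covariation", c_frac = 0.2,
                 seed = 4)
  ic1 <- fastica(fit, mode = "spatial", seed = 8)
  fit2 <- fit
  fit2$T[, 1] <- -fit2$T[, 1]     # flip one PCA component's sign
  fit2$S[1, ] <- -fit2$S[1, ]
  ic2 <- fastica(fit2, mode = "spatial", seed = 8)
  m1 <- match_components(ic1, sim$truth$timecourses, what = "temporal")
  m2 <- match_components(ic2, sim$truth$timecourses, what = "temporal")
  expect_equal(sort(m1$abs_r), sort(m2$abs_r), tolerance = 1e-6)
})

test_that("ICA is a rotation of the reduced space in both modes", {
  sim <- synthetic_movie(two_glom_spec())
  fit <- fastpca(sim$movie, k = 3, strategy = "covariation", c_frac = 0.2,
                 seed = 4)
  base <- fit$T %*% fit$S
  for (mode in c("spatial", "temporal")) {
    ic <- fastica(fit, mode = mode, seed = 10)
    expect_lt(fnorm_oracle(base - ic$T_ica %*% ic$S_ica),
              1e-6 * fnorm_oracle(base))
    expect_equal(dim(ic$T_ica), dim(fit$T))
    expect_equal(dim(ic$S_ica), dim(fit$S))
  }
  expect_error(fastica(fastpca(sim$movie, k = 1, strategy = "exact")),
               "at least 2")
})

test_that("component matching recovers permutations and handles noise", {
  set.seed(63)
  X <- matrix(rnorm(5 * 100), 5, 100)
  self <- match_components(X, X, what = "spatial")
  expect_equal(self$x, self$y)
  expect_equal(self$abs_r, rep(1, 5), tolerance = 1e-12)

  perm <- c(3, 1, 5, 2, 4)
  Y <- X[perm, ] * c(1, -1, 1, -1, 1)
  mt <- match_components(X, Y, what = "spatial")
  expect_equal(mt$y[order(mt$x)], order(perm))
  expect_equal(mt$abs_r, rep(1, 5), tolerance = 1e-12)

  Z <- matrix(rnorm(5 * 100), 5, 100)   # unrelated components
  mt <- match_components(X, Z, what = "spatial")
  expect_equal(nrow(mt), 5)             # matching is still total
  expect_true(all(mt$abs_r < 0.6))
})

test_that("the bleach trend separates from glomerular signals", {
  sim <- synthetic_movie(two_glom_spec(dims = c(32, 32), bleach = 0.4,
                                       seed = 17))
  mv <- center_movie(sim$movie)
  fit <- fastpca(mv, k = 4, strategy = "covariation", c_frac = 0.15,
                 seed = 2)
  ic <- fastica(fit, mode = "spatial", seed = 6)

  # one component captures the bleach trend
  trend_r <- apply(ic$T_ica, 2, function(tc)
    abs(cor(tc, sim$truth$trend)))
  expect_gt(max(trend_r), 0.9)

  # matched glomerular timecourses beat the raw mean timeseries, which
  # still carries the trend
  mt <- match_components(ic$T_ica, sim$truth$timecourses,
                         what = "temporal")
  for (i in seq_len(nrow(mt))) {
    raw_mean <- rowMeans(sim$movie$data[, sim$truth$masks[[mt$y[i]]]])
    raw_r <- abs(cor(raw_mean, sim$truth$timecourses[, mt$y[i]]))
    expect_gt(mt$abs_r[i], raw_r)
  }
})

test_that("component pixel extraction finds planted glomeruli", {
  sim <- synthetic_movie(two_glom_spec(dims = c(32, 32), seed = 19))
  fit <- fastpca(sim$movie, k = 3, strategy = "covariation", c_frac = 0.2,
                 seed = 3)
  ic <- fastica(fit, mode = "spatial", seed = 7)
  G <- matrix(0, 2, ncol(sim$movie$data))
  for (g in 1:2) G[g, sim$truth$masks[[g]]] <- sim$truth$weights[[g]]
  mt <- match_components(ic$S_ica, G, what = "spatial")
  for (i in seq_len(nrow(mt))) {
    px <- component_pixels(ic, mt$x[i], quantile = 0.99)
    overlap <- mean(px %in% sim$truth$masks[[mt$y[i]]])
    expect_gt(overlap, 0.8)   # top-1% pixels lie inside the glomerulus
  }
})
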