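test_that("norm probabilities are squared column norms over total energy", {
  A <- movie_matrix(matrix(c(3, -3, 4, -4), 2, 2), c(2, 1), centered = TRUE)
  expect_equal(norm_probabilities(A)$p, c(0.36, 0.64))

  same <- center_movie(movie_matrix(matrix(rnorm(3), 3, 1)[, c(1, 1, 1, 1)],
                                    c(2, 2)))
  expect_equal(norm_probabilities(same)$p, rep(0.25, 4))

  A <- random_movie(20, c(10, 5), seed = 11)
  p <- norm_probabilities(A)$p
  # brute-force elementwise oracle
  oracle <- apply(A$data, 2, function(col) sum(col * col)) /
    sum(A$data * A$data)
  expect_equal(p, oracle, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  zero <- movie_matrix(matrix(0, 3, 4), c(2, 2), centered = TRUE)
  expect_error(norm_probabilities(zero), "all-zero")
})

test_that("local covariation norms match the explicit L = f(A'A) oracle", {
  # isolated active pixel: every neighbour product vanishes
  X <- matrix(0, 6, 9)
  X[, 5] <- rnorm(6)
  A <- movie_matrix(scale(X, scale = FALSE), c(3, 3), centered = TRUE)
  expect_equal(as.numeric(local_covariation_norms(A))[5], 0)

  # identical timeseries everywhere: norm is sqrt(#neighbours) * |t|^2
  t <- rnorm(8); t <- t - mean(t)
  A <- movie_matrix(matrix(t, 8, 9), c(3, 3), centered = TRUE)
  ln <- as.numeric(local_covariation_norms(A))
  expect_equal(ln[5], sqrt(8) * sum(t^2), tolerance = 1e-10)
  expect_equal(ln[1], sqrt(3) * sum(t^2), tolerance = 1e-10)

  for (dims in list(c(4, 4), c(5, 3), c(3, 3, 2))) {
    A <- random_movie(10, dims, seed = sum(dims))
    ln <- local_covariation_norms(A)
    orc <- oracle_local_norms(A, dims)
    expect_equal(as.numeric(ln), orc$norms, tolerance = 1e-10)
    expect_equal(attr(ln, "total_norm"), orc$total, tolerance = 1e-10)
  }
})

test_that("covariation probabilities concentrate on covarying structure", {
  # one active 3x3 blob in a zero background
  A <- matrix(0, 10, 100)
  g <- pixel_grid(c(10, 10))
  blob <- as.vector(outer(4:6, (4:6 - 1) * 10, `+`))
  tc <- rnorm(10); tc <- tc - mean(tc)
  A[, blob] <- tc
  mv <- movie_matrix(A, g, centered = TRUE)
  p <- covariation_probabilities(mv)
  expect_equal(sum(p$p[blob]), 1, tolerance = 1e-12)
  expect_equal(p$strategy, "covariation")

  # identical timeseries: interior pixels share mass, edges get less
  t <- rnorm(6); t <- t - mean(t)
  mv <- movie_matrix(matrix(t, 6, 25), c(5, 5), centered = TRUE)
  p <- covariation_probabilities(mv)$p
  interior <- grid_index(pixel_grid(c(5, 5)),
                         as.matrix(expand.grid(2:4, 2:4)))
  expect_true(max(abs(p[interior] - p[interior][1])) < 1e-14)
  expect_lt(p[1], p[interior][1])

  A <- random_movie(10, c(4, 4), seed = 2)
  orc <- oracle_local_norms(A, c(4, 4))
  expect_equal(covariation_probabilities(A)$p, orc$norms^2 / orc$total^2,
               tolerance = 1e-10)

  # spatially independent realisation with literally zero covariation
  flat <- movie_matrix(rbind(c(1, 0, 1, 0), c(-1, 0, -1, 0),
                             c(1, 0, 1, 0), c(-1, 0, -1, 0)) * 0,
                       c(2, 2), centered = TRUE)
  expect_error(covariation_probabilities(flat), "undefined")
})

test_that("with-replacement sampling rescales and honours probabilities", {
  A <- movie_matrix(cbind(rnorm(5), 0), c(2, 1), centered = FALSE)
  A <- center_movie(A)
  p <- sampling_prob(c(1, 0), "norm")
  smp <- sample_pixels(A, 4, p, replace = TRUE, seed = 1)
  expect_true(all(smp$indices == 1))
  expect_equal(smp$C, A$data[, c(1, 1, 1, 1)] / sqrt(4 * 1),
               tolerance = 1e-14)
  expect_true(smp$rescaled)

  # determinism
  s1 <- sample_pixels(A, 3, p, replace = TRUE, seed = 7)
  s2 <- sample_pixels(A, 3, p, replace = TRUE, seed = 7)
  expect_identical(s1$indices, s2$indices)
  expect_identical(s1$C, s2$C)

  # empirical frequencies within 3 binomial standard errors
  A4 <- random_movie(5, c(2, 2), seed = 3)
  p4 <- sampling_prob(c(0.1, 0.2, 0.3, 0.4), "norm")
  smp <- suppressWarnings(sample_pixels(A4, 10000, p4, replace = TRUE,
                                        seed = 42))
  freq <- tabulate(smp$indices, 4) / 10000
  se <- sqrt(p4$p * (1 - p4$p) / 10000)
  expect_true(all(abs(freq - p4$p) <= 3 * se))
})

test_that("without-replacement sampling draws distinct unscaled columns", {
  A <- random_movie(6, c(3, 2), seed = 8)
  p <- norm_probabilities(A)
  smp <- sample_pixels(A, 6, p, replace = FALSE, seed = 2)
  expect_setequal(smp$indices, 1:6)              # exhaustive draw: permutation
  expect_equal(smp$C, A$data[, smp$indices], tolerance = 1e-14)
  expect_false(smp$rescaled)

  smp <- sample_pixels(A, 4, p, replace = FALSE, seed = 3)
  expect_length(unique(smp$indices), 4)

  # c = 1 draw frequency across seeds matches p
  p2 <- sampling_prob(c(0.7, 0.3, 0, 0, 0, 0), "norm")
  draws <- vapply(1:2000, function(s)
    sample_pixels(A, 1, p2, replace = FALSE, seed = s)$indices, integer(1))
  f1 <- mean(draws == 1)
  expect_lt(abs(f1 - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))
  expect_error(sample_pixels(A, 3, p2, replace = FALSE), "positive prob")
})

test_that("covariation energy deduplicates indices and spans [0, 1]", {
  A <- random_movie(8, c(4, 4), seed = 5)
  ln <- local_covariation_norms(A)
  expect_equal(covariation_energy(1:16, ln), 1)
  expect_equal(covariation_energy(integer(0), ln), 0)
  expect_equal(covariation_energy(c(3, 3, 3, 7), ln),
               covariation_energy(c(3, 7), ln))
  expect_error(covariation_energy(1:3, as.numeric(ln), total_norm = 0),
               "zero")
})

test_that("adaptive sampling stops at the energy threshold", {
  # all covariation in one 3x3 blob of 9 pixels
  A <- matrix(0, 12, 64)
  blob <- as.vector(outer(3:5, (3:5 - 1) * 8, `+`))
  tc <- rnorm(12); tc <- tc - mean(tc)
  A[, blob] <- tc
  mv <- movie_matrix(A, c(8, 8), centered = TRUE)
  smp <- adaptive_sample(mv, threshold = 1.0, seed = 4)
  expect_setequal(smp$indices, blob)     # exactly the covarying pixels

  smp1 <- adaptive_sample(mv, threshold = 1e-12, seed = 4)
  expect_length(smp1$indices, 1)

  sim <- synthetic_movie(two_glom_spec())
  mv <- center_movie(sim$movie)
  prob <- covariation_probabilities(mv)
  smp <- adaptive_sample(mv, threshold = 0.95, seed = 9, prob = prob)
  en_full <- covariation_energy(smp, prob$local_norms, prob$total_norm)
  en_drop <- covariation_energy(smp$indices[-length(smp$indices)],
                                prob$local_norms, prob$total_norm)
  expect_gte(en_full, 0.95)
  expect_lt(en_drop, 0.95)
  expect_equal(attr(smp, "energy"), en_full, tolerance = 1e-12)
})

test_that("fixed seeds fix every sampled index sequence", {
  sim <- synthetic_movie(two_glom_spec(dims = c(16, 16)))
  mv <- center_movie(sim$movie)
  for (builder in list(norm_probabilities, covariation_probabilities)) {
    p <- builder(mv)
    for (repl in c(TRUE, FALSE)) {
      a <- suppressWarnings(sample_pixels(mv, 20, p, replace = repl,
                                          seed = 123))
      b <- suppressWarnings(sample_pixels(mv, 20, p, replace = repl,
                                          seed = 123))
      expect_identical(a$indices, b$indices)
    }
  }
})
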