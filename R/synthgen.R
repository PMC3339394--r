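#' Specification of a synthetic glomerular movie
#'
#' Describes a synthetic calcium-imaging movie of the kind recorded from
#' the insect antennal lobe: a concatenation of measurements, each with an
#' odor presentation in the middle, glomeruli as Gaussian intensity blobs
#' whose pixels share one odor-response timecourse, a bleaching trend that
#' restarts at every measurement and is shared by all pixels, and
#' independent additive Gaussian noise. Differential response amplitudes
#' across measurements (different odors) make glomeruli separable.
#'
#' Defaults mimic a desk-scale two-photon recording: a 64 x 64 frame, 6
#' measurements of 40 frames, three glomeruli of radius ~ min(dims)/13
#' with distinct per-odor amplitude patterns, two 1 s odor pulses per
#' measurement, peak response amplitude ~2 fluorescence units with an
#' undershoot below baseline, bleach amplitude 0.3 and noise sd 0.1.
#'
#' @param dims grid dims `c(width, height[, depth])`.
#' @param n_measurements number of concatenated measurements.
#' @param frames_per_measurement frames in each measurement.
#' @param glomeruli list of glomeruli, each a list with `centre` (grid
#'   coordinates), `radius` (pixels, >= 1) and `amplitudes` (response
#'   amplitude per measurement, >= 0). `NULL` places three default
#'   glomeruli scaled to the grid.
#' @param response transient shape: list with `onsets` (pulse onset frames
#'   within a measurement), `tau_rise`, `tau_decay` (frames) and
#'   `undershoot` (fraction of the peak the decay settles below baseline).
#' @param bleach list with `amplitude` and `tau` (frames) of the
#'   per-measurement exponential trend; amplitude 0 disables it.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed; fixes the movie bitwise.
#' @return An object of class `synthetic_movie_spec`.
#' @seealso [synthetic_movie()], [response_timecourse()]
#' @export
synthetic_movie_spec <- function(dims = c(64, 64), n_measurements = 6,
                                 frames_per_measurement = 40,
                                 glomeruli = NULL, response = NULL,
                                 bleach = list(amplitude = 0.3,
                                               tau = 0.75 * frames_per_measurement),
                                 noise_sd = 0.1, seed = 1L) {
  grid <- pixel_grid(dims)
  if (n_measurements < 1 || frames_per_measurement < 2)
    stop("need at least 1 measurement of at least 2 frames")
  if (is.null(response))
    response <- list(onsets = round(frames_per_measurement * c(0.375, 0.575)),
                     tau_rise = 1.5, tau_decay = 6, undershoot = 0.2)
  if (is.null(glomeruli)) {
    radius <- max(2, round(min(grid$dims[1:2]) / 13))
    frac <- list(c(0.25, 0.25), c(0.70, 0.30), c(0.45, 0.75))
    amps <- list(c(2.0, 0.4, 1.6, 0.2, 1.2, 0.6),
                 c(0.3, 1.8, 0.5, 1.5, 0.2, 1.0),
                 c(1.0, 1.0, 0.2, 1.8, 1.6, 0.4))
    glomeruli <- lapply(1:3, function(g) {
      ctr <- round(frac[[g]] * grid$dims[1:2])
      if (grid$ndim == 3L) ctr <- c(ctr, ceiling(grid$dims[3] / 2))
      list(centre = ctr, radius = radius,
           amplitudes = rep_len(amps[[g]], n_measurements))
    })
  }
  rise_len <- ceiling(3 * response$tau_rise)
  if (max(response$onsets) + rise_len > frames_per_measurement)
    stop("measurement too short for the response onset + rise")
  for (g in glomeruli) {
    if (g$radius < 1) stop("glomerulus radius must be >= 1")
    if (length(g$centre) != grid$ndim) stop("glomerulus centre/grid mismatch")
    if (any(g$centre - g$radius < 1) ||
        any(g$centre + g$radius > grid$dims))
      stop("glomerulus support extends beyond the grid")
    if (length(g$amplitudes) != n_measurements || any(g$amplitudes < 0))
      stop("need one nonnegative amplitude per measurement")
  }
  if (noise_sd < 0 || bleach$amplitude < 0) stop("negative scale parameter")
  structure(list(grid = grid, n_measurements = n_measurements,
                 frames_per_measurement = frames_per_measurement,
                 glomeruli = glomeruli, response = response,
                 bleach = bleach, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_movie_spec")
}

#' @export
print.synthetic_movie_spec <- function(x, ...) {
  cat(sprintf("synthetic_movie_spec: %s grid, %d x %d frames, %d glomeruli, noise sd %g, bleach %g\n",
              paste(x$grid$dims, collapse = "x"), x$n_measurements,
              x$frames_per_measurement, length(x$glomeruli), x$noise_sd,
              x$bleach$amplitude))
  invisible(x)
}

#' Odor-response transient
#'
#' The canonical calcium transient used by the generator: baseline 0, a
#' sharp saturating-exponential rise at each pulse onset (peaking at the
#' end of the rise, `ceiling(3 * tau_rise)` frames), then an exponential
#' decay that settles `undershoot * amplitude` *below* baseline. Multiple
#' pulses superpose, giving e.g. the double response to a double odor
#' presentation.
#'
#' @param n_frames length of the returned vector.
#' @param onsets pulse onset frames (1-based).
#' @param amplitude peak amplitude; 0 gives a flat zero vector.
#' @param tau_rise,tau_decay rise/decay time constants in frames.
#' @param undershoot fraction of the peak reached below baseline.
#' @return Numeric vector of length `n_frames`.
#' @export
response_timecourse <- function(n_frames, onsets = c(15, 23), amplitude = 1,
                                tau_rise = 1.5, tau_decay = 6,
                                undershoot = 0.2) {
  if (n_frames < 1) stop("n_frames must be positive")
  v <- numeric(n_frames)
  if (amplitude == 0) return(v)
  rise_len <- ceiling(3 * tau_rise)
  for (o in onsets) {
    s <- seq_len(n_frames) - o  # frames since onset
    pulse <- numeric(n_frames)
    rising <- s >= 0 & s < rise_len
    pulse[rising] <- amplitude * (1 - exp(-(s[rising] + 1) / tau_rise)) /
      (1 - exp(-rise_len / tau_rise))
    decaying <- s >= rise_len
    pulse[decaying] <- amplitude * (1 + undershoot) *
      exp(-(s[decaying] - rise_len + 1) / tau_decay) -
      amplitude * undershoot
    v <- v + pulse
  }
  v
}

# Gaussian blob weights (sd = radius/2, truncated at radius) around a
# centre; returns pixel indices and weights.
glomerulus_blob <- function(grid, centre, radius) {
  co <- grid_coords(grid, seq_len(grid$n))
  d2 <- rowSums(sweep(co, 2, as.numeric(centre), `-`)^2)
  idx <- which(d2 <= radius^2)
  list(indices = idx, weights = exp(-d2[idx] / (2 * (radius / 2)^2)))
}

#' Generate a synthetic glomerular movie with ground truth
#'
#' Builds the movie described by a [synthetic_movie_spec()]:
#' `A = sum_g blob_g x timecourse_g + trend + noise`, where each
#' glomerulus's timecourse is the response transient scaled by its
#' per-measurement amplitude, the bleach trend is an exponential decay
#' shared by all pixels and restarting each measurement, and the noise is
#' independent Gaussian per pixel and frame. Deterministic given the
#' spec's seed.
#'
#' @param spec a [synthetic_movie_spec()].
#' @return List with `movie` (a raw [movie_matrix()]) and `truth`, a list
#'   carrying per-glomerulus pixel `masks` and blob `weights`, the clean
#'   `timecourses` (m x g matrix), the bleach `trend` (length m), and
#'   `overlapping` (`TRUE` if any two glomerulus supports share pixels).
#' @export
synthetic_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_movie_spec"))
  grid <- spec$grid
  fpm <- spec$frames_per_measurement
  m <- spec$n_measurements * fpm
  n <- grid$n
  g <- length(spec$glomeruli)

  template <- response_timecourse(fpm, onsets = spec$response$onsets,
                                  amplitude = 1,
                                  tau_rise = spec$response$tau_rise,
                                  tau_decay = spec$response$tau_decay,
                                  undershoot = spec$response$undershoot)
  timecourses <- matrix(0, m, max(g, 1))
  A <- matrix(0, m, n)
  masks <- list(); weights <- list()
  for (i in seq_len(g)) {
    gl <- spec$glomeruli[[i]]
    blob <- glomerulus_blob(grid, gl$centre, gl$radius)
    masks[[i]] <- blob$indices
    weights[[i]] <- blob$weights
    tc <- as.vector(outer(template, gl$amplitudes))  # concatenated measurements
    timecourses[, i] <- tc
    A[, blob$indices] <- A[, blob$indices] + tc %o% blob$weights
  }
  trend <- rep(spec$bleach$amplitude *
                 exp(-(seq_len(fpm) - 1) / spec$bleach$tau),
               spec$n_measurements)
  A <- A + trend
  if (spec$noise_sd > 0)
    A <- A + with_seed(spec$seed,
                       matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n))
  overlapping <- FALSE
  if (g > 1)
    for (i in seq_len(g - 1))
      for (j in (i + 1):g)
        if (length(intersect(masks[[i]], masks[[j]]))) overlapping <- TRUE
  if (overlapping) warning("glomerulus supports overlap")

  list(movie = movie_matrix(A, grid, centered = FALSE),
       truth = list(masks = masks, weights = weights,
                    timecourses = timecourses[, seq_len(g), drop = FALSE],
                    trend = trend, overlapping = overlapping))
}

# Union of a pixel set and its Moore neighbours (mask dilation by 1).
dilate_pixels <- function(grid, idx) {
  sort(unique(c(idx, unlist(lapply(idx, function(j) neighbours(grid, j))))))
}
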