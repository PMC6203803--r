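#' Kymograph container
#'
#' Peripheral fluorescence intensities over angular position and time, one
#' matrix per channel, in cytoplasm-normalized (dimensionless) units.
#'
#' @param angles angular positions in degrees, uniform over [0, 360).
#' @param times frame times (s), uniform.
#' @param channels named list of `length(angles) x length(times)` matrices.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(angles, times, channels) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  for (ch in channels)
    if (!all(dim(ch) == c(length(angles), length(times))))
      stop("each channel must be a length(angles) x length(times) matrix")
  if (length(angles) > 1 && stats::sd(diff(angles)) > 1e-9)
    stop("angle grid must be uniform")
  structure(list(angles = angles, times = times, channels = channels),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d angles x %d frames, channels: %s\n",
              length(x$angles), length(x$times),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# circular distance in degrees, in [0, 180]
circ_dist_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# half-width (FWHM / 2) of an angular profile: baseline = minimum, half
# level midway to the maximum, circular linear interpolation between grid
# samples on both flanks of the peak.
profile_half_width <- function(angles, profile) {
  n <- length(profile)
  rng <- max(profile) - min(profile)
  if (rng <= 1e-12 * max(abs(profile), 1)) stop("no peak: flat profile")
  half <- min(profile) + rng / 2
  i_pk <- which.max(profile)
  step <- 360 / n
  cross <- function(dir) {
    # walk from the peak in direction dir until profile drops below half
    for (k in seq_len(n - 1L)) {
      i_prev <- ((i_pk - 1L + dir * (k - 1L)) %% n) + 1L
      i_cur <- ((i_pk - 1L + dir * k) %% n) + 1L
      if (profile[i_cur] < half) {
        frac <- (profile[i_prev] - half) / (profile[i_prev] - profile[i_cur])
        return((k - 1L + frac) * step)
      }
    }
    180   # never crosses: half width capped at half the circle
  }
  (cross(1L) + cross(-1L)) / 2
}

# wrapped-Gaussian angular bump, unit peak height
wave_bump <- function(angles, center, s) {
  exp(-circ_dist_deg(angles, center)^2 / (2 * s^2))
}

#' Simulate a traveling-wave peripheral kymograph
#'
#' Generates a two-channel kymograph emulating antiphase traveling waves of
#' a lipid marker and its antagonist along the cell periphery: channel
#' `pip3` is a wrapped-Gaussian angular bump rotating with the given
#' temporal period, channel `pten` is its antiphase complement (so that the
#' noiseless sum of the two spatial patterns is constant), plus additive
#' Gaussian noise clipped at zero intensity. The bump-shape parameter is
#' calibrated by root finding so that the generated profile's half-width
#' (half of the full width at half maximum, baseline at the profile
#' minimum) equals `half_width` on the simulated angle grid.
#'
#' @param period temporal rotation period (s); must exceed two frame
#'   intervals.
#' @param half_width angular half-width (degrees), in (0, 180).
#' @param n_angles number of angular samples (>= 8), default 72 (5 deg).
#' @param n_frames number of frames, default 360 (30 min at 5 s).
#' @param frame_interval frame time step (s), default 5.
#' @param noise_sd additive Gaussian noise sd (normalized intensity units).
#' @param baseline numeric length 2, baseline intensity of the two
#'   channels; default c(0.5, 0.5).
#' @param amplitude bump amplitude (normalized units), default 1.
#' @param seed integer seed.
#' @return A [kymograph] with channels `pip3` and `pten`.
#' @export
simulate_wave_kymograph <- function(period, half_width, n_angles = 72L,
                                    n_frames = 360L, frame_interval = 5,
                                    noise_sd = 0, baseline = c(0.5, 0.5),
                                    amplitude = 1, seed = 1L) {
  if (period <= 2 * frame_interval)
    stop("period must exceed two frame intervals")
  if (half_width <= 0 || half_width >= 180)
    stop("half_width must be in (0, 180) degrees")
  if (n_angles < 8) stop("n_angles must be >= 8")
  set.seed(seed)
  angles <- seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)]
  # calibrate the wrapped-Gaussian scale so the grid profile's measured
  # half-width equals the requested one
  target <- function(s) profile_half_width(angles, wave_bump(angles, 0, s)) - half_width
  s_cal <- stats::uniroot(target, lower = 360 / n_angles / 4, upper = 400,
                          tol = 1e-6)$root
  times <- (seq_len(n_frames) - 1L) * frame_interval
  centers <- (360 * times / period) %% 360
  ch1 <- vapply(centers, function(c0)
    baseline[1] + amplitude * wave_bump(angles, c0, s_cal), numeric(n_angles))
  ch2 <- vapply(centers, function(c0)
    baseline[2] + amplitude * (1 - wave_bump(angles, c0, s_cal)),
    numeric(n_angles))
  if (noise_sd > 0) {
    ch1 <- ch1 + matrix(stats::rnorm(length(ch1), 0, noise_sd), nrow = n_angles)
    ch2 <- ch2 + matrix(stats::rnorm(length(ch2), 0, noise_sd), nrow = n_angles)
  }
  ch1[ch1 < 0] <- 0; ch2[ch2 < 0] <- 0
  kymograph(angles, times, list(pip3 = ch1, pten = ch2))
}

#' Intensity scatter container
#'
#' Per-position pairs of cytoplasm-normalized peripheral intensities, e.g.
#' ([PTEN], [PIP3]) measured in small ROIs along the cell periphery.
#'
#' @param x,y normalized intensities of the two channels (>= 0).
#' @param labels channel names, default c("ch1", "ch2").
#' @param condition_label free-text condition label.
#' @param n_cells number of cells contributing points.
#' @return An object of class `intensity_scatter`.
#' @export
intensity_scatter <- function(x, y, labels = c("ch1", "ch2"),
                              condition_label = "", n_cells = 1L) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("normalized intensities must be >= 0")
  structure(list(x = as.numeric(x), y = as.numeric(y), labels = labels,
                 condition_label = condition_label,
                 n_cells = as.integer(n_cells)),
            class = "intensity_scatter")
}

#' Simulate a two-channel intensity scatter from a Gaussian mixture
#'
#' Samples per-position intensity pairs from an isotropic 2D Gaussian
#' mixture truncated to the non-negative quadrant (rejection sampling),
#' emulating the bimodal scatter of antagonistic membrane markers.
#'
#' @param components list of components, each
#'   `list(mean = c(x, y), sd = s, weight = w)`; weights must sum to 1.
#' @param n number of points.
#' @param seed integer seed.
#' @inheritParams intensity_scatter
#' @return An [intensity_scatter].
#' @export
simulate_intensity_scatter <- function(components, n, seed = 1L,
                                       labels = c("ch1", "ch2"),
                                       condition_label = "", n_cells = 1L) {
  if (length(components) == 0) stop("empty component list")
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1")
  set.seed(seed)
  if (n == 0)
    return(intensity_scatter(numeric(0), numeric(0), labels,
                             condition_label, n_cells))
  xs <- numeric(n); ys <- numeric(n)
  comp <- sample.int(length(components), n, replace = TRUE, prob = w)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    for (j in unique(comp[todo])) {
      idx <- todo[comp[todo] == j]
      m <- components[[j]]$mean; s <- components[[j]]$sd
      xs[idx] <- stats::rnorm(length(idx), m[1], s)
      ys[idx] <- stats::rnorm(length(idx), m[2], s)
    }
    todo <- todo[xs[todo] < 0 | ys[todo] < 0]
  }
  intensity_scatter(xs, ys, labels, condition_label, n_cells)
}

#' Migration track container
#'
#' Cell centroid positions at a uniform 5-second sampling interval, with an
#' optional chemoattractant source position.
#'
#' @param positions two-column matrix or data.frame of x, y (um).
#' @param dt sampling interval (s), default 5.
#' @param source_position optional c(x, y) (um) of the attractant source.
#' @return An object of class `migration_track`.
#' @export
migration_track <- function(positions, dt = 5, source_position = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("positions must have two columns (x, y)")
  structure(list(positions = positions, dt = dt,
                 source_position = source_position),
            class = "migration_track")
}

#' Simulate a biased random-walk migration track
#'
#' Fixed-step-length random walk sampled every 5 s: each step has length
#' `speed / 12` um and a direction drawn from a wrapped-Cauchy circular
#' distribution centered on the direction toward the source, with mean
#' resultant length equal to `bias` (bias 0 gives a uniform direction,
#' bias 1 a step exactly toward the source).
#'
#' @param speed migration speed (um/min): the fixed step length is
#'   speed / 12 um per 5-s step.
#' @param bias chemotactic bias in [0, 1].
#' @param n_steps number of 5-s steps (361 positions for 30 min = 360).
#' @param source_position c(x, y) of the attractant source (um).
#' @param start starting position, default the origin.
#' @param seed integer seed.
#' @return A [migration_track].
#' @export
simulate_migration_track <- function(speed, bias, n_steps = 360L,
                                     source_position = c(0, 1000),
                                     start = c(0, 0), seed = 1L) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (bias < 0 || bias > 1) stop("bias must be in [0, 1]")
  set.seed(seed)
  step_len <- speed / 12
  pos <- matrix(0, n_steps + 1L, 2)
  pos[1, ] <- start
  u <- stats::runif(n_steps)
  for (i in seq_len(n_steps)) {
    to_src <- source_position - pos[i, ]
    theta0 <- atan2(to_src[2], to_src[1])
    if (bias >= 1) {
      theta <- theta0
    } else {
      # wrapped-Cauchy inverse CDF with mean resultant length = bias
      theta <- theta0 +
        2 * atan((1 - bias) / (1 + bias) * tan(pi * (u[i] - 0.5)))
    }
    pos[i + 1L, ] <- pos[i, ] + step_len * c(cos(theta), sin(theta))
  }
  migration_track(pos, dt = 5, source_position = source_position)
}
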