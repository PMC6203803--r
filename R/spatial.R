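#' Normalize peripheral intensities to the cytoplasm mean
#'
#' Divides each raw peripheral channel by the mean fluorescence intensity
#' measured in the cytoplasm, yielding the dimensionless intensities used
#' throughout the polarity analysis. Raw means are retained as metadata.
#'
#' @param raw_periphery named list of raw intensity matrices
#'   (angle x time), or a [kymograph] whose channels are raw.
#' @param cytoplasm_mean named numeric of per-channel cytoplasm means
#'   (all > 0), names matching the channels.
#' @param angles,times grids for matrix input (ignored for kymograph
#'   input).
#' @return A [kymograph] with normalized channels and attribute
#'   `raw_means`.
#' @export
normalize_to_cytoplasm <- function(raw_periphery, cytoplasm_mean,
                                   angles = NULL, times = NULL) {
  if (inherits(raw_periphery, "kymograph")) {
    channels <- raw_periphery$channels
    angles <- raw_periphery$angles
    times <- raw_periphery$times
  } else {
    channels <- raw_periphery
  }
  if (is.null(names(cytoplasm_mean)))
    names(cytoplasm_mean) <- names(channels)
  for (nm in names(channels)) {
    cm <- cytoplasm_mean[[nm]]
    if (is.null(cm) || !is.finite(cm) || cm <= 0)
      stop("cytoplasm mean for channel '", nm, "' must be positive")
    channels[[nm]] <- channels[[nm]] / cm
  }
  out <- kymograph(angles, times, channels)
  attr(out, "raw_means") <- cytoplasm_mean
  out
}

#' Oscillation period by temporal autocorrelation
#'
#' For each angular position, computes the mean-subtracted autocorrelation
#' of the intensity time series and takes the lag of the first local
#' maximum (at positive lag) whose value exceeds `prominence`; positions
#' with no qualifying peak are excluded. The per-position periods are
#' summarized by their mean and SD.
#'
#' @param kym a [kymograph].
#' @param channel channel name.
#' @param prominence minimum autocorrelation value (relative to the
#'   zero-lag value of 1) a peak must reach; default 0.1.
#' @param max_lag maximum lag in frames; default half the record.
#' @return list with `periods` (s, NA where aperiodic), `mean`, `sd`,
#'   `n_positions`, and `aperiodic` (TRUE when no position qualifies).
#' @export
autocorrelation_period <- function(kym, channel, prominence = 0.1,
                                   max_lag = NULL) {
  stopifnot(inherits(kym, "kymograph"))
  m <- kym$channels[[channel]]
  if (is.null(m)) stop("no channel '", channel, "'")
  nt <- ncol(m)
  dt <- if (nt > 1) diff(kym$times[1:2]) else stop("need >= 2 frames")
  if (is.null(max_lag)) max_lag <- floor(nt / 2)
  periods <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (stats::sd(x) == 0) next
    r <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    # r[1] is lag 0; local maxima over lags 1..max_lag-1
    for (k in 2:(length(r) - 1L)) {
      if (r[k] > r[k - 1L] && r[k] >= r[k + 1L] && r[k] >= prominence) {
        periods[i] <- (k - 1L) * dt
        break
      }
    }
  }
  ok <- !is.na(periods)
  list(periods = periods,
       mean = if (any(ok)) mean(periods[ok]) else NA_real_,
       sd = if (sum(ok) > 1) stats::sd(periods[ok]) else NA_real_,
       n_positions = sum(ok),
       aperiodic = !any(ok))
}

#' Aligned angular profile half-width
#'
#' Rotates each frame's angular profile so that the maximum of the
#' alignment channel sits at angle 0, averages the measurement channel's
#' aligned profiles over frames, and returns half of the full width at half
#' maximum of the mean profile (baseline at the profile minimum, circular
#' linear interpolation between angular samples).
#'
#' @param kym a [kymograph].
#' @param align_channel channel whose per-frame maximum defines angle 0.
#' @param measure_channel channel whose aligned mean profile is measured.
#' @return Half-width in degrees, with attribute `profile` (the aligned
#'   mean profile) and `angles`.
#' @export
aligned_profile_half_width <- function(kym, align_channel,
                                       measure_channel = align_channel) {
  stopifnot(inherits(kym, "kymograph"))
  a <- kym$channels[[align_channel]]
  m <- kym$channels[[measure_channel]]
  if (is.null(a) || is.null(m)) stop("unknown channel")
  n <- nrow(m)
  prof <- numeric(n)
  for (j in seq_len(ncol(m))) {
    shift <- which.max(a[, j]) - 1L
    idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
    prof <- prof + m[idx, j]
  }
  prof <- prof / ncol(m)
  hw <- profile_half_width(kym$angles, prof)
  attr(hw, "profile") <- prof
  attr(hw, "angles") <- kym$angles
  hw
}

#' Normalized 2D density map of an intensity scatter
#'
#' Two-dimensional histogram of the intensity pairs, normalized so that the
#' density integrates to 1 over the histogram range; points outside the
#' range are counted and reported, not binned.
#'
#' @param scatter an [intensity_scatter].
#' @param bins number of bins per axis (default 50).
#' @param range list with `x = c(lo, hi)`, `y = c(lo, hi)`; default spans
#'   the data.
#' @return An object of class `density_map2d`: `density` (x-bin by y-bin
#'   matrix, per intensity^2), `x_breaks`, `y_breaks`, `n_in`, `n_out`.
#' @export
density_map <- function(scatter, bins = 50L, range = NULL) {
  stopifnot(inherits(scatter, "intensity_scatter"))
  if (length(scatter$x) == 0) stop("empty scatter")
  if (is.null(range))
    range <- list(x = base::range(scatter$x), y = base::range(scatter$y))
  xb <- seq(range$x[1], range$x[2], length.out = bins + 1L)
  yb <- seq(range$y[1], range$y[2], length.out = bins + 1L)
  inside <- scatter$x >= xb[1] & scatter$x <= xb[length(xb)] &
    scatter$y >= yb[1] & scatter$y <= yb[length(yb)]
  xi <- pmin(pmax(findInterval(scatter$x[inside], xb, rightmost.closed = TRUE), 1L), bins)
  yi <- pmin(pmax(findInterval(scatter$y[inside], yb, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(xi, levels = seq_len(bins)),
               factor(yi, levels = seq_len(bins)))
  counts[] <- as.numeric(tab)
  area <- diff(xb)[1] * diff(yb)[1]
  n_in <- sum(inside)
  structure(
    list(density = counts / (n_in * area), x_breaks = xb, y_breaks = yb,
         n_in = n_in, n_out = sum(!inside)),
    class = "density_map2d")
}

#' Fit one or two 2D Gaussian components to an intensity scatter
#'
#' Maximum-likelihood Gaussian mixture fit (isotropic components by
#' default, full covariance optionally) to the intensity pairs, reporting
#' components in decreasing weight. With two requested components, a
#' degeneracy flag is raised when the fitted means are closer than the sum
#' of the component spreads (unimodal data).
#'
#' @param scatter an [intensity_scatter].
#' @param k number of components, 1 or 2.
#' @param covariance "isotropic" (default) or "full".
#' @return list of class `gaussian2d_fit` with `components` (each
#'   `list(mean, sd, cov, weight)`, decreasing weight), `k`, `overlap`
#'   (degeneracy flag), `logLik`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_two_gaussians <- function(scatter, k = 2L, covariance = "isotropic") {
  stopifnot(inherits(scatter, "intensity_scatter"), k %in% c(1L, 2L))
  n <- length(scatter$x)
  if (n < 50 * k)
    stop("need at least ", 50 * k, " points for k = ", k, " components")
  model <- if (covariance == "isotropic") "VII" else "VVV"
  dat <- cbind(x = scatter$x, y = scatter$y)
  fit <- Mclust(dat, G = k, modelNames = model, verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed")
  pars <- fit$parameters
  comps <- lapply(seq_len(k), function(j) {
    cv <- pars$variance$sigma[, , j]
    list(mean = unname(pars$mean[, j]),
         sd = sqrt(mean(diag(cv))),
         cov = unname(cv),
         weight = pars$pro[j])
  })
  comps <- comps[order(-vapply(comps, `[[`, numeric(1), "weight"))]
  overlap <- FALSE
  if (k == 2L) {
    d <- sqrt(sum((comps[[1]]$mean - comps[[2]]$mean)^2))
    overlap <- d < comps[[1]]$sd + comps[[2]]$sd
  }
  structure(list(components = comps, k = k, covariance = covariance,
                 overlap = overlap, logLik = fit$loglik),
            class = "gaussian2d_fit")
}

#' Bistability boundary between two intensity distributions
#'
#' Computes the equal-density locus of two fitted isotropic Gaussian
#' components (the density modes of the low- and high-PIP3 conditions) and
#' approximates it, inside the region between the two means, by the
#' through-origin line `y = a x` minimizing the squared vertical deviation
#' from the locus; `a` is the bistability boundary constant. When the two
#' means differ almost only along the y axis (axis-dominance ratio above
#' `horizontal_ratio`), the boundary is reported as the horizontal line
#' `y = level` instead. A locus whose deviation from linearity exceeds
#' `curvature_tol` (residual sd relative to the locus span) is flagged
#' nonlinear.
#'
#' @param fit_a,fit_b fitted components: each either a `gaussian2d_fit`
#'   (its heaviest component is used) or a `list(mean, sd, weight)`.
#' @param n_locus number of locus sample points (default 201).
#' @param horizontal_ratio |dy|/|dx| threshold above which the boundary is
#'   constrained horizontal; default 5.
#' @param curvature_tol relative nonlinearity tolerance; default 0.02.
#' @return An object of class `boundary_fit`: `slope`, `orientation`
#'   ("oblique" or "horizontal"), `level` (horizontal case), `nonlinear`,
#'   `component_means`, `component_sds`, `method_record`.
#' @export
boundary_slope <- function(fit_a, fit_b, n_locus = 201L,
                           horizontal_ratio = 5, curvature_tol = 0.02) {
  get_comp <- function(f)
    if (inherits(f, "gaussian2d_fit")) f$components[[1]] else f
  c1 <- get_comp(fit_a); c2 <- get_comp(fit_b)
  w1 <- if (is.null(c1$weight)) 1 else c1$weight
  w2 <- if (is.null(c2$weight)) 1 else c2$weight
  m1 <- c1$mean; m2 <- c2$mean; s1 <- c1$sd; s2 <- c2$sd
  dvec <- m2 - m1
  if (sqrt(sum(dvec^2)) < 1e-9) stop("component means coincide")

  # log-density difference of the two weighted isotropic Gaussians
  ldiff <- function(x, y) {
    (log(w1) - log(s1^2) - ((x - m1[1])^2 + (y - m1[2])^2) / (2 * s1^2)) -
      (log(w2) - log(s2^2) - ((x - m2[1])^2 + (y - m2[2])^2) / (2 * s2^2))
  }
  mid <- (m1 + m2) / 2
  span <- sqrt(sum(dvec^2)) + 2 * (s1 + s2)
  # sample the locus along the direction perpendicular to the mean-mean axis
  perp <- c(-dvec[2], dvec[1]) / sqrt(sum(dvec^2))
  axis <- dvec / sqrt(sum(dvec^2))
  ts <- seq(-span / 2, span / 2, length.out = n_locus)
  locus <- matrix(NA_real_, n_locus, 2)
  for (i in seq_len(n_locus)) {
    base_pt <- mid + ts[i] * perp
    g <- function(u) {
      p <- base_pt + u * axis
      ldiff(p[1], p[2])
    }
    lo <- -span; hi <- span
    if (sign(g(lo)) == sign(g(hi))) next
    u0 <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-9)$root
    locus[i, ] <- mid + ts[i] * perp + u0 * axis
  }
  locus <- locus[stats::complete.cases(locus), , drop = FALSE]
  # keep the part of the locus inside the region the data occupy
  keep <- locus[, 1] >= min(m1[1], m2[1]) - (s1 + s2) &
    locus[, 1] <= max(m1[1], m2[1]) + (s1 + s2) &
    locus[, 2] >= min(m1[2], m2[2]) - (s1 + s2) &
    locus[, 2] <= max(m1[2], m2[2]) + (s1 + s2) &
    locus[, 1] >= 0 & locus[, 2] >= 0
  locus <- locus[keep, , drop = FALSE]
  if (nrow(locus) < 5) stop("equal-density locus not found in data range")

  # nonlinearity: residual sd of an affine fit, relative to the locus span
  lf <- stats::lm(locus[, 2] ~ locus[, 1])
  rel_dev <- stats::sd(stats::residuals(lf)) /
    max(diff(range(locus[, 1])), diff(range(locus[, 2])))
  nonlinear <- is.finite(rel_dev) && rel_dev > curvature_tol

  horizontal <- abs(dvec[2]) / max(abs(dvec[1]), 1e-12) > horizontal_ratio
  if (horizontal) {
    out <- list(slope = NA_real_, orientation = "horizontal",
                level = mean(locus[, 2]))
  } else {
    slope <- sum(locus[, 1] * locus[, 2]) / sum(locus[, 1]^2)
    if (slope <= 0) stop("boundary slope not positive")
    out <- list(slope = slope, orientation = "oblique", level = NA_real_)
  }
  out$nonlinear <- nonlinear
  out$component_means <- list(m1, m2)
  out$component_sds <- c(s1, s2)
  out$locus <- locus
  out$method_record <- paste0(
    "equal-density locus of weighted isotropic Gaussians, through-origin ",
    "least-squares line; horizontal if |dy|/|dx| > ", horizontal_ratio,
    "; nonlinear if relative locus deviation > ", curvature_tol)
  structure(out, class = "boundary_fit")
}

#' @export
print.boundary_fit <- function(x, ...) {
  if (x$orientation == "oblique")
    cat(sprintf("<boundary_fit> y = %.4g x (oblique)%s\n", x$slope,
                if (x$nonlinear) " [nonlinear locus]" else ""))
  else
    cat(sprintf("<boundary_fit> y = %.4g (horizontal)%s\n", x$level,
                if (x$nonlinear) " [nonlinear locus]" else ""))
  invisible(x)
}

#' Co-localization probability over an intensity rectangle
#'
#' Integral of the normalized 2D density over a rectangle of the intensity
#' plane, with bins partially covered by the rectangle weighted by their
#' overlap fraction.
#'
#' @param map a [density_map()] result.
#' @param x_range,y_range c(lo, hi) integration limits, inside the
#'   histogram range.
#' @return Probability in [0, 1].
#' @export
coloc_probability <- function(map, x_range, y_range) {
  stopifnot(inherits(map, "density_map2d"))
  for (r in list(x_range, y_range))
    if (length(r) != 2 || r[1] >= r[2]) stop("inverted or malformed range")
  xb <- map$x_breaks; yb <- map$y_breaks
  if (x_range[1] < xb[1] - 1e-9 || x_range[2] > xb[length(xb)] + 1e-9 ||
      y_range[1] < yb[1] - 1e-9 || y_range[2] > yb[length(yb)] + 1e-9)
    stop("integration range outside histogram range")
  overlap_frac <- function(breaks, r) {
    lo <- breaks[-length(breaks)]; hi <- breaks[-1]
    pmax(pmin(hi, r[2]) - pmax(lo, r[1]), 0) / (hi - lo)
  }
  wx <- overlap_frac(xb, x_range)
  wy <- overlap_frac(yb, y_range)
  area <- diff(xb)[1] * diff(yb)[1]
  sum((wx %o% wy) * map$density) * area
}

#' Instantaneous migration velocity statistics
#'
#' Converts 5-second cell displacements to instantaneous velocities
#' (multiplying by 12 to express um/min) and summarizes them by the
#' five-number summary and mean shown in migration box plots.
#'
#' @param track a [migration_track].
#' @return list with `velocities` (um/min per step), `summary` (min, q1,
#'   median, q3, max), `mean`.
#' @export
instantaneous_velocity_stats <- function(track) {
  stopifnot(inherits(track, "migration_track"))
  p <- track$positions
  if (nrow(p) < 2) stop("need at least 2 positions")
  steps <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  v <- steps * 12    # um per 5 s -> um/min
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(velocities = v,
       summary = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]),
       mean = mean(v))
}

#' Chemotactic index of a migration track
#'
#' Translates the track so that the starting position is at the origin and
#' rotates it so that the attractant source lies on the positive y axis;
#' the chemotactic index is the mean y component of the 5-s displacements
#' divided by the mean 2D displacement length, in [-1, 1].
#'
#' @param track a [migration_track] with a `source_position`.
#' @return Chemotactic index (dimensionless).
#' @export
chemotactic_index <- function(track) {
  stopifnot(inherits(track, "migration_track"))
  if (is.null(track$source_position))
    stop("chemotactic index needs a source position")
  p <- sweep(track$positions, 2, track$positions[1, ])
  src <- track$source_position - track$positions[1, ]
  phi <- atan2(src[2], src[1])
  rot <- pi / 2 - phi    # source onto +y axis
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  pr <- p %*% t(R)
  dx <- diff(pr[, 1]); dy <- diff(pr[, 2])
  denom <- mean(sqrt(dx^2 + dy^2))
  if (denom == 0) stop("immotile track: zero total displacement")
  mean(dy) / denom
}
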