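test_that("cytoplasm normalization divides channels and validates means", {
  raw <- list(pip3 = matrix(200, 8, 4), pten = matrix(150, 8, 4))
  kym <- normalize_to_cytoplasm(raw, c(pip3 = 100, pten = 75),
                                angles = seq(0, 315, by = 45), times = 0:3 * 5)
  expect_true(all(kym$channels$pip3 == 2))
  expect_true(all(kym$channels$pten == 2))
  expect_error(normalize_to_cytoplasm(raw, c(pip3 = 0, pten = 75),
                                      angles = seq(0, 315, by = 45),
                                      times = 0:3 * 5), "positive")
})

test_that("autocorrelation recovers the oscillation period of a clean wave", {
  kym <- simulate_wave_kymograph(period = 95, half_width = 62, noise_sd = 0,
                                 seed = 2)
  per <- autocorrelation_period(kym, "pip3")
  expect_false(per$aperiodic)
  expect_lte(abs(per$mean - 95), 5)   # within one 5-s frame
  # a pure sine series behaves identically
  tt <- 0:359 * 5
  m <- matrix(rep(sin(2 * pi * tt / 95), each = 8), nrow = 8, byrow = FALSE)
  kym2 <- kymograph(seq(0, 315, by = 45), tt, list(s = m))
  expect_lte(abs(autocorrelation_period(kym2, "s")$mean - 95), 5)
})

test_that("constant signals yield an aperiodic result, not an error", {
  kym <- kymograph(seq(0, 315, by = 45), 0:99 * 5,
                   list(flat = matrix(1, 8, 100)))
  res <- autocorrelation_period(kym, "flat")
  expect_true(res$aperiodic)
  expect_true(is.na(res$mean))
})

test_that("noisy traveling waves give periods within 10% over many seeds", {
  errs <- vapply(1:20, function(s) {
    kym <- simulate_wave_kymograph(period = 95, half_width = 62,
                                   noise_sd = 0.33, seed = s)
    abs(autocorrelation_period(kym, "pip3")$mean / 95 - 1)
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})

test_that("aligned profile half-width matches analytic and generated widths", {
  # truncated-cosine bump: FWHM/2 is exactly 60 degrees
  angles <- seq(0, 359, by = 1)
  prof <- pmax(0, cos(angles * pi / 180))
  m <- matrix(rep(prof, 5), ncol = 5)
  kym <- kymograph(angles, 0:4 * 5, list(c = m))
  expect_equal(as.numeric(aligned_profile_half_width(kym, "c")), 60,
               tolerance = 0.5)
  # generated widths recovered across the biological range
  set.seed(8)
  for (w in c(62, 104, stats::runif(4, 30, 140))) {
    kym <- simulate_wave_kymograph(period = 95, half_width = w, noise_sd = 0,
                                   seed = 3)
    hw <- as.numeric(aligned_profile_half_width(kym, "pip3"))
    expect_lt(abs(hw / w - 1), 0.05)
  }
  expect_error(aligned_profile_half_width(
    kymograph(angles, 0:4 * 5, list(c = matrix(1, 360, 5))), "c"), "flat")
})

test_that("kymograph statistics are equivariant under angular rotation", {
  kym <- simulate_wave_kymograph(period = 95, half_width = 62, noise_sd = 0.1,
                                 seed = 4)
  rot <- kym
  shift <- 20L
  for (nm in names(rot$channels)) {
    m <- rot$channels[[nm]]
    rot$channels[[nm]] <- m[c((shift + 1):nrow(m), 1:shift), ]
  }
  expect_equal(autocorrelation_period(kym, "pip3")$mean,
               autocorrelation_period(rot, "pip3")$mean, tolerance = 1e-9)
  expect_equal(as.numeric(aligned_profile_half_width(kym, "pip3")),
               as.numeric(aligned_profile_half_width(rot, "pip3")),
               tolerance = 1e-9)
})

test_that("antiphase construction keeps the channel sum constant", {
  kym <- simulate_wave_kymograph(period = 95, half_width = 62, noise_sd = 0,
                                 seed = 1)
  s <- kym$channels$pip3 + kym$channels$pten
  expect_lt(max(s) - min(s), 1e-9)
})

test_that("density maps normalize and agree with analytic bin masses", {
  sc <- intensity_scatter(rep(0.5, 10), rep(0.5, 10))
  dm <- density_map(sc, bins = 4, range = list(x = c(0, 2), y = c(0, 2)))
  area <- diff(dm$x_breaks)[1] * diff(dm$y_breaks)[1]
  expect_equal(max(dm$density), 1 / area)
  expect_equal(sum(dm$density) * area, 1, tolerance = 1e-9)
  # Gaussian sample against analytic bin probabilities
  sc2 <- simulate_intensity_scatter(
    list(list(mean = c(1, 1), sd = 0.2, weight = 1)), n = 20000, seed = 5)
  dm2 <- density_map(sc2, bins = 10, range = list(x = c(0, 2), y = c(0, 2)))
  a2 <- diff(dm2$x_breaks)[1] * diff(dm2$y_breaks)[1]
  px <- diff(stats::pnorm(dm2$x_breaks, 1, 0.2))
  masses <- px %o% px   # isotropic, symmetric range
  counts <- dm2$density * dm2$n_in * a2
  se <- sqrt(dm2$n_in * masses * (1 - masses))
  expect_true(all(abs(counts - dm2$n_in * masses) < 4 * se + 3))
})

test_that("Gaussian component fitting locates single and double peaks", {
  sc1 <- simulate_intensity_scatter(
    list(list(mean = c(1.4, 0.9), sd = 0.15, weight = 1)), n = 3000, seed = 6)
  f1 <- fit_two_gaussians(sc1, k = 1)
  se <- 0.15 / sqrt(3000)
  expect_true(all(abs(f1$components[[1]]$mean - c(1.4, 0.9)) < 3 * se + 0.01))
  comps <- list(list(mean = c(0.7, 1.5), sd = 0.15, weight = 0.5),
                list(mean = c(1.4, 0.9), sd = 0.15, weight = 0.5))
  f2 <- fit_two_gaussians(simulate_intensity_scatter(comps, 10000, seed = 7),
                          k = 2)
  means <- lapply(f2$components, `[[`, "mean")
  d_to <- function(m) vapply(means, function(x) sqrt(sum((x - m)^2)), numeric(1))
  expect_lt(min(d_to(c(0.7, 1.5))), 0.05)
  expect_lt(min(d_to(c(1.4, 0.9))), 0.05)
  expect_false(f2$overlap)
  # unimodal data with k = 2 raise the degeneracy flag
  f3 <- fit_two_gaussians(sc1, k = 2)
  expect_true(f3$overlap)
})

test_that("boundary slope reproduces the bisector geometry and symmetries", {
  c1 <- list(mean = c(0.7, 1.5), sd = 0.15, weight = 0.5)
  c2 <- list(mean = c(1.4, 0.9), sd = 0.15, weight = 0.5)
  b <- boundary_slope(c1, c2)
  # oracle: perpendicular bisector of the printed peaks is y = 7/6 x - 0.025;
  # the through-origin approximation sits slightly below 7/6
  expect_lt(abs(b$slope - 7 / 6), 0.035)
  expect_false(b$nonlinear)
  # swapping arguments changes nothing
  b_swap <- boundary_slope(c2, c1)
  expect_equal(b$slope, b_swap$slope, tolerance = 1e-9)
  # components symmetric about y = x give slope exactly 1
  s1 <- list(mean = c(0.6, 1.4), sd = 0.2, weight = 0.5)
  s2 <- list(mean = c(1.4, 0.6), sd = 0.2, weight = 0.5)
  expect_equal(boundary_slope(s1, s2)$slope, 1, tolerance = 1e-6)
  # y-dominated separation triggers the horizontal boundary rule
  h <- boundary_slope(list(mean = c(0.4, 0.8), sd = 0.15, weight = 0.5),
                      list(mean = c(0.41, 2.0), sd = 0.15, weight = 0.5))
  expect_equal(h$orientation, "horizontal")
  expect_true(is.finite(h$level))
})

test_that("co-localization probability integrates the density map", {
  sc <- simulate_intensity_scatter(
    list(list(mean = c(0.7, 1.5), sd = 0.15, weight = 0.5),
         list(mean = c(1.4, 0.9), sd = 0.15, weight = 0.5)), 20000, seed = 8)
  dm <- density_map(sc, bins = 80, range = list(x = c(0, 4), y = c(0, 5)))
  expect_equal(coloc_probability(dm, c(0, 4), c(0, 5)), 1, tolerance = 1e-9)
  # against direct point counting
  p <- coloc_probability(dm, c(1.1, 4), c(1.375, 5))
  direct <- mean(sc$x >= 1.1 & sc$x <= 4 & sc$y >= 1.375 & sc$y <= 5)
  expect_lt(abs(p - direct), 1 / sqrt(length(sc$x)) + 0.01)
  # uniform density: probability equals the area ratio
  set.seed(9)
  u <- intensity_scatter(stats::runif(50000, 0, 2), stats::runif(50000, 0, 2))
  dmu <- density_map(u, bins = 40, range = list(x = c(0, 2), y = c(0, 2)))
  expect_equal(coloc_probability(dmu, c(1, 2), c(1, 2)), 0.25, tolerance = 0.02)
  expect_error(coloc_probability(dm, c(2, 1), c(0, 1)), "inverted")
})

test_that("velocity statistics convert 5-s displacements to um/min", {
  p <- cbind(seq(0, 18, by = 0.5), 0)   # 0.5 um per 5-s step
  v <- instantaneous_velocity_stats(migration_track(p))
  expect_true(all(abs(v$velocities - 6) < 1e-12))
  expect_equal(unname(v$summary), rep(6, 5))
  still <- instantaneous_velocity_stats(migration_track(matrix(1, 10, 2)))
  expect_true(all(still$velocities == 0))
  tr <- simulate_migration_track(6, bias = 0.5, n_steps = 100, seed = 3)
  expect_equal(instantaneous_velocity_stats(tr)$mean, 6, tolerance = 1e-9)
})

test_that("chemotactic index hits its geometric limits and mean behavior", {
  src <- c(0, 1000)
  up <- migration_track(cbind(0, seq(0, 50, by = 0.5)), source_position = src)
  expect_equal(chemotactic_index(up), 1, tolerance = 1e-9)
  sideways <- migration_track(cbind(seq(0, 50, by = 0.5), 0),
                              source_position = src)
  expect_lt(abs(chemotactic_index(sideways)), 1e-12)
  expect_error(chemotactic_index(
    migration_track(matrix(0, 5, 2), source_position = src)), "immotile")
  expect_equal(chemotactic_index(simulate_migration_track(6, 1, seed = 2)), 1,
               tolerance = 1e-9)
  # for a far source the wrapped-Cauchy step model gives E[CI] ~ bias
  for (bias in c(0, 0.6)) {
    cis <- vapply(1:30, function(s)
      chemotactic_index(simulate_migration_track(6, bias, n_steps = 360,
                                                 seed = s)), numeric(1))
    se <- stats::sd(cis) / sqrt(length(cis))
    expect_lt(abs(mean(cis) - bias), 3 * se + 0.01)
  }
})

test_that("scatter simulation respects weights, truncation and emptiness", {
  expect_error(simulate_intensity_scatter(list(), 10), "empty")
  expect_error(simulate_intensity_scatter(
    list(list(mean = c(1, 1), sd = 0.1, weight = 0.5)), 10), "sum to 1")
  sc0 <- simulate_intensity_scatter(
    list(list(mean = c(1, 1), sd = 0.1, weight = 1)), 0)
  expect_length(sc0$x, 0)
  sc <- simulate_intensity_scatter(
    list(list(mean = c(0.7, 1.5), sd = 0.15, weight = 1)), 5000, seed = 10)
  se <- 0.15 / sqrt(5000)
  expect_lt(abs(mean(sc$x) - 0.7), 3 * se + 0.005)
  expect_lt(abs(mean(sc$y) - 1.5), 3 * se + 0.005)
  expect_true(all(sc$x >= 0) && all(sc$y >= 0))
})
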