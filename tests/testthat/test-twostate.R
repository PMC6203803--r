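test_that("two-state closed form matches decoupled, conserved and oracle cases", {
  tt <- seq(0, 3, by = 0.05)
  # decoupled limit
  kin <- list(k_off1 = 0.2, k_off2p = 1.5, k_12p = 0, k_2p1 = 0, a = 0.3)
  sol <- two_state_solution(kin, tt)
  expect_equal(sol$P1, 0.3 * exp(-0.2 * tt), tolerance = 1e-12)
  expect_equal(sol$P2p, 0.7 * exp(-1.5 * tt), tolerance = 1e-12)
  # conservation without dissociation
  kin0 <- list(k_off1 = 0, k_off2p = 0, k_12p = 0.8, k_2p1 = 1.3, a = 0.6)
  expect_equal(two_state_solution(kin0, tt)$P, rep(1, length(tt)),
               tolerance = 1e-12)
  # arbitrary rates vs matrix-exponential oracle at t = 0.5
  kin2 <- list(k_off1 = 0.15, k_off2p = 1.3, k_12p = 1.2, k_2p1 = 2.6, a = 0.25)
  A <- matrix(c(-(0.15 + 1.2), 1.2, 2.6, -(1.3 + 2.6)), 2, 2)
  p_oracle <- expm_taylor(A * 0.5) %*% c(0.25, 0.75)
  s <- two_state_solution(kin2, 0.5)
  expect_equal(c(s$P1, s$P2p), as.numeric(p_oracle), tolerance = 1e-10)
  # repeated-eigenvalue branch stays finite and continuous
  kin3 <- list(k_off1 = 1, k_off2p = 1, k_12p = 0, k_2p1 = 0, a = 0.5)
  s3 <- two_state_solution(kin3, tt)
  expect_equal(s3$P, exp(-tt), tolerance = 1e-10)
  # total bound fraction monotone non-increasing
  for (kin_i in list(kin, kin0, kin2)) {
    expect_true(all(diff(two_state_solution(kin_i, tt)$P) <= 1e-12))
  }
})

test_that("state fractions stay near 1 when all molecules are stable", {
  spec <- simulation_spec(3, diffusion = c(0.01, 0.05, 0.52),
                          dissoc_rate = c(0.5, 0.5, 0.5),
                          transition_rates = matrix(0, 3, 3),
                          loc_error = 0.023, movie_duration = 30,
                          n_molecules = 1200, init_state_probs = c(1, 0, 0),
                          seed = 2)
  series <- fractions_vs_time(simulate_ensemble(spec), c(0.01, 0.05, 0.52),
                              0.023, min_count = 1000)
  expect_true(all(series$q1 >= 0.95))
  expect_equal(series$q1 + series$q2p, rep(1, length(series$q1)),
               tolerance = 1e-9)
})

test_that("per-bin fractions track ground-truth occupancy", {
  # stable and fast states widely separated, and the unpopulated middle
  # component adjacent to the fast one: any weight it absorbs stays inside
  # the lumped transient fraction, so the stable-vs-transient split is
  # near-binomial
  tm <- matrix(c(0, 0, 1.0,
                 0, 0, 0,
                 2.0, 0, 0), 3, 3, byrow = TRUE)
  spec <- simulation_spec(3, diffusion = c(0.01, 0.40, 0.52),
                          dissoc_rate = c(0.2, 0.2, 0.8),
                          transition_rates = tm, loc_error = 0.02,
                          movie_duration = 30, n_molecules = 2000,
                          init_state_probs = c(0.4, 0, 0.6), seed = 13)
  ens <- simulate_ensemble(spec)
  series <- fractions_vs_time(ens, c(0.01, 0.40, 0.52), 0.02)
  kept <- drop_censored(ens)
  tr <- kept$tracks[order(kept$tracks$molecule_id, kept$tracks$frame), ]
  # ground truth: interval-average occupancy over each displacement's frame
  # pair (trapezoid over the two endpoint states), matching what a
  # displacement measured across that interval reflects
  has_next <- c(tr$molecule_id[-1L] == tr$molecule_id[-nrow(tr)], FALSE)
  stable_now <- tr$state == 1
  stable_next <- c(tr$state[-1L] == 1, FALSE)
  for (i in seq_len(min(15, length(series$times)))) {
    sel <- has_next & abs(tr$t_s - series$times[i]) < 1e-9
    truth <- mean((stable_now[sel] + stable_next[sel]) / 2)
    n <- sum(sel)
    se <- sqrt(max(truth * (1 - truth), 0.01) / n)
    expect_lt(abs(series$q1[i] - truth), 3 * se + 0.02)
  }
})

test_that("fractions approach steady state within a second at realistic rates", {
  spec <- two_state_study_spec(seed = 5, n_molecules = 3000L)
  series <- fractions_vs_time(simulate_ensemble(spec), c(0.01, 0.05, 0.52),
                              0.023)
  late <- series$q1[series$times > 1 & series$times < 2]
  expect_lt(stats::sd(late), 0.05)
  early <- series$q1[1]
  expect_gt(abs(mean(late) - early), 0.2)  # a genuine transient happened
})

test_that("noiseless synthetic series recover the kinetics within 2%", {
  kin <- list(k_off1 = 0.1, k_off2p = 1.3, k_12p = 0.7, k_2p1 = 1.0, a = 0.4)
  tt <- seq(0, 2, by = 1 / 30)
  sol <- two_state_solution(kin, tt)
  series <- make_series(tt, sol$P1 / sol$P)
  curve <- make_curve(tt, sol$P)
  fit <- fit_two_state(series, curve)
  est <- unlist(fit[c("k_off1", "k_off2p", "k_12p", "k_2p1", "a")])
  expect_true(all(abs(est / unlist(kin) - 1) < 0.02))
})

test_that("small-noise series recover the kinetics within 15% across replicates", {
  kin <- list(k_off1 = 0.15, k_off2p = 1.3, k_12p = 1.2, k_2p1 = 2.6, a = 0.25)
  tt <- seq(0, 2, by = 1 / 30)
  sol <- two_state_solution(kin, tt)
  truth <- unlist(kin)
  set.seed(202)
  worst <- 0
  n_rep <- 12
  fails <- 0L
  for (r in seq_len(n_rep)) {
    q1 <- pmin(pmax(sol$P1 / sol$P + stats::rnorm(length(tt), 0, 0.02), 0), 1)
    p <- pmin(pmax(sol$P + stats::rnorm(length(tt), 0, 0.02), 0), 1)
    p[1] <- 1
    fit <- fit_two_state(make_series(tt, q1), make_curve(tt, p), n_starts = 4L)
    est <- unlist(fit[c("k_off1", "k_off2p", "k_12p", "k_2p1", "a")])
    if (any(abs(est / truth - 1) >= 0.15)) fails <- fails + 1L
  }
  expect_lte(fails, 2L)
})

test_that("a stationary series with exponential survival satisfies the flux balance", {
  # constant q1 and single-exponential survival: the fitted model must keep
  # the surviving-population composition stationary, i.e. the net transition
  # flux balances the differential dissociation:
  # q1 k_12' - (1 - q1) k_2'1 = q1 (1 - q1) (k_off2' - k_off1)
  tt <- seq(0, 2, by = 1 / 30)
  q1c <- 0.6
  series <- make_series(tt, rep(q1c, length(tt)))
  curve <- make_curve(tt, exp(-0.8 * tt))
  fit <- fit_two_state(series, curve)
  lhs <- q1c * fit$k_12p - (1 - q1c) * fit$k_2p1
  rhs <- q1c * (1 - q1c) * (fit$k_off2p - fit$k_off1)
  scale <- max(q1c * fit$k_12p, (1 - q1c) * fit$k_2p1, abs(rhs), 0.8)
  expect_lt(abs(lhs - rhs) / scale, 0.05)
  # and the total decay must match the survival rate
  mix <- q1c * fit$k_off1 + (1 - q1c) * fit$k_off2p
  expect_lt(abs(mix - 0.8) / 0.8, 0.05)
})

test_that("a generator without stable-state dissociation fits k_off1 near zero", {
  tm <- matrix(c(0, 1.0, 0.2,
                 2.6, 0, 0.3,
                 2.6, 0.5, 0), 3, 3, byrow = TRUE)
  spec <- simulation_spec(3, diffusion = c(0.01, 0.05, 0.52),
                          dissoc_rate = c(0, 1.2, 1.2),
                          transition_rates = tm, bleach_rate = 0,
                          loc_error = 0.023, movie_duration = 30,
                          n_molecules = 1500,
                          init_state_probs = c(0.25, 0.55, 0.20), seed = 23)
  ens <- simulate_ensemble(spec)
  series <- fractions_vs_time(ens, c(0.01, 0.05, 0.52), 0.023)
  fit <- fit_two_state(series, build_survival(ens))
  expect_lte(fit$k_off1, 0.05)
})

test_that("association frequency regression separates and calibrates", {
  set.seed(31)
  x <- stats::runif(20, 0.5, 3)
  g <- list(a = data.frame(intensity = x, appearance_rate = 2 * x),
            b = data.frame(intensity = x, appearance_rate = 1 * x))
  res <- association_rate_regression(g)
  expect_equal(unname(res$slopes), c(2, 1), tolerance = 1e-12)
  expect_lt(res$p_value, 1e-10)
  # degenerate design
  expect_error(association_rate_regression(list(
    a = data.frame(intensity = rep(2, 5), appearance_rate = 1:5),
    b = data.frame(intensity = 1:5, appearance_rate = 1:5))),
    "zero-variance")
  # type-I error calibration under a shared Poisson generative slope
  set.seed(99)
  rejections <- replicate(1000, {
    gg <- lapply(1:2, function(i) {
      xx <- stats::runif(8, 1, 4)
      data.frame(intensity = xx,
                 appearance_rate = stats::rpois(8, 20 * xx) / 20)
    })
    association_rate_regression(gg)$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})
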