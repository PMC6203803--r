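#' Time-resolved binding-state fractions after membrane association
#'
#' For each frame-interval bin of time since membrane association, estimates
#' the fractions of the three diffusion components by maximum likelihood on
#' the single-lag displacements starting in that bin, with the diffusion
#' coefficients and localization error fixed to externally estimated values.
#' The fractions of the two faster components (primary and weakly binding)
#' are summed into the transiently binding fraction, so the series feeds the
#' two-state kinetic fit directly. Bins with fewer displacements than
#' `min_count` are merged rightward (their displacements pooled into the
#' following bin); a starved tail is truncated with a warning record.
#'
#' @param ensemble a [trajectory_ensemble].
#' @param fixed_D three strictly increasing diffusion coefficients (um^2/s).
#' @param loc_error localization error (um).
#' @param min_count minimum displacements per bin (default 50).
#' @param t_max analyze bins with time since binding below this (s);
#'   default covers the whole record.
#' @return An object of class `state_fraction_series`: `times` (bin left
#'   edges, s), `q1` (stably binding fraction), `q2p` (transient fraction),
#'   `q3` (matrix of the three raw fractions), `n_per_bin`, `fixed_D`,
#'   `frame_interval`, `warnings`.
#' @export
fractions_vs_time <- function(ensemble, fixed_D, loc_error,
                              min_count = 50L, t_max = Inf) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (length(fixed_D) != 3 || any(diff(fixed_D) <= 0))
    stop("fixed_D must be three strictly increasing diffusion coefficients")
  ds <- extract_displacements(ensemble)
  dt <- ds$lag
  keep <- ds$time_since_binding < t_max
  dr2 <- ds$displacements[keep]^2
  tb <- ds$time_since_binding[keep]
  bin <- round(tb / dt)
  sigma2 <- 2 * fixed_D * dt + 2 * loc_error^2

  bins <- sort(unique(bin))
  warnings <- character(0)
  times <- numeric(0); qmat <- NULL; n_per_bin <- integer(0)
  pending <- numeric(0)   # displacements carried from starved bins
  pending_t <- NA_real_
  for (b in bins) {
    cur <- c(pending, dr2[bin == b])
    t_left <- if (length(pending) > 0) pending_t else b * dt
    if (length(cur) < min_count) {
      pending <- cur
      if (is.na(pending_t)) pending_t <- t_left
      pending_t <- min(pending_t, t_left)
      next
    }
    q <- fit_fractions_fixed_D(cur, sigma2)
    times <- c(times, t_left)
    qmat <- rbind(qmat, q)
    n_per_bin <- c(n_per_bin, length(cur))
    pending <- numeric(0); pending_t <- NA_real_
  }
  if (length(pending) > 0)
    warnings <- c(warnings, sprintf(
      "tail truncated: %d displacements after t = %.3f s fell below min_count",
      length(pending), if (is.na(pending_t)) max(tb) else pending_t))
  if (is.null(qmat)) stop("no bin reached min_count = ", min_count)
  rownames(qmat) <- NULL
  structure(
    list(times = times, q1 = qmat[, 1], q2p = qmat[, 2] + qmat[, 3],
         q3 = qmat, n_per_bin = n_per_bin, fixed_D = fixed_D,
         loc_error = loc_error, frame_interval = dt, warnings = warnings),
    class = "state_fraction_series")
}

# EM over fractions only, Rayleigh mixture with fixed scales
fit_fractions_fixed_D <- function(dr2, sigma2, max_iter = 500L, tol = 1e-10) {
  J <- length(sigma2)
  lp0 <- vapply(seq_len(J), function(j)
    -log(sigma2[j]) - dr2 / (2 * sigma2[j]), numeric(length(dr2)))
  lp0 <- matrix(lp0, ncol = J)
  q <- rep(1 / J, J)
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    lp <- sweep(lp0, 2, log(q), "+")
    mx <- lp[, 1]
    for (j in 2:J) mx <- pmax(mx, lp[, j])
    w <- exp(lp - mx)
    rs <- rowSums(w)
    ll <- sum(log(rs) + mx)
    q <- colSums(w / rs) / length(dr2)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  q
}

#' @export
print.state_fraction_series <- function(x, ...) {
  cat(sprintf("<state_fraction_series> %d bins, dt = %.4g s\n",
              length(x$times), x$frame_interval))
  invisible(x)
}

#' Closed-form solution of the two-state membrane-binding kinetics
#'
#' Occupancy probabilities of the stably (P1) and transiently (P2')
#' binding states under the linear kinetic scheme
#' \deqn{dP_1/dt = -(k_{off1} + k_{12'}) P_1 + k_{2'1} P_{2'},}
#' \deqn{dP_{2'}/dt = -(k_{off2'} + k_{2'1}) P_{2'} + k_{12'} P_1,}
#' with initial condition P1(0) = a, P2'(0) = 1 - a, solved in closed form
#' by eigen-decomposition of the 2 x 2 rate matrix (with the degenerate
#' repeated-eigenvalue branch handled analytically). The total bound
#' fraction is P = P1 + P2'.
#'
#' @param kin list with `k_off1`, `k_off2p`, `k_12p`, `k_2p1`, `a`
#'   (all rates in 1/s, `a` in `[0, 1]`), e.g. a [fit_two_state()] result.
#' @param times numeric vector of times (s).
#' @return data.frame with columns `t`, `P1`, `P2p`, `P`.
#' @export
two_state_solution <- function(kin, times) {
  with(kin, {
    if (any(c(k_off1, k_off2p, k_12p, k_2p1) < 0) || a < 0 || a > 1)
      stop("invalid kinetics: rates must be >= 0 and a in [0, 1]")
    A <- matrix(c(-(k_off1 + k_12p), k_12p,
                  k_2p1, -(k_off2p + k_2p1)), 2, 2)
    p0 <- c(a, 1 - a)
    tr <- A[1, 1] + A[2, 2]
    det_ <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    disc <- tr^2 / 4 - det_
    if (disc > 1e-14 * max(tr^2, 1)) {
      sq <- sqrt(disc)
      l1 <- tr / 2 + sq; l2 <- tr / 2 - sq
      # spectral projectors: P(t) = e^{l1 t} G1 p0 + e^{l2 t} G2 p0
      I2 <- diag(2)
      G1 <- (A - l2 * I2) / (l1 - l2)
      G2 <- (A - l1 * I2) / (l2 - l1)
      v1 <- G1 %*% p0; v2 <- G2 %*% p0
      P1 <- exp(l1 * times) * v1[1] + exp(l2 * times) * v2[1]
      P2p <- exp(l1 * times) * v1[2] + exp(l2 * times) * v2[2]
    } else {
      # repeated eigenvalue: e^{At} = e^{lt} (I + (A - lI) t)
      l <- tr / 2
      N <- A - l * diag(2)
      P1 <- exp(l * times) * (p0[1] + (N[1, 1] * p0[1] + N[1, 2] * p0[2]) * times)
      P2p <- exp(l * times) * (p0[2] + (N[2, 1] * p0[1] + N[2, 2] * p0[2]) * times)
    }
    data.frame(t = times, P1 = P1, P2p = P2p, P = P1 + P2p)
  })
}

#' Fit the two-state kinetic model to state fractions and survival
#'
#' Joint least-squares fit of the two-state kinetic scheme to the
#' time-resolved occupancy fractions among survivors, P1/(P1 + P2') vs
#' q1(t) and P2'/(P1 + P2') vs q2'(t), and the dissociation curve vs
#' P(t) = P1 + P2', restricted to t < `t_max`, with the survival residuals
#' weighted `survival_weight`-fold. All four rate constants and the initial
#' stable-state probability a are free; optimization is seeded multi-start
#' (square-root rate and logit-a parameterization keeps the constraints),
#' initialized at the point consistent with stationary occupancy of the
#' observed early-time fractions.
#'
#' @param series a [fractions_vs_time()] series.
#' @param survival a [build_survival()] curve from the same ensemble.
#' @param t_max fit window (s), default 2.
#' @param survival_weight relative weight of the survival residuals
#'   (default 3).
#' @param bleach_rate optional photobleaching rate (1/s); when given,
#'   bleach-corrected dissociation rates are reported alongside.
#' @param n_starts number of random starts.
#' @param seed seed for the random starts.
#' @return An object of class `two_state_kinetics` with `k_off1`,
#'   `k_off2p`, `k_12p`, `k_2p1`, `a`, `residual`, `fit_window`, `weights`,
#'   and (when `bleach_rate` is given) `k_off1_corrected`,
#'   `k_off2p_corrected`.
#' @export
fit_two_state <- function(series, survival, t_max = 2, survival_weight = 3,
                          bleach_rate = NULL, n_starts = 12L, seed = 1L) {
  stopifnot(inherits(series, "state_fraction_series"),
            inherits(survival, "survival_curve"))
  if (abs(series$frame_interval - survival$frame_interval) > 1e-9)
    stop("series and survival curve have different frame intervals")
  sel_f <- series$times < t_max
  tf <- series$times[sel_f]
  q1 <- series$q1[sel_f]; q2p <- series$q2p[sel_f]
  sel_s <- survival$times < t_max
  ts <- survival$times[sel_s]
  ys <- survival$fraction_bound[sel_s]
  if (length(tf) == 0 || length(ts) == 0)
    stop("no data before t_max = ", t_max)

  obj <- function(par) {
    k <- par[1:4]^2
    a <- stats::plogis(par[5])
    kin <- list(k_off1 = k[1], k_off2p = k[2], k_12p = k[3], k_2p1 = k[4], a = a)
    solf <- two_state_solution(kin, tf)
    tot <- solf$P
    sols <- two_state_solution(kin, ts)
    sum((q1 - solf$P1 / tot)^2) + sum((q2p - solf$P2p / tot)^2) +
      survival_weight * sum((ys - sols$P)^2)
  }

  # stationarity-consistent initial point: early fractions + survival decay
  q1bar <- mean(q1)
  k_tot0 <- max(-stats::coef(stats::lm(log(pmax(ys, 1e-6)) ~ ts))[[2]], 0.05)
  k12_0 <- 0.5; k21_0 <- max(k12_0 * q1bar / max(1 - q1bar, 0.05), 1e-3)
  init <- c(sqrt(0.1 * k_tot0), sqrt(k_tot0), sqrt(k12_0), sqrt(k21_0),
            stats::qlogis(min(max(q1bar, 0.05), 0.95)))
  rng <- local({ set.seed(seed); function(n) stats::runif(n) })
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- if (s == 1L) init else
      init * exp((rng(5) - 0.5) * 1.5) + c(0, 0, 0, 0, (rng(1) - 0.5))
    res <- tryCatch(
      stats::optim(p0, obj, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res)) {
      res <- tryCatch(
        stats::optim(res$par, obj, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-15)),
        error = function(e) res)
      if (is.null(best) || res$value < best$value) best <- res
    }
  }
  if (is.null(best)) stop("two-state fit failed to converge")
  k <- best$par[1:4]^2
  out <- structure(
    list(k_off1 = k[1], k_off2p = k[2], k_12p = k[3], k_2p1 = k[4],
         a = stats::plogis(best$par[5]), residual = best$value,
         fit_window = t_max, weights = survival_weight),
    class = "two_state_kinetics")
  if (!is.null(bleach_rate)) {
    out$bleach_rate <- bleach_rate
    out$k_off1_corrected <- max(k[1] - bleach_rate, 0)
    out$k_off2p_corrected <- max(k[2] - bleach_rate, 0)
  }
  out
}

#' @export
print.two_state_kinetics <- function(x, ...) {
  cat(sprintf(
    "<two_state_kinetics> k_off1 = %.3g, k_off2' = %.3g, k_12' = %.3g, k_2'1 = %.3g (1/s), a = %.3g\n",
    x$k_off1, x$k_off2p, x$k_12p, x$k_2p1, x$a))
  invisible(x)
}

#' Membrane-association frequency comparison by regression slope test
#'
#' For each condition, fits a through-origin least-squares line of the
#' membrane-association count rate (appearances per second per um^2) against
#' cytoplasmic fluorophore intensity across cells; the slope is the relative
#' association frequency. Because appearance counts carry Poisson-type noise
#' whose variance grows with intensity, slope standard errors use the HC3
#' heteroscedasticity-robust estimator; two conditions are compared by a t
#' statistic on the slope difference with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param groups named list of two data.frames, each with columns
#'   `intensity` and `appearance_rate` (one row per cell, >= 3 cells).
#' @return list with `slopes`, `se`, `n`, `t`, `df`, `p_value`.
#' @export
association_rate_regression <- function(groups) {
  if (!is.list(groups) || length(groups) != 2)
    stop("groups must be a list of two per-condition data.frames")
  fit1 <- lapply(groups, function(g) {
    if (nrow(g) < 3) stop("need >= 3 cells per condition")
    x <- g$intensity; y <- g$appearance_rate
    if (stats::var(x) == 0)
      stop("zero-variance intensities: degenerate regression design")
    sxx <- sum(x^2)
    b <- sum(x * y) / sxx
    e <- y - b * x
    h <- x^2 / sxx                       # leverages of the one-parameter fit
    se2 <- sum((x * e / (1 - h))^2) / sxx^2   # HC3
    list(slope = b, se = sqrt(se2), n = length(x))
  })
  b <- vapply(fit1, `[[`, numeric(1), "slope")
  se <- vapply(fit1, `[[`, numeric(1), "se")
  n <- vapply(fit1, `[[`, numeric(1), "n")
  if (sum(se^2) == 0) {
    # noise-free fits: slopes are known exactly
    return(list(slopes = b, se = se, n = n,
                t = if (b[1] == b[2]) 0 else sign(b[1] - b[2]) * Inf,
                df = sum(n) - 2, p_value = as.numeric(b[1] == b[2])))
  }
  tstat <- (b[1] - b[2]) / sqrt(sum(se^2))
  df <- sum(se^2)^2 / sum(se^4 / (n - 1))   # Welch-Satterthwaite
  list(slopes = b, se = se, n = n, t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}
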