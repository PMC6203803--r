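#' Extract single-lag displacements from an ensemble
#'
#' Euclidean step lengths between consecutive frames, pooled over all
#' uncensored trajectories irrespective of time since binding; the time since
#' binding of each step's first frame is recorded for the time-resolved
#' state-fraction analysis.
#'
#' @param ensemble a [trajectory_ensemble].
#' @return An object of class `displacement_set`: `displacements` (um),
#'   `lag` (s), `time_since_binding` (s, age of the first frame of each
#'   step), `M` (number of displacements).
#' @export
extract_displacements <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  kept <- drop_censored(ensemble)
  tr <- kept$tracks
  if (nrow(tr) == 0) stop("no displacements: ensemble empty after censoring")
  tr <- tr[order(tr$molecule_id, tr$frame), ]
  same <- tr$molecule_id[-1L] == tr$molecule_id[-nrow(tr)]
  if (!any(same)) stop("no displacements: no trajectory has >= 2 points")
  dx <- diff(tr$x_um)[same]
  dy <- diff(tr$y_um)[same]
  structure(
    list(displacements = sqrt(dx^2 + dy^2),
         lag = kept$frame_interval,
         time_since_binding = tr$t_s[-nrow(tr)][same],
         M = sum(same)),
    class = "displacement_set")
}

#' @export
print.displacement_set <- function(x, ...) {
  cat(sprintf("<displacement_set> M = %d single-lag steps, lag = %.4g s\n",
              x$M, x$lag))
  invisible(x)
}

#' Estimate the localization error by MSD regression
#'
#' Computes the mean squared displacement at lags of one and two frame
#' intervals and fits the straight line MSD(tau) = 4 D tau + 4 eps^2 through
#' the two points; the intercept yields the localization error
#' eps = sqrt(intercept / 4). A negative intercept (possible by sampling
#' noise when the true error is tiny) returns 0 with a warning attribute.
#'
#' @param ensemble a [trajectory_ensemble] with tracks long enough for
#'   two-frame lags.
#' @return Localization error estimate (um), with attribute `msd` carrying
#'   the two MSD values and attribute `warning` if the intercept was clipped.
#' @export
estimate_localization_error <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  kept <- drop_censored(ensemble)
  tr <- kept$tracks[order(kept$tracks$molecule_id, kept$tracks$frame), ]
  msd_at <- function(lag_frames) {
    n <- nrow(tr)
    if (n <= lag_frames) return(NA_real_)
    i1 <- seq_len(n - lag_frames)
    i2 <- i1 + lag_frames
    ok <- tr$molecule_id[i1] == tr$molecule_id[i2]
    if (!any(ok)) return(NA_real_)
    mean((tr$x_um[i2] - tr$x_um[i1])[ok]^2 + (tr$y_um[i2] - tr$y_um[i1])[ok]^2)
  }
  m1 <- msd_at(1L); m2 <- msd_at(2L)
  if (is.na(m1) || is.na(m2))
    stop("tracks too short for lag-2 displacements")
  dt <- kept$frame_interval
  slope <- (m2 - m1) / dt
  intercept <- m1 - slope * dt       # = 2 m1 - m2
  warn <- NULL
  if (intercept < 0) {
    warn <- "negative MSD intercept; localization error clipped to 0"
    intercept <- 0
  }
  out <- sqrt(intercept / 4)
  attr(out, "msd") <- c(lag1 = m1, lag2 = m2)
  attr(out, "D") <- slope / 4
  if (!is.null(warn)) attr(out, "warning") <- warn
  out
}

#' Displacement-distribution mixture density
#'
#' Probability density of a single-lag step length under a J-component
#' mixture of two-dimensional Brownian motions observed with localization
#' error eps:
#' \deqn{p(\Delta r) = \sum_j q_j \frac{\Delta r}{2 D_j \Delta t + 2\varepsilon^2}
#'   \exp\!\left(-\frac{\Delta r^2}{4 D_j \Delta t + 4\varepsilon^2}\right),}
#' a Rayleigh mixture with per-component scale
#' sigma_j^2 = 2 D_j dt + 2 eps^2.
#'
#' @param dr displacement(s) (um), >= 0.
#' @param dt lag time (s).
#' @param fit a `diffusion_mixture_fit`, or any list with `D`, `fractions`,
#'   `loc_error`.
#' @return Density value(s) (per um).
#' @export
mixture_pdf <- function(dr, dt, fit) {
  stopifnot(all(dr >= 0), dt > 0)
  sigma2 <- 2 * fit$D * dt + 2 * fit$loc_error^2
  dens <- vapply(seq_along(sigma2), function(j)
    dr / sigma2[j] * exp(-dr^2 / (2 * sigma2[j])), numeric(length(dr)))
  if (length(dr) == 1L) sum(dens * fit$fractions)
  else drop(matrix(dens, ncol = length(sigma2)) %*% fit$fractions)
}

# EM for the Rayleigh mixture with eps fixed and per-sample weights
# (weights > 1 arise from the binned representation used for the cheap
# multi-start phase). Components with sigma2 <= 2 eps^2 are clipped at
# D = 0 (sigma2 floor). log_dr_sum is the constant sum of weighted log
# displacements entering the log likelihood.
rayleigh_mix_em <- function(dr2, wts, log_dr_sum, J, eps, sigma2_init, q_init,
                            max_iter = 500L, tol = 1e-10) {
  floor2 <- 2 * eps^2 + 1e-12
  sigma2 <- pmax(sigma2_init, floor2)
  q <- q_init / sum(q_init)
  Mw <- sum(wts)
  ll <- -Inf; ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- matrix(0, length(dr2), J)
    for (j in seq_len(J))
      lp[, j] <- log(q[j]) - log(sigma2[j]) - dr2 / (2 * sigma2[j])
    mx <- lp[, 1]
    if (J > 1) for (j in 2:J) mx <- pmax(mx, lp[, j])
    w <- exp(lp - mx)
    rs <- rowSums(w)
    ll <- sum(wts * (log(rs) + mx)) + log_dr_sum
    w <- w * (wts / rs)
    nk <- colSums(w)
    q <- nk / Mw
    # Rayleigh scale MLE: sigma2_j = sum w dr2 / (2 sum w)
    sigma2 <- pmax(colSums(w * dr2) / (2 * nk), floor2)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(sigma2 = sigma2, q = q, logL = ll, iter = iter)
}

# collapse squared displacements to ~n_bins weighted representatives
# (quantile bins carrying their mean dr2 and count)
bin_dr2 <- function(dr2, n_bins = 4000L) {
  M <- length(dr2)
  if (M <= n_bins) return(list(dr2 = dr2, wts = rep(1, M)))
  o <- order(dr2)
  grp <- ceiling(seq_along(o) / (M / n_bins))
  s <- dr2[o]
  list(dr2 = as.numeric(tapply(s, grp, mean)),
       wts = as.numeric(tapply(s, grp, length)))
}

new_diffusion_mixture_fit <- function(J, D, q, eps, logL, M, flag = NULL) {
  ord <- order(D)
  structure(
    list(J = J, D = D[ord], fractions = q[ord], loc_error = eps,
         logL = logL, aic = -2 * logL + (2 * J - 1) * log(log(M)),
         M = M, degenerate = isTRUE(flag)),
    class = "diffusion_mixture_fit")
}

#' @export
print.diffusion_mixture_fit <- function(x, ...) {
  cat(sprintf("<diffusion_mixture_fit> J = %d, logL = %.2f, AIC = %.2f, M = %d\n",
              x$J, x$logL, x$aic, x$M))
  cat("  D (um^2/s):", paste(sprintf("%.4g", x$D), collapse = ", "), "\n")
  cat("  q         :", paste(sprintf("%.3g", x$fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood fit of a J-component diffusion mixture
#'
#' Maximizes the displacement log likelihood
#' \deqn{L_J = \sum_{m=1}^M \log p(\Delta r_m)}
#' over the J diffusion coefficients and J - 1 free fractions with the
#' localization error fixed (estimated separately and shared across
#' components). Optimization is EM with a seeded set of random
#' quantile-anchored starts; the reported information criterion is
#' AIC_J = -2 L_J + (2J - 1) log(log M) (natural logarithms).
#'
#' @param samples a [extract_displacements()] set, or numeric vector of
#'   displacements with attribute-free defaults via `lag`.
#' @param J number of diffusion components.
#' @param loc_error localization error eps (um), fixed during the fit.
#' @param n_starts number of random EM starts (default 20).
#' @param seed seed for the random starts.
#' @return A `diffusion_mixture_fit`: `J`, `D` (ascending), `fractions`,
#'   `loc_error`, `logL`, `aic`, `M`, and `degenerate` (TRUE when two
#'   components collapsed onto the same scale).
#' @export
fit_mixture <- function(samples, J, loc_error, n_starts = 20L, seed = 1L) {
  stopifnot(inherits(samples, "displacement_set"))
  J <- as.integer(J)
  dr <- samples$displacements
  dt <- samples$lag
  M <- length(dr)
  if (M < 10 * (2 * J - 1))
    stop("too few displacements (M = ", M, ") for J = ", J)
  dr2 <- dr^2
  pos <- dr2 > 0
  log_dr <- ifelse(pos, 0.5 * log(dr2), -Inf)
  if (any(!pos)) {
    # zero displacements carry zero density mass; drop with note
    dr2 <- dr2[pos]; log_dr <- log_dr[pos]; M <- length(dr2)
  }
  eps <- loc_error
  floor2 <- 2 * eps^2

  log_dr_sum <- sum(log_dr)

  # multi-start on the binned (weighted) representation, then polish the
  # winner with exact full-data EM; the reported logL is exact
  binned <- bin_dr2(dr2)
  lds_bin <- log_dr_sum   # constant offset; identical across starts

  # quantile-anchored deterministic start + jittered random starts
  qs <- stats::quantile(dr2, probs = (seq_len(J) - 0.5) / J, names = FALSE)
  base_sigma2 <- pmax(qs / 2, floor2 + 1e-10)
  rng <- local({ set.seed(seed); function(n) stats::runif(n) })
  best <- NULL
  for (s in seq_len(n_starts)) {
    if (s == 1L) {
      s2 <- base_sigma2; q0 <- rep(1 / J, J)
    } else {
      s2 <- base_sigma2 * exp((rng(J) - 0.5) * 3)
      q0 <- rng(J) + 0.1
    }
    em <- rayleigh_mix_em(binned$dr2, binned$wts, lds_bin, J, eps, s2, q0)
    if (is.null(best) || em$logL > best$logL) best <- em
  }
  if (!is.null(best) && is.finite(best$logL))
    best <- rayleigh_mix_em(dr2, rep(1, length(dr2)), log_dr_sum, J, eps,
                            best$sigma2, best$q, max_iter = 50L, tol = 1e-12)
  if (is.null(best) || !is.finite(best$logL))
    stop("diffusion mixture fit failed to converge")
  D <- (best$sigma2 - 2 * eps^2) / (2 * dt)
  D[D < 0] <- 0
  flag <- FALSE
  if (J > 1) {
    ls <- sort(log(best$sigma2))
    flag <- any(diff(ls) < 1e-3)
  }
  new_diffusion_mixture_fit(J, D, best$q, eps, best$logL, samples$M, flag)
}

#' Select the number of diffusion components by AIC
#'
#' Fits mixtures with J = 1 .. `J_max` components and returns the fit
#' minimizing AIC_J = -2 L_J + (2J - 1) log(log M). All candidate fits and
#' their AIC values are retained in the result.
#'
#' @inheritParams fit_mixture
#' @param J_max largest number of components to consider (default 4).
#' @return The AIC-minimizing `diffusion_mixture_fit`, with attributes
#'   `aic_table` (data.frame of J, logL, AIC) and `all_fits`.
#' @export
select_model <- function(samples, J_max = 4L, loc_error, n_starts = 20L,
                         seed = 1L) {
  fits <- vector("list", J_max)
  errs <- character(J_max)
  for (J in seq_len(J_max)) {
    fits[[J]] <- tryCatch(
      fit_mixture(samples, J, loc_error, n_starts = n_starts, seed = seed + J),
      error = function(e) { errs[J] <<- conditionMessage(e); NULL })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all mixture fits failed: ", paste(errs[nzchar(errs)], collapse = "; "))
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  best <- fits[ok][[which.min(aics)]]
  attr(best, "aic_table") <- data.frame(
    J = which(ok),
    logL = vapply(fits[ok], function(f) f$logL, numeric(1)),
    aic = aics)
  attr(best, "all_fits") <- fits
  best
}
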