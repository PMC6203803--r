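#' Specification of a single-molecule membrane-binding simulation
#'
#' Collects every parameter of the generative model behind
#' [simulate_ensemble()]: a continuous-time Markov chain over membrane-binding
#' states, per-state lateral diffusion and dissociation, photobleaching as a
#' competing loss process, localization noise, and the imaging geometry.
#'
#' Molecules either form a synchronized cohort released at movie start
#' (`n_molecules`) -- the natural frame for estimators that measure time since
#' membrane association -- or appear by a Poisson process (`arrival_rate`),
#' optionally pre-equilibrated over a `burn_in` window so that molecules
#' already bound at movie start are emitted with `censored_start = TRUE`.
#'
#' @param n_states number of membrane-binding states (>= 1).
#' @param diffusion numeric vector of per-state diffusion coefficients
#'   (um^2/s).
#' @param dissoc_rate per-state membrane-dissociation rate constants (1/s).
#' @param transition_rates `n_states x n_states` matrix of state-transition
#'   rate constants (1/s); off-diagonal entries must be >= 0, the diagonal is
#'   ignored. May be omitted when `n_states == 1`.
#' @param bleach_rate photobleaching rate constant k_b (1/s), a loss process
#'   additive to dissociation in the observed track durations.
#' @param loc_error localization error (um): standard deviation of the
#'   Gaussian position-measurement noise per axis per frame.
#' @param frame_interval frame interval (s); default 1/30 (30 fps imaging).
#' @param movie_duration movie length (s); must be >= 2 frame intervals.
#' @param n_molecules cohort size released at movie start (exclusive with
#'   `arrival_rate`).
#' @param arrival_rate rate of new membrane associations (molecules/s)
#'   for Poisson arrivals (exclusive with `n_molecules`).
#' @param burn_in pre-movie window (s) over which Poisson arrivals also
#'   occur, so the movie starts with a bound population; default 0.
#' @param init_state_probs probability of each state at the moment of
#'   membrane association; must sum to 1. Default uniform.
#' @param field_size c(width, height) of the imaged field (um).
#' @param n_cells number of cells to attribute molecules to (round robin).
#' @param seed integer seed; identical spec (including seed) gives
#'   byte-identical simulated ensembles.
#'
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_states,
                            diffusion,
                            dissoc_rate,
                            transition_rates = NULL,
                            bleach_rate = 0,
                            loc_error = 0,
                            frame_interval = 1 / 30,
                            movie_duration = 10,
                            n_molecules = NULL,
                            arrival_rate = NULL,
                            burn_in = 0,
                            init_state_probs = NULL,
                            field_size = c(10, 10),
                            n_cells = 1L,
                            seed = 1L) {
  n_states <- as.integer(n_states)
  if (n_states < 1) stop("n_states must be >= 1")
  if (length(diffusion) != n_states || any(diffusion < 0))
    stop("diffusion must be ", n_states, " non-negative coefficients")
  if (length(dissoc_rate) != n_states || any(dissoc_rate < 0))
    stop("dissoc_rate must be ", n_states, " non-negative rates")
  if (is.null(transition_rates)) {
    if (n_states > 1) stop("transition_rates required when n_states > 1")
    transition_rates <- matrix(0, 1, 1)
  }
  transition_rates <- as.matrix(transition_rates)
  if (!all(dim(transition_rates) == n_states))
    stop("transition_rates must be a ", n_states, " x ", n_states, " matrix")
  off <- transition_rates[row(transition_rates) != col(transition_rates)]
  if (any(off < 0))
    stop("non-conservative transition matrix: negative off-diagonal rate")
  diag(transition_rates) <- 0
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  if (loc_error < 0) stop("loc_error must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (movie_duration < 2 * frame_interval)
    stop("movie_duration must be >= 2 * frame_interval")
  if (is.null(n_molecules) == is.null(arrival_rate))
    stop("give exactly one of n_molecules or arrival_rate")
  if (!is.null(arrival_rate) && arrival_rate < 0)
    stop("arrival_rate must be >= 0")
  if (burn_in < 0) stop("burn_in must be >= 0")
  if (is.null(init_state_probs)) init_state_probs <- rep(1 / n_states, n_states)
  if (length(init_state_probs) != n_states || any(init_state_probs < 0))
    stop("init_state_probs must be ", n_states, " non-negative probabilities")
  if (abs(sum(init_state_probs) - 1) > 1e-12)
    stop("init_state_probs must sum to 1")
  structure(
    list(n_states = n_states, diffusion = as.numeric(diffusion),
         dissoc_rate = as.numeric(dissoc_rate),
         transition_rates = transition_rates,
         bleach_rate = bleach_rate, loc_error = loc_error,
         frame_interval = frame_interval, movie_duration = movie_duration,
         n_molecules = if (is.null(n_molecules)) NULL else as.integer(n_molecules),
         arrival_rate = arrival_rate, burn_in = burn_in,
         init_state_probs = as.numeric(init_state_probs),
         field_size = as.numeric(field_size), n_cells = as.integer(n_cells),
         seed = as.integer(seed)),
    class = "simulation_spec")
}

# Gillespie path of one molecule: exact exponential event times.
# Returns list(seg_t0, seg_t1, seg_state, loss_time, cause) where segments
# partition [0, loss_time) (or [0, Inf) truncated later if censored).
# cause is "unbind", "bleach" or NA (still bound at t_stop).
sim_state_path <- function(spec, t_stop) {
  trans <- spec$transition_rates
  exit_trans <- rowSums(trans)
  s <- sample.int(spec$n_states, 1L, prob = spec$init_state_probs)
  t <- 0
  seg_t0 <- numeric(0); seg_t1 <- numeric(0); seg_state <- integer(0)
  cause <- NA_character_; loss_time <- NA_real_
  repeat {
    total <- exit_trans[s] + spec$dissoc_rate[s] + spec$bleach_rate
    if (total <= 0) { # absorbing occupancy: bound forever
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t_stop); seg_state <- c(seg_state, s)
      break
    }
    dt <- stats::rexp(1L, total)
    t_next <- t + dt
    if (t_next >= t_stop) {
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t_stop); seg_state <- c(seg_state, s)
      break
    }
    u <- stats::runif(1L) * total
    if (u < spec$dissoc_rate[s]) {
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t_next); seg_state <- c(seg_state, s)
      cause <- "unbind"; loss_time <- t_next
      break
    } else if (u < spec$dissoc_rate[s] + spec$bleach_rate) {
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t_next); seg_state <- c(seg_state, s)
      cause <- "bleach"; loss_time <- t_next
      break
    } else {
      # state transition
      u2 <- u - spec$dissoc_rate[s] - spec$bleach_rate
      cum <- cumsum(trans[s, ])
      s_new <- which(u2 < cum)[1L]
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t_next); seg_state <- c(seg_state, s)
      t <- t_next; s <- s_new
    }
  }
  list(seg_t0 = seg_t0, seg_t1 = seg_t1, seg_state = seg_state,
       loss_time = loss_time, cause = cause)
}

# per-axis displacement variances over consecutive age intervals:
# v_j = 2 * integral of D(state(u)) du over [ages_j, ages_{j+1}],
# via the cumulative diffusion-time integral evaluated at the frame times
path_disp_vars <- function(path, diffusion, ages) {
  if (length(path$seg_state) == 1L)
    return(rep(2 * diffusion[path$seg_state] * diff(ages[1:2]),
               length(ages) - 1L))
  d_seg <- diffusion[path$seg_state]
  cum0 <- c(0, cumsum(d_seg * (path$seg_t1 - path$seg_t0)))
  idx <- findInterval(ages, path$seg_t0)
  idx[idx < 1L] <- 1L
  dint <- cum0[idx] + d_seg[idx] * (pmin(ages, path$seg_t1[idx]) - path$seg_t0[idx])
  2 * diff(dint)
}

path_state_at <- function(path, times) {
  idx <- findInterval(times, path$seg_t0)
  idx[idx < 1L] <- 1L
  path$seg_state[idx]
}

#' Simulate a single-molecule trajectory ensemble
#'
#' Generates membrane-binding trajectories under the full generative model of
#' a [simulation_spec]: each molecule associates at a uniform random position,
#' its binding state evolves as a continuous-time Markov chain with exact
#' exponential event times (Gillespie algorithm, so the frame interval never
#' biases the kinetics), it diffuses laterally with the per-state coefficient
#' (the within-frame displacement variance integrates the diffusion
#' coefficient over the true state occupancy times), and it disappears at the
#' earlier of membrane dissociation (state-specific rate), photobleaching, or
#' movie end (then flagged `censored_end`). Observed positions carry i.i.d.
#' Gaussian localization noise per axis per frame; the noiseless positions
#' and the per-frame true state are kept as ground truth.
#'
#' @param spec a [simulation_spec].
#' @return A [trajectory_ensemble] whose `tracks` include the ground-truth
#'   `state`, `x_true_um`, `y_true_um` columns and whose `molecules` carry
#'   `loss_cause` and `true_duration`.
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  dt <- spec$frame_interval
  dur <- spec$movie_duration

  # appearance times
  if (!is.null(spec$n_molecules)) {
    appear <- rep(0, spec$n_molecules)
  } else {
    window <- spec$burn_in + dur
    n_arr <- stats::rpois(1L, spec$arrival_rate * window)
    appear <- sort(stats::runif(n_arr, -spec$burn_in, dur))
  }
  n <- length(appear)
  if (n == 0)
    return(trajectory_ensemble(
      data.frame(molecule_id = integer(0), cell_id = integer(0),
                 frame = integer(0), t_s = numeric(0),
                 x_um = numeric(0), y_um = numeric(0)),
      data.frame(molecule_id = integer(0), cell_id = integer(0),
                 censored_start = logical(0), censored_end = logical(0)),
      dt, n_cells = spec$n_cells))

  tr_list <- vector("list", n)
  mol <- data.frame(molecule_id = seq_len(n),
                    cell_id = ((seq_len(n) - 1L) %% spec$n_cells) + 1L,
                    censored_start = FALSE, censored_end = FALSE,
                    loss_cause = NA_character_, true_duration = NA_real_)
  for (i in seq_len(n)) {
    t_a <- appear[i]
    horizon <- dur - t_a   # max observable age
    path <- sim_state_path(spec, t_stop = max(horizon, 0) + dt)
    if (is.na(path$loss_time) || path$loss_time > horizon) {
      t_end <- horizon
      mol$censored_end[i] <- TRUE
      mol$loss_cause[i] <- "censored"
    } else {
      t_end <- path$loss_time
      mol$loss_cause[i] <- path$cause
      mol$true_duration[i] <- path$loss_time
    }
    # observation grid in molecule age; censored-start molecules are observed
    # from the first frame falling inside the movie
    k0 <- if (t_a < 0) ceiling((-t_a - 1e-9) / dt) else 0
    k1 <- floor(t_end / dt + 1e-9)
    if (k1 < k0) { tr_list[[i]] <- NULL; next }
    mol$censored_start[i] <- t_a < 0
    ages <- (k0:k1) * dt
    m <- length(ages)
    x <- numeric(m); y <- numeric(m)
    x[1] <- stats::runif(1L, 0, spec$field_size[1])
    y[1] <- stats::runif(1L, 0, spec$field_size[2])
    if (m > 1) {
      sdv <- sqrt(path_disp_vars(path, spec$diffusion, ages))
      x <- x[1] + c(0, cumsum(stats::rnorm(m - 1L, 0, sdv)))
      y <- y[1] + c(0, cumsum(stats::rnorm(m - 1L, 0, sdv)))
    }
    xo <- x + stats::rnorm(m, 0, spec$loc_error)
    yo <- y + stats::rnorm(m, 0, spec$loc_error)
    tr_list[[i]] <- list(
      molecule_id = rep.int(i, m), cell_id = rep.int(mol$cell_id[i], m),
      frame = 0:(m - 1L), t_s = ages - ages[1],
      x_um = xo, y_um = yo,
      x_true_um = x, y_true_um = y,
      state = path_state_at(path, pmin(ages, max(path$seg_t1) - 1e-12)))
  }
  keep <- !vapply(tr_list, is.null, logical(1))
  cols <- names(tr_list[[which(keep)[1]]])
  tracks <- as.data.frame(
    lapply(stats::setNames(cols, cols), function(cn)
      unlist(lapply(tr_list[keep], `[[`, cn), use.names = FALSE)))
  trajectory_ensemble(tracks, mol[keep, , drop = FALSE], dt,
                      n_cells = spec$n_cells)
}

#' Simulate immobilized fluorophores bleaching on a coverslip
#'
#' Stationary single dyes whose only loss process is photobleaching; the
#' survival curve of such an ensemble calibrates the photobleaching rate
#' constant k_b used to correct membrane-dissociation rates.
#'
#' @param bleach_rate photobleaching rate constant (1/s).
#' @param n number of dye molecules.
#' @param frame_interval frame interval (s), default 1/30.
#' @param duration movie length (s).
#' @param loc_error localization noise sd (um), default 0.02.
#' @param seed integer seed.
#' @return A [trajectory_ensemble].
#' @export
simulate_immobilized <- function(bleach_rate, n, frame_interval = 1 / 30,
                                 duration = 60, loc_error = 0.02, seed = 1L) {
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  spec <- simulation_spec(
    n_states = 1L, diffusion = 0, dissoc_rate = 0,
    bleach_rate = bleach_rate, loc_error = loc_error,
    frame_interval = frame_interval, movie_duration = duration,
    n_molecules = n, seed = seed)
  out <- simulate_ensemble(spec)
  out$condition_label <- "immobilized"
  out
}
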