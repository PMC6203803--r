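# Independent numerical oracles used by the tests. These deliberately avoid
# the package's own code paths.

# matrix exponential by scaling-and-squaring of a Taylor series
expm_taylor <- function(A, order = 24L) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 2L)
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% As / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# mean absorption time of a CTMC with generator-with-loss matrix A
# (dP/dt = A P), starting distribution p0: E[T] = -1' A^{-1} p0
ctmc_mean_absorption <- function(A, p0) {
  -sum(solve(A) %*% p0)
}

# handmade survival curve object (bypasses build_survival)
make_curve <- function(times, fraction_bound, n0 = 1000L,
                       frame_interval = diff(times[1:2])) {
  structure(list(times = times, fraction_bound = fraction_bound,
                 n0 = n0, frame_interval = frame_interval),
            class = "survival_curve")
}

# handmade state-fraction series (bypasses fractions_vs_time)
make_series <- function(times, q1, n = 1000L, frame_interval = diff(times[1:2])) {
  structure(list(times = times, q1 = q1, q2p = 1 - q1,
                 n_per_bin = rep(n, length(times)),
                 fixed_D = c(0.01, 0.05, 0.52),
                 frame_interval = frame_interval),
            class = "state_fraction_series")
}

# common two-state study conditions: three diffusion states whose two fast
# states are lumpable (equal dissociation and equal return rates), giving
# lumped truth k_off1 = 0.15, k_off2p = 1.3 (observed, incl. 0.1 bleach),
# k_12p = 1.2, k_2p1 = 2.6, a = 0.25
two_state_study_spec <- function(seed, n_molecules = 1500L) {
  tm <- matrix(c(0, 1.0, 0.2,
                 2.6, 0, 0.3,
                 2.6, 0.5, 0), 3, 3, byrow = TRUE)
  simulation_spec(
    3, diffusion = c(0.01, 0.05, 0.52), dissoc_rate = c(0.05, 1.2, 1.2),
    transition_rates = tm, bleach_rate = 0.1, loc_error = 0.023,
    movie_duration = 30, n_molecules = n_molecules,
    init_state_probs = c(0.25, 0.55, 0.20), seed = seed)
}

two_state_study_truth <- c(k_off1 = 0.15, k_off2p = 1.3,
                           k_12p = 1.2, k_2p1 = 2.6, a = 0.25)

# reference dissociation / diffusion parameters used as generative truth
ref_k_lowPIP3 <- c(0.22, 1.37, 5.01)   # DdPTEN, high-PIP3 membrane
ref_q_lowPIP3 <- c(0.03, 0.22, 0.75)
ref_D <- c(0.01, 0.05, 0.52)           # DdPTEN, low-PIP3 membrane
ref_qD <- c(0.67, 0.30, 0.03)

# single-state displacement factory: tracks with known D, eps
single_state_displacements <- function(D, eps, n_molecules = 2100L,
                                       dissoc = 0.6, seed = 1L) {
  spec <- simulation_spec(1, diffusion = D, dissoc_rate = dissoc,
                          loc_error = eps, movie_duration = 60,
                          n_molecules = n_molecules, seed = seed)
  simulate_ensemble(spec)
}
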