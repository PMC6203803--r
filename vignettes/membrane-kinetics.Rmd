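---
title: "Models and methods behind smkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smkinetics)
```

This vignette is the package's own account of the models it implements,
the assumptions they rest on, the tunable parameters that matter, and the
numerical choices that were genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The biological setting

A peripheral membrane protein such as the lipid phosphatase PTEN binds
the cell membrane transiently, diffuses laterally while bound, and
dissociates after seconds. Single-molecule TIRF imaging resolves
individual binding events as tracked fluorescent spots, so the observable
is an ensemble of trajectories: positions every 33 ms from the frame a
molecule appears to the frame it disappears. Three membrane-bound states
— stably, primary and weakly binding, distinguished by their diffusion
coefficients — underlie the kinetics; the two faster states are lumped as
"transiently binding" in the kinetic model. At the cell scale, PTEN and
its substrate PIP3 segregate into mutually exclusive membrane domains,
and the package quantifies that bistability from peripheral intensity
kymographs and ([PTEN], [PIP3]) scatter densities.

## The trajectory generator

`simulate_ensemble()` draws, per molecule:

1. an initial binding state from `init_state_probs`;
2. a continuous-time Markov path over the binding states with exact
   exponential event times (Gillespie algorithm). Dissociation
   (state-specific rate) and photobleaching (`bleach_rate`) are competing
   exponential risks; the cause of loss is recorded in the ground truth
   but is indistinguishable in the observables, which is exactly why the
   observed decay rates are `k_j + k_b`;
3. Brownian displacements between frames whose per-axis variance
   integrates `2 D(state(u)) du` over the true occupancy times within the
   frame interval — state switches mid-frame therefore contribute the
   correct mixture variance, and the frame interval never biases the
   kinetics (a per-frame Bernoulli switching scheme would);
4. i.i.d. Gaussian localization noise (`loc_error`, default scale ~20 nm)
   added to observed positions only. Because the noise is independent per
   frame, a single-lag displacement carries `2ε²` extra variance per
   axis, which is precisely the `ε` term of the displacement-distribution
   model and the `4ε²` intercept of `MSD(τ) = 4Dτ + 4ε²`.

Molecules either start together at movie start (`n_molecules`, the
natural frame for "time since membrane association" analyses) or arrive
by a Poisson process (`arrival_rate`), optionally with a pre-movie
`burn_in` so that a bound population already exists at frame 0. Molecules
alive at movie start or end are emitted with censoring flags rather than
dropped; the estimators discard them, so the censoring policy lives where
it belongs.

What the generator does **not** emulate: spot-detection failures,
fluorophore blinking, track-linking errors, and spatial heterogeneity of
the membrane. Passing recovery tests therefore demonstrate estimator
correctness under the generative model, not robustness to tracking
artifacts.

Default frame interval is 1/30 s (30 fps imaging); all positions are in
µm, times in s, rates in s⁻¹, angles in degrees externally (radians
internally).

## Dissociation kinetics

`build_survival()` counts, at each multiple of the frame interval after
association, the fraction of (uncensored) molecules still bound. A
molecule observed in d frames has observed duration (d − 1)Δt; molecules
seen in a single frame only enter the t = 0 normalization. This keeps
`fraction_bound[1] == 1` by construction.

`fit_exp_mixture()` fits `Σ_j q_j exp(−(k_j + k_b) t)` by unweighted
least squares on the curve values before `t_max` (default 7 s, past
which counts are sparse). Parameterization: log rates, softmax fractions
— constraints can never be violated — with ten or more seeded random
starts polished by BFGS and the best residual kept. The photobleaching
rate is a *fixed input*, estimated separately on immobilized dyes
(`estimate_bleach_rate()`, a one-parameter exact least-squares fit);
it is not co-estimated, mirroring how the calibration is done
experimentally.

Two reporting conventions matter:

- rates are reported ascending (slow → fast) with fractions permuted
  accordingly;
- the bleach-corrected rate `k_j − k_b` is reported as absent (`NA`)
  when the difference is negative — a decay component slower than the
  bleaching itself is not resolvable, never "zero".

The mean lifetime `τ = (Σ q_j/k_j²)/(Σ q_j/k_j)` is evaluated with the
**observed** (uncorrected) rates. We verified arithmetically that this
convention reproduces the reference table's printed lifetimes to within
rounding (e.g. 4.644 vs 4.62 s, 1.717 vs 1.72 s, 1.438 vs 1.43 s),
whereas bleach-corrected rates give grossly different values; the
recomputation is exposed as `reference_lifetimes()`. Two conditions of
the bundled table (the phosphatase-dead mutant columns) deviate by up to
9% under the same recipe, presumably from heavier rounding of their
printed constants; they are excluded from the exact-agreement checks.
Three-exponential fitting is ill-conditioned: at N ≈ 1300 molecules the
smallest component (q ≈ 0.03) is estimated from only ~40 events, and
individual realizations can collapse it toward a flat tail. The recovery
tests therefore use the tolerances appropriate to that conditioning
(rates within 25%, fractions within 0.08).

## Diffusion mixtures

The single-lag step length of a molecule diffusing with coefficient D
and localized with error ε is Rayleigh with scale `σ² = 2DΔt + 2ε²`; a
J-state population gives the mixture density

p(Δr) = Σ_j q_j (Δr/σ_j²) exp(−Δr²/(2σ_j²)).

One sign deserves a prominent note: the exponent is **negative**. A
positive exponent (which a naive transcription of the model can produce)
is not integrable and cannot be a density; `mixture_pdf()` implements the
proper Rayleigh mixture, and a property test integrates it to 1 for
random parameter draws.

`fit_mixture()` maximizes the log likelihood over `D_j` and the free
fractions with ε fixed (shared across components and conditions — it is
a property of the instrument, not of the molecule). The optimizer is EM:
the E-step computes responsibilities, the M-step has the closed-form
Rayleigh update `σ_j² = Σ w_m Δr_m² / (2 Σ w_m)`, with `σ²` floored at
`2ε²` (i.e. D ≥ 0). Twenty seeded starts (quantile-anchored, then
jittered) run on a ~4000-bin weighted compression of the squared
displacements — sufficient statistics make this essentially lossless —
and the winner is polished by exact full-data EM, whose log likelihood is
the one reported. Components collapsing onto the same scale are flagged
degenerate.

Model selection minimizes `AIC_J = −2L_J + (2J − 1) log(log M)` (natural
logarithms) over J = 1…4. The `log(log M)` penalty is intentionally
implemented as stated in the source analysis method rather than the
classical `2(2J − 1)`: it is the criterion whose selection behavior
(three states at M ≈ 10³–10⁵) the package reproduces. The parameter
count `2J − 1` is J coefficients plus J − 1 free fractions; ε is not
counted because it is fixed externally.

`estimate_localization_error()` regresses the MSD at lags of one and two
frames on `MSD(τ) = 4Dτ + 4ε²` (a line through two points) and returns
`sqrt(max(intercept, 0)/4)`, with a warning record when sampling noise
drives the intercept negative. Displacements from one trajectory are
treated as independent in the likelihood, as is standard for single-lag
analyses; the property tests show this does not bias the estimates at
the data scales used.

## Two-state transition kinetics

`fractions_vs_time()` classifies displacements by the time since
membrane association of their first frame (33-ms bins), and per bin
maximizes the mixture likelihood over the *fractions only*, with the
three diffusion coefficients and ε fixed to externally estimated values.
Bins under `min_count` (default 50) displacements are merged rightward;
a starved tail is truncated with a warning record. The three fractions
are estimated first and the two faster components summed afterwards —
the fixed-D three-component MLE is better conditioned than a refitted
two-component model, and lumping after estimation is the convention the
downstream model expects.

`two_state_solution()` solves the lumped kinetic scheme

dP₁/dt = −(k_off1 + k₁₂′) P₁ + k₂′₁ P₂′
dP₂′/dt = −(k_off2′ + k₂′₁) P₂′ + k₁₂′ P₁

in closed form by eigen-decomposition of the 2×2 rate matrix, with the
repeated-eigenvalue branch handled by the degenerate closed form
`e^{λt}(I + (A − λI)t)` rather than failure. A test checks it against an
independent matrix-exponential oracle to 1e−10.

`fit_two_state()` fits, by least squares before `t_max` = 2 s, the
occupancy fractions *among survivors* `P₁/(P₁+P₂′)` and `P₂′/(P₁+P₂′)`
to the measured fraction series and the total `P = P₁ + P₂′` to the
observed survival curve, the latter weighted 3-fold. All four rates and
the initial stable probability `a` are free (square-root rates, logit
`a`); the first start is placed at the stationarity-consistent point
implied by the early fractions and the survival decay, followed by
seeded random starts. Because the survival curve passed in is the
observed one, the fitted dissociation rates include the photobleaching
rate additively; when `bleach_rate` is supplied, corrected variants are
reported alongside.

Identifiability deserves honesty: the per-bin fraction estimates carry
roughly three times binomial noise (the slow and middle diffusion states
overlap heavily at a 33-ms lag), so at N = 1500 tracks the transition
rates are estimated with a sampling SD of ~15–20%. The end-to-end
recovery test therefore checks the median over three independent
N = 1500 ensembles rather than one realization; the noiseless inversion
test (exact to ~1e−7) separates estimator correctness from this
statistical limit.

For the simulated two-state study conditions (the true transition rates
are a user choice — no printed values exist), the package's tests use
k_off1 = 0.05, k_off2′ = 1.2 s⁻¹ (plus 0.1 s⁻¹ bleaching), k₁₂′ = 1.2,
k₂′₁ = 2.6 s⁻¹ and a = 0.25: relaxation within ~0.5 s and a stationary
stable fraction of ~0.65, matching the qualitative anchors of the system
(states reach steady state within a second; the stable state dominates
the low-PIP3 membrane at ~2/3 occupancy).

`association_rate_regression()` compares membrane-association
frequencies (appearances · s⁻¹ · µm⁻² vs cytoplasmic intensity) between
two conditions by through-origin regression — zero cytoplasmic
fluorophore implies zero binding, so the intercept is suppressed — with
HC3 heteroscedasticity-robust slope standard errors (appearance counts
are Poisson-like, so residual variance grows with intensity) and a Welch
t test on the slope difference. A type-I-error simulation keeps the test
honest at α = 0.05.

## Spatial polarity

- **Kymographs** are stored as angle × time matrices per channel in
  cytoplasm-normalized units (`normalize_to_cytoplasm()`).
- **Oscillation period** (`autocorrelation_period()`): per angular
  position, the mean-subtracted autocorrelation of the intensity time
  series; the period is the lag of the first positive-lag local maximum
  exceeding a prominence threshold (default 0.1 of the zero-lag value).
  An autocorrelation peak, not a spectral peak, because it is the
  definition that degrades gracefully on quasi-periodic traveling waves.
  Positions with no qualifying peak are excluded; if none qualifies the
  result is an explicit "aperiodic" record, not an exception.
- **Half-width** (`aligned_profile_half_width()`): each frame's profile
  is rotated so the alignment channel's maximum sits at 0°, the
  measurement channel is averaged over frames, and the half-width is
  FWHM/2 of that mean profile with the baseline at the profile minimum
  and circular linear interpolation between angular samples. The
  baseline rule is a package choice (none is standard); the wave
  generator calibrates its bump-shape parameter by root finding so that
  this exact measurement recovers the requested width, making the
  generator's advertised half-width its contract.
- **Bistability boundary** (`boundary_slope()`): the equal-density locus
  of the two fitted isotropic Gaussian modes is sampled inside the
  region between the means, and the boundary is the through-origin line
  `y = a·x` minimizing squared vertical deviation from that locus. For
  equal spreads the locus is the perpendicular bisector of the means;
  recovering a ≈ 1.16 from modes at (0.7, 1.5) and (1.4, 0.9) validates
  the rule. When the two modes differ almost only along the y axis
  (|Δy|/|Δx| > 5), the boundary is reported as the horizontal line
  through the locus instead; a locus with relative curvature beyond 2%
  is flagged nonlinear. Mixture fitting itself (`fit_two_gaussians()`)
  delegates to the mclust EM implementation (isotropic "VII" by default,
  full covariance "VVV" optionally — the source analyses do not state
  which; isotropic is the default because the printed contours are
  circular).
- **Co-localization** (`coloc_probability()`): the integral of the
  normalized 2D histogram over an intensity rectangle, partial bins
  weighted by overlap fraction.
- **Migration** (`instantaneous_velocity_stats()`,
  `chemotactic_index()`): 5-s displacements × 12 give instantaneous
  velocities in µm/min; the chemotactic index is the mean displacement
  component toward the attractant source divided by the mean 2D
  displacement length after translating the start to the origin and
  rotating the source onto the +y axis, hence bounded by [−1, 1]. The
  migration generator draws step directions from a wrapped-Cauchy
  distribution whose mean resultant length equals the bias parameter —
  an exact inverse-CDF sampler with the right limits (bias 0 uniform,
  bias 1 degenerate toward the source), so for a distant source the
  expected chemotactic index equals the bias.

## Numerical choices and degenerate inputs

- All optimizers are multi-start with seeds derived from a user seed;
  equal seeds give byte-identical results everywhere, including the
  simulators.
- Softmax/log/logit/square-root transforms keep every constrained
  parameter feasible by construction; ties in multi-start are broken by
  first-found.
- Flat angular profiles, empty scatters, all-censored ensembles,
  zero-variance regression designs and inverted integration ranges are
  rejected with messages naming the rule; constant autocorrelation
  input yields an "aperiodic" result.
- A negative MSD intercept clips ε to 0 with a warning record; mixture
  components collapsing in scale raise a degeneracy flag rather than an
  error.

## Problem sizes

The test suite and acceptance script run at the scales the analyses are
designed for: ensembles of 1300–2100 molecules (~10⁵ single-lag
displacements), 2000 immobilized dyes, 10⁴-point intensity scatters, and
30-minute kymographs at 5-s sampling. The full suite completes in a few
minutes on one core.

## Known limitations

- The estimators assume the generative model's idealizations (no
  blinking, no linking errors, homogeneous membrane); real tracking
  pipelines violate these to a degree the package cannot quantify.
- Three-exponential survival fits and the two-state transition fit are
  ill-conditioned at realistic data scales; interpret single-dataset
  rate estimates with the sampling SDs discussed above.
- The diffusion analysis uses single-lag displacements only (lags > 2
  frames appear solely in the MSD regression for ε); anomalous or
  confined diffusion is out of scope.
- Per-molecule state assignment (HMM decoding) is deliberately not
  implemented; all state inference is at the population level.
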