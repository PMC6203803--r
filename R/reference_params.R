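#' Reference single-molecule membrane-binding parameters for PTEN
#'
#' Published single-molecule TIRF estimates for DdPTEN, the phosphatase-dead
#' DdPTEN G129E mutant, and HsPTEN on low- and high-PIP3 membranes:
#' triple-exponential dissociation rate constants (observed, and corrected
#' by the photobleaching rate of 0.1 1/s; `NA` where the correction is not
#' resolvable), their fractions, fit residuals, mean lifetimes, the three
#' diffusion coefficients with their fractions, and the data sizes. Shipped
#' as a plain-text table; used as the worked-example fixture for the
#' estimators and as generative truth for recovery tests.
#'
#' @return data.frame with one row per condition.
#' @export
pten_reference_params <- function() {
  path <- system.file("extdata", "pten_membrane_binding_params.csv",
                      package = "smkinetics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute mean membrane-binding lifetimes from the reference constants
#'
#' Applies the intensity-weighted mean-lifetime formula
#' tau = (sum q_j / k_j^2) / (sum q_j / k_j), with the observed
#' (uncorrected) rate constants, to every condition of
#' [pten_reference_params()], alongside the published lifetime for
#' comparison.
#'
#' @return data.frame with `condition`, `lifetime_recomputed_s`,
#'   `lifetime_published_s`.
#' @export
reference_lifetimes <- function() {
  p <- pten_reference_params()
  tau <- vapply(seq_len(nrow(p)), function(i)
    mean_lifetime(list(rates_observed = c(p$k1[i], p$k2[i], p$k3[i]),
                       fractions = c(p$qk1[i], p$qk2[i], p$qk3[i]))),
    numeric(1))
  data.frame(condition = p$condition,
             lifetime_recomputed_s = tau,
             lifetime_published_s = p$lifetime_s)
}
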