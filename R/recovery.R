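#' Injected-effect recovery experiments
#'
#' Repeatedly simulates cohorts under the calibrated generative model with a
#' known injected per-SD effect, runs the full pipeline (genotypes -> PRS ->
#' adjusted model) on each, and collects the fitted per-SD estimates. These
#' experiments are how the package validates itself in the absence of the
#' restricted real cohort: the average fitted estimate must reproduce the
#' injected one within Monte-Carlo error.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n Cohort size (default 967).
#' @param effect_per_sd Injected linear per-SD effect (continuous mode).
#' @param seed_base Cohort k uses seeds derived from \code{seed_base + k}.
#' @param weights,allele_freqs,noise Optional precomputed pieces; calibrated
#'   once from the defaults when NULL.
#' @return \code{recover_linear}: numeric vector of fitted per-SD linear
#'   coefficients, one per cohort.
#' @export
recover_linear <- function(n_cohorts, n = 967, effect_per_sd = -0.63,
                           seed_base = 0, weights = NULL, allele_freqs = NULL,
                           noise = NULL) {
  if (is.null(weights)) weights <- bdr_weight_table()
  if (is.null(allele_freqs)) allele_freqs <- calibrate_allele_freqs(weights)
  if (is.null(noise)) noise <- calibrate_bdr_noise(effect_per_sd = effect_per_sd)
  vapply(seq_len(n_cohorts), function(k) {
    cfg <- simulation_config(n = n, seed = seed_base + 3L * k,
                             weights = weights, allele_freqs = allele_freqs,
                             mode = "continuous", effect_per_sd = effect_per_sd,
                             noise = noise)
    sim <- simulate_cohort(cfg)
    fit_linear_adjusted(sim$cohort, sim$prs)$estimate
  }, numeric(1))
}

#' @rdname recover_linear
#' @param or_per_sd Injected odds ratio per SD (threshold mode).
#' @param threshold BDR cut-point, 12 or 8; sets the target marginal
#'   prevalence (166/967 or 275/967).
#' @return \code{recover_logistic}: numeric vector of fitted log odds
#'   ratios per SD, one per cohort.
#' @export
recover_logistic <- function(n_cohorts, n = 967, or_per_sd = 0.80,
                             threshold = 12, seed_base = 0, weights = NULL,
                             allele_freqs = NULL) {
  if (is.null(weights)) weights <- bdr_weight_table()
  if (is.null(allele_freqs)) allele_freqs <- calibrate_allele_freqs(weights)
  vapply(seq_len(n_cohorts), function(k) {
    cfg <- simulation_config(n = n, seed = seed_base + 3L * k,
                             weights = weights, allele_freqs = allele_freqs,
                             mode = "threshold_logistic", or_per_sd = or_per_sd,
                             threshold = threshold)
    sim <- simulate_cohort(cfg)
    fit_logistic_threshold(sim$cohort, sim$prs, threshold)$estimate
  }, numeric(1))
}
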