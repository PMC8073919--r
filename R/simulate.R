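#' Simulation configuration for synthetic BDR cohorts
#'
#' Bundles the generative parameters of the synthetic cohort. Defaults are
#' the study conditions of the cohort the generator emulates: n = 967
#' school-aged children, a 16-variant score with allele frequencies
#' calibrated so the raw PRS has mean 3.84 and SD 7.41, a BDR noise mixture
#' calibrated to marginal mean 5.6\%, SD 10.2\% and exceedance fractions
#' 166/967 (>= 12\%) and 275/967 (>= 8\%), and injected per-SD effects of
#' -0.63 BDR \% (continuous mode) or odds ratio 0.80 (threshold mode).
#'
#' @param n Cohort size.
#' @param seed Base integer seed; genotypes, covariates and outcomes use
#'   \code{seed}, \code{seed + 1}, \code{seed + 2} in that order.
#' @param weights A \code{weight_table} (default: the packaged 16-variant
#'   table).
#' @param allele_freqs Per-variant effect-allele frequencies; if NULL they
#'   are calibrated with [calibrate_allele_freqs()].
#' @param mode \code{"continuous"} or \code{"threshold_logistic"}.
#' @param effect_per_sd True linear per-SD effect on BDR \% (continuous
#'   mode).
#' @param or_per_sd True odds ratio per SD (threshold mode).
#' @param threshold BDR cut-point for threshold mode (12 or 8).
#' @param noise \code{mixture_params}; if NULL, calibrated with
#'   [calibrate_bdr_noise()].
#' @param covariate_params See [simulate_covariates()].
#' @param prevalence Marginal responder fraction targeted in threshold mode;
#'   default 166/967 at the 12\% cut-point and 275/967 at 8\%.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n = 967, seed = 1, weights = bdr_weight_table(),
                              allele_freqs = NULL, mode = c("continuous", "threshold_logistic"),
                              effect_per_sd = -0.63, or_per_sd = 0.80,
                              threshold = 12, noise = NULL,
                              covariate_params = default_covariate_params(),
                              prevalence = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 2, inherits(weights, "weight_table"))
  if (is.null(allele_freqs)) {
    allele_freqs <- calibrate_allele_freqs(weights)
  }
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.null(noise) && mode == "continuous") {
    noise <- calibrate_bdr_noise(effect_per_sd = effect_per_sd)
  }
  if (is.null(prevalence)) {
    prevalence <- if (threshold == 8) 275 / 967 else 166 / 967
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), weights = weights,
         allele_freqs = allele_freqs, mode = mode,
         effect_per_sd = effect_per_sd, or_per_sd = or_per_sd,
         threshold = threshold, noise = noise,
         covariate_params = covariate_params, prevalence = prevalence),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @export
default_covariate_params <- function() {
  list(age_mean = 9.3, age_sd = 1.9, age_min = 6, age_max = 14,
       male_fraction = 0.59,
       bmi_probs = c(normal = 0.65, underweight = 0.03,
                     overweight = 0.15, obese = 0.17),
       visits_median = 3, visits_q1 = 1, visits_q3 = 5,
       n_pcs = 6)
}

prs_moments <- function(p, beta) {
  c(mean = sum(2 * p * beta), var = sum(2 * p * (1 - p) * beta^2))
}

#' Calibrate HWE allele frequencies to target raw-PRS moments
#'
#' Finds per-variant effect-allele frequencies p_j in [0.01, 0.99] such
#' that, under Hardy-Weinberg equilibrium and linkage equilibrium, the raw
#' score has the target mean and SD:
#' \code{sum(2 p_j beta_j) = target_mean} and
#' \code{sum(2 p_j (1 - p_j) beta_j^2) = target_sd^2}.
#' The system is underdetermined (16 unknowns, 2 equations); a deterministic
#' least-norm Gauss-Newton iteration from the fixed start p_j = 0.3 picks
#' one solution, with a bounded least-squares fallback.
#'
#' @param weights A \code{weight_table}.
#' @param target_mean Target raw-PRS mean (default 3.84).
#' @param target_sd Target raw-PRS SD (default 7.41).
#' @return Named vector of frequencies (by rsID), with both moments matched
#'   within 1e-6.
#' @export
calibrate_allele_freqs <- function(weights, target_mean = 3.84, target_sd = 7.41) {
  stopifnot(inherits(weights, "weight_table"))
  beta <- weights$beta
  lo_mean <- 2 * sum(beta[beta < 0])
  hi_mean <- 2 * sum(beta[beta > 0])
  max_var <- sum(beta^2) / 2
  if (target_mean < lo_mean || target_mean > hi_mean) {
    stop(sprintf("infeasible target mean %.4g: achievable range is [%.4g, %.4g]",
                 target_mean, lo_mean, hi_mean), call. = FALSE)
  }
  if (target_sd^2 > max_var * (1 + 1e-12)) {
    stop(sprintf("infeasible target variance %.4g: maximum achievable is %.4g",
                 target_sd^2, max_var), call. = FALSE)
  }
  targets <- c(target_mean, target_sd^2)
  g <- function(p) {
    m <- prs_moments(p, beta)
    c(m["mean"] - targets[1], m["var"] - targets[2])
  }
  p <- rep(0.3, length(beta))
  for (it in 1:200) {
    r <- g(p)
    if (max(abs(r)) < 1e-10) break
    jac <- rbind(2 * beta, 2 * (1 - 2 * p) * beta^2)
    step <- -crossprod(jac, solve(tcrossprod(jac) + 1e-12 * diag(2), r))
    p_new <- pmin(0.99, pmax(0.01, p + as.numeric(step)))
    # damp if the step overshoots
    if (sum(g(p_new)^2) > sum(r^2)) {
      for (h in 1:30) {
        p_try <- pmin(0.99, pmax(0.01, p + as.numeric(step) / 2^h))
        if (sum(g(p_try)^2) < sum(r^2)) { p_new <- p_try; break }
      }
    }
    p <- p_new
  }
  if (max(abs(g(p))) >= 1e-6) {
    obj <- function(q) sum(g(q)^2)
    opt <- optim(p, obj, method = "L-BFGS-B", lower = 0.01, upper = 0.99,
                 control = list(maxit = 500, factr = 1))
    p <- opt$par
  }
  if (max(abs(g(p))) >= 1e-6) {
    stop("allele-frequency calibration did not reach tolerance; residuals: ",
         paste(signif(g(p), 4), collapse = ", "), call. = FALSE)
  }
  setNames(p, weights$rsid)
}

#' Two-component Gaussian mixture parameters for BDR noise
#'
#' @param weight_1 Mixing proportion of the first component, in (0, 1).
#' @param mu_1,sigma_1,mu_2,sigma_2 Component means and SDs (BDR \%).
#' @return A list of class \code{mixture_params}.
#' @export
mixture_params <- function(weight_1, mu_1, sigma_1, mu_2, sigma_2) {
  stopifnot(weight_1 > 0, weight_1 < 1, sigma_1 > 0, sigma_2 > 0)
  structure(list(weight_1 = weight_1, mu_1 = mu_1, sigma_1 = sigma_1,
                 mu_2 = mu_2, sigma_2 = sigma_2),
            class = "mixture_params")
}

# marginal functionals of BDR = effect * Z + mixture noise, Z ~ N(0,1)
mixture_marginal <- function(par, effect, thresholds) {
  w <- par$weight_1
  v1 <- par$sigma_1^2 + effect^2
  v2 <- par$sigma_2^2 + effect^2
  m <- w * par$mu_1 + (1 - w) * par$mu_2
  ex2 <- w * (par$mu_1^2 + v1) + (1 - w) * (par$mu_2^2 + v2)
  tail <- function(t) {
    w * pnorm(t, par$mu_1, sqrt(v1), lower.tail = FALSE) +
      (1 - w) * pnorm(t, par$mu_2, sqrt(v2), lower.tail = FALSE)
  }
  c(mean = m, sd = sqrt(ex2 - m^2),
    p_hi = tail(thresholds[1]), p_lo = tail(thresholds[2]))
}

#' Calibrate the BDR noise mixture to marginal targets
#'
#' Solves for the five parameters of a two-component Gaussian mixture so
#' that the MARGINAL BDR distribution under the full generative model
#' (injected per-SD effect times a standard-normal PRS, plus mixture noise)
#' matches four targets: mean, SD, and the exceedance fractions at two
#' cut-points. A single normal cannot fit the printed targets (it would put
#' ~26\% above 12 and ~41\% above 8), so the mixture is the minimal family.
#' Deterministic: fixed start (75:25 mixture near N(2, 6^2) and
#' N(16.4, 12.35^2)) and a fixed optimizer sequence (nlminb, then BFGS
#' polish if needed).
#'
#' @param target_mean Marginal BDR mean (default 5.6).
#' @param target_sd Marginal BDR SD (default 10.2).
#' @param p_ge_hi Target fraction at or above the upper cut-point
#'   (default 166/967).
#' @param p_ge_lo Target fraction at or above the lower cut-point
#'   (default 275/967).
#' @param effect_per_sd Injected linear per-SD effect (default -0.63).
#' @param thresholds The two cut-points (default c(12, 8)).
#' @return A \code{mixture_params} whose sum of squared relative errors over
#'   the four targets is below 1e-6.
#' @export
calibrate_bdr_noise <- function(target_mean = 5.6, target_sd = 10.2,
                                p_ge_hi = 166 / 967, p_ge_lo = 275 / 967,
                                effect_per_sd = -0.63,
                                thresholds = c(12, 8)) {
  if (p_ge_hi >= p_ge_lo) {
    stop("exceedance at the upper cut-point must be below the lower one (",
         signif(p_ge_hi, 4), " >= ", signif(p_ge_lo, 4), ")", call. = FALSE)
  }
  targets <- c(mean = target_mean, sd = target_sd, p_hi = p_ge_hi, p_lo = p_ge_lo)
  obj <- function(theta) {
    par <- list(weight_1 = theta[1], mu_1 = theta[2], sigma_1 = theta[3],
                mu_2 = theta[4], sigma_2 = theta[5])
    got <- mixture_marginal(par, effect_per_sd, thresholds)
    sum(((got - targets) / targets)^2)
  }
  start <- c(0.75, 2, 6, 16.4, 12.35)
  lower <- c(0.01, -60, 0.05, -60, 0.05)
  upper <- c(0.99, 60, 60, 60, 60)
  fit <- nlminb(start, obj, lower = lower, upper = upper,
                control = list(iter.max = 2000, eval.max = 4000,
                               abs.tol = 0, rel.tol = 1e-14))
  theta <- fit$par
  if (obj(theta) >= 1e-6) {
    polish <- optim(theta, obj, method = "L-BFGS-B", lower = lower,
                    upper = upper, control = list(maxit = 2000, factr = 1))
    if (polish$value < obj(theta)) theta <- polish$par
  }
  if (obj(theta) >= 1e-6) {
    got <- mixture_marginal(
      list(weight_1 = theta[1], mu_1 = theta[2], sigma_1 = theta[3],
           mu_2 = theta[4], sigma_2 = theta[5]), effect_per_sd, thresholds)
    stop("noise calibration did not reach tolerance; achieved (mean, sd, p_hi, p_lo) = ",
         paste(signif(got, 5), collapse = ", "), " vs targets ",
         paste(signif(targets, 5), collapse = ", "), call. = FALSE)
  }
  mixture_params(theta[1], theta[2], theta[3], theta[4], theta[5])
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Independent Binomial(2, p_j) draws per individual and variant (HWE,
#' linkage equilibrium across variants).
#'
#' @param allele_freqs Named effect-allele frequencies (names = rsIDs).
#' @param n Number of individuals.
#' @param seed Integer seed; identical seed and frequencies give an
#'   identical matrix.
#' @return A \code{dosage_matrix} of hard calls.
#' @export
simulate_genotypes <- function(allele_freqs, n, seed) {
  stopifnot(all(allele_freqs >= 0), all(allele_freqs <= 1), n >= 1)
  set.seed(seed)
  m <- length(allele_freqs)
  dos <- matrix(rbinom(n * m, size = 2,
                       prob = rep(allele_freqs, each = n)), nrow = n, ncol = m)
  ids <- names(allele_freqs)
  if (is.null(ids)) ids <- paste0("var", seq_len(m))
  dosage_matrix(dos, sprintf("S%04d", seq_len(n)), ids)
}

fit_visits_nb <- local({
  cache <- new.env(parent = emptyenv())
  function(median_target = 3, q1_target = 1, q3_target = 5) {
    key <- paste(median_target, q1_target, q3_target)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # deterministic grid search over (size, mu) matching the quartiles
    sizes <- seq(0.4, 8, by = 0.05)
    mus <- seq(1.5, 6, by = 0.05)
    best <- NULL
    best_loss <- Inf
    for (size in sizes) {
      q <- qnbinom(c(0.25, 0.5, 0.75), size = size, mu = rep(mus, each = 3))
      qm <- matrix(q, nrow = 3)
      prim <- colSums((qm - c(q1_target, median_target, q3_target))^2)
      for (k in which(prim == min(prim))) {
        mu <- mus[k]
        sec <- sum((pnbinom(c(q1_target, median_target, q3_target),
                            size = size, mu = mu) - c(0.25, 0.5, 0.75))^2)
        loss <- prim[k] * 1e6 + sec
        if (loss < best_loss) {
          best_loss <- loss
          best <- c(size = size, mu = mu)
        }
      }
    }
    cache[[key]] <- best
    best
  }
})

#' Simulate cohort covariates
#'
#' Age from a Normal(9.3, 1.9) truncated to 6-14 years (inverse-CDF
#' sampling), sex Bernoulli(0.59) male, BMI category
#' Categorical(0.65, 0.03, 0.15, 0.17) over (normal, underweight,
#' overweight, obese), asthma doctor visits from a negative binomial whose
#' (size, mu) are grid-fitted so the quartiles are (1, 3, 5), and six iid
#' standard-normal PC columns. Covariates carry no effect on BDR in the
#' generative model.
#'
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param params List as produced by [default_covariate_params()].
#' @return A data.frame of covariate columns (no outcome).
#' @export
simulate_covariates <- function(n, seed, params = default_covariate_params()) {
  stopifnot(abs(sum(params$bmi_probs) - 1) < 1e-8)
  set.seed(seed)
  lo <- pnorm(params$age_min, params$age_mean, params$age_sd)
  hi <- pnorm(params$age_max, params$age_mean, params$age_sd)
  age <- qnorm(lo + runif(n) * (hi - lo), params$age_mean, params$age_sd)
  sex <- ifelse(runif(n) < params$male_fraction, "male", "female")
  bmi <- sample(names(params$bmi_probs), n, replace = TRUE,
                prob = params$bmi_probs)
  nb <- fit_visits_nb(params$visits_median, params$visits_q1, params$visits_q3)
  visits <- rnbinom_det(n, nb["size"], nb["mu"])
  pcs <- matrix(rnorm(n * params$n_pcs), nrow = n)
  colnames(pcs) <- paste0("PC", seq_len(params$n_pcs))
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             age_years = age, sex = sex, bmi_category = bmi,
             doctor_visits = visits, pcs,
             stringsAsFactors = FALSE)
}

rnbinom_det <- function(n, size, mu) {
  stats::qnbinom(runif(n), size = size, mu = mu)
}

#' Simulate BDR outcomes given standardized PRS values
#'
#' Continuous mode: \code{BDR_i = effect_per_sd * z_i + eps_i} with eps
#' drawn from the calibrated two-component Gaussian mixture. Threshold mode:
#' responder_i ~ Bernoulli(expit(alpha + log(or_per_sd) * z_i)) with alpha
#' solved numerically so the expected marginal prevalence over the cohort's
#' z values equals the target.
#'
#' @param prs_z Standardized PRS values (mean 0, SD 1).
#' @param config A \code{simulation_config}.
#' @param seed Integer seed.
#' @return Continuous mode: numeric BDR \%. Threshold mode: integer 0/1
#'   responder flags.
#' @export
simulate_bdr <- function(prs_z, config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(prs_z)
  set.seed(seed)
  if (config$mode == "continuous") {
    if (is.null(config$noise)) {
      stop("continuous mode requires calibrated noise parameters", call. = FALSE)
    }
    mx <- config$noise
    comp1 <- runif(n) < mx$weight_1
    mu <- ifelse(comp1, mx$mu_1, mx$mu_2)
    sg <- ifelse(comp1, mx$sigma_1, mx$sigma_2)
    config$effect_per_sd * prs_z + rnorm(n, mu, sg)
  } else {
    b <- log(config$or_per_sd)
    alpha <- uniroot(function(a) mean(plogis(a + b * prs_z)) - config$prevalence,
                     lower = -30, upper = 30, tol = 1e-12)$root
    rbinom(n, 1, plogis(alpha + b * prs_z))
  }
}

#' Simulate a complete cohort in memory
#'
#' Runs the generative model end to end: HWE genotypes at the calibrated
#' allele frequencies, raw and standardized PRS with the weight table,
#' covariates, and BDR outcomes with the injected per-SD effect. Sub-seeds:
#' genotypes use \code{config$seed}, covariates \code{config$seed + 1},
#' outcomes \code{config$seed + 2}.
#'
#' @param config A \code{simulation_config}.
#' @return A list with \code{dosages} (\code{dosage_matrix}), \code{prs}
#'   (standardized \code{prs_result}), \code{cohort} (\code{cohort_table}),
#'   and \code{truth} (the generative parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  dos <- simulate_genotypes(config$allele_freqs, config$n, config$seed)
  prs <- standardize(compute_prs(dos, config$weights))
  cov <- simulate_covariates(config$n, config$seed + 1L, config$covariate_params)
  out <- simulate_bdr(prs$z_score, config, config$seed + 2L)
  df <- cov
  if (config$mode == "continuous") {
    df$bdr_percent <- out
  } else {
    df$responder <- as.logical(out)
  }
  truth <- list(
    n = config$n, seed = config$seed, mode = config$mode,
    effect_per_sd = config$effect_per_sd, or_per_sd = config$or_per_sd,
    threshold = config$threshold, prevalence = config$prevalence,
    allele_freqs = as.list(config$allele_freqs),
    noise = if (!is.null(config$noise)) unclass(config$noise) else NULL,
    covariate_params = config$covariate_params
  )
  list(dosages = dos, prs = prs, cohort = cohort_table(df), truth = truth)
}

# REF allele paired with each effect (ALT) allele; chosen so no generated
# variant is palindromic (A/T or C/G)
ref_for_effect <- c(A = "C", C = "A", G = "A", T = "C")

#' Write a simulated cohort to standard files
#'
#' Emits a VCF 4.2 with hard genotype calls for the weight-table variants
#' (ALT = effect allele, REF chosen non-palindromic), a phenotype/covariate
#' CSV, and a truth JSON recording every generative parameter verbatim.
#' Re-reading the VCF with [read_dosages()] reproduces the simulated dosage
#' matrix exactly; identical config and seed give byte-identical files.
#'
#' @param config A \code{simulation_config}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "cohort").
#' @return Invisibly, a named list of the three file paths plus the
#'   in-memory simulation.
#' @export
generate_cohort <- function(config, dir, prefix = "cohort") {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_cohort(config)
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  pheno_path <- file.path(dir, paste0(prefix, "_pheno.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_cohort_vcf(sim$dosages, config$weights, vcf_path)
  write_cohort(sim$cohort, pheno_path)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(vcf = vcf_path, pheno = pheno_path, truth = truth_path,
                 sim = sim))
}

write_cohort_vcf <- function(dosages, weights, path) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  w <- weights[match(dosages$variant_ids, weights$rsid), ]
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bdrprs synthetic cohort generator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dosages$sample_ids), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(w)), function(j) {
    eff <- w$effect_allele[j]
    gts <- gt_codes[dosages$dosages[, j] + 1]
    paste(c(w$chrom[j], format(w$pos[j], scientific = FALSE), w$rsid[j],
            ref_for_effect[[eff]], eff, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
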