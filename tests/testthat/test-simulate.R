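published <- bdr_weight_table()

test_that("allele-frequency calibration matches the closed-form moments", {
  # single-variant toy: mean = 4p, so target mean 2 with beta 2 gives p = 0.5
  w1 <- toy_weights(betas = 2, alleles = "A", rsids = "rs1")
  p1 <- calibrate_allele_freqs(w1, target_mean = 2,
                               target_sd = sqrt(2 * 0.5 * 0.5 * 4))
  expect_equal(unname(p1), 0.5, tolerance = 1e-6)

  p <- calibrate_allele_freqs(published)
  expect_true(all(p >= 0.01 & p <= 0.99))
  expect_lt(abs(sum(2 * p * published$beta) - 3.84), 1e-6)
  expect_lt(abs(sum(2 * p * (1 - p) * published$beta^2) - 7.41^2), 1e-6)
  # deterministic: same inputs, same frequencies
  expect_identical(p, calibrate_allele_freqs(published))
})

test_that("infeasible moment targets are rejected with the feasible range", {
  expect_error(calibrate_allele_freqs(published, target_mean = 100),
               "infeasible target mean.*78.14")
  expect_error(calibrate_allele_freqs(published, target_sd = 50),
               "infeasible target variance")
})

test_that("BDR noise calibration reproduces all four marginal targets", {
  mx <- calibrate_bdr_noise()
  got <- bdrprs:::mixture_marginal(mx, -0.63, c(12, 8))
  expect_equal(unname(got["mean"]), 5.6, tolerance = 1e-4)
  expect_equal(unname(got["sd"]), 10.2, tolerance = 1e-4)
  expect_equal(unname(got["p_hi"]), 166 / 967, tolerance = 1e-4)
  expect_equal(unname(got["p_lo"]), 275 / 967, tolerance = 1e-4)

  # self-consistency: targets taken from a single known normal are recovered
  tm <- 2; tsd <- 3
  mx2 <- calibrate_bdr_noise(target_mean = tm, target_sd = tsd,
                             p_ge_hi = pnorm(6, tm, tsd, lower.tail = FALSE),
                             p_ge_lo = pnorm(3, tm, tsd, lower.tail = FALSE),
                             effect_per_sd = 0, thresholds = c(6, 3))
  got2 <- bdrprs:::mixture_marginal(mx2, 0, c(6, 3))
  expect_equal(unname(got2["mean"]), tm, tolerance = 1e-4)
  expect_equal(unname(got2["sd"]), tsd, tolerance = 1e-4)

  expect_error(calibrate_bdr_noise(p_ge_hi = 0.4, p_ge_lo = 0.3), "must be below")
})

test_that("a single normal cannot fit the printed BDR margins", {
  # with mean 5.6 and SD 10.2 a normal puts far more mass above the
  # cut-points than observed, which is why the noise family is a mixture
  expect_gt(pnorm(12, 5.6, 10.2, lower.tail = FALSE), 0.25)
  expect_gt(pnorm(8, 5.6, 10.2, lower.tail = FALSE), 0.40)
})

test_that("genotype simulation is HWE-consistent and seed-reproducible", {
  expect_true(all(simulate_genotypes(c(a = 0), 50, 1)$dosages == 0))
  expect_true(all(simulate_genotypes(c(a = 1), 50, 1)$dosages == 2))

  dm <- simulate_genotypes(c(v = 0.3), 100000, seed = 13)
  counts <- table(factor(dm$dosages[, 1], levels = 0:2))
  expected <- c(0.49, 0.42, 0.09) * 100000
  chi <- sum((counts - expected)^2 / expected)
  expect_gt(pchisq(chi, df = 2, lower.tail = FALSE), 0.001)

  d1 <- simulate_genotypes(c(x = 0.4, y = 0.2), 100, seed = 5)
  d2 <- simulate_genotypes(c(x = 0.4, y = 0.2), 100, seed = 5)
  expect_identical(d1$dosages, d2$dosages)
})

test_that("covariate generator matches its target descriptives", {
  n <- 50000
  cov <- simulate_covariates(n, seed = 17)
  expect_true(all(cov$age_years >= 6 & cov$age_years <= 14))
  se_male <- sqrt(0.59 * 0.41 / n)
  expect_lt(abs(mean(cov$sex == "male") - 0.59), 3 * se_male)
  se_ob <- sqrt(0.17 * 0.83 / n)
  expect_lt(abs(mean(cov$bmi_category == "obese") - 0.17), 3 * se_ob)
  q <- unname(quantile(cov$doctor_visits, c(0.25, 0.5, 0.75)))
  expect_equal(q, c(1, 3, 5))
  expect_true(all(cov$doctor_visits >= 0))
  expect_equal(colnames(cov)[grep("^PC", colnames(cov))], paste0("PC", 1:6))
})

test_that("outcome generator honors the injected effect and prevalence", {
  cfg <- simulation_config(n = 967, seed = 1)
  n <- 100000
  set.seed(2)
  z <- (function(x) (x - mean(x)) / sd(x))(rnorm(n))
  null_cfg <- cfg
  null_cfg$effect_per_sd <- 0
  y0 <- simulate_bdr(z, null_cfg, seed = 3)
  expect_lt(abs(cor(y0, z)), 3 / sqrt(n))

  thr_cfg <- simulation_config(n = 967, seed = 1, mode = "threshold_logistic",
                               threshold = 12, allele_freqs = cfg$allele_freqs)
  r <- simulate_bdr(z, thr_cfg, seed = 4)
  prev <- 166 / 967
  expect_lt(abs(mean(r) - prev), 3 * sqrt(prev * (1 - prev) / n))

  expect_identical(simulate_bdr(z, thr_cfg, seed = 4), r)
})

test_that("generated files round-trip and record the truth verbatim", {
  cfg <- simulation_config(n = 120, seed = 6)
  dir <- withr::local_tempdir()
  g <- generate_cohort(cfg, dir)
  expect_true(all(file.exists(unlist(g[c("vcf", "pheno", "truth")]))))

  dos <- read_dosages(g$vcf, cfg$weights)
  expect_identical(unname(dos$dosages), unname(g$sim$dosages$dosages))
  ch <- read_cohort(g$pheno)
  expect_equal(nrow(ch), 120)
  expect_equal(ch$bdr_percent, g$sim$cohort$bdr_percent, tolerance = 1e-10)

  truth <- jsonlite::read_json(g$truth, simplifyVector = TRUE)
  expect_equal(truth$effect_per_sd, cfg$effect_per_sd)
  expect_equal(truth$seed, cfg$seed)
  expect_equal(truth$n, 120)
})

test_that("identical config and seed give byte-identical files", {
  cfg <- simulation_config(n = 60, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- generate_cohort(cfg, d1)
  g2 <- generate_cohort(cfg, d2)
  for (f in c("vcf", "pheno", "truth")) {
    expect_identical(unname(tools::md5sum(g1[[f]])),
                     unname(tools::md5sum(g2[[f]])), label = f)
  }
})

test_that("simulated raw-PRS moments converge to the closed form", {
  cfg <- simulation_config(n = 2, seed = 1)  # for the calibrated pieces
  p <- cfg$allele_freqs
  beta <- published$beta
  mu <- sum(2 * p * beta)
  sig <- sqrt(sum(2 * p * (1 - p) * beta^2))
  n <- 100000
  dm <- simulate_genotypes(p, n, seed = 7)
  raw <- compute_prs(dm, published)$raw_score
  expect_lt(abs(mean(raw) - mu), 3 * sig / sqrt(n))
  expect_lt(abs(sd(raw) - sig), 3 * sig / sqrt(2 * (n - 1)))
})
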