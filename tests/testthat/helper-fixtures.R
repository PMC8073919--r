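# Shared fixture builders. Everything is generated in code at test time.

table1_betas <- c(-3.51, -2.70, 4.85, 3.17, -3.30, 3.63, 2.98, 3.44,
                  2.81, 5.36, -3.77, -4.23, 2.58, 3.95, 2.80, 3.50)

# a small, fully in-memory weight table
toy_weights <- function(betas = c(1.5, -2.0, 0.5),
                        alleles = c("A", "G", "T"),
                        rsids = paste0("rsT", seq_along(betas))) {
  tab <- data.frame(
    chrom = as.character(seq_along(betas)),
    pos = 1000 * seq_along(betas),
    rsid = rsids,
    effect_allele = alleles,
    beta = betas,
    p_value = NA_real_, cadd_phred = NA_real_, gene_label = NA_character_,
    stringsAsFactors = FALSE
  )
  bdrprs:::as_weight_table(tab, provenance = "toy")
}

# minimal VCF writer for hand-constructed records
write_toy_vcf <- function(path, records, sample_ids) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  rows <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT", r$gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# a cohort table with independent covariates and a chosen outcome
make_cohort <- function(n, seed, bdr = NULL, responder = NULL) {
  cov <- simulate_covariates(n, seed)
  if (n >= 4) {
    # guarantee every BMI category is observed so the design is full rank
    cov$bmi_category[1:4] <- c("normal", "underweight", "overweight", "obese")
  }
  if (!is.null(bdr)) cov$bdr_percent <- bdr
  if (!is.null(responder)) cov$responder <- responder
  if (is.null(bdr) && is.null(responder)) cov$responder <- rep(FALSE, n)
  cohort_table(cov)
}

# a standardized PRS object from arbitrary raw scores
make_prs <- function(raw, ids = sprintf("S%04d", seq_along(raw))) {
  out <- data.frame(sample_id = ids, raw_score = raw, z_score = NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- 0L
  attr(out, "weights_provenance") <- "test"
  class(out) <- c("prs_result", "data.frame")
  standardize(out)
}

# ordinary least squares by the normal equations: the independent oracle
ols_oracle <- function(x, y) {
  as.numeric(solve(crossprod(x), crossprod(x, y)))
}

# direct maximization of the logistic log-likelihood: the independent oracle
logistic_loglik <- function(b, x, y) {
  eta <- as.numeric(x %*% b)
  sum(y * eta - log1p(exp(eta)))
}
logistic_oracle <- function(x, y, start = rep(0, ncol(x))) {
  # damped Newton ascent on the log-likelihood
  b <- start
  for (it in 1:100) {
    p <- plogis(as.numeric(x %*% b))
    score <- crossprod(x, y - p)
    info <- crossprod(x, x * (p * (1 - p)))
    step <- solve(info + 1e-12 * diag(ncol(x)), score)
    ll <- logistic_loglik(b, x, y)
    h <- 1
    while (logistic_loglik(b + h * step, x, y) < ll && h > 1e-8) h <- h / 2
    b <- b + h * as.numeric(step)
    if (max(abs(score)) < 1e-10) break
  }
  b
}
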