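#' Run the full PRS-BDR analysis pipeline
#'
#' Orchestrates the whole analysis: variant selection (or a ready-made
#' weight table), VCF dosage harmonization, mean-dosage imputation, PRS
#' computation and per-SD standardization, and the three primary adjusted
#' association models (linear on continuous BDR; logistic at the 12\% and
#' 8\% cut-points) plus sex/BMI/age interaction tests. Inputs are either
#' real files (VCF + phenotype CSV) or a simulation block; every stage is
#' logged to standard error with counts.
#'
#' @param config A list (or path to a YAML/JSON file) with components:
#'   \describe{
#'     \item{weights}{path to a weight table, or \code{NULL} to use
#'       \code{summary_stats} + thresholds, or the packaged table if both
#'       are absent.}
#'     \item{summary_stats}{optional path to GWAS summary statistics; when
#'       given, [select_prs_variants()] is applied with \code{p_max} and
#'       \code{cadd_min} (paper-default 0.001 and 10).}
#'     \item{vcf, pheno}{paths to the genotype VCF and phenotype CSV.}
#'     \item{simulate}{alternatively, a list of arguments for
#'       [simulation_config()]; the cohort is generated in memory.}
#'     \item{thresholds}{BDR cut-points for the logistic models (default
#'       c(12, 8)).}
#'     \item{mismatch_policy}{"error" or "drop" (default "error").}
#'     \item{seed}{integer seed used for simulation.}
#'   }
#' @param quiet Suppress progress logging.
#' @return A \code{pipeline_report} list: weight-table summary, cohort
#'   summary (n, BDR mean/SD, responder fractions, raw PRS mean/SD),
#'   association results, interaction p-values, software version, config
#'   echo and seed.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  log_msg <- function(...) if (!quiet) message("[bdrprs] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  thresholds <- config$thresholds %||% c(12, 8)
  seed <- config$seed %||% 1L

  weights <- stage("weights", {
    if (!is.null(config$summary_stats)) {
      recs <- load_summary_stats(config$summary_stats)
      w <- select_prs_variants(recs,
                               p_max = config$p_max %||% 0.001,
                               cadd_min = config$cadd_min %||% 10)
      log_msg("selected %d of %d candidate variants", nrow(w), nrow(recs))
      w
    } else if (!is.null(config$weights)) {
      if (inherits(config$weights, "weight_table")) config$weights
      else read_weight_table(config$weights)
    } else {
      bdr_weight_table()
    }
  })
  log_msg("weight table: %d variants", nrow(weights))

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$weights <- weights
    sim_args$seed <- sim_args$seed %||% seed
    sim_cfg <- stage("simulate", do.call(simulation_config, sim_args))
    sim <- stage("simulate", simulate_cohort(sim_cfg))
    dosages <- sim$dosages
    cohort <- sim$cohort
    log_msg("simulated cohort: n = %d (%s mode)", sim_cfg$n, sim_cfg$mode)
  } else {
    if (is.null(config$vcf) || is.null(config$pheno)) {
      stop("config must provide either a simulate block or vcf + pheno paths",
           call. = FALSE)
    }
    dosages <- stage("genotypes", read_dosages(config$vcf, weights,
                                               config$mismatch_policy %||% "error"))
    log_msg("genotypes: %d samples x %d variants, %d missing calls",
            nrow(dosages$dosages), ncol(dosages$dosages),
            sum(dosages$missing_mask))
    dosages <- stage("imputation", impute_missing(dosages))
    cohort <- stage("phenotypes", read_cohort(config$pheno))
    if (!setequal(cohort$sample_id, dosages$sample_ids)) {
      keep <- intersect(cohort$sample_id, dosages$sample_ids)
      log_msg("restricting to %d samples present in both files", length(keep))
      cohort <- cohort_table(as.data.frame(cohort)[cohort$sample_id %in% keep, ])
    }
  }

  prs <- stage("prs", standardize(compute_prs(dosages, weights)))
  idx <- match(cohort$sample_id, prs$sample_id)
  prs_matched <- prs[idx, ]
  class(prs_matched) <- class(prs)
  log_msg("PRS: raw mean %.3f, raw SD %.3f over %d samples",
          mean(prs$raw_score), sd(prs$raw_score), nrow(prs))

  has_cont <- !is.null(cohort$bdr_percent) && !all(is.na(cohort$bdr_percent))
  results <- list()
  interactions <- list()
  if (has_cont) {
    results$linear <- stage("linear model", fit_linear_adjusted(cohort, prs_matched))
    for (mod in c("sex", "bmi_category", "age")) {
      interactions[[mod]] <- stage(
        paste0("interaction (", mod, ")"),
        test_interaction(cohort, prs_matched, mod, threshold = NULL))
    }
    for (t in thresholds) {
      results[[paste0("logistic_", t)]] <-
        stage(paste0("logistic model (", t, "%)"),
              fit_logistic_threshold(cohort, prs_matched, t))
    }
  } else {
    t <- config$simulate$threshold %||% thresholds[1]
    results[[paste0("logistic_", t)]] <-
      stage(paste0("logistic model (", t, "%)"),
            fit_logistic_threshold(cohort, prs_matched, t))
  }

  bdr <- cohort$bdr_percent
  cohort_summary <- list(
    n = nrow(cohort),
    bdr_mean = if (has_cont) mean(bdr) else NA,
    bdr_sd = if (has_cont) sd(bdr) else NA,
    frac_ge_12 = if (has_cont) mean(dichotomize_bdr(bdr, 12)) else
      mean(cohort$responder),
    frac_ge_8 = if (has_cont) mean(dichotomize_bdr(bdr, 8)) else NA,
    prs_raw_mean = mean(prs$raw_score),
    prs_raw_sd = sd(prs$raw_score)
  )
  report <- list(
    schema_version = "1.0",
    weight_table_summary = list(
      n_selected = nrow(weights),
      provenance = attr(weights, "provenance"),
      p_max = config$p_max %||% 0.001,
      cadd_min = config$cadd_min %||% 10
    ),
    cohort_summary = cohort_summary,
    association_results = lapply(results, as_report_entry),
    interaction_p_values = interactions,
    software_version = as.character(packageVersion("bdrprs")),
    config_echo = config_echo(config),
    seed = seed
  )
  class(report) <- "pipeline_report"
  validate_report(report)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_echo <- function(config) {
  lapply(config, function(x) {
    if (inherits(x, "weight_table")) paste0("<weight_table: ", nrow(x), " variants>")
    else if (is.list(x)) lapply(x, function(y) if (is.atomic(y)) y else "<object>")
    else x
  })
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a pipeline report as JSON
#'
#' @param report A \code{pipeline_report}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Validate a pipeline report against the shipped schema
#'
#' Structural validation against \code{inst/schema/pipeline-report-1.0.json}:
#' required fields present, numeric fields numeric, responder fractions in
#' [0, 1], every model naming its covariate set.
#'
#' @param report A \code{pipeline_report} (or the list parsed from its JSON).
#' @return Invisibly TRUE; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "pipeline-report-1.0.json",
                             package = "bdrprs")
  schema <- jsonlite::read_json(schema_path)
  for (f in names(schema$required_fields)) {
    if (is.null(report[[f]])) stop("report missing field: ", f, call. = FALSE)
  }
  cs <- report$cohort_summary
  fr <- c(cs$frac_ge_12, cs$frac_ge_8)
  fr <- fr[!is.na(fr)]
  if (any(fr < 0 | fr > 1)) {
    stop("responder fractions must lie in [0, 1]", call. = FALSE)
  }
  for (nm in names(report$association_results)) {
    r <- report$association_results[[nm]]
    if (is.null(r$formula) || !nzchar(r$formula)) {
      stop("association result '", nm, "' does not name its covariate set",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
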