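#' Bronchodilator response from pre/post spirometry
#'
#' BDR is the percent change in FEV1 after albuterol:
#' \code{100 * (post - pre) / pre}. Negative values (paradoxical response)
#' are legitimate.
#'
#' @param pre_fev1 Baseline FEV1 in liters, strictly positive.
#' @param post_fev1 Post-bronchodilator FEV1 in liters.
#' @return BDR as a percent.
#' @export
compute_bdr <- function(pre_fev1, post_fev1) {
  if (any(!is.finite(pre_fev1)) || any(pre_fev1 <= 0)) {
    stop("pre-bronchodilator FEV1 must be positive", call. = FALSE)
  }
  100 * (post_fev1 - pre_fev1) / pre_fev1
}

#' Dichotomize BDR at a clinical threshold
#'
#' Responder status at a BDR cut-point, inclusive: a BDR exactly at the
#' threshold counts as a responder. The 12\% cut-point is the usual
#' clinical-trial inclusion criterion; 8\% is a sensitive and specific
#' indicator of airway reversibility used as a sensitivity analysis.
#'
#' @param bdr_percent Numeric BDR values (\%).
#' @param threshold Cut-point in BDR \% (commonly 12 or 8).
#' @return Logical responder flags.
#' @export
dichotomize_bdr <- function(bdr_percent, threshold = 12) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  bdr_percent >= threshold
}

BMI_LEVELS <- c("normal", "underweight", "overweight", "obese")
SEX_LEVELS <- c("male", "female")

#' Assemble a cohort phenotype/covariate table
#'
#' Builds the per-individual table used by the association models. If raw
#' pre/post FEV1 are supplied, BDR is computed from them; when a
#' \code{bdr_percent} column is also supplied it must agree with the
#' recomputed value within 0.01 (the raw spirometry wins).
#'
#' @param df A data.frame with columns \code{sample_id}, \code{age_years},
#'   \code{sex} ("male"/"female"), \code{bmi_category} ("normal",
#'   "underweight", "overweight", "obese"), \code{doctor_visits},
#'   \code{PC1}..\code{PC6}, and either \code{bdr_percent} or both
#'   \code{pre_fev1} and \code{post_fev1}. A logical \code{responder}
#'   column may stand in for \code{bdr_percent} for threshold-only cohorts.
#' @return A data.frame of class \code{cohort_table}.
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "age_years", "sex", "bmi_category", "doctor_visits")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing cohort column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_raw <- all(c("pre_fev1", "post_fev1") %in% names(df)) &&
    !all(is.na(df$pre_fev1))
  if (has_raw) {
    bdr <- compute_bdr(df$pre_fev1, df$post_fev1)
    if ("bdr_percent" %in% names(df) && !all(is.na(df$bdr_percent))) {
      bad <- which(abs(df$bdr_percent - bdr) >= 0.01)
      if (length(bad) > 0) {
        stop("bdr_percent disagrees with pre/post FEV1 (|diff| >= 0.01) for sample(s): ",
             paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
      }
    }
    df$bdr_percent <- bdr
  }
  if (!"bdr_percent" %in% names(df) && !"responder" %in% names(df)) {
    stop("cohort needs bdr_percent, pre/post FEV1, or a responder column",
         call. = FALSE)
  }
  bad_bmi <- which(!df$bmi_category %in% BMI_LEVELS)
  if (length(bad_bmi) > 0) {
    stop("unknown bmi_category value(s): ",
         paste(unique(df$bmi_category[bad_bmi]), collapse = ", "),
         "; allowed: ", paste(BMI_LEVELS, collapse = ", "), call. = FALSE)
  }
  bad_sex <- which(!df$sex %in% SEX_LEVELS)
  if (length(bad_sex) > 0) {
    stop("sex must be 'male' or 'female'; offending sample(s): ",
         paste(df$sample_id[bad_sex], collapse = ", "), call. = FALSE)
  }
  if (any(df$doctor_visits < 0)) {
    stop("doctor_visits must be nonnegative", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Encode model covariates as numeric design columns
#'
#' Fixed, documented encoding for the adjustment set "age, sex, BMI
#' category, genotype PCs 1-6, doctor visits": age and visits continuous;
#' sex as a male indicator; BMI as three indicators (underweight,
#' overweight, obese) with normal as the reference; six PC columns. Column
#' order: \code{age_years, sex_male, bmi_underweight, bmi_overweight,
#' bmi_obese, doctor_visits, PC1..PC6}.
#'
#' @param cohort A \code{cohort_table} with \code{PC1}..\code{PC6} columns.
#' @return A numeric matrix with one row per individual.
#' @export
encode_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  pc_cols <- paste0("PC", 1:6)
  need <- c("age_years", "sex", "bmi_category", "doctor_visits", pc_cols)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sub <- as.data.frame(cohort)[, need]
  incomplete <- !complete.cases(sub)
  if (any(incomplete)) {
    stop("missing covariate values for sample(s): ",
         paste(cohort$sample_id[incomplete], collapse = ", "), call. = FALSE)
  }
  x <- cbind(
    age_years = cohort$age_years,
    sex_male = as.numeric(cohort$sex == "male"),
    bmi_underweight = as.numeric(cohort$bmi_category == "underweight"),
    bmi_overweight = as.numeric(cohort$bmi_category == "overweight"),
    bmi_obese = as.numeric(cohort$bmi_category == "obese"),
    doctor_visits = cohort$doctor_visits,
    as.matrix(as.data.frame(cohort)[, pc_cols])
  )
  rownames(x) <- cohort$sample_id
  x
}

#' Read a phenotype/covariate CSV into a cohort table
#'
#' @param path CSV with the columns documented in [cohort_table()]; missing
#'   values as empty fields.
#' @return A \code{cohort_table}.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("phenotype file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if ("responder" %in% names(df)) df$responder <- as.logical(df$responder)
  cohort_table(df)
}

#' Write a cohort table as CSV
#'
#' @param cohort A \code{cohort_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
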