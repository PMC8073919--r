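Z975 <- 1.959964

association_result <- function(model, outcome, estimate, se, n,
                               covariate_estimates, formula_str) {
  res <- list(
    model = model,
    outcome = outcome,
    estimate = estimate,
    se = se,
    p_value = 2 * pnorm(-abs(estimate / se)),
    n = n,
    covariate_estimates = covariate_estimates,
    formula = formula_str
  )
  if (model == "logistic") {
    res$odds_ratio <- exp(estimate)
    res$ci_low <- exp(estimate - Z975 * se)
    res$ci_high <- exp(estimate + Z975 * se)
  } else {
    res$ci_low <- estimate - Z975 * se
    res$ci_high <- estimate + Z975 * se
  }
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s model, outcome %s (n = %d)\n", x$model, x$outcome, x$n))
  if (x$model == "logistic") {
    cat(sprintf("  OR per SD of PRS: %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
                x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  } else {
    cat(sprintf("  BDR %% per SD of PRS: %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
                x$estimate, x$ci_low, x$ci_high, x$p_value))
  }
  invisible(x)
}

model_frame <- function(cohort, prs) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(prs, "prs_result"))
  if (all(is.na(prs$z_score))) {
    stop("PRS must be standardized before modelling; run standardize()",
         call. = FALSE)
  }
  if (!identical(cohort$sample_id, prs$sample_id)) {
    idx <- match(cohort$sample_id, prs$sample_id)
    if (anyNA(idx)) {
      stop("cohort sample(s) without a PRS: ",
           paste(cohort$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    prs <- prs[idx, ]
  }
  x <- encode_covariates(cohort)
  # a BMI category absent from the cohort leaves an all-zero indicator;
  # drop it, as factor coding would
  bmi_cols <- intersect(c("bmi_underweight", "bmi_overweight", "bmi_obese"),
                        colnames(x))
  empty <- bmi_cols[colSums(x[, bmi_cols, drop = FALSE] != 0) == 0]
  if (length(empty) > 0) x <- x[, setdiff(colnames(x), empty), drop = FALSE]
  list(z = prs$z_score, covars = x)
}

check_full_rank <- function(design) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Adjusted linear model for PRS and continuous BDR
#'
#' Ordinary least squares of BDR (\%) on the standardized PRS, adjusted for
#' age, sex, BMI category, doctor visits, and genotype PCs 1-6. The
#' reported estimate is the per-SD PRS coefficient with a 95\% Wald
#' interval (estimate +/- 1.959964 se).
#'
#' @param cohort A \code{cohort_table} with \code{bdr_percent}.
#' @param prs A standardized \code{prs_result}.
#' @return An \code{association_result}.
#' @export
fit_linear_adjusted <- function(cohort, prs) {
  mf <- model_frame(cohort, prs)
  y <- cohort$bdr_percent
  if (is.null(y) || any(is.na(y))) {
    stop("bdr_percent missing for modelled individuals", call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, z_score = mf$z, mf$covars)
  if (nrow(design) <= ncol(design)) {
    stop("more parameters than observations", call. = FALSE)
  }
  check_full_rank(design)
  dat <- data.frame(y = y, z_score = mf$z, mf$covars, check.names = FALSE)
  fit <- lm(y ~ ., data = dat)
  est <- coef(fit)["z_score"]
  se <- sqrt(diag(vcov(fit)))["z_score"]
  association_result(
    model = "linear", outcome = "bdr_percent",
    estimate = unname(est), se = unname(se), n = nrow(dat),
    covariate_estimates = as.list(coef(fit)),
    formula_str = paste("bdr_percent ~ z_score +",
                        paste(colnames(mf$covars), collapse = " + "))
  )
}

#' Adjusted logistic model for PRS and threshold-defined BDR response
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of responder status at a BDR cut-point on the standardized PRS
#' and the same adjustment set as the linear model. Responder status is
#' \code{bdr_percent >= threshold} (inclusive); a cohort carrying only a
#' precomputed \code{responder} column is also accepted. Reported as an
#' odds ratio per SD with an exponentiated Wald interval. Complete
#' separation (divergent coefficients or non-convergence) raises an error
#' rather than returning an unstable estimate.
#'
#' @param cohort A \code{cohort_table}.
#' @param prs A standardized \code{prs_result}.
#' @param threshold BDR cut-point in percent (12 or 8 in the primary and
#'   sensitivity analyses).
#' @return An \code{association_result} with \code{odds_ratio} filled.
#' @export
fit_logistic_threshold <- function(cohort, prs, threshold = 12) {
  mf <- model_frame(cohort, prs)
  if (!is.null(cohort$bdr_percent) && !all(is.na(cohort$bdr_percent))) {
    y <- as.numeric(dichotomize_bdr(cohort$bdr_percent, threshold))
  } else if (!is.null(cohort$responder)) {
    y <- as.numeric(cohort$responder)
  } else {
    stop("cohort has neither bdr_percent nor responder", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("single-class outcome at threshold ", threshold,
         "; logistic model needs both responders and non-responders",
         call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, z_score = mf$z, mf$covars)
  check_full_rank(design)
  dat <- data.frame(y = y, z_score = mf$z, mf$covars, check.names = FALSE)
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("detected separation: fitted probabilities at 0/1", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || any(abs(coef(fit)) > 50)) {
    stop("detected separation or non-convergence in the logistic fit",
         call. = FALSE)
  }
  est <- coef(fit)["z_score"]
  se <- sqrt(diag(vcov(fit)))["z_score"]
  association_result(
    model = "logistic", outcome = paste0("responder_", threshold),
    estimate = unname(est), se = unname(se), n = nrow(dat),
    covariate_estimates = as.list(coef(fit)),
    formula_str = paste0("I(bdr_percent >= ", threshold, ") ~ z_score + ",
                         paste(colnames(mf$covars), collapse = " + "))
  )
}

#' Wald test for effect modification of the PRS association
#'
#' Adds modifier-by-PRS product term(s) to the adjusted model and returns
#' the Wald p-value for the interaction: a single-term test for sex or age,
#' a joint 3-df chi-square test for BMI category (three indicators).
#'
#' @param cohort A \code{cohort_table}.
#' @param prs A standardized \code{prs_result}.
#' @param modifier One of \code{"sex"}, \code{"bmi_category"}, \code{"age"}.
#' @param threshold \code{NULL} for the linear (continuous BDR) model, or a
#'   BDR cut-point for the logistic model.
#' @return The interaction p-value (scalar).
#' @export
test_interaction <- function(cohort, prs, modifier = c("sex", "bmi_category", "age"),
                             threshold = NULL) {
  modifier <- match.arg(modifier)
  mf <- model_frame(cohort, prs)
  mod_cols <- switch(modifier,
    sex = mf$covars[, "sex_male", drop = FALSE],
    age = mf$covars[, "age_years", drop = FALSE],
    bmi_category = mf$covars[, c("bmi_underweight", "bmi_overweight", "bmi_obese"),
                             drop = FALSE]
  )
  if (all(apply(mod_cols, 2, function(v) length(unique(v)) == 1))) {
    stop("modifier '", modifier, "' is constant in the cohort", call. = FALSE)
  }
  inter <- mod_cols * mf$z
  colnames(inter) <- paste0("z_x_", colnames(mod_cols))
  if (is.null(threshold)) {
    y <- cohort$bdr_percent
  } else if (!is.null(cohort$bdr_percent) && !all(is.na(cohort$bdr_percent))) {
    y <- as.numeric(dichotomize_bdr(cohort$bdr_percent, threshold))
  } else {
    y <- as.numeric(cohort$responder)
  }
  dat <- data.frame(y = y, z_score = mf$z, mf$covars, inter, check.names = FALSE)
  check_full_rank(cbind(1, as.matrix(dat[, -1])))
  fit <- if (is.null(threshold)) {
    lm(y ~ ., data = dat)
  } else {
    glm(y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100))
  }
  terms_idx <- match(colnames(inter), names(coef(fit)))
  b <- coef(fit)[terms_idx]
  v <- vcov(fit)[terms_idx, terms_idx, drop = FALSE]
  w <- as.numeric(t(b) %*% solve(v, b))
  if (length(terms_idx) == 1 && is.null(threshold)) {
    # single-term linear interaction: use the t-based p-value of the fit
    summary(fit)$coefficients[colnames(inter), "Pr(>|t|)"]
  } else {
    unname(pchisq(w, df = length(terms_idx), lower.tail = FALSE))
  }
}

#' Serialize an association result as a JSON-ready list
#' @param x An \code{association_result}.
#' @return A plain list suitable for \code{jsonlite::toJSON}.
#' @export
as_report_entry <- function(x) {
  stopifnot(inherits(x, "association_result"))
  unclass(x)
}
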