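#' Weighted allele-dosage polygenic risk score
#'
#' The raw score for individual i is \code{sum_j dosage_ij * beta_j}: the
#' number of effect alleles carried at each scoring variant weighted by the
#' GWAS effect size, summed over variants in weight-table order. The matrix
#' may cover a subset of the weight table (e.g. after dropping unresolvable
#' variants); every matrix variant must have a weight, and missing dosages
#' must already have been imputed.
#'
#' @param matrix A \code{dosage_matrix}.
#' @param weights A \code{weight_table} covering the matrix's variants.
#' @return A \code{prs_result}: data.frame with \code{sample_id} and
#'   \code{raw_score}, plus attributes \code{n_variants_used} and
#'   \code{weights_provenance}. \code{z_score} is filled by [standardize()].
#' @export
compute_prs <- function(matrix, weights) {
  stopifnot(inherits(matrix, "dosage_matrix"), inherits(weights, "weight_table"))
  unknown <- setdiff(matrix$variant_ids, weights$rsid)
  if (length(unknown) > 0) {
    stop("matrix variant(s) absent from the weight table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(matrix$dosages))) {
    stop("dosage matrix contains unimputed missing values", call. = FALSE)
  }
  # weight-table order restricted to the variants present
  vorder <- weights$rsid[weights$rsid %in% matrix$variant_ids]
  dos <- matrix$dosages[, vorder, drop = FALSE]
  beta <- weights$beta[match(vorder, weights$rsid)]
  raw <- as.numeric(dos %*% beta)
  out <- data.frame(sample_id = matrix$sample_ids, raw_score = raw,
                    z_score = NA_real_, stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- length(vorder)
  attr(out, "weights_provenance") <- attr(weights, "provenance")
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Standardize a PRS to the per-SD scale
#'
#' In-sample z-scoring: \code{z = (raw - mean(raw)) / sd(raw)} with the
#' sample standard deviation (n - 1 denominator). Association models report
#' effects per one standard deviation of the score, so their coefficients
#' are invariant to affine changes of the raw score.
#'
#' @param result A \code{prs_result} from [compute_prs()].
#' @return The same object with \code{z_score} filled.
#' @export
standardize <- function(result) {
  stopifnot(inherits(result, "prs_result"))
  raw <- result$raw_score
  if (length(raw) < 2) {
    stop("standardization needs at least 2 individuals", call. = FALSE)
  }
  s <- sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("raw scores are constant; zero variance", call. = FALSE)
  }
  result$z_score <- (raw - mean(raw)) / s
  result
}

#' Write PRS results as CSV
#'
#' @param result A \code{prs_result}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_prs <- function(result, path) {
  stopifnot(inherits(result, "prs_result"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
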