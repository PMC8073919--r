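#' Effect-allele dosage matrix
#'
#' Constructor for the \code{dosage_matrix} container: individuals x variants
#' counts of the effect allele (0..2; fractional after imputation), a
#' missingness mask recording where the original genotype call was absent,
#' and the per-variant effect-allele frequency among non-missing calls.
#'
#' @param dosages Numeric matrix, samples x variants, values in [0, 2].
#' @param sample_ids Character vector of row identifiers.
#' @param variant_ids Character vector of column identifiers (rsIDs).
#' @param missing_mask Logical matrix, same shape, TRUE where the original
#'   call was missing. Defaults to all FALSE.
#' @return A \code{dosage_matrix} object.
#' @export
dosage_matrix <- function(dosages, sample_ids, variant_ids,
                          missing_mask = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(missing_mask)) {
    missing_mask <- matrix(FALSE, nrow(dosages), ncol(dosages))
  }
  stopifnot(
    nrow(dosages) == length(sample_ids),
    ncol(dosages) == length(variant_ids),
    identical(dim(dosages), dim(missing_mask))
  )
  if (any(dosages < 0 | dosages > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  dimnames(dosages) <- list(sample_ids, variant_ids)
  dimnames(missing_mask) <- list(sample_ids, variant_ids)
  eaf <- vapply(seq_len(ncol(dosages)), function(j) {
    ok <- !missing_mask[, j]
    if (!any(ok)) NA_real_ else mean(dosages[ok, j]) / 2
  }, numeric(1))
  structure(
    list(sample_ids = as.character(sample_ids),
         variant_ids = as.character(variant_ids),
         dosages = dosages,
         missing_mask = missing_mask,
         effect_allele_freq = setNames(eaf, variant_ids)),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", length(x$sample_ids), "samples x",
      length(x$variant_ids), "variants;",
      sum(x$missing_mask), "missing calls\n")
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

revcomp <- function(allele) {
  chartr("ACGT", "TGCA", allele)
}

is_palindromic <- function(ref, alt) {
  ref == revcomp(alt)
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts hard genotype calls for the weight-table variants from a VCF
#' (plain or bgzipped) and harmonizes them to counts of the EFFECT allele.
#' Variants are matched by rsID first, with a (chrom, pos) fallback. If the
#' VCF ALT allele equals the effect allele the dosage is the ALT count; if
#' REF equals the effect allele it is 2 minus the ALT count; otherwise the
#' reverse complement is tried for non-palindromic variants (strand flip).
#' Palindromic (A/T, C/G) variants must match literally. Missing genotypes
#' are flagged in the missingness mask with a provisional dosage of 0; run
#' [impute_missing()] before scoring.
#'
#' @param vcf_path Path to a VCF with GT fields.
#' @param weights A \code{weight_table}.
#' @param mismatch_policy What to do when alleles cannot be reconciled:
#'   \code{"error"} (default) or \code{"drop"} the variant with a warning.
#' @return A \code{dosage_matrix} whose columns follow weight-table order
#'   (dropped variants omitted).
#' @export
read_dosages <- function(vcf_path, weights, mismatch_policy = c("error", "drop")) {
  mismatch_policy <- match.arg(mismatch_policy)
  stopifnot(inherits(weights, "weight_table"))
  if (!file.exists(vcf_path)) {
    stop("VCF file not found: ", vcf_path, call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  sample_ids <- colnames(gt)
  n <- length(sample_ids)

  vcf_ids <- as.character(fix[, "ID"])
  vcf_key <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")

  # locate each scoring variant: rsID first, (chrom, pos) fallback
  row_of <- integer(nrow(weights))
  for (j in seq_len(nrow(weights))) {
    hit <- which(vcf_ids == weights$rsid[j])
    if (length(hit) == 0) {
      hit <- which(vcf_key == paste(weights$chrom[j], weights$pos[j], sep = ":"))
    }
    row_of[j] <- if (length(hit) >= 1) hit[1] else NA_integer_
  }
  if (anyNA(row_of)) {
    stop("weight-table variant(s) absent from VCF: ",
         paste(weights$rsid[is.na(row_of)], collapse = ", "), call. = FALSE)
  }

  keep <- logical(nrow(weights))
  dos <- matrix(NA_real_, n, nrow(weights))
  miss <- matrix(FALSE, n, nrow(weights))
  for (j in seq_len(nrow(weights))) {
    i <- row_of[j]
    ref <- toupper(fix[i, "REF"])
    alt <- toupper(fix[i, "ALT"])
    if (grepl(",", alt, fixed = TRUE)) {
      stop("multiallelic VCF record at scoring variant ", weights$rsid[j],
           call. = FALSE)
    }
    eff <- weights$effect_allele[j]
    orient <- if (alt == eff) {
      "alt"
    } else if (ref == eff) {
      "ref"
    } else if (!is_palindromic(ref, alt) && revcomp(alt) == eff) {
      "alt"
    } else if (!is_palindromic(ref, alt) && revcomp(ref) == eff) {
      "ref"
    } else {
      NA_character_
    }
    if (is.na(orient)) {
      msg <- paste0("allele mismatch at ", weights$rsid[j], ": VCF ", ref, "/",
                    alt, " vs effect allele ", eff)
      if (mismatch_policy == "error") stop(msg, call. = FALSE)
      warning(msg, "; variant dropped", call. = FALSE)
      next
    }
    calls <- gt[i, ]
    alt_count <- count_alt_alleles(calls)
    d <- if (orient == "alt") alt_count else 2 - alt_count
    m <- is.na(d)
    d[m] <- 0
    dos[, j] <- d
    miss[, j] <- m
    keep[j] <- TRUE
  }
  if (!any(keep)) {
    stop("no scoring variants could be harmonized", call. = FALSE)
  }
  dosage_matrix(dos[, keep, drop = FALSE], sample_ids,
                weights$rsid[keep], miss[, keep, drop = FALSE])
}

count_alt_alleles <- function(calls) {
  vapply(calls, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Impute missing dosages with the mean-dosage rule
#'
#' Replaces each missing call by twice the effect-allele frequency of its
#' variant (computed from the non-missing calls), the standard mean-dosage
#' imputation used in PRS scoring. The missingness mask is preserved for
#' reporting; per-variant mean dosage is unchanged.
#'
#' @param matrix A \code{dosage_matrix}.
#' @return A \code{dosage_matrix} with no unresolved missing values.
#' @export
impute_missing <- function(matrix) {
  stopifnot(inherits(matrix, "dosage_matrix"))
  if (!any(matrix$missing_mask)) return(matrix)
  all_missing <- colSums(!matrix$missing_mask) == 0
  if (any(all_missing)) {
    stop("variant(s) with no non-missing calls: ",
         paste(matrix$variant_ids[all_missing], collapse = ", "), call. = FALSE)
  }
  dos <- matrix$dosages
  for (j in seq_along(matrix$variant_ids)) {
    m <- matrix$missing_mask[, j]
    if (any(m)) dos[m, j] <- 2 * matrix$effect_allele_freq[j]
  }
  out <- matrix
  out$dosages <- dos
  out
}

#' Genotype principal components
#'
#' Principal-component scores of the column-centered dosage matrix, ordered
#' by decreasing variance. Sign convention: within each component the
#' largest-magnitude loading is made positive, so scores are reproducible.
#' A small utility for simulated data; real analyses derive PCs from
#' genome-wide genotypes.
#'
#' @param matrix A \code{dosage_matrix} (imputed).
#' @param k Number of components.
#' @return Numeric matrix, samples x k, columns \code{PC1..PCk}.
#' @export
compute_pcs <- function(matrix, k) {
  stopifnot(inherits(matrix, "dosage_matrix"), k >= 1)
  x <- scale(matrix$dosages, center = TRUE, scale = FALSE)
  r <- qr(x)$rank
  if (k > r) {
    stop("k = ", k, " exceeds the rank (", r, ") of the centered dosage matrix",
         call. = FALSE)
  }
  pc <- prcomp(matrix$dosages, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- matrix$sample_ids
  scores
}

#' Export a dosage matrix as tab-separated text
#'
#' @param matrix A \code{dosage_matrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_dosages <- function(matrix, path) {
  stopifnot(inherits(matrix, "dosage_matrix"))
  out <- data.frame(sample_id = matrix$sample_ids,
                    matrix$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
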