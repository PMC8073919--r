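#' Load GWAS summary statistics with CADD annotations
#'
#' Reads a tab-separated summary-statistics file into a variant table. The
#' file must carry the columns \code{Chr}, \code{bp}, \code{rsID},
#' \code{EffectAllele}, \code{Beta}, \code{P}; \code{CADD} (PHRED-scaled
#' deleteriousness score) and \code{Gene} are optional. Empty \code{CADD} or
#' \code{Gene} cells are read as missing.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data.frame of class \code{variant_table} with columns
#'   \code{chrom}, \code{pos}, \code{rsid}, \code{effect_allele},
#'   \code{beta}, \code{p_value}, \code{cadd_phred}, \code{gene_label}.
#' @export
load_summary_stats <- function(path) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = TRUE, na.strings = NULL,
                    blank.lines.skip = TRUE)
  required <- c("Chr", "bp", "rsID", "EffectAllele", "Beta", "P")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(empty_variant_table())
  }
  parse_num <- function(x, what) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & nzchar(x) | !nzchar(x))
    if (length(bad) > 0) {
      stop("unparseable ", what, " on data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out
  }
  beta <- parse_num(raw$Beta, "beta")
  pval <- parse_num(raw$P, "p-value")
  cadd <- if ("CADD" %in% names(raw)) {
    x <- trimws(raw$CADD)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & nzchar(x))
    if (length(bad) > 0) {
      stop("unparseable CADD on data row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out
  } else {
    rep(NA_real_, nrow(raw))
  }
  gene <- if ("Gene" %in% names(raw)) {
    g <- trimws(raw$Gene)
    ifelse(nzchar(g), g, NA_character_)
  } else {
    rep(NA_character_, nrow(raw))
  }
  tab <- data.frame(
    chrom = trimws(raw$Chr),
    pos = parse_num(raw$bp, "position"),
    rsid = trimws(raw$rsID),
    effect_allele = toupper(trimws(raw$EffectAllele)),
    beta = beta,
    p_value = pval,
    cadd_phred = cadd,
    gene_label = gene,
    stringsAsFactors = FALSE
  )
  validate_variant_table(tab)
  class(tab) <- c("variant_table", "data.frame")
  tab
}

empty_variant_table <- function() {
  tab <- data.frame(
    chrom = character(0), pos = numeric(0), rsid = character(0),
    effect_allele = character(0), beta = numeric(0), p_value = numeric(0),
    cadd_phred = numeric(0), gene_label = character(0),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("variant_table", "data.frame")
  tab
}

validate_variant_table <- function(tab, require_p = TRUE) {
  if (any(!nzchar(tab$rsid))) {
    stop("empty rsID on row(s) ", paste(which(!nzchar(tab$rsid)), collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(tab$rsid[duplicated(tab$rsid)])
  if (length(dup) > 0) {
    stop("duplicate rsID(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_allele <- which(!tab$effect_allele %in% c("A", "C", "G", "T"))
  if (length(bad_allele) > 0) {
    stop("effect allele must be a single nucleotide A/C/G/T; offending row(s): ",
         paste(bad_allele, collapse = ", "), call. = FALSE)
  }
  if (require_p && nrow(tab) > 0) {
    bad_p <- which(!is.na(tab$p_value) & (tab$p_value <= 0 | tab$p_value > 1))
    if (length(bad_p) > 0) {
      stop("p-value outside (0, 1] on row(s) ", paste(bad_p, collapse = ", "),
           call. = FALSE)
    }
  }
  bad_cadd <- which(!is.na(tab$cadd_phred) & tab$cadd_phred < 0)
  if (length(bad_cadd) > 0) {
    stop("negative CADD score on row(s) ", paste(bad_cadd, collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

#' Select PRS scoring variants by p-value and CADD score
#'
#' Applies the two-stage filter used to build the bronchodilator-response
#' score: keep GWAS variants with association p-value strictly below
#' \code{p_max} and PHRED-scaled CADD score at or above \code{cadd_min}
#' (inclusive). Variants without a CADD annotation fail the CADD filter.
#' The retained set is ordered by descending CADD score (the prioritization
#' ranking), ties broken by chromosome then position.
#'
#' @param records A \code{variant_table} from [load_summary_stats()].
#' @param p_max Strict upper bound on the GWAS p-value (default 0.001).
#' @param cadd_min Inclusive lower bound on the PHRED-scaled CADD score
#'   (default 10).
#' @param provenance Free-text tag recording where the weights came from.
#' @return A \code{weight_table}: the selected variants with their signed
#'   effect-allele betas, carrying a \code{provenance} attribute.
#' @export
select_prs_variants <- function(records, p_max = 0.001, cadd_min = 10,
                                provenance = "selected") {
  stopifnot(is.data.frame(records))
  if (any(is.na(records$p_value))) {
    stop("every record must have a p-value", call. = FALSE)
  }
  keep <- records$p_value < p_max &
    !is.na(records$cadd_phred) & records$cadd_phred >= cadd_min
  sel <- records[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no variants pass p < ", p_max, " and CADD >= ", cadd_min,
         "; review the thresholds", call. = FALSE)
  }
  ord <- order(-sel$cadd_phred, chrom_sort_key(sel$chrom), sel$pos)
  sel <- sel[ord, , drop = FALSE]
  rownames(sel) <- NULL
  as_weight_table(sel, provenance = provenance)
}

# numeric-aware chromosome ordering (1..22 before X/Y/MT)
chrom_sort_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), 100 + as.integer(factor(chrom)), num)
  key
}

as_weight_table <- function(tab, provenance = "unspecified") {
  stopifnot(is.data.frame(tab), nrow(tab) > 0)
  validate_variant_table(tab, require_p = FALSE)
  if (any(is.na(tab$beta))) {
    stop("every weight-table entry must have a beta", call. = FALSE)
  }
  attr(tab, "provenance") <- provenance
  class(tab) <- c("weight_table", "variant_table", "data.frame")
  tab
}

#' Read a PRS weight table
#'
#' Reads a tab-separated scoring table (columns \code{Chr}, \code{bp},
#' \code{rsID}, \code{EffectAllele}, \code{Beta}, optional \code{P},
#' \code{CADD}, \code{Gene}) such as the packaged 16-variant
#' bronchodilator-response table (`system.file("extdata",
#' "bdr_prs_weights.tsv", package = "bdrprs")`).
#'
#' @param path Path to the tab-separated weight table.
#' @param provenance Free-text source tag; defaults to the file path.
#' @return A \code{weight_table}.
#' @export
read_weight_table <- function(path, provenance = path) {
  if (!file.exists(path)) {
    stop("weight-table file not found: ", path, call. = FALSE)
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    na.strings = NULL, blank.lines.skip = TRUE)
  required <- c("Chr", "bp", "rsID", "EffectAllele", "Beta")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_or_na <- function(x) {
    x <- trimws(x)
    ifelse(nzchar(x), suppressWarnings(as.numeric(x)), NA_real_)
  }
  tab <- data.frame(
    chrom = trimws(raw$Chr),
    pos = as.numeric(raw$bp),
    rsid = trimws(raw$rsID),
    effect_allele = toupper(trimws(raw$EffectAllele)),
    beta = as.numeric(raw$Beta),
    p_value = if ("P" %in% names(raw)) num_or_na(raw$P) else NA_real_,
    cadd_phred = if ("CADD" %in% names(raw)) num_or_na(raw$CADD) else NA_real_,
    gene_label = if ("Gene" %in% names(raw)) {
      g <- trimws(raw$Gene); ifelse(nzchar(g), g, NA_character_)
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  as_weight_table(tab, provenance = provenance)
}

#' Write a PRS weight table
#'
#' Serializes a \code{weight_table} as tab-separated text with full-precision
#' betas; [read_weight_table()] of the written file reproduces the table.
#'
#' @param table A \code{weight_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "weight_table"))
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  out <- data.frame(
    Chr = table$chrom,
    bp = format(table$pos, scientific = FALSE, trim = TRUE),
    rsID = table$rsid,
    EffectAllele = table$effect_allele,
    Beta = fmt(table$beta),
    P = fmt(table$p_value),
    CADD = fmt(table$cadd_phred),
    Gene = ifelse(is.na(table$gene_label), "", table$gene_label),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged 16-variant bronchodilator-response weight table
#'
#' Convenience loader for the published 16-SNP scoring table shipped with
#' the package: effect alleles and betas (BDR \% per effect allele) from a
#' GWAS of albuterol bronchodilator response, restricted to variants with
#' p < 0.001 and PHRED-scaled CADD score of 10 or higher.
#'
#' @return A \code{weight_table} with 16 entries.
#' @export
bdr_weight_table <- function() {
  read_weight_table(
    system.file("extdata", "bdr_prs_weights.tsv", package = "bdrprs"),
    provenance = "packaged 16-variant BDR scoring table"
  )
}
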