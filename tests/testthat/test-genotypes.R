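test_that("dosages count effect alleles under every allele orientation", {
  w <- toy_weights(betas = c(1, 1, 1, 1),
                   alleles = c("A", "A", "A", "T"),
                   rsids = c("rs1", "rs2", "rs3", "rs4"))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(tmp, list(
    # ALT is the effect allele: dosage = ALT count
    list(chrom = "1", pos = 1000, id = "rs1", ref = "G", alt = "A",
         gt = c("0/1", "1/1", "0/0")),
    # REF is the effect allele: dosage = 2 - ALT count
    list(chrom = "2", pos = 2000, id = "rs2", ref = "A", alt = "G",
         gt = c("0/0", "0/1", "1/1")),
    # strand-flipped: effect A matches revcomp(ALT = T); non-palindromic G/T
    list(chrom = "3", pos = 3000, id = "rs3", ref = "G", alt = "T",
         gt = c("1/1", "0/1", "0/0")),
    # effect T with REF T: complement coding, phased separator
    list(chrom = "4", pos = 4000, id = "rs4", ref = "T", alt = "G",
         gt = c("0|1", "0|0", "1|1"))
  ), c("I1", "I2", "I3"))
  dm <- read_dosages(tmp, w)
  expect_equal(unname(dm$dosages[, "rs1"]), c(1, 2, 0))
  expect_equal(unname(dm$dosages[, "rs2"]), c(2, 1, 0))
  expect_equal(unname(dm$dosages[, "rs3"]), c(2, 1, 0))
  expect_equal(unname(dm$dosages[, "rs4"]), c(1, 2, 0))
  expect_true(all(dm$dosages %in% 0:2))
  expect_equal(unname(dm$effect_allele_freq["rs1"]), 0.5)
})

test_that("irreconcilable alleles error or drop per policy; absences error", {
  # effect allele A against a C/T record; revcomp gives G/A -> REF G no, ALT A?
  # revcomp(T) = A matches: use a truly irreconcilable case, effect A vs C/G
  # palindromic record, which must match literally and cannot
  w <- toy_weights(betas = 1, alleles = "A", rsids = "rs1")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(tmp, list(
    list(chrom = "1", pos = 1000, id = "rs1", ref = "C", alt = "G",
         gt = c("0/1", "0/0"))
  ), c("I1", "I2"))
  expect_error(read_dosages(tmp, w, "error"), "allele mismatch at rs1")
  expect_warning(expect_error(read_dosages(tmp, w, "drop"), "no scoring variants"),
                 "dropped")

  w2 <- toy_weights(betas = c(1, 1), alleles = c("A", "C"),
                    rsids = c("rs1", "rsMissing"))
  write_toy_vcf(tmp, list(
    list(chrom = "1", pos = 1000, id = "rs1", ref = "G", alt = "A",
         gt = c("0/1", "0/0"))
  ), c("I1", "I2"))
  expect_error(read_dosages(tmp, w2), "absent from VCF.*rsMissing")
})

test_that("variants are matched by rsID with a positional fallback", {
  w <- toy_weights(betas = c(2, 3), alleles = c("A", "C"),
                   rsids = c("rs1", "rs2"))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  # first record matches by ID despite a different position; second has no ID
  # and matches by (chrom, pos)
  write_toy_vcf(tmp, list(
    list(chrom = "1", pos = 999999, id = "rs1", ref = "G", alt = "A",
         gt = c("1/1", "0/0")),
    list(chrom = "2", pos = 2000, id = ".", ref = "T", alt = "C",
         gt = c("0/1", "1/1"))
  ), c("I1", "I2"))
  dm <- read_dosages(tmp, w)
  expect_equal(unname(dm$dosages[, "rs1"]), c(2, 0))
  expect_equal(unname(dm$dosages[, "rs2"]), c(1, 2))
})

test_that("swapping REF/ALT with recoded genotypes leaves dosages unchanged", {
  w <- toy_weights(betas = 1.7, alleles = "A", rsids = "rs1")
  tmp1 <- withr::local_tempfile(fileext = ".vcf")
  tmp2 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(tmp1, list(
    list(chrom = "1", pos = 1000, id = "rs1", ref = "G", alt = "A",
         gt = c("0/0", "0/1", "1/1"))
  ), c("I1", "I2", "I3"))
  write_toy_vcf(tmp2, list(
    list(chrom = "1", pos = 1000, id = "rs1", ref = "A", alt = "G",
         gt = c("1/1", "0/1", "0/0"))
  ), c("I1", "I2", "I3"))
  d1 <- read_dosages(tmp1, w)
  d2 <- read_dosages(tmp2, w)
  expect_equal(d1$dosages, d2$dosages)
})

test_that("missing genotypes are masked and mean-imputed at 2 x frequency", {
  w <- toy_weights(betas = 1, alleles = "A", rsids = "rs1")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(tmp, list(
    list(chrom = "1", pos = 1000, id = "rs1", ref = "G", alt = "A",
         gt = c("0/1", "./.", "0/0", "0/0"))
  ), c("I1", "I2", "I3", "I4"))
  dm <- read_dosages(tmp, w)
  expect_equal(unname(dm$missing_mask[, 1]), c(FALSE, TRUE, FALSE, FALSE))
  # frequency among non-missing: mean(1,0,0)/2 = 1/6
  expect_equal(unname(dm$effect_allele_freq[1]), 1 / 6)
  imp <- impute_missing(dm)
  expect_equal(unname(imp$dosages[2, 1]), 2 * (1 / 6))
  expect_equal(imp$missing_mask, dm$missing_mask)
  # imputation preserves per-variant mean over the imputed matrix
  expect_equal(mean(imp$dosages[, 1]), mean(dm$dosages[!dm$missing_mask[, 1], 1]))

  # no-missing matrix is returned untouched
  dm2 <- dosage_matrix(matrix(c(0, 1, 2), 3, 1), paste0("I", 1:3), "rs1")
  expect_identical(impute_missing(dm2), dm2)

  # a fully missing variant cannot be imputed
  dm3 <- dosage_matrix(matrix(0, 2, 1), c("I1", "I2"), "rs1",
                       missing_mask = matrix(TRUE, 2, 1))
  expect_error(impute_missing(dm3), "rs1")
})

test_that("imputation with a toy frequency reproduces the 2 x AF rule", {
  dm <- dosage_matrix(matrix(c(1, 0, 0, 0, 0), 5, 1), paste0("I", 1:5), "rsX",
                      missing_mask = matrix(c(FALSE, FALSE, TRUE, FALSE, FALSE),
                                            5, 1))
  # AF among non-missing = (1+0+0+0)/8 ... = mean(1,0,0,0)/2 = 0.125
  expect_equal(unname(dm$effect_allele_freq[1]), 0.125)
  dm$effect_allele_freq[1] <- 0.25  # spec worked example: AF 0.25 -> 0.5
  imp <- impute_missing(dm)
  expect_equal(unname(imp$dosages[3, 1]), 0.5)
})

test_that("principal components are orthogonal, ordered, and symmetric", {
  set.seed(11)
  n <- 40
  dos <- matrix(rbinom(n * 8, 2, 0.4), n, 8)
  dos[2, ] <- dos[1, ]  # duplicated individuals
  dm <- dosage_matrix(dos, sprintf("I%02d", 1:n), paste0("rs", 1:8))
  pcs <- compute_pcs(dm, 4)
  expect_equal(dim(pcs), c(n, 4))
  expect_equal(pcs[1, ], pcs[2, ])
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  vars <- apply(pcs, 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  expect_error(compute_pcs(dm, 30), "rank")
  # sign convention makes scores reproducible under reruns
  expect_equal(compute_pcs(dm, 4), pcs)
})
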