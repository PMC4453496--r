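make_doses <- function(mat, ids = NULL, snps = NULL) {
  rownames(mat) <- ids %||% sprintf("I%03d", seq_len(nrow(mat)))
  colnames(mat) <- snps %||% sprintf("snp%02d", seq_len(ncol(mat)))
  mat
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("call-rate QC flags SNPs below threshold", {
  m <- make_doses(matrix(rbinom(500, 2, 0.4), 100, 5))
  m[1:6, 2] <- NA                        # 94/100
  m[1, 3] <- NA                          # 99/100
  qc <- qc_call_rate(m, threshold = 0.95)
  expect_equal(qc$pass_call_rate, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(qc$call_rate[2], 0.94)

  # one fully missing individual leaves every SNP at 999/1000
  m2 <- make_doses(matrix(1, 1000, 4))
  m2[500, ] <- NA
  expect_true(all(qc_call_rate(m2, 0.95)$pass_call_rate))
  expect_error(qc_call_rate(m2[0, , drop = FALSE]), "empty")
})

test_that("monomorphic SNPs are detected from non-missing calls", {
  m <- make_doses(cbind(rep(0, 50), rep(2, 50), rbinom(50, 2, 0.5),
                        c(rep(0, 49), NA)))
  expect_equal(unname(is_monomorphic(m)), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("tri-allelic genotypes recode to risk-allele counts", {
  expect_equal(recode_triallelic(c("A/A", "A/B", "A/C", "B/C", "C/C", NA), "A"),
               c(2L, 1L, 1L, 0L, 0L, NA))
  expect_error(recode_triallelic(c("A/B", "A/Z"), "A",
                                 valid_alleles = c("A", "B", "C")),
               "unknown allele")
  expect_equal(recode_triallelic(c(0, 1, 2, NA), "A"), c(0L, 1L, 2L, NA))
  expect_error(recode_triallelic(c(0, 3), "A"), "0, 1, 2")
  # codomain on a random tri-allelic sample
  set.seed(1)
  g <- paste(sample(c("A", "B", "C"), 200, TRUE),
             sample(c("A", "B", "C"), 200, TRUE), sep = "/")
  expect_true(all(recode_triallelic(g, "A") %in% 0:2))
})

test_that("Hardy-Weinberg chi-square matches hand arithmetic", {
  # exact HWE proportions: statistic 0, p 1
  r <- hwe_test(c(25, 50, 25))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # (10,10,10): freq 0.5, expected (7.5, 15, 7.5), X2 = 10/3
  r2 <- hwe_test(c(10, 10, 10))
  expect_equal(r2$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(r2$p, pchisq(10 / 3, 1, lower.tail = FALSE))
  expect_equal(r2$freq, 0.5)
  # exact test agrees with chi-square asymptotically at balanced counts
  r3 <- hwe_test(c(10, 10, 10), method = "exact")
  expect_lt(r3$p, 0.2)
})

test_that("sibship sampling takes one representative per mother", {
  coh <- simulate_cohort(sim_config(n_families = 60, seed = 21))
  doses <- genotype_doses(coh$genotypes)
  hw <- hwe_test_sibship(doses, coh$pedigree, seed = 3)
  sampled <- attr(hw, "sampled_ids")
  mums <- coh$pedigree$mother_id[match(sampled, coh$pedigree$individual_id)]
  expect_equal(length(sampled), 60L)
  expect_false(any(duplicated(mums)))
  expect_equal(attr(hw, "threshold"), 0.05 / ncol(doses))
  # same seed, same draw
  hw2 <- hwe_test_sibship(doses, coh$pedigree, seed = 3)
  expect_identical(sampled, attr(hw2, "sampled_ids"))
  # individuals absent from the pedigree are singleton sibships
  hw3 <- hwe_test_sibship(doses, coh$pedigree[-1, ], seed = 3)
  n_expected <- length(unique(coh$pedigree$mother_id[-1])) + 1L
  expect_equal(length(attr(hw3, "sampled_ids")), n_expected)
})

test_that("mean-allele imputation follows the twice-frequency rule", {
  set.seed(4)
  m <- make_doses(matrix(rbinom(28 * 40, 2, 0.3), 40, 28))
  m[1, 1:6] <- NA                        # 6 of 28 -> excluded
  m[2, 1:5] <- NA                        # 5 of 28 -> retained
  m[3, 7] <- NA
  imp <- impute_missing(m)
  expect_true(imp$excluded[1])
  expect_false(imp$excluded[2])
  f1 <- mean(m[, 1], na.rm = TRUE) / 2
  expect_equal(imp$doses[2, 1], 2 * f1)
  expect_true(all(is.na(imp$doses[1, 1:6])))
  # with nobody excluded, imputation preserves each SNP's observed mean
  m3 <- make_doses(matrix(rbinom(28 * 50, 2, 0.4), 50, 28))
  m3[matrix(runif(length(m3)) < 0.05, 50, 28)] <- NA
  m3 <- m3[rowSums(is.na(m3)) <= 5, , drop = FALSE]
  imp3 <- impute_missing(m3)
  for (j in seq_len(ncol(m3))) {
    expect_equal(mean(imp3$doses[, j]), mean(m3[, j], na.rm = TRUE),
                 tolerance = 1e-12)
  }
  m_all_na <- m; m_all_na[, 2] <- NA
  expect_error(impute_missing(m_all_na), "zero non-missing")
})

test_that("score bounds, sums and order invariance hold", {
  m <- make_doses(rbind(rep(2, 28), rep(0, 28), c(2, 1, 0, rep(0, 25))))
  sc <- compute_score(m)
  expect_equal(sc$score, c(56, 0, 3))
  perm <- sample(ncol(m))
  expect_equal(compute_score(m[, perm])$score, sc$score)
  m_na <- m; m_na[1, 1] <- NA
  expect_error(compute_score(m_na), "impute_missing")
})

test_that("imputed scores are unbiased for the true score under MCAR", {
  set.seed(11)
  reps <- 200
  err <- replicate(reps, {
    m <- matrix(rbinom(28 * 60, 2, runif(28, 0.2, 0.8)[rep(1:28, each = 60)]),
                60, 28)
    truth <- rowSums(m)
    m_obs <- m
    m_obs[matrix(runif(length(m)) < 0.03, 60, 28)] <- NA
    imp <- impute_missing(make_doses(m_obs))
    keep <- !imp$excluded
    mean(rowSums(imp$doses[keep, , drop = FALSE]) - truth[keep])
  })
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(reps))
})

test_that("end-to-end score construction drops the right SNPs", {
  coh <- simulate_cohort(sim_config(n_families = 80, seed = 22))
  sc <- build_allele_score(coh$genotypes, coh$pedigree, seed = 22)
  panel <- coh$genotypes$panel
  expect_setequal(sc$snp_qc$snp_id[sc$snp_qc$monomorphic],
                  panel$snp_id[panel$monomorphic])
  expect_lte(length(sc$scored_snps), 28L)
  ok <- !sc$scores$excluded
  expect_true(all(sc$scores$score[ok] >= 0 &
                    sc$scores$score[ok] <= 2 * length(sc$scored_snps)))
  # scores track the generator truth closely (only imputation noise)
  truth <- coh$truth$true_scores[sc$scores$individual_id[ok]]
  expect_gt(cor(sc$scores$score[ok], truth), 0.98)
})

test_that("VCF export and ingest round-trip the dose matrix", {
  coh <- simulate_cohort(sim_config(n_families = 15, seed = 23))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(coh, path)
  panel <- coh$genotypes$panel
  panel$risk_allele <- ifelse(panel$triallelic, "A", "A")
  doses_vcf <- read_genotypes_vcf(path, panel)
  doses <- genotype_doses(coh$genotypes)
  expect_equal(doses_vcf[rownames(doses), colnames(doses)], doses)
})
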