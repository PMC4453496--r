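## Genotype QC and combined risk-allele score construction.
##
## Genotypes are counts of BMI-increasing alleles (0/1/2, NA when missing);
## allele-pair strings (e.g. "A/C") are recoded to risk-allele counts first.
## QC: call-rate filter (default 0.95), monomorphic-SNP exclusion,
## Hardy-Weinberg test on one randomly sampled representative per sibship
## with a Bonferroni threshold computed as 0.05 / number of SNPs tested.
## Missing genotypes are imputed with the mean allele count (twice the
## risk-allele frequency) unless an individual misses too many SNPs, in which
## case the individual is excluded from scoring.

as_geno_matrix <- function(genotypes) {
  if (inherits(genotypes, "grs_genotypes")) genotypes <- genotypes$calls
  if (is.data.frame(genotypes)) {
    ids <- if ("individual_id" %in% names(genotypes)) {
      genotypes$individual_id
    } else {
      rownames(genotypes)
    }
    genotypes <- genotypes[, setdiff(names(genotypes), "individual_id"),
                           drop = FALSE]
    m <- if (all(vapply(genotypes, is.numeric, logical(1)))) {
      data.matrix(genotypes)
    } else {
      ## column-wise conversion: as.matrix() would format-pad numeric columns
      vapply(genotypes, as.character, character(nrow(genotypes)))
    }
    if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, names(genotypes)))
    rownames(m) <- ids
    m
  } else {
    as.matrix(genotypes)
  }
}

#' Recode allele-pair genotypes to risk-allele counts
#'
#' Counts occurrences of the risk allele in genotype strings such as `"A/C"`,
#' regardless of which non-risk alleles are present; this is how a
#' tri-allelic marker is recoded to a biallelic dose. Numeric input is
#' validated and passed through.
#'
#' @param calls Vector of genotype calls: numeric counts in `{0,1,2}` or
#'   strings `"X/Y"`; `NA` allowed.
#' @param risk_allele Single allele code counted as the risk allele.
#' @param valid_alleles Optional character vector; allele codes outside it are
#'   an error.
#' @return Integer vector of risk-allele counts (`NA` preserved).
#' @export
#' @examples
#' recode_triallelic(c("A/A", "A/C", "B/C", NA), "A")
recode_triallelic <- function(calls, risk_allele, valid_alleles = NULL) {
  if (is.numeric(calls)) {
    bad <- !is.na(calls) & !calls %in% 0:2
    if (any(bad)) stop("numeric genotype calls must be 0, 1, 2 or NA",
                       call. = FALSE)
    return(as.integer(calls))
  }
  parts <- strsplit(as.character(calls), "/", fixed = TRUE)
  ok <- !is.na(calls)
  if (any(lengths(parts)[ok] != 2L)) {
    stop("genotype strings must be of the form 'X/Y'", call. = FALSE)
  }
  alleles <- unlist(parts[ok])
  if (!is.null(valid_alleles) && !all(alleles %in% valid_alleles)) {
    stop("unknown allele code in genotype calls: ",
         paste(setdiff(alleles, valid_alleles), collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_integer_, length(calls))
  out[ok] <- vapply(parts[ok], function(p) sum(p == risk_allele), integer(1))
  out
}

#' Standardize a genotype table to a numeric dose matrix
#'
#' Converts any character (allele-pair) columns to risk-allele counts using
#' the panel's risk-allele codes, leaving numeric columns untouched.
#'
#' @param genotypes Genotype table (`grs_genotypes`, data frame with
#'   `individual_id`, or matrix).
#' @param risk_alleles Named character vector `snp_id -> risk allele code` for
#'   any string-coded SNPs (default `"A"`).
#' @return Numeric matrix individuals x SNPs of risk-allele counts.
#' @export
genotype_doses <- function(genotypes, risk_alleles = NULL) {
  m <- as_geno_matrix(genotypes)
  if (is.numeric(m)) return(m)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(is.na(col)) || all(grepl("^[0-9.]+$", col[!is.na(col)]))) {
      out[, j] <- as.numeric(col)
    } else {
      ra <- if (!is.null(risk_alleles) && colnames(m)[j] %in% names(risk_alleles))
        risk_alleles[[colnames(m)[j]]] else "A"
      out[, j] <- recode_triallelic(col, ra)
    }
  }
  out
}

#' Flag SNPs by genotyping call rate
#'
#' @param doses Numeric dose matrix (individuals x SNPs, `NA` = missing).
#' @param threshold Minimum call rate, in `(0,1]`; default 0.95.
#' @return Data frame `snp_id`, `call_rate`, `pass_call_rate`.
#' @export
qc_call_rate <- function(doses, threshold = 0.95) {
  doses <- as_geno_matrix(doses)
  if (nrow(doses) == 0L || ncol(doses) == 0L) {
    stop("empty genotype matrix", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold <= 1)
  cr <- colMeans(!is.na(doses))
  data.frame(snp_id = colnames(doses), call_rate = as.numeric(cr),
             pass_call_rate = as.numeric(cr) >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag monomorphic SNPs
#'
#' A SNP is monomorphic when its non-missing calls show a single allele, i.e.
#' all doses are 0 or all are 2.
#'
#' @param doses Numeric dose matrix.
#' @return Logical vector, `TRUE` where monomorphic (all-`NA` SNPs included).
#' @export
is_monomorphic <- function(doses) {
  doses <- as_geno_matrix(doses)
  apply(doses, 2, function(g) {
    g <- g[!is.na(g)]
    length(g) == 0L || all(g == 0) || all(g == 2)
  })
}

#' Chi-square (or exact) Hardy-Weinberg goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' Hardy-Weinberg expectations at the sample allele frequency, without
#' continuity correction; optionally the exact heterozygote-conditional test
#' for low-frequency alleles.
#'
#' @param counts Integer vector `(n0, n1, n2)` of genotype counts by
#'   risk-allele dose.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return List with `statistic` (chi-square; `NA` for exact), `p`, `freq`.
#' @export
#' @examples
#' hwe_test(c(10, 10, 10))$statistic  # 10/3
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0L) return(list(statistic = NA_real_, p = NA_real_, freq = NA_real_))
  p_hat <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p_hat %in% c(0, 1)) {
    return(list(statistic = 0, p = 1, freq = p_hat))
  }
  if (method == "chisq") {
    expected <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    stat <- sum((counts - expected)^2 / expected)
    list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
         freq = p_hat)
  } else {
    list(statistic = NA_real_, p = hwe_exact_p(counts), freq = p_hat)
  }
}

## exact HWE p-value: probability, conditional on allele counts, of
## heterozygote counts at least as improbable as observed
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_rare <- min(2 * counts[3] + counts[2], 2 * counts[1] + counts[2])
  het_obs <- counts[2]
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  log_prob <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  min(1, sum(prob[prob <= prob[match(het_obs, hets)] + 1e-12]))
}

#' Per-SNP Hardy-Weinberg test on one representative per sibship
#'
#' Samples one individual per sibship (individuals sharing a mother; anyone
#' absent from the pedigree is a singleton sibship) with the given seed, then
#' tests each SNP's genotype counts against Hardy-Weinberg expectations.
#' SNPs with p below the Bonferroni threshold `alpha / n_snps_tested` are
#' flagged.
#'
#' @param doses Numeric dose matrix.
#' @param pedigree Data frame with `individual_id` and `mother_id`.
#' @param seed Integer seed for the one-per-sibship sampling.
#' @param alpha Familywise error rate for the Bonferroni flag (default 0.05).
#' @param method Passed to [hwe_test()].
#' @param min_sampled Minimum sampled individuals required; below it the test
#'   is skipped with a warning.
#' @return Data frame `snp_id`, `chisq`, `p`, `freq`, `fail_hwe`, with
#'   attributes `threshold` and `sampled_ids`.
#' @export
hwe_test_sibship <- function(doses, pedigree, seed = 1L, alpha = 0.05,
                             method = "chisq", min_sampled = 20L) {
  doses <- as_geno_matrix(doses)
  ids <- rownames(doses)
  sib <- pedigree$mother_id[match(ids, pedigree$individual_id)]
  sib[is.na(sib)] <- paste0("singleton:", ids[is.na(sib)])
  set.seed(seed)
  pick <- tapply(seq_along(ids), sib, function(ix)
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)])
  pick <- sort(unlist(pick, use.names = FALSE))
  if (length(pick) < min_sampled) {
    warning("fewer than ", min_sampled,
            " sampled sibship representatives; Hardy-Weinberg test skipped")
    return(data.frame(snp_id = colnames(doses), chisq = NA_real_,
                      p = NA_real_, freq = NA_real_, fail_hwe = FALSE,
                      stringsAsFactors = FALSE))
  }
  sub <- doses[pick, , drop = FALSE]
  res <- lapply(seq_len(ncol(sub)), function(j) {
    g <- sub[, j]
    g <- g[!is.na(g)]
    hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2)), method = method)
  })
  thr <- alpha / ncol(sub)
  out <- data.frame(
    snp_id = colnames(doses),
    chisq = vapply(res, function(r) r$statistic %||% NA_real_, numeric(1)),
    p = vapply(res, `[[`, numeric(1), "p"),
    freq = vapply(res, `[[`, numeric(1), "freq"),
    stringsAsFactors = FALSE
  )
  out$fail_hwe <- !is.na(out$p) & out$p < thr
  attr(out, "threshold") <- thr
  attr(out, "sampled_ids") <- ids[pick]
  out
}

#' Mean-allele imputation of missing genotypes
#'
#' Replaces each missing genotype with the mean number of risk alleles for
#' that SNP, i.e. twice the risk-allele frequency computed from the
#' non-missing calls of the full analysis sample. Individuals missing
#' `max_missing + 1` or more SNPs are flagged excluded and receive no
#' imputation.
#'
#' @param doses Numeric dose matrix over the SNPs to be scored.
#' @param max_missing Largest number of missing SNPs an individual may have
#'   and still be imputed/scored (default 5, i.e. excluded at 6+ of 28).
#' @return List with `doses` (imputed matrix), `excluded` (logical per
#'   individual), `n_missing` (per individual), `allele_freq` (per SNP).
#' @export
impute_missing <- function(doses, max_missing = 5L) {
  doses <- as_geno_matrix(doses)
  n_obs <- colSums(!is.na(doses))
  if (any(n_obs == 0L)) {
    stop("cannot impute SNP(s) with zero non-missing calls: ",
         paste(colnames(doses)[n_obs == 0L], collapse = ", "), call. = FALSE)
  }
  freq <- colMeans(doses, na.rm = TRUE) / 2
  n_missing <- rowSums(is.na(doses))
  excluded <- n_missing > max_missing
  imp <- doses
  for (j in seq_len(ncol(imp))) {
    miss <- is.na(imp[, j]) & !excluded
    imp[miss, j] <- 2 * freq[j]
  }
  list(doses = imp, excluded = excluded, n_missing = n_missing,
       allele_freq = freq)
}

#' Combined risk-allele score
#'
#' Sums risk-allele counts (fractional after imputation) across all scored
#' SNPs. Excluded individuals must already have been removed; any remaining
#' missing value is a contract violation and errors.
#'
#' @param doses Imputed dose matrix (no `NA`).
#' @param n_missing Optional per-individual count of originally missing
#'   genotypes, recorded in the output.
#' @return Data frame `individual_id`, `score`, `n_imputed`.
#' @export
compute_score <- function(doses, n_missing = NULL) {
  doses <- as_geno_matrix(doses)
  if (anyNA(doses)) {
    stop("missing genotypes remain; run impute_missing() first",
         call. = FALSE)
  }
  if (any(doses < 0 | doses > 2)) {
    stop("genotype doses must lie in [0, 2]", call. = FALSE)
  }
  data.frame(individual_id = rownames(doses) %||% seq_len(nrow(doses)),
             score = rowSums(doses),
             n_imputed = if (is.null(n_missing)) 0L else as.integer(n_missing),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full genotype QC and score construction
#'
#' Applies, in order: allele-pair recoding to risk-allele doses, the
#' call-rate filter, monomorphic-SNP exclusion, the one-per-sibship
#' Hardy-Weinberg screen (failing SNPs dropped by default), the
#' missing-genotype exclusion rule, mean-allele imputation, and score
#' summation.
#'
#' @param genotypes Genotype table (`grs_genotypes`, data frame or matrix).
#' @param pedigree Pedigree data frame (for sibship sampling).
#' @param call_rate_threshold Minimum per-SNP call rate (default 0.95).
#' @param max_missing Individual exclusion threshold (default 5 missing
#'   retained, 6+ excluded).
#' @param hwe_alpha Familywise alpha for the Hardy-Weinberg flag.
#' @param hwe_method `"chisq"` or `"exact"`.
#' @param drop_hwe_failures Drop SNPs failing the Hardy-Weinberg screen from
#'   the score (default `TRUE`).
#' @param risk_alleles Named risk-allele codes for string-coded SNPs.
#' @param seed Seed for the sibship sampling.
#' @return Object of class `allele_score`: list with `scores` (data frame
#'   `individual_id`, `score`, `n_imputed`, `excluded`), `snp_qc` (per-SNP
#'   report), `scored_snps`, `allele_freq`, `hwe` and `excluded_ids`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_families = 40, seed = 3))
#' sc <- build_allele_score(coh$genotypes, coh$pedigree, seed = 3)
#' sc
build_allele_score <- function(genotypes, pedigree,
                               call_rate_threshold = 0.95,
                               max_missing = 5L,
                               hwe_alpha = 0.05,
                               hwe_method = "chisq",
                               drop_hwe_failures = TRUE,
                               risk_alleles = NULL,
                               seed = 1L) {
  doses <- genotype_doses(genotypes, risk_alleles)
  qc <- qc_call_rate(doses, call_rate_threshold)
  qc$monomorphic <- as.logical(is_monomorphic(doses))

  keep <- qc$pass_call_rate & !qc$monomorphic
  hwe <- hwe_test_sibship(doses[, keep, drop = FALSE], pedigree, seed = seed,
                          alpha = hwe_alpha, method = hwe_method)
  qc$fail_hwe <- FALSE
  qc$fail_hwe[match(hwe$snp_id, qc$snp_id)] <- hwe$fail_hwe
  qc$hwe_p <- NA_real_
  qc$hwe_p[match(hwe$snp_id, qc$snp_id)] <- hwe$p

  scored <- keep & (!drop_hwe_failures | !qc$fail_hwe)
  qc$scored <- scored
  if (!any(scored)) stop("no SNPs left to score after QC", call. = FALSE)

  sub <- doses[, scored, drop = FALSE]
  imp <- impute_missing(sub, max_missing = max_missing)
  retained <- !imp$excluded
  scores <- compute_score(imp$doses[retained, , drop = FALSE],
                          imp$n_missing[retained])
  scores$excluded <- FALSE
  if (any(imp$excluded)) {
    excl <- data.frame(individual_id = rownames(doses)[imp$excluded],
                       score = NA_real_,
                       n_imputed = as.integer(imp$n_missing[imp$excluded]),
                       excluded = TRUE, stringsAsFactors = FALSE)
    scores <- rbind(scores, excl)
  }
  scores <- scores[match(rownames(doses), scores$individual_id), ]
  rownames(scores) <- NULL
  structure(list(scores = scores, snp_qc = qc,
                 scored_snps = qc$snp_id[scored],
                 allele_freq = imp$allele_freq, hwe = hwe,
                 excluded_ids = rownames(doses)[imp$excluded]),
            class = "allele_score")
}

#' @export
print.allele_score <- function(x, ...) {
  n <- nrow(x$scores)
  cat("Combined risk-allele score over", length(x$scored_snps), "SNPs\n")
  cat(sprintf("  %d individuals (%d excluded for missingness)\n",
              n, length(x$excluded_ids)))
  s <- x$scores$score[!x$scores$excluded]
  cat(sprintf("  score: mean %.2f, sd %.2f, range [%.1f, %.1f]\n",
              mean(s), sd(s), min(s), max(s)))
  if (any(x$snp_qc$monomorphic)) {
    cat("  monomorphic SNPs dropped:",
        paste(x$snp_qc$snp_id[x$snp_qc$monomorphic], collapse = ", "), "\n")
  }
  if (any(x$snp_qc$fail_hwe, na.rm = TRUE)) {
    cat("  Hardy-Weinberg failures:",
        paste(x$snp_qc$snp_id[x$snp_qc$fail_hwe], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read genotypes from a minimal VCF using a risk-allele panel
#'
#' Maps each variant's GT field to a count of the panel's risk allele.
#' Requires the vcfR package.
#'
#' @param vcf_path Path to a VCF file.
#' @param panel Data frame with `snp_id` and `risk_allele` (allele base).
#' @return Numeric dose matrix individuals x SNPs.
#' @export
read_genotypes_vcf <- function(vcf_path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingest requires the vcfR package", call. = FALSE)
  }
  assert_columns(panel, c("snp_id", "risk_allele"), "panel")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- matrix(NA_real_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), fix[, "ID"]))
  for (j in seq_len(nrow(gt))) {
    alleles <- c(fix[j, "REF"], strsplit(fix[j, "ALT"], ",", fixed = TRUE)[[1]])
    risk <- panel$risk_allele[match(fix[j, "ID"], panel$snp_id)]
    risk_idx <- as.character(which(alleles == risk) - 1L)
    parts <- strsplit(gt[j, ], "[/|]")
    out[, j] <- vapply(parts, function(p) {
      if (length(p) == 0L || anyNA(p) || any(p == ".")) NA_real_
      else sum(p == risk_idx)
    }, numeric(1))
  }
  out
}
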