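## Synthetic cohort generator
##
## Emulates a rural-subsistence cohort followed from birth into adulthood:
## mother-defined sibships, a SNP panel transmitted Mendelianly from simulated
## parents, a dense infant / sparse later measurement schedule, and a
## per-allele effect on weight-for-height that grows linearly with age,
## injected on the z-scale on top of family / individual / observation
## variance components.

#' Default SNP panel for the cohort simulator
#'
#' Thirty biallelic-coded SNPs: 27 polymorphic biallelic markers with
#' risk-allele frequencies spread over (0.15, 0.85), one tri-allelic marker
#' (three allele codes, recoded downstream by risk-allele count), and two
#' monomorphic distractors that carry no risk allele and are expected to be
#' dropped by QC, leaving 28 scored SNPs.
#'
#' @return Data frame with columns `snp_id`, `risk_freq`, `triallelic`,
#'   `monomorphic`.
#' @export
default_snp_panel <- function() {
  n_scored <- 28L
  panel <- data.frame(
    snp_id = sprintf("snp%02d", 1:30),
    risk_freq = c(seq(0.15, 0.85, length.out = n_scored), 0, 0),
    triallelic = FALSE,
    monomorphic = c(rep(FALSE, n_scored), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  panel$triallelic[10L] <- TRUE
  panel
}

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic cohort. The
#' defaults emulate the target study population: ~625 sibships with a mean of
#' 4 offspring (~2,500 individuals), ~17 weight/height measurements each
#' (dense to 2 years, sparse to adulthood), a 30-SNP panel of which 28 are
#' scored, and a per-allele weight-for-height effect `delta0 + delta1 * age`
#' in z-units injected over family / individual / observation variance
#' components.
#'
#' @param n_families Number of sibships (mothers).
#' @param offspring List `(min, max, mean)` for the truncated-Poisson
#'   offspring-count distribution.
#' @param snp_panel Data frame as returned by [default_snp_panel()].
#' @param missing_rate Per-genotype missingness probability (MCAR), in `[0,1)`.
#' @param effect_intercept Per-allele z-score effect at birth (z-units/allele).
#' @param effect_slope Increase of the per-allele effect with age
#'   (z-units/allele/year).
#' @param var_family,var_individual,var_observation Variance components on the
#'   z-scale (z-units squared).
#' @param n_villages Number of villages (categorical covariate levels).
#' @param birth_year_range Two-element numeric, inclusive birth-year range.
#' @param study_end_year Calendar year at which follow-up stops.
#' @param schedule List with `dense_n` (measurements after birth within the
#'   first `dense_max_age` years), `dense_max_age`, `sparse_interval` (years
#'   between later visits) and `max_age` (oldest measured age).
#' @param twin_rate Probability that a sibship of two or more contains a twin
#'   pair, scaled per offspring; the default yields about nine pairs in a
#'   2,500-child cohort.
#' @param sex_ratio_female Probability that a child is female.
#' @param ref_sd Reference SD of log-weight used to map z-scale effects onto
#'   the measurement scale.
#' @param height_cv SD of the individual log-height multiplier.
#' @param height_noise_sd SD of per-measurement log-height noise.
#' @param seed Integer seed; fans out to per-stage seeds.
#' @return Object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_families = 5, seed = 1)
sim_config <- function(n_families = 625L,
                       offspring = list(min = 1L, max = 8L, mean = 4),
                       snp_panel = default_snp_panel(),
                       missing_rate = 0.012,
                       effect_intercept = 0,
                       effect_slope = 0.0083,
                       var_family = 0.2,
                       var_individual = 0.3,
                       var_observation = 0.5,
                       n_villages = 3L,
                       birth_year_range = c(1950, 2005),
                       study_end_year = 2008,
                       schedule = list(dense_n = 11L, dense_max_age = 2,
                                       sparse_interval = 5, max_age = 60),
                       twin_rate = 0.0036,
                       sex_ratio_female = 0.5,
                       ref_sd = 0.12,
                       height_cv = 0.03,
                       height_noise_sd = 0.006,
                       seed = 1L) {
  if (!is_count(n_families) || n_families < 1) {
    stop("n_families must be a positive integer", call. = FALSE)
  }
  off <- offspring
  if (!all(c("min", "max", "mean") %in% names(off)) ||
      off$min < 1 || off$max < off$min ||
      (off$min < off$max && (off$mean <= off$min || off$mean >= off$max)) ||
      (off$min == off$max && off$mean != off$min)) {
    stop("offspring must give min >= 1, max >= min and min < mean < max ",
         "(or min = mean = max for a fixed count)", call. = FALSE)
  }
  assert_columns(snp_panel, c("snp_id", "risk_freq", "triallelic", "monomorphic"),
                 "snp_panel")
  if (any(snp_panel$risk_freq < 0 | snp_panel$risk_freq > 1)) {
    stop("risk-allele frequencies must lie in [0,1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0,1)", call. = FALSE)
  }
  for (v in c(var_family, var_individual, var_observation)) {
    if (!is.finite(v) || v < 0) stop("variances must be finite and >= 0",
                                     call. = FALSE)
  }
  max_age <- schedule$max_age
  if (!all(is.finite(effect_intercept + effect_slope * c(0, max_age)))) {
    stop("effect trajectory must be finite over the age range", call. = FALSE)
  }
  if (twin_rate < 0 || twin_rate >= 1) stop("twin_rate must lie in [0,1)",
                                            call. = FALSE)
  structure(list(
    n_families = as.integer(n_families), offspring = off,
    snp_panel = snp_panel, missing_rate = missing_rate,
    effect_intercept = effect_intercept, effect_slope = effect_slope,
    var_family = var_family, var_individual = var_individual,
    var_observation = var_observation, n_villages = as.integer(n_villages),
    birth_year_range = birth_year_range, study_end_year = study_end_year,
    schedule = schedule, twin_rate = twin_rate,
    sex_ratio_female = sex_ratio_female, ref_sd = ref_sd,
    height_cv = height_cv, height_noise_sd = height_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## truncated Poisson on [min, max]; lambda solved so the truncated mean hits
## the requested mean
truncpois_lambda <- function(mean, min, max) {
  tmean <- function(lam) {
    k <- min:max
    p <- dpois(k, lam)
    sum(k * p) / sum(p)
  }
  uniroot(function(l) tmean(l) - mean, c(1e-8, 4 * max), tol = 1e-10)$root
}

rtruncpois <- function(n, mean, min, max) {
  if (min == max) return(rep(min, n))
  lam <- truncpois_lambda(mean, min, max)
  k <- min:max
  p <- dpois(k, lam)
  sample(k, n, replace = TRUE, prob = p)
}

#' Simulate the pedigree skeleton of a cohort
#'
#' Draws sibships (a mother and her offspring), assigns villages, sexes and
#' continuous birth dates, and marks twin pairs (twins share a birth date).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding the pedigree-stage seed derived
#'   from `config$seed`.
#' @return Data frame of class `grs_pedigree`: one row per child with
#'   `individual_id`, `mother_id`, `village`, `sex`, `birth_year`,
#'   `birth_date` (decimal year), `twin_id`, `ethnicity`.
#' @export
simulate_pedigree <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% fan_out_seeds(config$seed, "pedigree")[["pedigree"]])
  nf <- config$n_families
  off <- config$offspring
  counts <- rtruncpois(nf, off$mean, off$min, off$max)
  n <- sum(counts)
  mother_id <- sprintf("M%04d", seq_len(nf))
  mother_village <- sprintf("V%d", sample.int(config$n_villages, nf,
                                              replace = TRUE))
  fam <- rep(seq_len(nf), counts)
  byr <- config$birth_year_range
  birth_date <- runif(n, byr[1], byr[2] + 1)
  sex <- ifelse(runif(n) < config$sex_ratio_female, "F", "M")

  twin_id <- rep(NA_character_, n)
  if (config$twin_rate > 0) {
    first_child <- match(seq_len(nf), fam)
    eligible <- which(counts >= 2)
    is_twin_fam <- runif(length(eligible)) < config$twin_rate * counts[eligible]
    tf <- eligible[is_twin_fam]
    for (j in seq_along(tf)) {
      i1 <- first_child[tf[j]]
      i2 <- i1 + 1L
      birth_date[i2] <- birth_date[i1]
      sex[i2] <- sex[i1]                       # monozygotic-style pairs
      twin_id[c(i1, i2)] <- sprintf("T%03d", j)
    }
  }

  ped <- data.frame(
    individual_id = sprintf("I%05d", seq_len(n)),
    mother_id = mother_id[fam],
    village = mother_village[fam],
    sex = sex,
    birth_year = floor(birth_date),
    birth_date = birth_date,
    twin_id = twin_id,
    ethnicity = ifelse(runif(n) < 0.95, "majority", "other"),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("grs_pedigree", "data.frame")
  ped
}

## allele draw for one SNP: founders Hardy-Weinberg at the configured
## frequency; offspring Mendelian given the simulated parental haplotypes
draw_snp <- function(ped, fam_index, nf, freq, triallelic, monomorphic) {
  n <- nrow(ped)
  if (monomorphic) {
    return(list(true = rep(0L, n), call = rep(0L, n)))
  }
  if (triallelic) {
    # risk allele "A"; the non-risk mass is split over "B" and "C"
    alleles <- c("A", "B", "C")
    p <- c(freq, (1 - freq) * 0.6, (1 - freq) * 0.4)
    draw <- function(k) matrix(sample(alleles, 2 * k, replace = TRUE, prob = p),
                               ncol = 2)
    mum <- draw(nf); dad <- draw(nf)
    a1 <- mum[cbind(fam_index, sample.int(2, n, replace = TRUE))]
    a2 <- dad[cbind(fam_index, sample.int(2, n, replace = TRUE))]
    gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    true <- (a1 == "A") + (a2 == "A")
    return(list(true = as.integer(true), call = gt))
  }
  mum <- matrix(rbinom(2 * nf, 1, freq), ncol = 2)
  dad <- matrix(rbinom(2 * nf, 1, freq), ncol = 2)
  a1 <- mum[cbind(fam_index, sample.int(2, n, replace = TRUE))]
  a2 <- dad[cbind(fam_index, sample.int(2, n, replace = TRUE))]
  cnt <- as.integer(a1 + a2)
  list(true = cnt, call = cnt)
}

#' Simulate genotypes with Mendelian transmission
#'
#' Founder (parental) genotypes are drawn at Hardy-Weinberg proportions at the
#' configured risk-allele frequency; each child inherits one allele from the
#' mother and one from a per-sibship father, so sibling genotypes are
#' correlated as the clustered models assume. The tri-allelic marker emits
#' sorted allele-pair strings over three codes; monomorphic markers are
#' constant. Missingness is applied completely at random.
#'
#' @param pedigree A `grs_pedigree`.
#' @param config The matching [sim_config()].
#' @param seed Optional integer overriding the genotype-stage seed.
#' @return Object of class `grs_genotypes`: list with `calls` (data frame,
#'   `individual_id` plus one column per SNP; counts for biallelic markers,
#'   allele-pair strings for the tri-allelic one, `NA` where missing),
#'   `panel`, and `true_counts` (complete risk-allele count matrix before
#'   missingness).
#' @export
simulate_genotypes <- function(pedigree, config, seed = NULL) {
  stopifnot(inherits(pedigree, "grs_pedigree"), inherits(config, "sim_config"))
  set.seed(seed %||% fan_out_seeds(config$seed, c("pedigree", "genotypes"))[["genotypes"]])
  panel <- config$snp_panel
  nf <- length(unique(pedigree$mother_id))
  fam_index <- match(pedigree$mother_id, unique(pedigree$mother_id))
  n <- nrow(pedigree)

  calls <- vector("list", nrow(panel))
  true_counts <- matrix(NA_integer_, n, nrow(panel),
                        dimnames = list(pedigree$individual_id, panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    g <- draw_snp(pedigree, fam_index, nf, panel$risk_freq[j],
                  panel$triallelic[j], panel$monomorphic[j])
    true_counts[, j] <- g$true
    cl <- g$call
    if (config$missing_rate > 0) {
      cl[runif(n) < config$missing_rate] <- NA
    }
    calls[[j]] <- cl
  }
  calls <- as.data.frame(calls, col.names = panel$snp_id,
                         stringsAsFactors = FALSE)
  calls <- cbind(data.frame(individual_id = pedigree$individual_id,
                            stringsAsFactors = FALSE), calls)
  structure(list(calls = calls, panel = panel, true_counts = true_counts),
            class = "grs_genotypes")
}

## sex-specific mean growth curves; monotone and realistic in range
## (birthweight ~2.9 kg, adult weight ~55-59 kg, adult height 1.59/1.70 m)
height_curve <- function(age, sex) {
  h_adult <- ifelse(sex == "F", 1.59, 1.70)
  frac <- 0.30 * (1 - exp(-1.1 * age)) + 0.70 * pmin(age, 16.5) / 16.5
  0.50 + (h_adult - 0.50) * frac
}

bmi_curve <- function(age, sex) {
  rise <- ifelse(sex == "F", 9, 7)
  11.6 + 5.4 * (1 - exp(-3 * age)) - 1.5 * (1 - exp(-(age / 4)^2)) +
    rise * age^2 / (age^2 + 500)
}

#' Simulate longitudinal weight/height measurements
#'
#' Each child receives a birth record, dense measurements to age 2, and sparse
#' later visits up to the attained age at end of follow-up. Log-weight is the
#' sex-specific mean body-mass curve plus a height coupling (coefficient 2 on
#' log-height) plus, on the z-scale scaled by `ref_sd`, the genetic effect
#' `score * (delta0 + delta1 * age)` and family / individual / observation
#' random effects with the configured variances.
#'
#' @param pedigree A `grs_pedigree`.
#' @param genotypes The matching `grs_genotypes`.
#' @param config The matching [sim_config()].
#' @param seed Optional integer overriding the measurement-stage seed.
#' @return Data frame of class `grs_anthro` with `individual_id`, `age`
#'   (years), `weight_kg`, `height_m`, and a truth channel `z_true` (the
#'   generated z-scale value `centered score * (delta0 + delta1 * age) +
#'   family + individual + observation effects`, exactly the model class of
#'   the three-level association model; ignored by the pipeline and omitted
#'   from written inputs).
#' @export
simulate_measurements <- function(pedigree, genotypes, config, seed = NULL) {
  stopifnot(inherits(pedigree, "grs_pedigree"),
            inherits(genotypes, "grs_genotypes"),
            inherits(config, "sim_config"))
  set.seed(seed %||% fan_out_seeds(
    config$seed, c("pedigree", "genotypes", "measurements"))[["measurements"]])

  scored <- !config$snp_panel$monomorphic
  true_score <- rowSums(genotypes$true_counts[, scored, drop = FALSE])
  ## center the score for the mean structure: the per-allele slope is
  ## unchanged, while the population-mean shift (mean score x effect) stays
  ## inside the sex-specific mean curve, keeping weights in range
  score_c <- true_score - 2 * sum(config$snp_panel$risk_freq[scored])

  nf <- length(unique(pedigree$mother_id))
  fam_index <- match(pedigree$mother_id, unique(pedigree$mother_id))
  u_f <- rnorm(nf, 0, sqrt(config$var_family))
  u_i <- rnorm(nrow(pedigree), 0, sqrt(config$var_individual))
  h_fac <- exp(rnorm(nrow(pedigree), 0, config$height_cv))

  sch <- config$schedule
  d0 <- config$effect_intercept
  d1 <- config$effect_slope

  out <- vector("list", nrow(pedigree))
  for (i in seq_len(nrow(pedigree))) {
    attained <- min(config$study_end_year + 1 - pedigree$birth_date[i],
                    sch$max_age)
    dense <- seq_len(sch$dense_n) * sch$dense_max_age / (sch$dense_n + 1)
    dense <- dense + runif(sch$dense_n, -0.04, 0.04)
    sparse <- seq(sch$dense_max_age + 1, sch$max_age, by = sch$sparse_interval)
    sparse <- sparse + runif(length(sparse), -0.5, 0.5)
    ages <- c(0, dense, sparse)
    ages <- sort(ages[ages >= 0 & ages <= attained])
    if (!length(ages)) ages <- 0

    sex <- pedigree$sex[i]
    h_true <- height_curve(ages, sex) * h_fac[i]
    h_meas <- h_true * exp(rnorm(length(ages), 0, config$height_noise_sd))
    z_part <- score_c[i] * (d0 + d1 * ages) + u_f[fam_index[i]] + u_i[i] +
      rnorm(length(ages), 0, sqrt(config$var_observation))
    log_w <- log(bmi_curve(ages, sex)) + 2 * log(h_meas) + config$ref_sd * z_part
    out[[i]] <- data.frame(individual_id = pedigree$individual_id[i],
                           age = ages, weight_kg = exp(log_w),
                           height_m = h_meas, z_true = z_part,
                           stringsAsFactors = FALSE)
  }
  anthro <- do.call(rbind, out)
  rownames(anthro) <- NULL
  class(anthro) <- c("grs_anthro", "data.frame")
  attr(anthro, "true_score") <- true_score
  anthro
}

#' Simulate a complete cohort with recorded ground truth
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_measurements()] with per-stage seeds fanned out from
#' `config$seed`, and attaches a truth record (realized effect parameters,
#' variance components, founder allele frequencies and per-individual true
#' scores) sufficient to score any estimator's recovery error.
#'
#' @param config A [sim_config()].
#' @return Object of class `grs_cohort`: list with `pedigree`, `genotypes`,
#'   `anthro`, `truth`, `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_families = 10, seed = 7))
#' nrow(coh$pedigree)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- fan_out_seeds(config$seed,
                         c("pedigree", "genotypes", "measurements"))
  ped <- simulate_pedigree(config, seed = seeds[["pedigree"]])
  gen <- simulate_genotypes(ped, config, seed = seeds[["genotypes"]])
  anthro <- simulate_measurements(ped, gen, config,
                                  seed = seeds[["measurements"]])
  scored <- !config$snp_panel$monomorphic
  obs_freq <- colMeans(gen$true_counts) / 2
  obs_freq[config$snp_panel$triallelic] <-
    colMeans(gen$true_counts[, config$snp_panel$triallelic, drop = FALSE]) / 2
  truth <- list(
    delta0 = config$effect_intercept,
    delta1 = config$effect_slope,
    var_family = config$var_family,
    var_individual = config$var_individual,
    var_observation = config$var_observation,
    founder_freqs = setNames(as.numeric(obs_freq), config$snp_panel$snp_id),
    true_scores = setNames(rowSums(gen$true_counts[, scored, drop = FALSE]),
                           ped$individual_id),
    seed = config$seed
  )
  structure(list(pedigree = ped, genotypes = gen, anthro = anthro,
                 truth = truth, config = config),
            class = "grs_cohort")
}

#' @export
print.grs_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$pedigree), "individuals in",
      length(unique(x$pedigree$mother_id)), "sibships;",
      nrow(x$anthro), "measurements;",
      nrow(x$genotypes$panel), "SNPs\n")
  invisible(x)
}

#' Write a simulated cohort as the standard pipeline inputs
#'
#' Writes `pedigree.tsv`, `genotypes.tsv`, `anthro.tsv` and `truth.json` into
#' a directory.
#'
#' @param cohort A `grs_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "grs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$pedigree, file.path(dir, "pedigree.tsv"))
  write_tsv(cohort$genotypes$calls, file.path(dir, "genotypes.tsv"))
  write_tsv(cohort$anthro[, c("individual_id", "age", "weight_kg",
                              "height_m")],
            file.path(dir, "anthro.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export simulated genotypes as a minimal VCF
#'
#' Writes a minimal VCF 4.2 file with GT fields only, coding the risk allele
#' as REF so that the GT allele-count equals the risk-allele count. The
#' tri-allelic marker uses two ALT alleles.
#'
#' @param cohort A `grs_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "grs_cohort"))
  calls <- cohort$genotypes$calls
  panel <- cohort$genotypes$panel
  ids <- calls$individual_id
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  for (j in seq_len(nrow(panel))) {
    v <- calls[[panel$snp_id[j]]]
    if (panel$triallelic[j]) {
      # alleles A (risk) -> 1, B -> 0, C -> 2 relative to REF=B? Keep risk as
      # allele index 1: REF=B (non-risk), ALT=A,C; GT counts of allele "1"
      # give the risk count.
      code <- function(a) c(A = "1", B = "0", C = "2")[a]
      gt <- ifelse(is.na(v), "./.",
                   vapply(strsplit(v, "/", fixed = TRUE), function(p)
                     paste(sort(code(p)), collapse = "/"), ""))
      ref <- "G"; alt <- "A,T"
    } else {
      gt <- c("1/1", "0/1", "0/0")[match(v, c(0, 1, 2))]
      gt[is.na(v)] <- "./."
      ref <- "A"; alt <- "G"
    }
    lines <- c(lines, paste(c("1", as.character(j * 1000), panel$snp_id[j],
                              ref, alt, ".", "PASS", ".", "GT", gt),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
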