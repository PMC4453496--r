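## End-to-end orchestration: simulate or load a cohort, preprocess (twin
## exclusion, missingness flags), QC and score genotypes, standardize,
## extract growth parameters, fit the association models, and emit a results
## bundle with a run manifest whose per-stage counts reconcile
## (stage input = stage output + exclusions).

config_hash <- function(x) {
  ## small stable config hash (polynomial rolling hash, 31-bit) over JSON
  s <- utf8ToInt(paste(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                     force = TRUE)),
                       collapse = ""))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `inputs` (paths to
#' `pedigree`, `genotypes`, `anthro` TSVs) must be given.
#'
#' @param simulation Optional [sim_config()] describing a synthetic cohort.
#' @param inputs Optional named list of input paths.
#' @param call_rate_threshold,max_missing,hwe_alpha,hwe_method Genotype QC
#'   options (see [build_allele_score()]).
#' @param age_degree,height_degree,var_degree Weight-for-height calibration
#'   degrees (see [fit_wfh_calibration()]).
#' @param infant_bin_width Age-bin width (years) for per-measurement infant
#'   z-scores.
#' @param adult_band_years Adult age-sex band width for discrete z-scores.
#' @param min_records,max_se Infant growth filters.
#' @param method Mixed-model estimation method, `"ML"` or `"REML"`.
#' @param include_age_main Include age-basis main effects in the interaction
#'   model.
#' @param seed Master seed; fans out to per-stage seeds.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            call_rate_threshold = 0.95, max_missing = 5L,
                            hwe_alpha = 0.05, hwe_method = "chisq",
                            age_degree = 5L, height_degree = 2L,
                            var_degree = 3L, infant_bin_width = 0.25,
                            adult_band_years = 10, min_records = 5L,
                            max_se = 0.4, method = "ML",
                            include_age_main = TRUE, seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("give exactly one of 'simulation' or 'inputs'", call. = FALSE)
  }
  if (!is.null(inputs)) {
    assert_columns(as.data.frame(inputs[c("pedigree", "genotypes", "anthro")]),
                   c("pedigree", "genotypes", "anthro"), "inputs")
  }
  stopifnot(call_rate_threshold > 0, call_rate_threshold <= 1,
            max_missing >= 0, hwe_alpha > 0, hwe_alpha < 1,
            infant_bin_width > 0, min_records >= 2, max_se > 0,
            method %in% c("ML", "REML"))
  structure(list(simulation = simulation, inputs = inputs,
                 call_rate_threshold = call_rate_threshold,
                 max_missing = as.integer(max_missing),
                 hwe_alpha = hwe_alpha, hwe_method = hwe_method,
                 age_degree = age_degree, height_degree = height_degree,
                 var_degree = var_degree, infant_bin_width = infant_bin_width,
                 adult_band_years = adult_band_years,
                 min_records = as.integer(min_records), max_se = max_se,
                 method = method, include_age_main = include_age_main,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file; a `simulation:` block is passed to [sim_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$simulation)) {
    cfg$simulation <- do.call(sim_config, cfg$simulation)
  }
  do.call(pipeline_config, cfg)
}

check_pedigree <- function(pedigree) {
  assert_columns(pedigree, c("individual_id", "mother_id"), "pedigree")
  mum <- setNames(pedigree$mother_id, pedigree$individual_id)
  for (id in names(mum)) {
    seen <- character(0)
    cur <- id
    while (cur %in% names(mum)) {
      if (cur %in% seen) stop("cyclic mother reference at individual ", cur,
                              call. = FALSE)
      seen <- c(seen, cur)
      cur <- mum[[cur]]
    }
  }
  invisible(pedigree)
}

#' Preprocess a cohort for analysis
#'
#' Randomly drops one member of each twin pair (seeded), removes that
#' member's measurements, and flags measurements with missing weight or
#' height.
#'
#' @param pedigree Pedigree data frame (with `twin_id`).
#' @param anthro Measurement data frame.
#' @param seed Seed for the twin draw.
#' @return List: `pedigree`, `anthro` (with `complete` flag),
#'   `twin_excluded` (ids), `n_incomplete`.
#' @export
preprocess_cohort <- function(pedigree, anthro, seed = 1L) {
  check_pedigree(pedigree)
  drop <- character(0)
  if ("twin_id" %in% names(pedigree) && any(!is.na(pedigree$twin_id))) {
    set.seed(seed)
    for (tid in unique(pedigree$twin_id[!is.na(pedigree$twin_id)])) {
      members <- pedigree$individual_id[pedigree$twin_id %in% tid]
      if (length(members) >= 2L) {
        drop <- c(drop, sample(members, 1L))
      }
    }
  }
  ped <- pedigree[!pedigree$individual_id %in% drop, , drop = FALSE]
  an <- anthro[!anthro$individual_id %in% drop, , drop = FALSE]
  an$complete <- is.finite(an$weight_kg) & is.finite(an$height_m) &
    is.finite(an$age)
  list(pedigree = ped, anthro = an, twin_excluded = drop,
       n_incomplete = sum(!an$complete))
}

#' Per-measurement infant z-scores in age-sex bins
#'
#' Internal z-scores (log-transformed weight and height) within sex x
#' age-bin groups over the 0-2 y records, used for the per-child infant
#' growth regressions.
#'
#' @param anthro Measurements (`individual_id`, `age`, `weight_kg`,
#'   `height_m`).
#' @param pedigree Pedigree with `individual_id` and `sex`.
#' @param bin_width Age-bin width in years (default 0.25).
#' @return Data frame `individual_id`, `age`, `zwt`, `zht`.
#' @export
infant_zscores <- function(anthro, pedigree, bin_width = 0.25) {
  d <- anthro[anthro$age <= 2 &
                is.finite(anthro$weight_kg) & is.finite(anthro$height_m), ]
  sex <- pedigree$sex[match(d$individual_id, pedigree$individual_id)]
  grp <- paste(sex, floor(d$age / bin_width), sep = ":")
  data.frame(individual_id = d$individual_id, age = d$age,
             zwt = group_zscore(d$weight_kg, grp, log_first = TRUE),
             zht = group_zscore(d$height_m, grp, log_first = TRUE),
             stringsAsFactors = FALSE)
}

## per-individual cross-sectional records: birth, 2-year anchor, first adult
cross_sectional_records <- function(anthro, pedigree, adult_band_years = 10,
                                    birth_age_max = 0.02) {
  d <- anthro[is.finite(anthro$weight_kg) & is.finite(anthro$height_m), ]
  d$sex <- pedigree$sex[match(d$individual_id, pedigree$individual_id)]
  ids <- unique(d$individual_id)
  birth <- list(); two <- list(); adult <- list()
  for (id in ids) {
    di <- d[d$individual_id == id, ]
    b <- which(di$age <= birth_age_max)
    if (length(b)) birth[[id]] <- di[b[which.min(di$age[b])], ]
    an <- select_anchor_measurements(di$age)
    if (!is.na(an$i2)) two[[id]] <- di[an$i2, ]
    if (!is.na(an$i_adult)) adult[[id]] <- di[an$i_adult, ]
  }
  birth <- do.call(rbind, birth); two <- do.call(rbind, two)
  adult <- do.call(rbind, adult)
  if (!is.null(birth) && nrow(birth) > 1L) {
    birth$zbw <- group_zscore(birth$weight_kg, birth$sex)  # BW not logged
  }
  if (!is.null(two) && nrow(two) > 1L) {
    two$zwt <- group_zscore(two$weight_kg, two$sex, log_first = TRUE)
    two$zht <- group_zscore(two$height_m, two$sex, log_first = TRUE)
  }
  if (!is.null(adult) && nrow(adult) > 1L) {
    band <- paste(adult$sex,
                  floor(adult$age / adult_band_years) * adult_band_years,
                  sep = ":")
    adult$zwt <- group_zscore(adult$weight_kg, band, log_first = TRUE)
    adult$zht <- group_zscore(adult$height_m, band, log_first = TRUE)
    adult$zbmi <- group_zscore(adult$weight_kg / adult$height_m^2, band)
  }
  list(birth = birth, two = two, adult = adult)
}

assoc_row <- function(fit, age_group, outcome) {
  data.frame(age_group = age_group, outcome = outcome, n = fit$n,
             coefficient = fit$coefficient,
             ci_low = fit$ci95[["low"]], ci_high = fit$ci95[["high"]],
             p = fit$p, stringsAsFactors = FALSE)
}

gls_on <- function(df, zcol, ped, method, age_group, outcome) {
  ix <- match(df$individual_id, ped$individual_id)
  fit <- fit_clustered_gls(
    df[[zcol]], df$score, ped$mother_id[ix],
    covariates = data.frame(village = ped$village[ix],
                            birth_year = ped$birth_year[ix]),
    outcome_name = outcome, method = method)
  list(fit = fit, row = assoc_row(fit, age_group, outcome))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing, genotype QC and scoring,
#' standardization, growth-parameter extraction and all association models,
#' returning a results bundle (Table-1-analogue association table,
#' effect-by-age curve, per-stage manifest) and optionally writing it to
#' disk.
#'
#' @param config A [pipeline_config()], or a path accepted by
#'   [read_pipeline_config()].
#' @param out_dir Optional output directory for the TSV/JSON bundle.
#' @return Object of class `grs_results`: list with `table1`,
#'   `effect_curve`, `interaction_fit`, `score_summary`, `scores`,
#'   `calibration`, `growth`, `manifest`, and (for simulated cohorts)
#'   `truth`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(
#'   simulation = sim_config(n_families = 60, seed = 11), seed = 11))
#' res$table1
#' }
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- fan_out_seeds(config$seed, c("simulate", "twins", "hwe"))
  manifest <- list(config_hash = config_hash(unclass(config)[
    setdiff(names(unclass(config)), c("simulation", "inputs"))]),
    seeds = as.list(seeds),
    package_version = as.character(packageVersion("grsgrowth")),
    stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  ## stage 1: cohort -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- sim_cfg$seed %||% seeds[["simulate"]]
    cohort <- simulate_cohort(sim_cfg)
    pedigree <- cohort$pedigree
    genotypes <- cohort$genotypes
    anthro <- cohort$anthro
    truth <- cohort$truth
  } else {
    pedigree <- read_tsv(config$inputs$pedigree)
    genotypes <- read_tsv(config$inputs$genotypes)
    anthro <- read_tsv(config$inputs$anthro)
  }
  n_in <- nrow(pedigree)
  log_stage("cohort", individuals = n_in, measurements = nrow(anthro),
            snps = if (inherits(genotypes, "grs_genotypes"))
              nrow(genotypes$panel) else ncol(genotypes) - 1L)

  ## stage 2: preprocessing ------------------------------------------------
  pre <- preprocess_cohort(pedigree, anthro, seed = seeds[["twins"]])
  pedigree <- pre$pedigree
  anthro <- pre$anthro
  log_stage("preprocess", individuals_in = n_in,
            twin_excluded = length(pre$twin_excluded),
            individuals_out = nrow(pedigree),
            incomplete_measurements = pre$n_incomplete)

  ## stage 3: genotype QC and score ----------------------------------------
  score_obj <- build_allele_score(
    genotypes, pedigree, call_rate_threshold = config$call_rate_threshold,
    max_missing = config$max_missing, hwe_alpha = config$hwe_alpha,
    hwe_method = config$hwe_method, seed = seeds[["hwe"]])
  scores <- score_obj$scores
  scores <- scores[scores$individual_id %in% pedigree$individual_id, ]
  analysed <- scores$individual_id[!scores$excluded]
  log_stage("genetics", individuals_in = nrow(pedigree),
            score_excluded = sum(scores$excluded),
            individuals_out = length(analysed),
            snps_scored = length(score_obj$scored_snps))
  pedigree <- pedigree[pedigree$individual_id %in% analysed, ]
  anthro <- anthro[anthro$individual_id %in% analysed & anthro$complete, ]
  pedigree$score <- scores$score[match(pedigree$individual_id,
                                       scores$individual_id)]

  ## stage 4: standardization ----------------------------------------------
  anthro$sex <- pedigree$sex[match(anthro$individual_id,
                                   pedigree$individual_id)]
  calibration <- fit_wfh_calibration(
    anthro, age_degree = config$age_degree,
    height_degree = config$height_degree, var_degree = config$var_degree)
  zwfh <- apply_wfh_calibration(calibration, anthro)
  zinf <- infant_zscores(anthro, pedigree, config$infant_bin_width)
  cs <- cross_sectional_records(anthro, pedigree, config$adult_band_years)
  log_stage("standardize", measurements = nrow(zwfh),
            birth_records = if (is.null(cs$birth)) 0L else nrow(cs$birth),
            two_year_anchors = if (is.null(cs$two)) 0L else nrow(cs$two),
            adult_anchors = if (is.null(cs$adult)) 0L else nrow(cs$adult))

  ## stage 5: growth parameters --------------------------------------------
  growth <- growth_parameters(anthro, zinf,
                              min_records = config$min_records,
                              max_se = config$max_se,
                              adult_band_years = config$adult_band_years)
  log_stage("growth", rows = nrow(growth), included = sum(growth$included),
            excluded = sum(!growth$included))

  ## stage 6: association --------------------------------------------------
  add_score <- function(df) {
    df$score <- pedigree$score[match(df$individual_id,
                                     pedigree$individual_id)]
    df
  }
  method <- config$method
  rows <- list(); fits <- list()
  if (!is.null(cs$birth) && nrow(cs$birth) > 30L) {
    g <- gls_on(add_score(cs$birth), "zbw", pedigree, method, "Birth", "zBW")
    rows$zbw <- g$row; fits$zbw <- g$fit
  }
  if (!is.null(cs$two) && nrow(cs$two) > 30L) {
    two <- add_score(cs$two)
    g <- gls_on(two, "zwt", pedigree, method, "2 years", "zWT")
    rows$zwt2 <- g$row; fits$zwt2 <- g$fit
    g <- gls_on(two, "zht", pedigree, method, "2 years", "zHT")
    rows$zht2 <- g$row; fits$zht2 <- g$fit
  }
  if (!is.null(cs$adult) && nrow(cs$adult) > 30L) {
    ad <- add_score(cs$adult)
    for (spec in list(c("zwt", "zWT"), c("zht", "zHT"), c("zbmi", "zBMI"))) {
      g <- gls_on(ad, spec[1], pedigree, method, "Adults", spec[2])
      rows[[paste0(spec[1], "_ad")]] <- g$row
      fits[[paste0(spec[1], "_ad")]] <- g$fit
    }
  }

  ## repeated-measures zWT-HT: three-level models on child/adult subsets
  ix <- match(zwfh$individual_id, pedigree$individual_id)
  mm <- data.frame(z = zwfh$zwfh, score = pedigree$score[ix],
                   family = pedigree$mother_id[ix],
                   individual = zwfh$individual_id, age = zwfh$age,
                   village = pedigree$village[ix],
                   birth_year = pedigree$birth_year[ix],
                   stringsAsFactors = FALSE)
  mm <- mm[is.finite(mm$z), ]
  covs <- function(d) data.frame(village = d$village,
                                 birth_year = d$birth_year)
  child <- mm[mm$age <= 20, ]
  if (nrow(child) > 100L) {
    f <- fit_three_level_wfh(child, covariates = covs(child),
                             outcome_name = "zWT-HT (<=20 y)",
                             method = method)
    rows$zwfh_child <- assoc_row(f, "<=20 years", "zWT-HT")
    fits$zwfh_child <- f
  }
  adult_mm <- mm[mm$age > 20, ]
  if (nrow(adult_mm) > 100L) {
    f <- fit_three_level_wfh(adult_mm, covariates = covs(adult_mm),
                             outcome_name = "zWT-HT (>20 y)", method = method)
    rows$zwfh_adult <- assoc_row(f, ">20 years", "zWT-HT")
    fits$zwfh_adult <- f
  }

  ## longitudinal rows: growth parameters as one-row-per-individual outcomes
  for (spec in list(c("0-2", "weight", "WT growth"),
                    c("0-2", "height", "LG growth"),
                    c("2-20", "weight", "zWT change"),
                    c("2-20", "height", "zHT change"))) {
    gsub_df <- growth[growth$period == spec[1] & growth$measure == spec[2] &
                        growth$included, ]
    if (nrow(gsub_df) > 30L) {
      g <- gls_on(add_score(gsub_df), "value", pedigree, method,
                  paste(spec[1], "years"), spec[3])
      rows[[paste(spec[1], spec[2], sep = "_")]] <- g$row
      fits[[paste(spec[1], spec[2], sep = "_")]] <- g$fit
    }
  }
  table1 <- do.call(rbind, rows)
  rownames(table1) <- NULL

  ## score x age interaction and effect-by-age curve
  interaction_fit <- fit_age_interaction(
    mm, covariates = covs(mm), include_age_main = config$include_age_main,
    method = method)
  effect_curve <- predict_effect_by_age(interaction_fit)

  adult_first <- if (!is.null(cs$adult)) {
    zz <- zwfh[paste(zwfh$individual_id, zwfh$age) %in%
                 paste(cs$adult$individual_id, cs$adult$age), ]
    add_score(zz)
  } else NULL
  score_summary <- if (!is.null(adult_first) && nrow(adult_first)) {
    score_distribution_summary(adult_first$score, adult_first$zwfh)
  } else NULL

  log_stage("associate", table1_rows = nrow(table1),
            interaction_n = interaction_fit$n,
            linear_interaction = round(interaction_fit$linear_raw$estimate, 5))

  results <- structure(list(
    table1 = table1, effect_curve = effect_curve,
    interaction_fit = interaction_fit, fits = fits,
    score_summary = score_summary, scores = scores,
    calibration = calibration, growth = growth, snp_qc = score_obj$snp_qc,
    manifest = manifest, truth = truth, config = config),
    class = "grs_results")

  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' Write a results bundle to a directory
#'
#' Emits `table1.tsv`, `effect_curve.tsv`, `scores.tsv`, `snp_qc.tsv`,
#' `growth.tsv`, `calibration.json` and `manifest.json`.
#'
#' @param results A `grs_results`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "grs_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(results$table1, file.path(out_dir, "table1.tsv"))
  write_tsv(results$effect_curve, file.path(out_dir, "effect_curve.tsv"))
  write_tsv(results$scores, file.path(out_dir, "scores.tsv"))
  write_tsv(results$snp_qc, file.path(out_dir, "snp_qc.tsv"))
  write_tsv(results$growth, file.path(out_dir, "growth.tsv"))
  cal <- results$calibration
  cal$fits <- lapply(cal$fits, function(f)
    lapply(f, function(v) if (is.list(v)) lapply(v, unclass) else unclass(v)))
  jsonlite::write_json(unclass(cal), file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.grs_results <- function(x, ...) {
  cat("Risk-allele score association results\n\n")
  print(x$table1, digits = 3)
  lr <- x$interaction_fit$linear_raw
  cat(sprintf(
    "\nLinear age interaction: %0.4f z/allele/year (95%% CI %0.4f to %0.4f), p = %.3g\n",
    lr$estimate, lr$ci95[["low"]], lr$ci95[["high"]], lr$p))
  invisible(x)
}
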