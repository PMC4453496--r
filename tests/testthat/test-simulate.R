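test_that("pedigree respects the configured sibship structure", {
  cfg <- sim_config(n_families = 1,
                    offspring = list(min = 3L, max = 3L, mean = 3),
                    seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3L)
  expect_equal(length(unique(ped$mother_id)), 1L)

  # no twins -> no two siblings share a birth date
  cfg2 <- sim_config(n_families = 100, twin_rate = 0, seed = 2)
  ped2 <- simulate_pedigree(cfg2)
  shared <- tapply(ped2$birth_date, ped2$mother_id,
                   function(b) any(duplicated(b)))
  expect_false(any(shared))
  expect_true(all(ped2$mother_id %in% unique(ped2$mother_id)))
})

test_that("total offspring matches the truncated-Poisson moments", {
  cfg <- sim_config(n_families = 200, seed = 31)
  ped <- simulate_pedigree(cfg)
  lam <- grsgrowth:::truncpois_lambda(4, 1, 8)
  mom <- truncpois_moments(lam, 1, 8)
  expect_equal(mom$mean, 4, tolerance = 1e-8)
  sd_total <- sqrt(200 * mom$var)
  expect_lt(abs(nrow(ped) - 200 * mom$mean), 3 * sd_total)
})

test_that("founder genotypes are Hardy-Weinberg at the configured frequency", {
  panel <- data.frame(snp_id = "s1", risk_freq = 0.5,
                      triallelic = FALSE, monomorphic = FALSE)
  cfg <- sim_config(n_families = 10000,
                    offspring = list(min = 1L, max = 1L, mean = 1),
                    snp_panel = panel, missing_rate = 0, seed = 5)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  g <- gen$true_counts[, 1]
  n <- length(g)
  for (k in 0:2) {
    p_exp <- c(0.25, 0.5, 0.25)[k + 1]
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(mean(g == k) - p_exp), 3 * se)
  }
})

test_that("degenerate allele frequencies are transmitted exactly", {
  panel <- data.frame(snp_id = c("fix1", "fix0"), risk_freq = c(1, 0),
                      triallelic = FALSE, monomorphic = FALSE)
  cfg <- sim_config(n_families = 50, snp_panel = panel, missing_rate = 0,
                    seed = 6)
  gen <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  expect_true(all(gen$true_counts[, "fix1"] == 2L))
  expect_true(all(gen$true_counts[, "fix0"] == 0L))
})

test_that("Mendelian transmission correlates sibling genotypes", {
  panel <- data.frame(snp_id = "s1", risk_freq = 0.5,
                      triallelic = FALSE, monomorphic = FALSE)
  cfg <- sim_config(n_families = 1500,
                    offspring = list(min = 2L, max = 2L, mean = 2),
                    snp_panel = panel, missing_rate = 0, seed = 7)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  g <- matrix(gen$true_counts[, 1], ncol = 2, byrow = TRUE)
  expect_gt(cor(g[, 1], g[, 2]), 0.3)   # expected sib correlation ~0.5
})

test_that("tri-allelic and monomorphic markers emit the expected codes", {
  cfg <- sim_config(n_families = 100, seed = 8)
  gen <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  tri <- gen$calls[[gen$panel$snp_id[gen$panel$triallelic]]]
  alleles <- unique(unlist(strsplit(tri[!is.na(tri)], "/")))
  expect_setequal(alleles, c("A", "B", "C"))
  for (snp in gen$panel$snp_id[gen$panel$monomorphic]) {
    v <- gen$calls[[snp]]
    expect_true(all(v[!is.na(v)] == 0))
  }
})

test_that("all noise off makes weight a deterministic function of sex and age", {
  cfg <- sim_config(n_families = 20, effect_intercept = 0, effect_slope = 0,
                    var_family = 0, var_individual = 0, var_observation = 0,
                    height_cv = 0, height_noise_sd = 0, seed = 9)
  coh <- simulate_cohort(cfg)
  an <- coh$anthro
  sex <- coh$pedigree$sex[match(an$individual_id,
                                coh$pedigree$individual_id)]
  expected <- grsgrowth:::bmi_curve(an$age, sex) * an$height_m^2
  expect_equal(an$weight_kg, expected, tolerance = 1e-12)
  expect_true(all(an$z_true == 0))
})

test_that("score-outcome covariance grows with age under a positive slope", {
  coh <- simulate_cohort(sim_config(n_families = 400, seed = 10))
  sc <- coh$truth$true_scores
  an <- coh$anthro
  s <- sc[match(an$individual_id, names(sc))]
  young <- an$age < 2
  old <- an$age > 20
  expect_gt(cov(s[old], an$z_true[old]), cov(s[young], an$z_true[young]))
})

test_that("simulation is deterministic given the config seed", {
  cfg <- sim_config(n_families = 30, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$pedigree, c2$pedigree)
  expect_identical(c1$genotypes$calls, c2$genotypes$calls)
  expect_identical(c1$anthro, c2$anthro)
})

test_that("measurement schedule matches the cohort description", {
  coh <- simulate_cohort(sim_config(n_families = 150, seed = 12))
  an <- coh$anthro
  per <- table(an$individual_id)
  expect_gt(mean(per), 12)          # ~17 on average
  expect_lt(mean(per), 22)
  infant <- tapply(an$age <= 2, an$individual_id, sum)
  expect_true(all(infant <= 12))
  expect_true(all(tapply(an$age, an$individual_id, min) == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(offspring = list(min = 1, max = 8, mean = 9)),
               "offspring")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(var_family = -1), "variance")
  panel <- default_snp_panel()
  panel$risk_freq[1] <- 1.2
  expect_error(sim_config(snp_panel = panel), "frequencies")
})

test_that("cohort writer emits the standard inputs", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(sim_config(n_families = 10, seed = 13))
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("pedigree.tsv", "genotypes.tsv", "anthro.tsv", "truth.json")))))
  an <- read_tsv(file.path(dir, "anthro.tsv"))
  expect_named(an, c("individual_id", "age", "weight_kg", "height_m"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$delta1, coh$truth$delta1)
})
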