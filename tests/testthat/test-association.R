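test_that("all-singleton clusters collapse to ordinary least squares", {
  set.seed(1)
  n <- 120
  s <- rpois(n, 28)
  y <- 0.03 * s + rnorm(n)
  fit <- fit_clustered_gls(y, s, cluster = seq_len(n))
  ols <- lm(y ~ s)
  expect_equal(unname(fit$coefficient), unname(coef(ols)["s"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$se),
               summary(ols)$coefficients["s", "Std. Error"],
               tolerance = 1e-10)
  expect_equal(fit$engine, "ols")
  expect_warning(fit_clustered_gls(y, s, cluster = rep(1, n)),
                 "single cluster")
  expect_error(fit_clustered_gls(y, rep(2, n), cluster = seq_len(n)),
               "constant")
})

test_that("clustered GLS recovers a known per-allele effect", {
  set.seed(2)
  nfam <- 400
  size <- sample(1:4, nfam, TRUE)
  cl <- rep(seq_len(nfam), size)
  n <- length(cl)
  s <- rpois(n, 28)
  village <- sample(c("V1", "V2", "V3"), n, TRUE)
  yob <- sample(1950:2000, n, TRUE)
  y <- 0.02 * s + 0.2 * (village == "V2") + 0.004 * (yob - 1975) +
    rnorm(nfam, 0, 0.5)[cl] + rnorm(n, 0, 0.8)
  fit <- fit_clustered_gls(y, s, cl,
                           covariates = data.frame(village = village,
                                                   birth_year = yob))
  expect_lt(abs(fit$coefficient - 0.02), 3 * fit$se)
  expect_equal(unname(fit$ci95["low"]), fit$coefficient - 1.96 * fit$se)
  expect_equal(unname(fit$ci95["high"]), fit$coefficient + 1.96 * fit$se)
  expect_gt(fit$varcomp[["cluster"]], 0.05)
})

test_that("orthogonal age basis has the defining properties", {
  set.seed(3)
  ages <- runif(400, 0, 60)
  b <- build_ortho_age_basis(ages, 3)
  B <- predict(b, ages)
  G <- crossprod(cbind(1, B))
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
  # columns have unit sample SD by construction
  expect_equal(unname(apply(B, 2, sd)), rep(1, 3), tolerance = 1e-10)
  # raw-map round-trip: basis evaluation equals the monomial expansion
  grid <- seq(0, 60, by = 5)
  expect_equal(predict(b, grid),
               outer(grid, 0:3, `^`) %*% b$raw_map,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(build_ortho_age_basis(c(1, 2, 3), 3), "distinct ages")
})

test_that("a symmetric three-point basis matches Gram-Schmidt by hand", {
  b <- build_ortho_age_basis(c(-1, 0, 1), 2)
  B <- predict(b, c(-1, 0, 1))
  # linear column proportional to age; quadratic to age^2 - 2/3
  expect_equal(B[, 1] / B[3, 1], c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(B[, 2] / B[1, 2], c(1/3, -2/3, 1/3) / (1/3),
               tolerance = 1e-12)
})

test_that("basis and raw cubic span the same column space", {
  set.seed(4)
  ages <- runif(200, 0, 50)
  y <- 0.5 + 0.1 * ages^3 / 1000 + rnorm(200, 0, 0.1)
  b <- build_ortho_age_basis(ages, 3)
  f1 <- lm(y ~ predict(b, ages))
  f2 <- lm(y ~ ages + I(ages^2) + I(ages^3))
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-10)
})

test_that("three-level model collapses correctly and checks nesting", {
  set.seed(5)
  n <- 400
  ind <- rep(1:100, each = 4)
  fam <- rep(1:25, each = 16)
  s <- rpois(100, 28)[ind]
  z <- 0.03 * s + rnorm(n)              # no family/individual variance
  d <- data.frame(z = z, score = s, family = fam, individual = ind)
  fit <- fit_three_level_wfh(d)
  expect_lt(fit$varcomp[["family"]], 0.05)
  expect_lt(fit$varcomp[["individual"]], 0.08)
  ols <- lm(z ~ s)
  expect_equal(unname(fit$coefficient), unname(coef(ols)["s"]),
               tolerance = 0.05)
  # an individual in two families is rejected
  d2 <- d; d2$family[1] <- 99
  expect_error(fit_three_level_wfh(d2), "more than one family")
})

test_that("duplicating every observation leaves fixed effects stable", {
  d <- make_mm_data(25, seed = 6)
  f1 <- fit_age_interaction(d)
  f2 <- fit_age_interaction(rbind(d, d), basis = NULL)
  expect_equal(unname(f2$coefficient), unname(f1$coefficient),
               tolerance = 0.02)
  expect_equal(f2$linear_raw$estimate, f1$linear_raw$estimate,
               tolerance = 0.005)
})

test_that("age-interaction fit is null-consistent and recovers a slope", {
  # no age trend: linear interaction within 3 SEs of zero
  d0 <- make_mm_data(60, seed = 7, effect_intercept = 0.02,
                     effect_slope = 0)
  f0 <- fit_age_interaction(d0, covariates = d0[, c("village",
                                                    "birth_year")])
  expect_lt(abs(f0$linear_raw$estimate), 3 * f0$linear_raw$se)
  # a positive slope is recovered within its Wald band
  d1 <- make_mm_data(80, seed = 8, effect_slope = 0.008)
  f1 <- fit_age_interaction(d1, covariates = d1[, c("village",
                                                    "birth_year")])
  expect_lt(abs(f1$linear_raw$estimate - 0.008), 3 * f1$linear_raw$se)
  expect_equal(unname(f1$linear_raw$ci95["low"]),
               f1$linear_raw$estimate - 1.96 * f1$linear_raw$se)
})

test_that("a mismatched basis sample is rejected", {
  d <- make_mm_data(20, seed = 9)
  wrong <- build_ortho_age_basis(runif(50, 0, 60))
  expect_error(fit_age_interaction(d, basis = wrong), "different sample")
})

test_that("effect-by-age prediction honors orthogonality and leverage", {
  d <- make_mm_data(60, seed = 10)
  f <- fit_age_interaction(d)
  # averaged over the construction ages, the effect equals the score
  # main-effect coefficient (orthogonality to the constant)
  eff <- predict_effect_by_age(f, d$age)
  expect_equal(mean(eff$effect), unname(f$coefficient), tolerance = 1e-8)
  # the band is narrowest where observations concentrate (dense infant
  # records) and widens toward the sparsely observed old-age end
  curve <- predict_effect_by_age(f)
  w <- curve$high - curve$low
  expect_lt(curve$age[which.min(w)], 5)
  expect_gt(w[length(w)], 1.5 * min(w))
  # extrapolation flagged
  ex <- predict_effect_by_age(f, c(1, 200))
  expect_equal(ex$extrapolated, c(FALSE, TRUE))
})

test_that("linear-only truth yields a straight predicted effect curve", {
  d <- make_mm_data(150, seed = 11, effect_slope = 0.01)
  f <- fit_age_interaction(d)
  curve <- predict_effect_by_age(f, seq(2, 55, by = 1))
  lfit <- lm(effect ~ age, curve)
  # curvature is small relative to the total rise of the line
  rise <- abs(diff(range(fitted(lfit))))
  expect_lt(max(abs(residuals(lfit))), 0.15 * rise)
})

test_that("score distribution summary handles edge cases", {
  s <- c(1, 1, 2, 3)
  z <- c(0.5, 0.5, 0.5, 0.5)
  sm <- score_distribution_summary(s, z)
  expect_equal(sm$mean_z, rep(0.5, 3))
  expect_equal(sm$se_z[sm$score_bin == 1], 0)
  expect_true(is.na(sm$se_z[sm$score_bin == 2]))  # singleton bin
  # positive association shows up through the bin means
  set.seed(12)
  s2 <- rpois(2000, 28)
  z2 <- 0.05 * s2 + rnorm(2000)
  sm2 <- score_distribution_summary(s2, z2)
  expect_gt(coef(lm(mean_z ~ score_bin, sm2, weights = sm2$n))[2], 0)
})
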