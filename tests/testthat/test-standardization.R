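skew <- function(x) mean((x - mean(x))^3) / sd(x)^3

test_that("group z-scores standardize exactly within groups", {
  expect_equal(group_zscore(c(2, 4, 6), rep("g", 3)), c(-1, 0, 1))
  set.seed(1)
  v <- rlnorm(300, 1, 0.4)
  g <- sample(letters[1:5], 300, TRUE)
  z <- group_zscore(v, g, log_first = TRUE)
  for (gi in letters[1:5]) {
    expect_equal(mean(z[g == gi]), 0, tolerance = 1e-12)
    expect_equal(sd(z[g == gi]), 1, tolerance = 1e-12)
  }
  # log transform reduces the skewness of a log-normal sample
  z_raw <- group_zscore(v, rep("g", 300))
  z_log <- group_zscore(v, rep("g", 300), log_first = TRUE)
  expect_lt(abs(skew(z_log)), abs(skew(z_raw)))
  expect_gt(skew(z_raw), 0)
})

test_that("degenerate groups error with the group named", {
  expect_error(group_zscore(c(1, 2), c("a", "b")), "'a'")
  expect_error(group_zscore(c(1, 1, 2), c("a", "a", "b")), "variance")
  expect_error(group_zscore(c(-1, 2), c("a", "a"), log_first = TRUE),
               "positive")
})

model_class_data <- function(n, seed, b = c(1.2, 0.02, -1e-4), ch = 1.6,
                             sigma = 0.1) {
  # log W truly polynomial in age (degree 2) plus log-height, constant noise
  set.seed(seed)
  age <- runif(n, 0, 60)
  sex <- sample(c("F", "M"), n, TRUE)
  logh <- log(grsgrowth:::height_curve(age, sex)) + rnorm(n, 0, 0.02)
  logw <- b[1] + b[2] * age + b[3] * age^2 + ch * logh + rnorm(n, 0, sigma)
  data.frame(individual_id = seq_len(n), age = age, sex = sex,
             weight_kg = exp(logw), height_m = exp(logh))
}

test_that("calibration recovers a polynomial mean and constant variance", {
  d <- model_class_data(6000, seed = 2)
  cal <- fit_wfh_calibration(d, age_degree = 3, height_degree = 1)
  # fitted mean tracks the generating mean on a grid
  for (sx in c("F", "M")) {
    grid <- data.frame(age = seq(1, 59, by = 2), sex = sx)
    grid$height_m <- grsgrowth:::height_curve(grid$age, sx)
    pr <- predict(cal, grid)
    truth <- 1.2 + 0.02 * grid$age - 1e-4 * grid$age^2 +
      1.6 * log(grid$height_m)
    expect_lt(max(abs(pr$mean_logwt - truth)), 0.02)
    # variance model recovers sigma within Monte-Carlo slack
    expect_equal(mean(pr$sd_logwt), 0.1, tolerance = 0.04)
  }
})

test_that("calibration is invariant to row order and sex-separable", {
  d <- model_class_data(2000, seed = 3)
  cal <- fit_wfh_calibration(d)
  calp <- fit_wfh_calibration(d[sample(nrow(d)), ])
  expect_equal(cal$fits$F$mean_coef, calp$fits$F$mean_coef,
               tolerance = 1e-9)
  # perturbing the other sex's data leaves this sex's fit unchanged
  d2 <- d
  d2$weight_kg[d2$sex == "M"] <- d2$weight_kg[d2$sex == "M"] * 1.5
  cal2 <- fit_wfh_calibration(d2)
  expect_equal(cal$fits$F$mean_coef, cal2$fits$F$mean_coef,
               tolerance = 1e-12)
})

test_that("noise-free data engages the variance floor", {
  d <- model_class_data(1500, seed = 4, sigma = 0)
  d$height_m <- grsgrowth:::height_curve(d$age, d$sex)   # exact heights
  d$weight_kg <- exp(1.2 + 0.02 * d$age - 1e-4 * d$age^2 +
                       1.6 * log(d$height_m))
  cal <- fit_wfh_calibration(d, age_degree = 2, height_degree = 1)
  z <- apply_wfh_calibration(cal, d)
  expect_true(all(is.finite(z$zwfh)))
  expect_true(all(vapply(cal$fits, function(f) f$floor > 0, logical(1))))
})

test_that("applying the calibration returns exact z at mean and mean + SD", {
  d <- model_class_data(3000, seed = 5)
  cal <- fit_wfh_calibration(d, age_degree = 3, height_degree = 1)
  probe <- d[1:10, ]
  pr <- predict(cal, probe)
  probe$weight_kg <- exp(pr$mean_logwt)
  z0 <- apply_wfh_calibration(cal, probe)
  expect_equal(z0$zwfh, rep(0, 10), tolerance = 1e-10)
  probe$weight_kg <- exp(pr$mean_logwt + pr$sd_logwt)
  z1 <- apply_wfh_calibration(cal, probe)
  expect_equal(z1$zwfh, rep(1, 10), tolerance = 1e-10)
  # missing weight is skipped, not fatal
  probe$weight_kg[1] <- NA
  z2 <- apply_wfh_calibration(cal, probe)
  expect_true(is.na(z2$zwfh[1]))
  expect_equal(attr(z2, "n_skipped"), 1L)
})

test_that("extrapolation beyond the fitted age range is flagged", {
  d <- model_class_data(2000, seed = 6)
  d <- d[d$age <= 40, ]
  cal <- fit_wfh_calibration(d, age_degree = 3, height_degree = 1)
  probe <- data.frame(age = c(10, 55), sex = "F",
                      height_m = grsgrowth:::height_curve(c(10, 55), "F"),
                      weight_kg = c(25, 55))
  z <- apply_wfh_calibration(cal, probe)
  expect_equal(z$extrapolated, c(FALSE, TRUE))
})
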