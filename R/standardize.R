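## Internal standardization.
##
## All z-scores are calibrated against the study sample itself, never an
## external growth reference. Discrete age-sex groups use
## z = (x - mean) / SD with the group's own sample moments (weight and
## height logged first to reduce skewness). Weight-for-height needs z-scores
## at every age, so its mean and SD are continuous sex-specific functions of
## age: log-weight is regressed on polynomials of age plus log-height
## (stage 1), and the squared stage-1 residuals on a polynomial of age
## (stage 2), giving a fitted variance that is floored to stay positive.

#' Group-based internal z-scores
#'
#' Standardizes each value against the sample mean and SD of its own group:
#' `z = (x - mean) / SD`. With `log_first = TRUE` the values are logged
#' before standardization (used for weight and height).
#'
#' @param values Numeric vector.
#' @param groups Group labels (age-sex groups), same length.
#' @param log_first Log-transform before standardizing?
#' @return Numeric z-score vector; within every group the z-scores have mean
#'   0 and sample SD 1 exactly.
#' @export
#' @examples
#' group_zscore(c(2, 4, 6), rep("g", 3))
group_zscore <- function(values, groups, log_first = FALSE) {
  stopifnot(length(values) == length(groups))
  if (log_first) {
    if (any(values <= 0, na.rm = TRUE)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    values <- log(values)
  }
  groups <- as.character(groups)
  z <- rep(NA_real_, length(values))
  for (g in unique(groups[!is.na(values)])) {
    ix <- which(groups == g & !is.na(values))
    if (length(ix) < 2L) {
      stop(sprintf("group '%s' has fewer than 2 members", g), call. = FALSE)
    }
    s <- sd(values[ix])
    if (!is.finite(s) || s == 0) {
      stop(sprintf("group '%s' has zero variance", g), call. = FALSE)
    }
    z[ix] <- (values[ix] - mean(values[ix])) / s
  }
  z
}

#' Fit the continuous weight-for-height calibration
#'
#' Two-stage least squares per sex: (1) log-weight on an orthogonal
#' polynomial in age of degree `age_degree` plus a polynomial in (log-)height
#' of degree `height_degree`, additively; (2) the squared stage-1 residuals
#' on an orthogonal polynomial in age of degree `var_degree`. The fitted
#' variance is floored at the `floor_quantile` quantile of its positive
#' fitted values so the implied SD is strictly positive.
#'
#' @param data Data frame with columns `age` (years), `weight_kg`,
#'   `height_m`, `sex`.
#' @param age_degree Degree of the age polynomial in the mean model
#'   (default 5).
#' @param height_degree Degree of the height polynomial (default 2).
#' @param var_degree Degree of the age polynomial in the variance model
#'   (default 3).
#' @param log_height Use log-height in the mean model (default `TRUE`)?
#' @param floor_quantile Quantile of positive fitted variances used as floor.
#' @param min_obs Minimum observations required per sex.
#' @return Object of class `wfh_calibration`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_families = 30, seed = 2))
#' cal <- fit_wfh_calibration(merge(coh$anthro,
#'   coh$pedigree[, c("individual_id", "sex")]))
#' cal
fit_wfh_calibration <- function(data, age_degree = 5L, height_degree = 2L,
                                var_degree = 3L, log_height = TRUE,
                                floor_quantile = 0.01, min_obs = 50L) {
  assert_columns(data, c("age", "weight_kg", "height_m", "sex"), "data")
  data <- data[complete.cases(data[, c("age", "weight_kg", "height_m", "sex")]), ]
  fits <- list()
  for (sx in sort(unique(data$sex))) {
    d <- data[data$sex == sx, ]
    if (nrow(d) < min_obs) {
      stop(sprintf("sex '%s' has %d observations; need at least %d",
                   sx, nrow(d), min_obs), call. = FALSE)
    }
    h <- if (log_height) log(d$height_m) else d$height_m
    X_age <- poly(d$age, age_degree)
    X_h <- poly(h, height_degree)
    fit1 <- lm(log(d$weight_kg) ~ X_age + X_h)
    if (any(is.na(coef(fit1)))) {
      stop("rank-deficient mean-model design; lower age_degree or height_degree",
           call. = FALSE)
    }
    r2 <- residuals(fit1)^2
    V_age <- poly(d$age, var_degree)
    fit2 <- lm(r2 ~ V_age)
    vf <- fitted(fit2)
    pos <- vf[vf > 0]
    floor_val <- if (length(pos)) as.numeric(quantile(pos, floor_quantile))
    else max(mean(r2), .Machine$double.eps)
    fits[[sx]] <- list(
      mean_coef = coef(fit1),
      age_basis = attr(X_age, "coefs"),
      height_basis = attr(X_h, "coefs"),
      var_coef = coef(fit2),
      var_basis = attr(V_age, "coefs"),
      floor = floor_val,
      age_range = range(d$age),
      n = nrow(d),
      sigma2_mean = mean(r2)
    )
  }
  structure(list(fits = fits, age_degree = age_degree,
                 height_degree = height_degree, var_degree = var_degree,
                 log_height = log_height, floor_quantile = floor_quantile),
            class = "wfh_calibration")
}

#' @export
print.wfh_calibration <- function(x, ...) {
  cat("Weight-for-height calibration (internal, sex-specific)\n")
  cat(sprintf("  mean model: log(WT) ~ poly(age, %d) + poly(%s, %d)\n",
              x$age_degree, if (x$log_height) "log(HT)" else "HT",
              x$height_degree))
  cat(sprintf("  variance model: residual^2 ~ poly(age, %d)\n", x$var_degree))
  for (sx in names(x$fits)) {
    f <- x$fits[[sx]]
    cat(sprintf("  sex %s: n = %d, ages %.2f-%.1f y, mean resid. var %.4f\n",
                sx, f$n, f$age_range[1], f$age_range[2], f$sigma2_mean))
  }
  invisible(x)
}

eval_poly_basis <- function(x, coefs) {
  ## evaluate a stats::poly basis (given its orthogonalization coefs) at new x
  poly(x, degree = length(coefs$norm2) - 2L, coefs = coefs)
}

#' Predicted mean and SD from a weight-for-height calibration
#'
#' @param object A `wfh_calibration`.
#' @param newdata Data frame with `age`, `height_m`, `sex`.
#' @param ... Unused.
#' @return Data frame with `mean_logwt`, `sd_logwt`, `extrapolated`.
#' @export
predict.wfh_calibration <- function(object, newdata, ...) {
  assert_columns(newdata, c("age", "height_m", "sex"), "newdata")
  out <- data.frame(mean_logwt = NA_real_, sd_logwt = NA_real_,
                    extrapolated = NA)[rep(1, nrow(newdata)), ]
  rownames(out) <- NULL
  for (sx in unique(newdata$sex)) {
    f <- object$fits[[sx]]
    if (is.null(f)) stop("no calibration fitted for sex '", sx, "'",
                         call. = FALSE)
    ix <- which(newdata$sex == sx)
    age <- newdata$age[ix]
    h <- if (object$log_height) log(newdata$height_m[ix]) else
      newdata$height_m[ix]
    Xa <- eval_poly_basis(age, f$age_basis)
    Xh <- eval_poly_basis(h, f$height_basis)
    out$mean_logwt[ix] <- as.numeric(cbind(1, Xa, Xh) %*% f$mean_coef)
    Va <- eval_poly_basis(age, f$var_basis)
    v <- as.numeric(cbind(1, Va) %*% f$var_coef)
    out$sd_logwt[ix] <- sqrt(pmax(v, f$floor))
    out$extrapolated[ix] <- age < f$age_range[1] | age > f$age_range[2]
  }
  out
}

#' Apply a weight-for-height calibration to measurements
#'
#' Computes `zWT-HT = (log(weight) - fitted mean) / fitted SD` per
#' observation. Records with missing weight or height are skipped (row kept,
#' z set `NA`, counted in the `n_skipped` attribute); ages beyond the fitted
#' range are flagged, not dropped.
#'
#' @param calibration A `wfh_calibration`.
#' @param data Data frame with `age`, `weight_kg`, `height_m`, `sex` (and
#'   usually `individual_id`).
#' @return `data` with added columns `zwfh` and `extrapolated`.
#' @export
apply_wfh_calibration <- function(calibration, data) {
  stopifnot(inherits(calibration, "wfh_calibration"))
  assert_columns(data, c("age", "weight_kg", "height_m", "sex"), "data")
  ok <- complete.cases(data[, c("age", "weight_kg", "height_m", "sex")])
  data$zwfh <- NA_real_
  data$extrapolated <- NA
  if (any(ok)) {
    pr <- predict(calibration, data[ok, , drop = FALSE])
    data$zwfh[ok] <- (log(data$weight_kg[ok]) - pr$mean_logwt) / pr$sd_logwt
    data$extrapolated[ok] <- pr$extrapolated
  }
  attr(data, "n_skipped") <- sum(!ok)
  data
}
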