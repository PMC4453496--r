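## Estimation machinery.
##
## Cross-sectional outcomes (one row per individual) are related to the
## combined risk-allele score by random-intercept regression with clusters
## defined by a mother and her offspring, controlling for village
## (categorical) and year of birth (centered, linear). Repeated
## weight-for-height z-scores use a three-level mixed model (family,
## individual within family, observation), optionally extended with
## interactions between the score and cubic orthogonal polynomials of age.
## Estimation is maximum likelihood by default (REML optional) via lme4;
## inference is Wald (z statistics, CI = estimate +/- 1.96 SE).

wald_ci <- function(est, se) c(low = est - 1.96 * se, high = est + 1.96 * se)
wald_p <- function(est, se) 2 * pnorm(-abs(est / se))

check_converged <- function(fit) {
  if (isTRUE(fit@optinfo$conv$opt != 0)) {
    stop("mixed-model optimizer reported non-convergence (code ",
         fit@optinfo$conv$opt, ")", call. = FALSE)
  }
  invisible(fit)
}

prep_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  ## center year of birth; village enters as a factor with the first level
  ## (alphabetical) as reference
  if ("birth_year" %in% names(covariates)) {
    covariates$birth_year <- covariates$birth_year -
      mean(covariates$birth_year)
  }
  if ("village" %in% names(covariates)) {
    covariates$village <- factor(covariates$village)
  }
  covariates
}

#' Mother-clustered random-effects regression of an outcome on the score
#'
#' Random-intercept (cluster + residual) model estimated by maximum
#' likelihood; the generalised-least-squares analysis for one-row-per-
#' individual outcomes. With fewer than two clusters, or with every cluster
#' of size one (where the model collapses), ordinary least squares is used.
#'
#' @param outcome Numeric outcome vector (one value per individual).
#' @param score Risk-allele score vector.
#' @param cluster Cluster labels (mother id).
#' @param covariates Optional data frame of covariates (a `village` column is
#'   treated as categorical, `birth_year` is centered and linear).
#' @param outcome_name Label used in printing and result tables.
#' @param method `"ML"` (default) or `"REML"`.
#' @return Object of class `grs_assoc`.
#' @export
#' @examples
#' set.seed(1)
#' cl <- rep(1:30, each = 3)
#' s <- rpois(90, 28)
#' y <- 0.05 * s + rnorm(30)[cl] + rnorm(90)
#' fit_clustered_gls(y, s, cl)
fit_clustered_gls <- function(outcome, score, cluster, covariates = NULL,
                              outcome_name = "outcome",
                              method = c("ML", "REML")) {
  method <- match.arg(method)
  n <- length(outcome)
  stopifnot(length(score) == n, length(cluster) == n)
  keep <- is.finite(outcome) & is.finite(score) & !is.na(cluster)
  outcome <- outcome[keep]; score <- score[keep]
  cluster <- as.character(cluster)[keep]
  covariates <- prep_covariates(covariates, n)
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  if (length(unique(score)) < 2L) {
    stop("score is constant; association is not estimable", call. = FALSE)
  }
  df <- data.frame(.y = outcome, score = score, .cluster = cluster,
                   stringsAsFactors = FALSE)
  rhs <- "score"
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  sizes <- table(cluster)
  collapse <- length(sizes) < 2L || max(sizes) == 1L
  if (length(sizes) < 2L) {
    warning("single cluster; falling back to ordinary least squares")
  }
  if (collapse) {
    fit <- lm(as.formula(paste(".y ~", rhs)), data = df)
    beta <- coef(fit)
    V <- vcov(fit)
    varcomp <- c(cluster = 0, residual = summary(fit)$sigma^2)
    ll <- as.numeric(logLik(fit))
    engine <- "ols"
  } else {
    fml <- as.formula(paste(".y ~", rhs, "+ (1 | .cluster)"))
    fit <- lme4::lmer(fml, data = df, REML = (method == "REML"),
                      control = lmm_control())
    check_converged(fit)
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- c(cluster = vc$vcov[vc$grp == ".cluster"],
                 residual = vc$vcov[vc$grp == "Residual"])
    ll <- as.numeric(logLik(fit))
    engine <- "lmer"
  }
  est <- unname(beta["score"])
  se <- sqrt(V["score", "score"])
  structure(list(
    outcome = outcome_name, n = length(outcome),
    n_clusters = length(sizes),
    coefficient = est, se = se, ci95 = wald_ci(est, se),
    p = wald_p(est, se),
    coefficients = beta, vcov = V, varcomp = varcomp,
    loglik = ll, method = method, engine = engine,
    covariates = if (is.null(covariates)) character(0) else names(covariates),
    fit = fit), class = "grs_assoc")
}

#' @export
print.grs_assoc <- function(x, ...) {
  cat(sprintf("Clustered association: %s ~ score  (%s, %s)\n", x$outcome,
              x$engine, x$method))
  cat(sprintf("  n = %d individuals in %d clusters\n", x$n, x$n_clusters))
  cat(sprintf("  score: %0.4f z/allele (95%% CI %0.4f to %0.4f), p = %.3g\n",
              x$coefficient, x$ci95[["low"]], x$ci95[["high"]], x$p))
  invisible(x)
}

#' @export
coef.grs_assoc <- function(object, ...) object$coefficients

#' @export
summary.grs_assoc <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  out <- data.frame(estimate = object$coefficients, se = se,
                    z = object$coefficients / se,
                    p = wald_p(object$coefficients, se))
  cat(sprintf("%s (%s; n = %d, clusters = %d)\n", object$outcome,
              object$engine, object$n, object$n_clusters))
  cat(sprintf("variance components: cluster %.4f, residual %.4f\n\n",
              object$varcomp[["cluster"]], object$varcomp[["residual"]]))
  print(out, digits = 4)
  invisible(out)
}

#' Orthogonal polynomial basis over observation ages
#'
#' Builds `degree` polynomial basis columns over the supplied ages, each
#' orthogonal to the constant and to one another on the construction sample,
#' together with the exact linear mapping back to raw-age monomials
#' `1, age, ..., age^degree`.
#'
#' @param ages Numeric ages (one entry per observation of the analysis
#'   sample).
#' @param degree Polynomial degree (default 3).
#' @return Object of class `ortho_age_basis`: list with `coefs` (the
#'   orthogonalization constants), `raw_map` (a `(degree+1) x degree` matrix
#'   `M` with `B_j(a) = sum_k M[k+1, j] a^k`), `degree`, `age_range`, `n`.
#' @export
#' @examples
#' b <- build_ortho_age_basis(runif(100, 0, 60))
#' colSums(predict(b, attr(b, "ages")))  # ~ 0
build_ortho_age_basis <- function(ages, degree = 3L) {
  ages <- as.numeric(ages)
  if (length(unique(ages)) < degree + 1L) {
    stop("need at least degree + 1 distinct ages", call. = FALSE)
  }
  B <- poly(ages, degree)
  coefs <- attr(B, "coefs")
  ## columns are rescaled from unit norm to unit sample SD so their scale is
  ## comparable to the other regressors
  scale <- sqrt(length(ages) - 1)
  ## exact mapping to raw monomials: evaluate the basis at degree + 1
  ## well-spread points and solve the Vandermonde system
  pts <- seq(min(ages), max(ages), length.out = degree + 1L)
  if (length(unique(pts)) < degree + 1L) pts <- sort(unique(ages))[1:(degree + 1L)]
  A <- outer(pts, 0:degree, `^`)
  Bp <- eval_poly_basis(pts, coefs) * scale
  raw_map <- solve(A, Bp)
  dimnames(raw_map) <- list(paste0("age^", 0:degree), paste0("b", 1:degree))
  out <- structure(list(coefs = coefs, raw_map = raw_map, scale = scale,
                        degree = as.integer(degree),
                        age_range = range(ages), n = length(ages),
                        age_sum = sum(ages)),
                   class = "ortho_age_basis")
  attr(out, "ages") <- ages
  out
}

#' Evaluate an orthogonal age basis at new ages
#'
#' @param object An `ortho_age_basis`.
#' @param newages Numeric ages.
#' @param ... Unused.
#' @return Matrix with `degree` columns `b1..bdegree`.
#' @export
predict.ortho_age_basis <- function(object, newages, ...) {
  B <- eval_poly_basis(as.numeric(newages), object$coefs) * object$scale
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  unclass(B)[, , drop = FALSE]
}

#' @export
print.ortho_age_basis <- function(x, ...) {
  cat(sprintf(
    "Orthogonal age basis: degree %d over %d ages in [%.2f, %.1f]\n",
    x$degree, x$n, x$age_range[1], x$age_range[2]))
  invisible(x)
}

check_basis_sample <- function(basis, ages) {
  if (basis$n != length(ages) ||
      abs(basis$age_sum - sum(ages)) > 1e-6 * max(1, abs(basis$age_sum))) {
    stop("orthogonal age basis was built on a different sample than the ",
         "model ages", call. = FALSE)
  }
  invisible(basis)
}

check_nesting <- function(family, individual) {
  tab <- tapply(as.character(family), as.character(individual),
                function(f) length(unique(f)))
  if (any(tab > 1L)) {
    stop("individual(s) appear in more than one family: ",
         paste(names(tab)[tab > 1L], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

## tight optimizer tolerances: the variance-parameter optimum is resolved
## well past the reporting precision of any coefficient
lmm_control <- function() {
  lme4::lmerControl(optCtrl = list(xtol_rel = 1e-14, ftol_rel = 1e-14,
                                   xtol_abs = 1e-12, ftol_abs = 1e-14),
                    calc.derivs = FALSE)
}

fit_lmm <- function(df, rhs, method) {
  fml <- as.formula(paste(".z ~", rhs, "+ (1 | .family) + (1 | .individual)"))
  fit <- lme4::lmer(fml, data = df, REML = (method == "REML"),
                    control = lmm_control())
  check_converged(fit)
  fit
}

varcomp3 <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  c(family = vc$vcov[vc$grp == ".family"],
    individual = vc$vcov[vc$grp == ".individual"],
    observation = vc$vcov[vc$grp == "Residual"])
}

#' Three-level mixed model for repeated weight-for-height z-scores
#'
#' Random intercepts for family and for individual within family plus an
#' observation-level residual; fixed effects for the risk-allele score and
#' covariates. The score coefficient is the all-ages association in
#' z-units/allele.
#'
#' @param data Data frame with columns `z` (weight-for-height z-score),
#'   `score`, `family`, `individual`, and optionally `age`.
#' @param covariates Optional data frame of covariates, as in
#'   [fit_clustered_gls()].
#' @param outcome_name Label for printing.
#' @param method `"ML"` (default) or `"REML"`.
#' @return Object of class `grs_mixed`.
#' @export
fit_three_level_wfh <- function(data, covariates = NULL,
                                outcome_name = "zWT-HT",
                                method = c("ML", "REML")) {
  method <- match.arg(method)
  assert_columns(data, c("z", "score", "family", "individual"), "data")
  check_nesting(data$family, data$individual)
  covariates <- prep_covariates(covariates, nrow(data))
  df <- data.frame(.z = data$z, score = data$score,
                   .family = as.character(data$family),
                   .individual = as.character(data$individual),
                   stringsAsFactors = FALSE)
  rhs <- "score"
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  fit <- fit_lmm(df, rhs, method)
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  est <- unname(beta["score"]); se <- sqrt(V["score", "score"])
  structure(list(
    outcome = outcome_name, n = nrow(df),
    n_individuals = length(unique(df$.individual)),
    n_families = length(unique(df$.family)),
    coefficient = est, se = se, ci95 = wald_ci(est, se), p = wald_p(est, se),
    coefficients = beta, vcov = V, varcomp = varcomp3(fit),
    loglik = as.numeric(logLik(fit)), method = method,
    covariates = if (is.null(covariates)) character(0) else names(covariates),
    fit = fit), class = "grs_mixed")
}

#' @export
print.grs_mixed <- function(x, ...) {
  cat(sprintf("Three-level mixed model: %s (%s)\n", x$outcome, x$method))
  cat(sprintf("  %d observations, %d individuals, %d families\n",
              x$n, x$n_individuals, x$n_families))
  cat(sprintf("  score: %0.4f z/allele (95%% CI %0.4f to %0.4f), p = %.3g\n",
              x$coefficient, x$ci95[["low"]], x$ci95[["high"]], x$p))
  cat(sprintf(
    "  variance: family %.4f, individual %.4f, observation %.4f\n",
    x$varcomp[["family"]], x$varcomp[["individual"]],
    x$varcomp[["observation"]]))
  invisible(x)
}

#' @export
coef.grs_mixed <- function(object, ...) object$coefficients

#' Three-level model with score x age-polynomial interactions
#'
#' Extends the three-level weight-for-height model with main effects of an
#' orthogonal cubic age basis and interactions between the score and each
#' basis column. The linear interaction is re-expressed on the raw-age scale
#' in z-units/allele/year via the basis's monomial mapping, with a
#' delta-method Wald CI; quadratic and cubic interactions are Wald-tested.
#'
#' @param data As in [fit_three_level_wfh()], with an `age` column.
#' @param basis Optional [build_ortho_age_basis()] object built on
#'   `data$age`; built internally when `NULL`.
#' @param covariates Optional covariate data frame.
#' @param degree Basis degree when building internally (default 3).
#' @param include_age_main Include the age-basis main effects alongside the
#'   interactions (hierarchy principle; default `TRUE`).
#' @param method `"ML"` (default) or `"REML"`.
#' @return Object of class `age_interaction` (extends `grs_mixed`), with
#'   components `interactions` (per-term table), `linear_raw` (raw-age-scale
#'   slope: estimate, se, ci, p) and `basis`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_families = 40, seed = 5))
#' # see the package vignette for the full pipeline to `data`
fit_age_interaction <- function(data, basis = NULL, covariates = NULL,
                                degree = 3L, include_age_main = TRUE,
                                method = c("ML", "REML")) {
  method <- match.arg(method)
  assert_columns(data, c("z", "score", "family", "individual", "age"), "data")
  check_nesting(data$family, data$individual)
  if (is.null(basis)) {
    basis <- build_ortho_age_basis(data$age, degree)
  } else {
    check_basis_sample(basis, data$age)
  }
  covariates <- prep_covariates(covariates, nrow(data))
  B <- predict(basis, data$age)
  df <- data.frame(.z = data$z, score = data$score,
                   .family = as.character(data$family),
                   .individual = as.character(data$individual),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(B))
  for (j in seq_len(ncol(B))) df[[paste0("sxb", j)]] <- df$score * B[, j]
  bn <- colnames(B)
  ixn <- paste0("sxb", seq_len(ncol(B)))
  rhs <- c("score", if (include_age_main) bn, ixn)
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    rhs <- c(rhs, names(covariates))
  }
  fit <- fit_lmm(df, paste(rhs, collapse = " + "), method)
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))

  g <- beta[ixn]
  se_g <- sqrt(diag(V)[ixn])
  interactions <- data.frame(
    term = c("linear", "quadratic", "cubic")[seq_along(ixn)],
    estimate = unname(g), se = unname(se_g),
    z = unname(g / se_g), p = wald_p(g, se_g), row.names = NULL)

  ## raw-age linear slope: d effect / d age |_(linear part) = M[2, ] . gamma
  m1 <- basis$raw_map[2, ]
  slope <- sum(m1 * g)
  slope_se <- sqrt(drop(t(m1) %*% V[ixn, ixn] %*% m1))
  linear_raw <- list(estimate = slope, se = slope_se,
                     ci95 = wald_ci(slope, slope_se),
                     p = wald_p(slope, slope_se))

  est <- unname(beta["score"]); se <- sqrt(V["score", "score"])
  structure(list(
    outcome = "zWT-HT", n = nrow(df),
    n_individuals = length(unique(df$.individual)),
    n_families = length(unique(df$.family)),
    coefficient = est, se = se, ci95 = wald_ci(est, se), p = wald_p(est, se),
    coefficients = beta, vcov = V, varcomp = varcomp3(fit),
    loglik = as.numeric(logLik(fit)), method = method,
    covariates = if (is.null(covariates)) character(0) else names(covariates),
    interactions = interactions, linear_raw = linear_raw, basis = basis,
    include_age_main = include_age_main,
    fit = fit), class = c("age_interaction", "grs_mixed"))
}

#' @export
print.age_interaction <- function(x, ...) {
  cat("Score x age interaction model (three-level,", x$method, ")\n")
  cat(sprintf("  %d observations, %d individuals, %d families\n",
              x$n, x$n_individuals, x$n_families))
  cat(sprintf("  score at mean age: %0.4f z/allele, p = %.3g\n",
              x$coefficient, x$p))
  lr <- x$linear_raw
  cat(sprintf(
    "  linear age interaction: %0.4f z/allele/year (95%% CI %0.4f to %0.4f), p = %.3g\n",
    lr$estimate, lr$ci95[["low"]], lr$ci95[["high"]], lr$p))
  hi <- x$interactions[x$interactions$term != "linear", ]
  if (nrow(hi)) {
    cat(sprintf("  %s interaction p = %.3g\n", hi$term, hi$p), sep = "")
  }
  cat(sprintf(
    "  variance: family %.4f, individual %.4f, observation %.4f\n",
    x$varcomp[["family"]], x$varcomp[["individual"]],
    x$varcomp[["observation"]]))
  invisible(x)
}

#' Per-allele effect on weight-for-height as a function of age
#'
#' Evaluates `effect(age) = score coefficient + sum_j gamma_j B_j(age)` from
#' a fitted [fit_age_interaction()] model, with a pointwise delta-method 95%
#' confidence band from the fixed-effect covariance.
#'
#' @param fit An `age_interaction` fit.
#' @param ages Age grid (default 200 points over the fitted range).
#' @return Data frame of class `effect_curve`: `age`, `effect`, `low`,
#'   `high`, `extrapolated`.
#' @export
predict_effect_by_age <- function(fit, ages = NULL) {
  stopifnot(inherits(fit, "age_interaction"))
  rng <- fit$basis$age_range
  if (is.null(ages)) ages <- seq(rng[1], rng[2], length.out = 200L)
  ixn <- paste0("sxb", seq_len(fit$basis$degree))
  sel <- c("score", ixn)
  V <- fit$vcov[sel, sel]
  if (any(!is.finite(V)) || any(diag(V) <= 0) ||
      inherits(try(chol(V), silent = TRUE), "try-error")) {
    stop("singular fixed-effect covariance; cannot form the confidence band",
         call. = FALSE)
  }
  B <- predict(fit$basis, ages)
  X <- cbind(1, B)
  eff <- drop(X %*% fit$coefficients[sel])
  se <- sqrt(rowSums((X %*% V) * X))
  out <- data.frame(age = ages, effect = eff,
                    low = eff - 1.96 * se, high = eff + 1.96 * se,
                    extrapolated = ages < rng[1] | ages > rng[2])
  class(out) <- c("effect_curve", "data.frame")
  out
}

#' @export
plot.effect_curve <- function(x, ...) {
  plot(x$age, x$effect, type = "n",
       ylim = range(c(x$low, x$high)),
       xlab = "Age (years)", ylab = "Effect per allele (zWT-HT)", ...)
  polygon(c(x$age, rev(x$age)), c(x$low, rev(x$high)),
          col = "grey88", border = NA)
  lines(x$age, x$effect, lwd = 2)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Score histogram and unadjusted outcome means per score bin
#'
#' Per integer score bin: count, unadjusted mean of the outcome, and its
#' standard error (no covariate correction). Bins with a single individual
#' report a missing SE.
#'
#' @param scores Risk-allele scores (fractional scores are rounded to the
#'   nearest integer bin).
#' @param z Outcome values, same length.
#' @return Data frame of class `score_summary`: `score_bin`, `n`, `mean_z`,
#'   `se_z`.
#' @export
score_distribution_summary <- function(scores, z) {
  stopifnot(length(scores) == length(z))
  ok <- is.finite(scores) & is.finite(z)
  bin <- round(scores[ok]); z <- z[ok]
  bins <- sort(unique(bin))
  out <- data.frame(
    score_bin = bins,
    n = as.integer(tapply(z, bin, length)[as.character(bins)]),
    mean_z = as.numeric(tapply(z, bin, mean)[as.character(bins)]),
    se_z = as.numeric(tapply(z, bin, function(v)
      if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v)))[
        as.character(bins)]),
    row.names = NULL)
  class(out) <- c("score_summary", "data.frame")
  out
}

#' @export
plot.score_summary <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  barplot(x$n, names.arg = x$score_bin, xlab = "Risk-allele score",
          ylab = "Individuals", ...)
  plot(x$score_bin, x$mean_z, pch = 19, xlab = "Risk-allele score",
       ylab = "Mean z (\u00b1SE)")
  ok <- !is.na(x$se_z)
  arrows(x$score_bin[ok], x$mean_z[ok] - x$se_z[ok],
         x$score_bin[ok], x$mean_z[ok] + x$se_z[ok],
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}
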