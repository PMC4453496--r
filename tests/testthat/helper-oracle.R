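# Independent oracles used across the suite.

# Dense-matrix maximum-likelihood fit of a Gaussian linear mixed model with
# any number of random-intercept groupings: y ~ X beta + sum_k u_k + e,
# V = sum_k s2_k Z_k Z_k' + s2_e I. Profiles beta, optimizes log-variances
# numerically. Only for small instances (n <= ~60).
oracle_lmm <- function(y, X, groups, reml = FALSE) {
  n <- length(y)
  X <- as.matrix(X)
  Zs <- lapply(groups, function(g) {
    g <- as.character(g)
    outer(g, unique(g), `==`) * 1
  })
  profile_beta <- function(vs) {
    V <- diag(vs[length(vs)], n)
    for (k in seq_along(Zs)) V <- V + vs[k] * tcrossprod(Zs[[k]])
    cV <- chol(V)
    solve_V <- function(M) backsolve(cV, forwardsolve(t(cV), M))
    XtViX <- crossprod(X, solve_V(X))
    beta <- solve(XtViX, crossprod(X, solve_V(y)))
    r <- y - X %*% beta
    ll <- -0.5 * (2 * sum(log(diag(cV))) +
                    drop(crossprod(r, solve_V(r))) + n * log(2 * pi))
    if (reml) {
      ll <- ll - 0.5 * (as.numeric(determinant(XtViX)$modulus) -
                          ncol(X) * log(2 * pi))
    }
    list(beta = drop(beta), loglik = ll)
  }
  nll <- function(lv) -profile_beta(exp(lv))$loglik
  v0 <- var(y) / (length(Zs) + 1)
  opt <- optim(rep(log(v0), length(Zs) + 1), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  vs <- exp(opt$par)
  pb <- profile_beta(vs)
  list(beta = pb$beta, varcomp = vs, loglik = pb$loglik)
}

# Hand-rolled simple-regression normal equations with the n-2 df residual SE.
oracle_slope <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- y - intercept - slope * x
  se <- sqrt(sum(r^2) / (n - 2) / sxx)
  list(slope = slope, intercept = intercept, se = se)
}

# Moments of the truncated Poisson on [min, max] by direct pmf enumeration.
truncpois_moments <- function(lambda, min, max) {
  k <- min:max
  p <- dpois(k, lambda)
  p <- p / sum(p)
  m <- sum(k * p)
  list(mean = m, var = sum((k - m)^2 * p))
}

# Small three-level simulated dataset on the true z scale (model class of the
# association module).
make_mm_data <- function(n_families, seed, effect_intercept = 0,
                         effect_slope = 0.0083, dense_n = 7L,
                         sparse_interval = 8, var_family = 0.2,
                         var_individual = 0.3, var_observation = 0.5,
                         max_age = 60) {
  coh <- simulate_cohort(sim_config(
    n_families = n_families, seed = seed,
    effect_intercept = effect_intercept, effect_slope = effect_slope,
    var_family = var_family, var_individual = var_individual,
    var_observation = var_observation,
    schedule = list(dense_n = dense_n, dense_max_age = 2,
                    sparse_interval = sparse_interval, max_age = max_age)))
  ped <- coh$pedigree
  sc <- coh$truth$true_scores - mean(coh$truth$true_scores)
  ix <- match(coh$anthro$individual_id, ped$individual_id)
  data.frame(z = coh$anthro$z_true, score = sc[ix],
             family = ped$mother_id[ix],
             individual = coh$anthro$individual_id,
             age = coh$anthro$age, village = ped$village[ix],
             birth_year = ped$birth_year[ix], stringsAsFactors = FALSE)
}
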