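## Per-individual longitudinal growth parameters.
##
## 0-2 y: each child's internal z-scores are regressed on age by ordinary
## least squares; the growth parameter is the age coefficient (z-units/year).
## Children are included only with at least `min_records` measurements,
## at least one in each of the first and second years of life, and a slope
## standard error below `max_se`. 2-20 y: the difference between the z-score
## at the measurement nearest age 2 (strictly within 1.5-2.5 y) and at the
## first adult measurement (age > 20 y).

#' Per-child infant growth slope with inclusion filters
#'
#' Ordinary least squares of z-score on age over a child's 0-2 y records.
#' The child is excluded (with a reason) if there are fewer than
#' `min_records` measurements, no measurement in the first (`[0, year_split)`)
#' or second (`[year_split, 2]`) year of life, the ages have zero variance,
#' or the slope standard error is `max_se` or larger.
#'
#' @param ages Ages in years, restricted to `[0, 2]`.
#' @param z Internal z-scores, same length.
#' @param min_records Minimum number of measurements (default 5).
#' @param max_se Exclusive upper bound on the slope SE in z-units/year
#'   (default 0.4).
#' @param year_split Boundary between the first and second year (default 1).
#' @return List: `slope`, `se`, `n`, `included`, `reason` (comma-separated
#'   list of every failed filter; `NA` when included).
#' @export
#' @examples
#' infant_growth_slope(c(0.1, 0.5, 0.9, 1.3, 1.8), c(-1, -0.8, -0.7, -0.5, -0.2))
infant_growth_slope <- function(ages, z, min_records = 5L, max_se = 0.4,
                                year_split = 1) {
  keep <- is.finite(ages) & is.finite(z)
  ages <- ages[keep]; z <- z[keep]
  if (any(ages < 0 | ages > 2)) {
    stop("infant growth slopes use ages in [0, 2] only", call. = FALSE)
  }
  ## filters are evaluated independently and all failures reported, so the
  ## outcome does not depend on any filter ordering
  reasons <- character(0)
  n <- length(ages)
  if (n < min_records) reasons <- c(reasons, "too_few_measurements")
  if (!any(ages < year_split)) reasons <- c(reasons, "no_first_year_record")
  if (!any(ages >= year_split)) reasons <- c(reasons, "no_second_year_record")
  zero_var <- n >= 2 && var(ages) == 0
  if (zero_var) reasons <- c(reasons, "zero_age_variance")
  slope <- se <- NA_real_
  if (n >= 3 && !zero_var) {
    xbar <- mean(ages); ybar <- mean(z)
    sxx <- sum((ages - xbar)^2)
    slope <- sum((ages - xbar) * (z - ybar)) / sxx
    resid <- z - ybar - slope * (ages - xbar)
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    if (se >= max_se) reasons <- c(reasons, "slope_se_too_large")
  }
  if (length(reasons)) {
    return(list(slope = NA_real_, se = NA_real_, n = n, included = FALSE,
                reason = paste(reasons, collapse = ",")))
  }
  list(slope = slope, se = se, n = n, included = TRUE, reason = NA_character_)
}

#' Select the 2-year and first-adult anchor measurements
#'
#' The 2-year anchor is the record minimizing `|age - 2|` among records with
#' `1.5 < age < 2.5` (strict bounds; ties go to the later age). The adult
#' anchor is the earliest record with `age > 20`. Either anchor may be
#' absent.
#'
#' @param ages Ages in years for one individual.
#' @param window Two-year selection window, exclusive bounds (default
#'   `c(1.5, 2.5)`).
#' @param adult_age Exclusive adult age cut-off (default 20).
#' @return List with indices `i2` and `i_adult` into `ages` (`NA` when no
#'   qualifying record exists).
#' @export
select_anchor_measurements <- function(ages, window = c(1.5, 2.5),
                                       adult_age = 20) {
  in_win <- which(ages > window[1] & ages < window[2])
  i2 <- if (length(in_win)) {
    d <- abs(ages[in_win] - 2)
    cand <- in_win[d == min(d)]
    cand[which.max(ages[cand])]          # tie: take the later record
  } else NA_integer_
  adult <- which(ages > adult_age)
  i_adult <- if (length(adult)) adult[which.min(ages[adult])] else NA_integer_
  list(i2 = i2, i_adult = i_adult)
}

#' Childhood-to-adult change in z-score
#'
#' `z(first adult) - z(2 years)`; individuals lacking either anchor are
#' excluded with a reason.
#'
#' @param z2 Z-score at the 2-year anchor (`NA` if absent).
#' @param z_adult Z-score at the first adult measurement (`NA` if absent).
#' @return List: `value`, `included`, `reason`.
#' @export
childhood_change <- function(z2, z_adult) {
  if (is.na(z2)) return(list(value = NA_real_, included = FALSE,
                             reason = "no_2y_anchor"))
  if (is.na(z_adult)) return(list(value = NA_real_, included = FALSE,
                                  reason = "no_adult_anchor"))
  list(value = z_adult - z2, included = TRUE, reason = NA_character_)
}

#' Infant (0-2 y) growth-slope table
#'
#' Applies [infant_growth_slope()] per individual and measure, given
#' per-measurement internal z-scores.
#'
#' @param zdata Data frame with `individual_id`, `age`, and per-measurement
#'   internal z-score columns `zwt`, `zht`.
#' @param min_records,max_se,year_split Passed to [infant_growth_slope()].
#' @return Data frame: one row per individual x measure with `value`
#'   (z-units/year), `se`, `n`, `included`, `reason`.
#' @export
infant_growth_table <- function(zdata, min_records = 5L, max_se = 0.4,
                                year_split = 1) {
  assert_columns(zdata, c("individual_id", "age", "zwt", "zht"), "zdata")
  zdata <- zdata[zdata$age <= 2, ]
  ids <- unique(zdata$individual_id)
  rows <- vector("list", 2L * length(ids))
  k <- 0L
  for (id in ids) {
    d <- zdata[zdata$individual_id == id, ]
    for (m in c("zwt", "zht")) {
      sl <- infant_growth_slope(d$age, d[[m]], min_records, max_se, year_split)
      k <- k + 1L
      rows[[k]] <- data.frame(
        individual_id = id, period = "0-2",
        measure = if (m == "zwt") "weight" else "height",
        value = sl$slope, se = sl$se, n = sl$n, included = sl$included,
        reason = sl$reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Childhood-to-adult (2-20 y) z-change table
#'
#' Selects each individual's 2-year and first-adult anchor measurements from
#' the raw anthropometry, standardizes the selected anchors internally
#' (2-year anchors by sex; adult anchors by sex and age band, weight and
#' height logged first), and returns the z-score differences.
#'
#' @param data Data frame with `individual_id`, `age`, `weight_kg`,
#'   `height_m`, `sex`.
#' @param window,adult_age Passed to [select_anchor_measurements()].
#' @param adult_band_years Width (years) of the adult age-sex standardization
#'   bands (default 10).
#' @return Data frame: one row per individual x measure with `value`
#'   (z-units), `included`, `reason`.
#' @export
childhood_change_table <- function(data, window = c(1.5, 2.5), adult_age = 20,
                                   adult_band_years = 10) {
  assert_columns(data, c("individual_id", "age", "weight_kg", "height_m",
                         "sex"), "data")
  ids <- unique(data$individual_id)
  pick <- lapply(ids, function(id) {
    d <- data[data$individual_id == id, ]
    an <- select_anchor_measurements(d$age, window, adult_age)
    list(row2 = if (is.na(an$i2)) NULL else d[an$i2, ],
         rowa = if (is.na(an$i_adult)) NULL else d[an$i_adult, ])
  })
  names(pick) <- ids

  anchors2 <- do.call(rbind, lapply(pick, `[[`, "row2"))
  anchorsA <- do.call(rbind, lapply(pick, `[[`, "rowa"))
  z2 <- zA <- NULL
  if (!is.null(anchors2) && nrow(anchors2)) {
    z2 <- data.frame(
      individual_id = anchors2$individual_id,
      zwt = group_zscore(anchors2$weight_kg, anchors2$sex, log_first = TRUE),
      zht = group_zscore(anchors2$height_m, anchors2$sex, log_first = TRUE),
      stringsAsFactors = FALSE)
  }
  if (!is.null(anchorsA) && nrow(anchorsA)) {
    band <- paste(anchorsA$sex,
                  floor(anchorsA$age / adult_band_years) * adult_band_years,
                  sep = ":")
    zA <- data.frame(
      individual_id = anchorsA$individual_id,
      zwt = group_zscore(anchorsA$weight_kg, band, log_first = TRUE),
      zht = group_zscore(anchorsA$height_m, band, log_first = TRUE),
      stringsAsFactors = FALSE)
  }

  rows <- list()
  for (id in ids) {
    for (m in c("zwt", "zht")) {
      v2 <- if (!is.null(z2) && id %in% z2$individual_id)
        z2[[m]][z2$individual_id == id] else NA_real_
      va <- if (!is.null(zA) && id %in% zA$individual_id)
        zA[[m]][zA$individual_id == id] else NA_real_
      ch <- childhood_change(v2, va)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, period = "2-20",
        measure = if (m == "zwt") "weight" else "height",
        value = ch$value, se = NA_real_, n = sum(!is.na(c(v2, va))),
        included = ch$included, reason = ch$reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Growth-parameter table for a cohort
#'
#' Combines [infant_growth_table()] (0-2 y slopes from per-measurement
#' internal z-scores) and [childhood_change_table()] (2-20 y z-changes from
#' internally standardized anchor measurements).
#'
#' @param data Raw anthropometry with `individual_id`, `age`, `weight_kg`,
#'   `height_m`, `sex`.
#' @param zdata Per-measurement z-scores for ages 0-2 (see
#'   [infant_growth_table()]).
#' @param ... Passed on to the two table builders (`min_records`, `max_se`,
#'   `year_split`, `window`, `adult_age`, `adult_band_years`).
#' @return Data frame of class `growth_params`.
#' @export
growth_parameters <- function(data, zdata, ...) {
  dots <- list(...)
  take <- function(f) dots[names(dots) %in% names(formals(f))]
  out <- rbind(
    do.call(infant_growth_table, c(list(zdata), take(infant_growth_table))),
    do.call(childhood_change_table, c(list(data),
                                      take(childhood_change_table))))
  class(out) <- c("growth_params", "data.frame")
  out
}
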