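#' Rate of change in the brain-age gap between two scans
#'
#' Pairs each participant's t1 and t2 BAG records and computes
#' \eqn{R_{BAG} = (\delta_{t2} - \delta_{t1}) / \Delta T} together with the
#' average chronological age \eqn{(Age_{t1} + Age_{t2}) / 2} used by the
#' longitudinal age-effect regression. Arithmetic is exact; unit conversions
#' for display are separate ([rbag_to_months()], [rbag_to_days()]).
#'
#' @param bag_records A data frame of per-session BAG records (e.g. from
#'   [predict.brain_age_model()]) with columns `participant_id`, `session`
#'   (values `"t1"`/`"t2"`), `age`, `delta`, and optionally `group`,
#'   `group_main`, `sex`.
#' @return One row per participant with both sessions present: carried
#'   grouping columns plus `delta_t1`, `delta_t2`, `age_t1`, `age_t2`, `dt`
#'   (years, > 0), `r_bag` (years of BAG per year), `avg_age`.
#' @export
compute_rbag <- function(bag_records) {
  d <- tibble::as_tibble(bag_records)
  stopifnot(all(c("participant_id", "session", "age", "delta") %in% names(d)))
  if (!all(d$session %in% c("t1", "t2"))) {
    stop("`session` must contain only \"t1\" and \"t2\"", call. = FALSE)
  }
  carry <- intersect(c("group", "group_main", "sex", "covid_status"), names(d))
  wide <- d |>
    dplyr::select(dplyr::all_of(c(
      "participant_id", carry, "session", "age",
      "delta"
    ))) |>
    tidyr::pivot_wider(
      names_from = "session", values_from = c("age", "delta")
    ) |>
    dplyr::filter(!is.na(.data$age_t1), !is.na(.data$age_t2))
  if (any(wide$age_t2 - wide$age_t1 <= 0)) {
    stop("inter-scan interval must be positive for every participant", call. = FALSE)
  }
  wide |>
    dplyr::mutate(
      dt = .data$age_t2 - .data$age_t1,
      r_bag = (.data$delta_t2 - .data$delta_t1) / .data$dt,
      avg_age = (.data$age_t1 + .data$age_t2) / 2
    )
}

#' Regression of the BAG rate on average chronological age
#'
#' Ordinary least squares of `r_bag` on `avg_age` (optionally per group and
#' optionally sex-adjusted). Regressing on the average of the two scan ages,
#' rather than either single time point, balances the estimate against
#' differing inter-scan intervals. The slope is reported both in years of
#' BAG per year per year of age and converted to days/year (x 365.25).
#'
#' @param records A data frame from [compute_rbag()].
#' @param by Optional grouping column (unquoted or string), e.g. `group`.
#' @param adjust_sex Include `sex` as a covariate (default FALSE).
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per group: `n`, `slope` (y/y per year),
#'   `slope_days` (days/year per year), `conf_low`, `conf_high` (same unit
#'   as `slope`), `p`.
#' @export
age_effect_regression <- function(records, by = NULL, adjust_sex = FALSE,
                                  conf = 0.95) {
  one <- function(d, label) {
    if (nrow(d) < 10) stop("need >= 10 records per group", call. = FALSE)
    if (stats::sd(d$avg_age) == 0) {
      stop("constant avg_age: slope undefined", call. = FALSE)
    }
    fml <- if (adjust_sex) r_bag ~ avg_age + sex else r_bag ~ avg_age
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)$coefficients["avg_age", ]
    ci <- stats::confint(fit, "avg_age", level = conf)
    tibble::tibble(
      group = label, n = nrow(d),
      slope = unname(sm["Estimate"]),
      slope_days = rbag_to_days(unname(sm["Estimate"])),
      conf_low = ci[1], conf_high = ci[2],
      p = unname(sm["Pr(>|t|)"])
    )
  }
  if (rlang::quo_is_null(rlang::enquo(by))) {
    return(one(records, "all"))
  }
  records |>
    dplyr::group_by(dplyr::across({{ by }})) |>
    dplyr::group_map(~ one(.x, paste(.y[[1]]))) |>
    dplyr::bind_rows()
}

# Two-way random-effects, absolute-agreement, single-measure intraclass
# correlation (McGraw & Wong case 2A,1) from the two-way ANOVA mean squares,
# with the standard F-based confidence interval.
icc21 <- function(ratings, conf = 0.95) {
  M <- as.matrix(ratings)
  n <- nrow(M)
  k <- ncol(M)
  stopifnot(n >= 5, k >= 2, !anyNA(M))
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) {
    return(tibble::tibble(icc = NA_real_, conf_low = NA_real_, conf_high = NA_real_))
  }
  icc <- (msr - mse) / denom

  alpha <- 1 - conf
  if (abs(1 - icc) < 1e-12) {
    return(tibble::tibble(icc = icc, conf_low = NA_real_, conf_high = NA_real_))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  tibble::tibble(icc = icc, conf_low = lower, conf_high = upper)
}

# correlation of residuals after regressing each variable on its own
# covariate column(s); p from t at n - 2 - n_covariates df
partial_cor <- function(x, y, cx, cy = cx, conf = 0.95) {
  rx <- stats::lm.fit(cbind(1, cx), x)$residuals
  ry <- stats::lm.fit(cbind(1, cy), y)$residuals
  n <- length(x)
  df <- n - 2 - NCOL(cx)
  r <- stats::cor(rx, ry)
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3 - NCOL(cx))
  tibble::tibble(
    r = r, conf_low = tanh(z - zc * se), conf_high = tanh(z + zc * se), p = p
  )
}

#' Scan-rescan reproducibility of predicted brain age
#'
#' Three complementary statistics on paired predictions: the Pearson
#' correlation between predicted brain ages at t1 and t2; the intraclass
#' correlation ICC(2,1) (two-way random effects, absolute agreement, single
#' measure) with its F-based 95% CI, which unlike Pearson r is penalised by
#' systematic offsets between sessions; and the partial correlation after
#' residualising each session's prediction on its own chronological age,
#' which removes the shared age trend.
#'
#' @param data A data frame with columns for the two predictions and ages.
#' @param yb_t1,yb_t2,age_t1,age_t2 Column names (strings or unquoted).
#' @param conf Confidence level.
#' @return A one-row tibble: `n`, `pearson_r`, `pearson_p`, `icc`,
#'   `icc_low`, `icc_high`, `partial_r`, `partial_low`, `partial_high`,
#'   `partial_p`. Statistics are NA (with a message) under zero variance.
#' @export
reproducibility_stats <- function(data, yb_t1 = "yb_t1", yb_t2 = "yb_t2",
                                  age_t1 = "age_t1", age_t2 = "age_t2",
                                  conf = 0.95) {
  y1 <- dplyr::pull(data, {{ yb_t1 }})
  y2 <- dplyr::pull(data, {{ yb_t2 }})
  a1 <- dplyr::pull(data, {{ age_t1 }})
  a2 <- dplyr::pull(data, {{ age_t2 }})
  n <- length(y1)
  stopifnot(n >= 5, length(y2) == n)
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0) {
    message("zero variance in predicted ages: reproducibility undefined")
    return(tibble::tibble(
      n = n, pearson_r = NA_real_, pearson_p = NA_real_, icc = NA_real_,
      icc_low = NA_real_, icc_high = NA_real_, partial_r = NA_real_,
      partial_low = NA_real_, partial_high = NA_real_, partial_p = NA_real_
    ))
  }
  ct <- stats::cor.test(y1, y2)
  ic <- icc21(cbind(y1, y2), conf = conf)
  pc <- partial_cor(y1, y2, cx = a1, cy = a2, conf = conf)
  tibble::tibble(
    n = n,
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
    icc = ic$icc, icc_low = ic$conf_low, icc_high = ic$conf_high,
    partial_r = pc$r, partial_low = pc$conf_low, partial_high = pc$conf_high,
    partial_p = pc$p
  )
}
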