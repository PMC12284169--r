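#' Longitudinal change in a cognitive score
#'
#' Computes, per participant, the percentage change
#' \eqn{(Score_{t2} - Score_{t1}) \times 100 / Score_{t1}} and the
#' interval-normalised rate \eqn{(Score_{t2} - Score_{t1}) / \Delta T}
#' between the two scans. For timed tests (e.g. Trail Making Test completion
#' times in seconds) a positive change means worse performance. Rows with a
#' missing score at either session are dropped; rows with a non-positive
#' baseline are rejected; both counts are attached via [qc_report()].
#'
#' @param data One row per participant, with columns `<test>_t1`,
#'   `<test>_t2` (positive reals) and the inter-scan interval column.
#' @param test Test identifier used as the column prefix, e.g. `"tmt_a"`.
#' @param isi Column holding the inter-scan interval in years.
#' @return A tibble with carried id/group columns plus `score_t1`,
#'   `score_t2`, `pct_change` (percent), `rate_change` (score units/year).
#' @export
cognitive_change <- function(data, test, isi = "isi") {
  c1 <- paste0(test, "_t1")
  c2 <- paste0(test, "_t2")
  d <- tibble::as_tibble(data)
  stopifnot(all(c(c1, c2) %in% names(d)))
  dt <- dplyr::pull(d, {{ isi }})
  s1 <- d[[c1]]
  s2 <- d[[c2]]
  missing <- is.na(s1) | is.na(s2) | is.na(dt)
  nonpos <- !missing & s1 <= 0
  keep <- !missing & !nonpos
  carry <- intersect(
    c("participant_id", "group", "group_main", "sex", "covid_status"),
    names(d)
  )
  out <- d[keep, carry, drop = FALSE] |>
    dplyr::mutate(
      test = test,
      score_t1 = s1[keep], score_t2 = s2[keep],
      pct_change = (.data$score_t2 - .data$score_t1) * 100 / .data$score_t1,
      rate_change = (.data$score_t2 - .data$score_t1) / dt[keep]
    )
  attr(out, "qc_report") <- tibble::tibble(
    rule = c("missing_score", "nonpositive_baseline"),
    n_excluded = c(sum(missing), sum(nonpos)),
    n_input = nrow(d), n_retained = nrow(out)
  )
  out
}

#' Sliding-window mean curve
#'
#' Smooths y against x with a moving window: at each centre on a regular
#' grid, the mean and standard error of `y` over points with
#' `|x - centre| <= width/2` are reported. Windows holding fewer than
#' `min_count` points are omitted. Used to display cognitive change across
#' the BAG rate-of-change axis.
#'
#' @param data A data frame.
#' @param x,y Column names (unquoted or strings).
#' @param width Window width in units of `x` (default 3).
#' @param step Grid step (default `width / 10`).
#' @param min_count Minimum points per reported window (default 5).
#' @return A tibble with one row per populated window: `centre`, `n`,
#'   `mean`, `se`. Empty (with a warning) if every window is under-populated.
#' @export
sliding_window_curve <- function(data, x, y, width = 3, step = width / 10,
                                 min_count = 5) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !(is.na(xv) | is.na(yv))
  xv <- xv[keep]
  yv <- yv[keep]
  stopifnot(length(xv) >= 5)
  assert_scalar(width, "width", min = 1e-12)
  assert_scalar(step, "step", min = 1e-12)
  centres <- seq(min(xv), max(xv), by = step)
  rows <- lapply(centres, function(ct) {
    inside <- abs(xv - ct) <= width / 2
    n <- sum(inside)
    if (n < min_count) {
      return(NULL)
    }
    yy <- yv[inside]
    tibble::tibble(
      centre = ct, n = n, mean = mean(yy),
      se = stats::sd(yy) / sqrt(n)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warning("all windows hold fewer than `min_count` points; empty curve",
      call. = FALSE
    )
    out <- tibble::tibble(
      centre = numeric(0), n = integer(0),
      mean = numeric(0), se = numeric(0)
    )
  }
  out
}

#' Association between the BAG rate and cognitive change
#'
#' Per group: the full Pearson correlation between R_BAG and the cognitive
#' change measure, and the partial correlation after residualising both on
#' average chronological age (removing the shared ageing trend), each with a
#' two-sided p-value.
#'
#' @param data A data frame joining R_BAG records with cognitive changes
#'   (e.g. `dplyr::inner_join(compute_rbag(...), cognitive_change(...))`).
#' @param rbag,change,age Column names: the BAG rate, the change measure,
#'   and average age (defaults `r_bag`, `pct_change`, `avg_age`).
#' @param by Optional grouping column.
#' @return A tibble per group: `n`, `full_r`, `full_p`, `partial_r`,
#'   `partial_p`.
#' @export
rbag_cognition_association <- function(data, rbag = "r_bag",
                                       change = "pct_change",
                                       age = "avg_age", by = NULL) {
  one <- function(d, label) {
    rv <- dplyr::pull(d, {{ rbag }})
    cv <- dplyr::pull(d, {{ change }})
    av <- dplyr::pull(d, {{ age }})
    keep <- !(is.na(rv) | is.na(cv) | is.na(av))
    rv <- rv[keep]
    cv <- cv[keep]
    av <- av[keep]
    n <- length(rv)
    stopifnot(n >= 10)
    if (stats::sd(rv) == 0 || stats::sd(cv) == 0) {
      message("zero variance: correlation undefined for group ", label)
      return(tibble::tibble(
        group = label, n = n, full_r = NA_real_, full_p = NA_real_,
        partial_r = NA_real_, partial_p = NA_real_
      ))
    }
    ct <- stats::cor.test(rv, cv)
    pc <- partial_cor(rv, cv, cx = av)
    tibble::tibble(
      group = label, n = n,
      full_r = unname(ct$estimate), full_p = ct$p.value,
      partial_r = pc$r, partial_p = pc$p
    )
  }
  if (rlang::quo_is_null(rlang::enquo(by))) {
    return(one(data, "all"))
  }
  data |>
    dplyr::group_by(dplyr::across({{ by }})) |>
    dplyr::group_map(~ one(.x, paste(.y[[1]]))) |>
    dplyr::bind_rows()
}
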