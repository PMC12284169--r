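DAYS_PER_YEAR <- 365.25
MONTHS_PER_YEAR <- 12

#' Convert a BAG rate between display units
#'
#' Rates of change in the brain-age gap (R_BAG) are computed internally in
#' years of BAG per year of follow-up. Figures in this field usually display
#' them in months/year or days/year; these helpers convert losslessly
#' (12 months/year, 365.25 days/year), so a round-trip through any unit is
#' the identity.
#'
#' @param x Numeric vector of rates in years of BAG per year.
#' @return Numeric vector in the requested unit.
#' @examples
#' rbag_to_months(0.25) # 3 months/year
#' rbag_to_days(0.00821) # ~3 days/year
#' @export
rbag_to_months <- function(x) x * MONTHS_PER_YEAR

#' @rdname rbag_to_months
#' @export
rbag_to_days <- function(x) x * DAYS_PER_YEAR

#' @rdname rbag_to_months
#' @export
months_to_rbag <- function(x) x / MONTHS_PER_YEAR

#' @rdname rbag_to_months
#' @export
days_to_rbag <- function(x) x / DAYS_PER_YEAR

#' Render a yearly BAG rate as "m months and d days"
#'
#' Display-only convention used for deprivation "clocks": the year-scale
#' value is multiplied by 12, the integer part gives months, and the
#' remainder is converted to days at 365.25/12 days per month and rounded.
#' The raw value should always be retained alongside the rendering.
#'
#' @param x Scalar rate in years of BAG per year.
#' @return A string such as "5 months and 25 days".
#' @examples
#' format_months_days(0.4861)
#' @export
format_months_days <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x))
  sign_chr <- if (x < 0) "-" else ""
  m_total <- abs(x) * MONTHS_PER_YEAR
  m <- floor(m_total)
  d <- round((m_total - m) * DAYS_PER_YEAR / MONTHS_PER_YEAR)
  # carry if rounding days reaches a full month
  month_days <- round(DAYS_PER_YEAR / MONTHS_PER_YEAR)
  if (d >= month_days + 1) {
    m <- m + 1
    d <- 0
  }
  sprintf("%s%d months and %d days", sign_chr, m, d)
}

# Deterministic child seeds: each pipeline stage draws from its own stream so
# stages can be regenerated independently of one another. Offsets are fixed
# and documented; the master seed is kept small so offsets stay in range.
child_seed <- function(seed, stage) {
  offsets <- c(
    structure_ = 1L, training = 2L, longitudinal = 3L, cognition = 4L,
    cv = 5L, permutation = 6L, pipeline = 7L
  )
  stage <- match.arg(stage, names(offsets))
  as.integer((as.numeric(seed) * 101 + offsets[[stage]]) %% 2147483647)
}

# shared input checks -------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
      call. = FALSE
    )
  }
  invisible(as.numeric(x))
}

assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || any(x <= 0) ||
    x[1] > x[2]) {
    stop(sprintf("`%s` must be a positive (min, max) pair with min <= max", name),
      call. = FALSE
    )
  }
  invisible(as.numeric(x))
}
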