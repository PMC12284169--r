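#' Cohen's d with pooled standard deviation
#'
#' Standardised mean difference \eqn{d = (\bar x_1 - \bar x_2) / s_p} with
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}. Location-scale
#' invariant under a common affine transform and antisymmetric in its
#' arguments.
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @return A single number. If both samples are constant and equal, 0; if the
#'   pooled SD is 0 with unequal means, a signed `Inf` (overflow sentinel).
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5)) # -2
#' @export
cohens_d <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  n1 <- length(x1)
  n2 <- length(x2)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  dm <- mean(x1) - mean(x2)
  if (sp2 == 0) {
    if (dm == 0) {
      return(0)
    }
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2)
}

#' Two-sample comparison as a tidy one-row result
#'
#' Runs a two-sided two-sample test and returns one row of a results table:
#' mean difference, Cohen's d, test statistic, raw p, sample sizes, and a
#' family label for later FDR pooling. The t-test uses the pooled-variance
#' Student form by default (`welch = TRUE` switches); the Mann-Whitney test
#' uses exact enumeration for small tie-free samples and the tie-corrected
#' normal approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @param kind `"t"` or `"mann_whitney"`.
#' @param label Comparison label stored in the output.
#' @param family Family identifier for FDR pooling (see [adjust_family()]).
#' @param welch Use the Welch (unequal-variance) t-test instead of pooled.
#' @return A one-row tibble with columns `family`, `label`, `kind`, `n1`,
#'   `n2`, `estimate` (mean(x1) - mean(x2)), `cohen_d`, `statistic`, `p`.
#' @examples
#' two_sample_tests(rnorm(20), rnorm(20, 1), kind = "t", label = "demo")
#' @export
two_sample_tests <- function(x1, x2, kind = c("t", "mann_whitney"),
                             label = "comparison", family = "default",
                             welch = FALSE) {
  kind <- match.arg(kind)
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  if (kind == "t") {
    ht <- stats::t.test(x1, x2, var.equal = !welch)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    if (length(unique(c(x1, x2))) == 1L) {
      statistic <- length(x1) * length(x2) / 2
      p <- 1
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x1, x2))
      statistic <- unname(ht$statistic)
      p <- min(1, ht$p.value)
    }
  }
  tibble::tibble(
    family = family, label = label, kind = kind,
    n1 = length(x1), n2 = length(x2),
    estimate = mean(x1) - mean(x2),
    cohen_d = cohens_d(x1, x2),
    statistic = statistic, p = p
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()]); values are
#' monotone in the ranked p-values, capped at 1, and returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0L) {
    return(numeric(0))
  }
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Apply FDR correction within families of comparisons
#'
#' Takes a results table (e.g. rows from [two_sample_tests()]) and adds a
#' `p_fdr` column, pooling p-values within each level of `family` — one
#' family per analysis panel, so users can re-pool by editing the label.
#'
#' @param results A data frame with columns `family` and `p`.
#' @return The input tibble with a `p_fdr` column appended.
#' @export
adjust_family <- function(results) {
  stopifnot(all(c("family", "p") %in% names(results)))
  results |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_fdr = fdr_bh(.data$p)) |>
    dplyr::ungroup()
}

#' Wilson score interval for a binomial proportion
#'
#' Centre \eqn{(\hat p + z^2/2n)/(1 + z^2/n)} and half-width
#' \eqn{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1 + z^2/n)}. Used here to put
#' a calibration band around empirical rejection rates of permutation tests:
#' for a nominal 5% test checked with 5000 draws the 95% band is
#' (0.0443, 0.0564).
#'
#' @param p_hat Observed proportion in \[0, 1\].
#' @param n Number of trials (>= 1).
#' @param conf Confidence level, default 0.95.
#' @return A named numeric vector `c(lower, upper)`.
#' @examples
#' wilson_ci(0.05, 5000)
#' @export
wilson_ci <- function(p_hat, n, conf = 0.95) {
  assert_scalar(p_hat, "p_hat", 0, 1)
  assert_count(n, "n")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = centre - half, upper = centre + half)
}

# Freedman-Lane permutation machinery ---------------------------------------

# F statistic for a single-column effect in a linear model, phrased through
# orthonormal bases so permuted copies can be scored with two matrix products.
# q: unit vector spanning the part of the target column orthogonal to the
# nuisance design; Q: orthonormal basis of the full design.
fl_bases <- function(target, nuisance) {
  qr_n <- qr(nuisance)
  t_res <- target - nuisance %*% qr.coef(qr_n, target)
  t_norm <- sqrt(sum(t_res^2))
  if (t_norm < 1e-10) stop("target effect is collinear with the nuisance design", call. = FALSE)
  q <- t_res / t_norm
  Qfull <- qr.Q(qr(cbind(nuisance, target)))
  list(q = q, Qfull = Qfull, qr_nuisance = qr_n)
}

# Scores observed + permuted responses. Y: n x m matrix of responses (first
# column is typically the observed data). Returns the F statistic per column.
fl_f_stats <- function(Y, bases, df_err) {
  ss_eff <- as.vector(crossprod(bases$q, Y))^2
  ss_tot <- colSums(Y^2)
  ss_model <- colSums(crossprod(bases$Qfull, Y)^2)
  ss_err <- pmax(ss_tot - ss_model, 0)
  # (near-)constant response: define F = 0 so all permutations tie and p = 1
  eps <- 1e-12 * pmax(ss_tot, 1)
  ifelse(ss_eff < eps & ss_err < eps, 0, ss_eff / (ss_err / df_err))
}

#' Freedman-Lane permutation test for one effect in a linear model
#'
#' Tests a single-column effect while nuisance terms are partialled out:
#' the response is residualised on the nuisance-only model, residuals are
#' permuted, the nuisance fit is added back, and the effect's F statistic is
#' recomputed on each reconstructed response. The p-value uses the add-one
#' convention \eqn{p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})}, so it can never
#' be exactly zero. With an intercept-only nuisance the scheme reduces to
#' plain label permutation.
#'
#' @param y Numeric response.
#' @param target Numeric vector coding the effect under test.
#' @param nuisance Matrix of nuisance regressors (include the intercept
#'   column); defaults to intercept only.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutation stream.
#' @param perms Optional integer matrix (`n_perm` x `n`) of explicit
#'   permutations, e.g. an exhaustive enumeration; overrides `n_perm`/`seed`.
#' @return A list with `statistic` (observed F), `p`, and `n_perm`.
#' @export
freedman_lane <- function(y, target, nuisance = NULL, n_perm = 5000,
                          seed = NULL, perms = NULL) {
  n <- length(y)
  if (is.null(nuisance)) nuisance <- matrix(1, n, 1)
  nuisance <- as.matrix(nuisance)
  target <- as.numeric(target)
  stopifnot(nrow(nuisance) == n, length(target) == n)
  bases <- fl_bases(target, nuisance)
  df_err <- n - ncol(nuisance) - 1L
  stopifnot(df_err >= 1)

  fitted_n <- nuisance %*% qr.coef(bases$qr_nuisance, y)
  resid_n <- y - fitted_n

  if (is.null(perms)) {
    perms <- make_perm_matrix(n, n_perm, seed)
  } else {
    perms <- as.matrix(perms)
    stopifnot(ncol(perms) == n)
    n_perm <- nrow(perms)
  }

  Y <- matrix(resid_n[t(perms)], nrow = n) + as.vector(fitted_n)
  f_obs <- fl_f_stats(cbind(y), bases, df_err)
  f_perm <- fl_f_stats(Y, bases, df_err)
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  list(statistic = unname(f_obs), p = p, n_perm = n_perm)
}

make_perm_matrix <- function(n, n_perm, seed = NULL) {
  gen <- function() {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen)
}

# minimal local seed scoping (avoids a hard dependency for one call site)
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Two-factor, two-level permutation ANOVA
#'
#' Permutation-based inference for the 2x2 design used to probe pandemic x
#' sex and pandemic x deprivation interplay on the BAG rate of change. Both
#' main effects and the interaction are tested with the Freedman-Lane scheme:
#' for each effect the other terms act as nuisance, the reduced-model
#' residuals are permuted, and the effect's F statistic is recomputed. Effects
#' are coded -1/+1 so the interaction column is the product of the mains.
#'
#' @param data A data frame.
#' @param response,factor_a,factor_b Column names (unquoted or strings):
#'   numeric response and two two-level factors.
#' @param n_perm Number of permutations (default 5000; < 100 warns about
#'   resolution).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `perm_anova_2x2`: a list with `result` (tibble
#'   with one row per effect: `effect`, `statistic`, `p`), `n_perm`, `seed`,
#'   `scheme`, and the cell counts.
#' @examples
#' d <- data.frame(
#'   y = rnorm(40), a = rep(c("x", "y"), 20),
#'   b = rep(c("u", "v"), each = 20)
#' )
#' permutation_anova_2x2(d, y, a, b, n_perm = 199, seed = 1)
#' @export
permutation_anova_2x2 <- function(data, response, factor_a, factor_b,
                                  n_perm = 5000, seed = NULL) {
  y <- dplyr::pull(data, {{ response }})
  a <- as.factor(dplyr::pull(data, {{ factor_a }}))
  b <- as.factor(dplyr::pull(data, {{ factor_b }}))
  keep <- !(is.na(y) | is.na(a) | is.na(b))
  y <- y[keep]
  a <- droplevels(a[keep])
  b <- droplevels(b[keep])
  if (nlevels(a) != 2L || nlevels(b) != 2L) {
    stop("both factors must have exactly two observed levels", call. = FALSE)
  }
  cells <- table(a, b)
  if (any(cells == 0)) stop("all four design cells must be non-empty", call. = FALSE)
  assert_count(n_perm, "n_perm")
  if (n_perm < 100) {
    warning("n_perm < 100 gives very coarse p-value resolution", call. = FALSE)
  }

  n <- length(y)
  ca <- ifelse(a == levels(a)[2], 1, -1)
  cb <- ifelse(b == levels(b)[2], 1, -1)
  X <- cbind(intercept = 1, a = ca, b = cb, ab = ca * cb)
  perms <- make_perm_matrix(n, n_perm, seed)

  effects <- c("a", "b", "ab")
  rows <- lapply(effects, function(eff) {
    fl <- freedman_lane(
      y,
      target = X[, eff],
      nuisance = X[, setdiff(colnames(X), eff), drop = FALSE],
      perms = perms
    )
    tibble::tibble(effect = eff, statistic = fl$statistic, p = fl$p)
  })
  res <- dplyr::bind_rows(rows)
  res$effect <- c("factor_a", "factor_b", "interaction")

  structure(
    list(
      result = res, n_perm = n_perm, seed = seed,
      scheme = "freedman_lane", cells = cells,
      factors = c(
        a = rlang::as_name(rlang::enquo(factor_a)),
        b = rlang::as_name(rlang::enquo(factor_b))
      )
    ),
    class = "perm_anova_2x2"
  )
}

#' @export
print.perm_anova_2x2 <- function(x, ...) {
  cat(sprintf(
    "2x2 permutation ANOVA (%s, %d permutations)\n",
    x$scheme, x$n_perm
  ))
  print(x$result)
  invisible(x)
}

#' Dichotomise scores at the 30th/70th percentiles
#'
#' Scores strictly above the `high_pct` percentile are labelled `"high"`,
#' scores strictly below the `low_pct` percentile `"low"`, and everything in
#' between `"unassigned"` (excluded from low-vs-high contrasts). Percentiles
#' use the linear-interpolation (type 7) quantile; labels are rank-based and
#' hence invariant under monotone transforms of the scores.
#'
#' @param scores Numeric vector (>= 10 non-missing values).
#' @param low_pct,high_pct Percentile cut points, defaults 30 and 70.
#' @param reference Optional numeric vector from which the percentiles are
#'   computed (e.g. a whole-population distribution); defaults to `scores`.
#' @return A factor with levels `low`, `unassigned`, `high` (NA for missing
#'   scores).
#' @examples
#' stratify_by_percentile(1:10)
#' @export
stratify_by_percentile <- function(scores, low_pct = 30, high_pct = 70,
                                   reference = NULL) {
  stopifnot(sum(!is.na(scores)) >= 10, low_pct < high_pct)
  ref <- if (is.null(reference)) scores else reference
  qs <- stats::quantile(ref, c(low_pct, high_pct) / 100, na.rm = TRUE, names = FALSE)
  if (qs[1] == qs[2]) {
    warning("degenerate score distribution: low and high percentiles coincide; all unassigned",
      call. = FALSE
    )
    out <- rep("unassigned", length(scores))
  } else {
    out <- dplyr::case_when(
      scores < qs[1] ~ "low",
      scores > qs[2] ~ "high",
      is.na(scores) ~ NA_character_,
      .default = "unassigned"
    )
  }
  factor(out, levels = c("low", "unassigned", "high"))
}

#' Deprivation "clock": low-vs-high difference in mean BAG rate
#'
#' Difference in the mean rate of change in BAG between the low and high
#' strata of a deprivation score, within one participant group; the raw
#' years/year value is kept alongside a months-and-days rendering (see
#' [format_months_days()]). The sign convention is mean(low) - mean(high),
#' so a positive clock means the more deprived stratum ages faster when low
#' scores mark deprivation (flip the labels otherwise).
#'
#' @param data A data frame with the rate column and a stratum label column.
#' @param rate Column holding R_BAG in years/year.
#' @param stratum Column holding labels from [stratify_by_percentile()].
#' @return A one-row tibble: `n_low`, `n_high`, `mean_low`, `mean_high`,
#'   `difference` (years/year), `months_days` (display string).
#' @export
deprivation_clock <- function(data, rate, stratum) {
  r <- dplyr::pull(data, {{ rate }})
  s <- as.character(dplyr::pull(data, {{ stratum }}))
  lo <- r[!is.na(s) & s == "low" & !is.na(r)]
  hi <- r[!is.na(s) & s == "high" & !is.na(r)]
  if (length(lo) == 0 || length(hi) == 0) {
    stop("both the low and high strata must be non-empty", call. = FALSE)
  }
  diff <- mean(lo) - mean(hi)
  tibble::tibble(
    n_low = length(lo), n_high = length(hi),
    mean_low = mean(lo), mean_high = mean(hi),
    difference = diff,
    months_days = format_months_days(diff)
  )
}
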