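#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted brain-age model
#'
#' One row per model term: the age-regression coefficients over SVD
#' components and the bias-correction coefficients over the age basis.
#'
#' @param x A `brain_age_model`.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `term`, `estimate`.
#' @method tidy brain_age_model
#' @export
tidy.brain_age_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      stage = "age_regression",
      term = c("(Intercept)", sprintf("component_%02d", seq_len(x$k))),
      estimate = unname(x$age_coef)
    ),
    tibble::tibble(
      stage = "bias_correction",
      term = c("(Intercept)", "age", "age^2")[seq_along(x$bias_coef)],
      estimate = unname(x$bias_coef)
    )
  )
}

#' @rdname tidy.brain_age_model
#' @return `glance()`: a one-row tibble with `n_train`, `n_idps`, `k`,
#'   `variance_explained` (cumulative over retained components),
#'   `train_r`, `train_mae`, and the stratum labels.
#' @method glance brain_age_model
#' @export
glance.brain_age_model <- function(x, ...) {
  tr <- x$training
  tibble::tibble(
    n_train = x$n_train, n_idps = length(x$feature_names), k = x$k,
    variance_explained = sum(x$variance_explained),
    train_r = stats::cor(tr$brain_age, tr$age),
    train_mae = mean(abs(tr$brain_age - tr$age)),
    sex = if (!is.null(x$stratum)) x$stratum[["sex"]] else NA_character_,
    tissue = if (!is.null(x$stratum)) x$stratum[["tissue"]] else NA_character_
  )
}

#' Tidy cross-validation results
#'
#' @param x A `brain_age_cv`.
#' @param ... Unused.
#' @return `tidy()`: per-repetition metrics (`repetition`, `r`, `mae`);
#'   `glance()`: the aggregate summary (mean and SD across repetitions).
#' @method tidy brain_age_cv
#' @export
tidy.brain_age_cv <- function(x, ...) {
  dplyr::select(x$metrics, "repetition", "r", "mae")
}

#' @rdname tidy.brain_age_cv
#' @method glance brain_age_cv
#' @export
glance.brain_age_cv <- function(x, ...) x$summary

#' Tidy a 2x2 permutation ANOVA
#'
#' @param x A `perm_anova_2x2`.
#' @param ... Unused.
#' @return `tidy()`: one row per effect (`effect`, `statistic`, `p`);
#'   `glance()`: the protocol (`n_perm`, `seed`, `scheme`, total n).
#' @method tidy perm_anova_2x2
#' @export
tidy.perm_anova_2x2 <- function(x, ...) x$result

#' @rdname tidy.perm_anova_2x2
#' @method glance perm_anova_2x2
#' @export
glance.perm_anova_2x2 <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    scheme = x$scheme,
    n = sum(x$cells)
  )
}
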