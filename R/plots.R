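# ggplot2 displays for the main result types. Styling is deliberately
# plain; all plots return the ggplot object for further theming.

#' Predicted vs chronological age
#'
#' Scatter of out-of-fold (or unseen-cohort) predictions against
#' chronological age with the identity line; annotation reports Pearson r
#' and MAE.
#'
#' @param object A `brain_age_cv` (autoplot method) or any data frame with
#'   `age` and `brain_age` columns ([plot_predicted_age()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brain_age_cv
#' @export
autoplot.brain_age_cv <- function(object, ...) {
  plot_predicted_age(object$predictions) +
    ggplot2::labs(
      subtitle = sprintf(
        "%d-fold CV x %d repeats: r = %.3f, MAE = %.2f y",
        object$folds, object$repeats,
        object$summary$r_mean, object$summary$mae_mean
      )
    )
}

#' @rdname autoplot.brain_age_cv
#' @param data A data frame with `age` and `brain_age` columns.
#' @export
plot_predicted_age <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$age, y = .data$brain_age)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Chronological age (years)", y = "Predicted brain age (years)"
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot of a fitted brain-age model
#'
#' Variance explained per retained SVD component.
#'
#' @param object A `brain_age_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brain_age_model
#' @export
autoplot.brain_age_model <- function(object, ...) {
  d <- tibble::tibble(
    component = seq_along(object$variance_explained),
    variance = object$variance_explained
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$variance)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "SVD component", y = "Fraction of variance",
      subtitle = sprintf(
        "%.1f%% of variance in %d components",
        100 * sum(object$variance_explained), length(object$variance_explained)
      )
    ) +
    ggplot2::theme_minimal()
}

#' BAG rate-of-change distributions by group
#'
#' Violin + jitter display of R_BAG (in months/year) per group.
#'
#' @param data A data frame with `r_bag` and a grouping column.
#' @param group Grouping column (default `group`).
#' @return A ggplot object.
#' @export
plot_rbag_groups <- function(data, group = "group") {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[group]], y = rbag_to_months(.data$r_bag),
    fill = .data[[group]]
  )) +
    ggplot2::geom_violin(alpha = 0.6, colour = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.25, size = 0.6) +
    ggplot2::labs(
      x = NULL, y = "Rate of change in BAG (months/year)"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' BAG rate against average age with per-group fits
#'
#' @param data A data frame from [compute_rbag()] with a grouping column.
#' @param group Grouping column (default `group_main`).
#' @return A ggplot object.
#' @export
plot_age_effect <- function(data, group = "group_main") {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$avg_age, y = rbag_to_months(.data$r_bag),
    colour = .data[[group]]
  )) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(
      x = "Average chronological age (years)",
      y = "Rate of change in BAG (months/year)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Sliding-window cognitive-change curve with SE band
#'
#' @param curve A tibble from [sliding_window_curve()], optionally with a
#'   `group` column (plot one call per group via `dplyr::bind_rows()`).
#' @return A ggplot object.
#' @export
plot_sliding_window <- function(curve) {
  has_group <- "group" %in% names(curve)
  aes <- if (has_group) {
    ggplot2::aes(
      x = .data$centre, y = .data$mean,
      colour = .data$group, fill = .data$group
    )
  } else {
    ggplot2::aes(x = .data$centre, y = .data$mean)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - .data$se,
        ymax = .data$mean + .data$se
      ),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Rate of change in BAG (years/year)",
      y = "Mean % change in completion time"
    ) +
    ggplot2::theme_minimal()
}
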