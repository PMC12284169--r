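#' Flag technical outliers in an IDP table
#'
#' Cells whose value lies more than `z_threshold` column standard deviations
#' from the column mean are flagged as technical outliers, and participants
#' with flagged cells are marked for exclusion. Zero-variance columns flag
#' nothing (convention: no spread, no outlier) and raise a warning once.
#'
#' @param data A data frame with one row per participant-session.
#' @param idps <[`tidy-select`][dplyr::dplyr_tidy_select]> IDP columns;
#'   defaults to columns starting with `"idp_"`.
#' @param z_threshold Flagging threshold in SD units (default 5).
#' @param max_fraction Exclusion policy: a participant-session is excluded
#'   when the fraction of its IDP cells flagged exceeds this value. The
#'   default 0 reproduces the any-flagged-cell policy.
#' @return The input tibble with two columns appended: `qc_outlier_cells`
#'   (count) and `qc_outlier` (logical exclusion flag); the `qc_` prefix
#'   keeps them clear of the `idp_` feature namespace. The full cell-level logical mask
#'   is attached as attribute `"outlier_mask"`.
#' @examples
#' d <- data.frame(id = 1:30, idp_1 = c(rep(0, 29), 100))
#' dplyr::filter(flag_idp_outliers(d), qc_outlier)
#' @export
flag_idp_outliers <- function(data, idps = dplyr::starts_with("idp_"),
                              z_threshold = 5, max_fraction = 0) {
  X <- as.matrix(dplyr::select(data, {{ idps }}))
  stopifnot(nrow(X) >= 2, ncol(X) >= 1)
  assert_scalar(z_threshold, "z_threshold", min = 0)
  mu <- colMeans(X, na.rm = TRUE)
  sdev <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sdev == 0, na.rm = TRUE)) {
    warning(sprintf(
      "%d zero-variance IDP column(s): no cells flagged there",
      sum(sdev == 0, na.rm = TRUE)
    ), call. = FALSE)
  }
  z <- sweep(sweep(X, 2, mu, "-"), 2, ifelse(sdev > 0, sdev, Inf), "/")
  mask <- !is.na(z) & abs(z) > z_threshold
  frac <- rowMeans(mask)
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    qc_outlier_cells = rowSums(mask),
    qc_outlier = frac > max_fraction
  )
  attr(out, "outlier_mask") <- mask
  out
}

#' Filter short inter-scan intervals
#'
#' Removes longitudinal rows whose inter-scan interval falls strictly below
#' either (a) the cohort's `lower_percentile` quantile of ISI
#' (linear-interpolation quantile; ties at the threshold are retained) or
#' (b) an absolute floor `min_years`. Re-applying the filter to its own
#' output with the same `min_years` removes nothing further only for the
#' absolute rule; the percentile rule is recomputed on the retained rows, so
#' the canonical usage is a single pass (the attached report records both
#' criteria's counts).
#'
#' @param data A data frame with an ISI column in years.
#' @param isi Column holding the interval (default `isi`).
#' @param lower_percentile Percentile cut, default 10.
#' @param min_years Absolute minimum interval, default 2.
#' @return The retained rows, with a `qc_report` attribute (tibble of counts
#'   per rule) readable via [qc_report()].
#' @examples
#' d <- data.frame(isi = c(1.0, 2.1, 2.2, 2.3, 2.4, 2.5, 2.6, 2.7, 2.8, 2.9))
#' nrow(filter_interscan_interval(d)) # 9
#' @export
filter_interscan_interval <- function(data, isi = "isi", lower_percentile = 10,
                                      min_years = 2.0) {
  v <- dplyr::pull(data, {{ isi }})
  stopifnot(all(!is.na(v)))
  assert_scalar(lower_percentile, "lower_percentile", 0, 100)
  assert_scalar(min_years, "min_years", min = 0)
  q <- stats::quantile(v, lower_percentile / 100, names = FALSE, type = 7)
  below_pct <- v < q
  below_min <- v < min_years
  keep <- !(below_pct | below_min)
  if (!any(keep)) {
    stop("no rows retained; relax `lower_percentile` or `min_years`",
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(data)[keep, ]
  attr(out, "qc_report") <- tibble::tibble(
    rule = c("isi_below_percentile", "isi_below_min_years", "either"),
    threshold = c(q, min_years, NA),
    n_excluded = c(sum(below_pct), sum(below_min), sum(!keep)),
    n_input = nrow(data),
    n_retained = sum(keep)
  )
  out
}

#' Retrieve the QC report attached to a filtered table
#'
#' @param data A tibble produced by a QC filter in this package.
#' @return The `qc_report` attribute (a tibble), or `NULL`.
#' @export
qc_report <- function(data) attr(data, "qc_report")

#' Assign pandemic/control groups from scan dates
#'
#' Longitudinal participants are labelled by the position of their two scans
#' relative to the pandemic onset date: both before onset = Control (G2);
#' exactly one after = Pandemic (G1), split into Pandemic-COVID (G3) and
#' Pandemic-NoCOVID (G4) by `covid_status`. Participants with both scans
#' after onset fall outside the study design and are dropped (counted in the
#' attached report).
#'
#' @param data One row per participant-session, with a session column (values
#'   `"t1"`/`"t2"`), a scan-date column (`Date` or coercible), a participant
#'   id column, and a logical `covid_status`.
#' @param onset_date Pandemic onset, default `"2020-03-01"`.
#' @param id,session,scan_date,covid_status Column names (strings).
#' @return The retained rows with `group_main` (`"G1"`/`"G2"`) and `group`
#'   (`"G2"`/`"G3"`/`"G4"`) columns appended; exclusions reported via
#'   [qc_report()].
#' @export
assign_groups <- function(data, onset_date = "2020-03-01", id = "participant_id",
                          session = "session", scan_date = "scan_date",
                          covid_status = "covid_status") {
  onset <- as.Date(onset_date)
  d <- tibble::as_tibble(data)
  stopifnot(all(c(id, session, scan_date, covid_status) %in% names(d)))
  per <- d |>
    dplyr::group_by(.data[[id]]) |>
    dplyr::summarise(
      n_after = sum(as.Date(.data[[scan_date]]) >= onset),
      covid = any(.data[[covid_status]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      group_main = dplyr::case_when(
        .data$n_after == 0 ~ "G2",
        .data$n_after == 1 ~ "G1",
        .default = NA_character_
      ),
      group = dplyr::case_when(
        .data$group_main == "G2" ~ "G2",
        .data$group_main == "G1" & .data$covid ~ "G3",
        .data$group_main == "G1" ~ "G4",
        .default = NA_character_
      )
    )
  dropped <- per[[id]][is.na(per$group_main)]
  out <- d |>
    dplyr::inner_join(
      dplyr::select(
        per, dplyr::all_of(id), "group_main", "group"
      ) |> dplyr::filter(!is.na(.data$group_main)),
      by = id
    )
  attr(out, "qc_report") <- tibble::tibble(
    rule = "both_scans_after_onset",
    n_excluded = length(dropped),
    n_input = dplyr::n_distinct(d[[id]]),
    n_retained = dplyr::n_distinct(out[[id]])
  )
  out
}

#' Covariate balance diagnostics between two groups
#'
#' For each covariate, group means (proportions for logicals), the
#' standardised mean difference (SMD = difference in means / pooled SD; 0 by
#' convention when the covariate is constant in both groups), and a
#' two-sample test p-value (t-test for numeric, chi-squared for logical).
#' Covariates with |SMD| > 0.1 are flagged as imbalanced. Balance
#' diagnostics, not a matching algorithm, are the contract here: what the
#' downstream analysis relies on is achieved balance.
#'
#' @param data A data frame.
#' @param covariates Character vector of covariate column names.
#' @param group Column name holding group labels.
#' @param group_pair Length-2 character vector choosing the two groups.
#' @param flag_threshold |SMD| above which a covariate is flagged.
#' @return A tibble with one row per covariate: `covariate`, `mean_1`,
#'   `mean_2`, `smd`, `p`, `flagged`.
#' @export
balance_table <- function(data, covariates, group, group_pair,
                          flag_threshold = 0.1) {
  g <- dplyr::pull(data, {{ group }})
  stopifnot(length(group_pair) == 2, all(group_pair %in% g))
  d1 <- data[g == group_pair[1], , drop = FALSE]
  d2 <- data[g == group_pair[2], , drop = FALSE]
  rows <- lapply(covariates, function(cv) {
    both <- c(d1[[cv]], d2[[cv]])
    if (!is.numeric(both)) {
      # two-level categorical -> indicator of the first level (proportion)
      lev <- sort(unique(as.character(both)))
      both <- as.numeric(as.character(both) == lev[1])
    }
    x1 <- both[seq_len(nrow(d1))]
    x2 <- both[-seq_len(nrow(d1))]
    sp2 <- (stats::var(x1) * (length(x1) - 1) + stats::var(x2) * (length(x2) - 1)) /
      (length(x1) + length(x2) - 2)
    smd <- if (sp2 == 0) 0 else (mean(x1) - mean(x2)) / sqrt(sp2)
    p <- if (sp2 == 0) 1 else stats::t.test(x1, x2)$p.value
    tibble::tibble(
      covariate = cv, mean_1 = mean(x1), mean_2 = mean(x2),
      smd = smd, p = p
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(flagged = abs(.data$smd) > flag_threshold)
}
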