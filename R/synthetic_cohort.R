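# Seeded synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes -- Gaussian age marginals, an age-driven low-rank IDP
# signal with additive confound contamination and iid measurement noise,
# paired scans with group-specific inter-scan intervals, and injectable
# effects on the true BAG rate -- while recording every injected value in a
# ground-truth table so downstream estimates can be checked by recovery.

#' Build a simulation configuration
#'
#' All knobs of the synthetic-cohort generator with defaults set to the
#' study conditions this package targets: training ages Gaussian 62.6 +/- 7.6
#' years truncated to \[45, 82\], longitudinal cohort 58.8 +/- 6.2,
#' Control inter-scan intervals narrowly Gaussian around 2.25 years and
#' Pandemic intervals uniform over a wider range reaching down to 1 year,
#' 46 generic confound variables, a Pandemic offset on the true BAG rate of
#' 0.458 years/year, and cognitive coupling confined to the infected
#' subgroup. Table sizes default to a desk-scale cohort (see the methods
#' vignette for the rationale).
#'
#' @param n_train Training-cohort size.
#' @param n_longitudinal Longitudinal participants per group (Control and
#'   Pandemic each).
#' @param age_mean,age_sd Training age marginal (years).
#' @param age_range Truncation bounds for ages (years).
#' @param age_mean_longitudinal,age_sd_longitudinal Longitudinal age
#'   marginal (years).
#' @param n_idps Number of IDP features.
#' @param n_signal_components Rank of the age-driven signal (<= `n_idps`;
#'   0 gives features with no age information).
#' @param n_trait_components Rank of the age-orthogonal, subject-stable
#'   structured variance (anatomy-like traits; carried across sessions with
#'   correlation `within_subject_cor`).
#' @param signal_to_noise Ratio of mean per-feature structured variance
#'   (signal + trait components) to unstructured noise variance; `Inf` gives
#'   noise-free features.
#' @param age_loading Correlation of each latent component with
#'   (standardised) effective age.
#' @param n_confounds Number of generic confound variables.
#' @param confound_strength Per-feature SD of the confound contamination.
#' @param confound_stability Session-to-session correlation of each
#'   confound value (most imaging confounds -- head size, site -- are
#'   largely stable within participant).
#' @param true_rbag_effect Offset added to Pandemic participants' true BAG
#'   rate (years of BAG per year).
#' @param deprivation_interaction Extra BAG-rate offset for deprived
#'   (low-employment-score) Pandemic participants (years/year).
#' @param rbag_drift_mean,rbag_age_slope,rbag_sd Baseline BAG-rate drift:
#'   mean (y/y), slope per year of average age (y/y per year; default
#'   0.00821 = 3 days/year), and between-participant SD.
#' @param bag_sd SD of the true baseline BAG (years).
#' @param within_subject_cor Session-to-session correlation of the
#'   non-age component of the latent scores (scan-rescan stability).
#' @param cognition_coupling Percent cognitive change per unit (y/y) of true
#'   BAG rate, applied in the infected subgroup only.
#' @param cognition_drift Mean percent change common to everyone.
#' @param cognition_noise SD of the percent-change noise.
#' @param female_fraction,covid_fraction Marginals for sex and (within the
#'   Pandemic group) infection.
#' @param isi_range_control,isi_range_pandemic (min, max) inter-scan
#'   intervals in years per group.
#' @param isi_control_mean,isi_control_sd Gaussian parameters of the Control
#'   interval inside its range.
#' @param onset_date Pandemic onset used to place scan dates.
#' @param seed Master seed; per-stage child seeds are derived
#'   deterministically so stages can be regenerated independently.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_train = 2000,
                              n_longitudinal = 400,
                              age_mean = 62.6, age_sd = 7.6,
                              age_range = c(45, 82),
                              age_mean_longitudinal = 58.8,
                              age_sd_longitudinal = 6.2,
                              n_idps = 200,
                              n_signal_components = 10,
                              n_trait_components = 40,
                              signal_to_noise = 4,
                              age_loading = 0.55,
                              n_confounds = 46,
                              confound_strength = 0.5,
                              confound_stability = 0.9,
                              true_rbag_effect = 0.458,
                              deprivation_interaction = 0.486,
                              rbag_drift_mean = 0.05,
                              rbag_age_slope = 0.00821,
                              rbag_sd = 0.3,
                              bag_sd = 3.5,
                              within_subject_cor = 0.985,
                              cognition_coupling = 15,
                              cognition_drift = 3,
                              cognition_noise = 10,
                              female_fraction = 0.55,
                              covid_fraction = 134 / 432,
                              isi_range_control = c(1.8, 2.8),
                              isi_range_pandemic = c(1.0, 4.5),
                              isi_control_mean = 2.25,
                              isi_control_sd = 0.25,
                              onset_date = "2020-03-01",
                              seed = 1L) {
  assert_count(n_train, "n_train")
  assert_count(n_longitudinal, "n_longitudinal")
  assert_scalar(age_sd, "age_sd", min = 1e-9)
  assert_scalar(age_sd_longitudinal, "age_sd_longitudinal", min = 1e-9)
  assert_range(age_range, "age_range")
  assert_count(n_idps, "n_idps")
  if (!is.numeric(n_signal_components) || n_signal_components < 0 ||
    n_signal_components > n_idps) {
    stop("`n_signal_components` must be an integer in [0, n_idps]", call. = FALSE)
  }
  if (!is.numeric(n_trait_components) || n_trait_components < 0 ||
    n_signal_components + n_trait_components > n_idps) {
    stop("`n_trait_components` must satisfy n_signal_components + n_trait_components <= n_idps",
      call. = FALSE
    )
  }
  assert_scalar(signal_to_noise, "signal_to_noise", min = 0)
  assert_scalar(age_loading, "age_loading", 0, 1)
  assert_count(n_confounds, "n_confounds", min = 0L)
  assert_scalar(confound_strength, "confound_strength", min = 0)
  assert_scalar(confound_stability, "confound_stability", 0, 1)
  assert_scalar(within_subject_cor, "within_subject_cor", 0, 1)
  assert_scalar(female_fraction, "female_fraction", 0, 1)
  assert_scalar(covid_fraction, "covid_fraction", 0, 1)
  assert_range(isi_range_control, "isi_range_control")
  assert_range(isi_range_pandemic, "isi_range_pandemic")
  assert_count(seed, "seed", min = 0L)

  cfg <- as.list(environment())
  cfg$n_signal_components <- as.integer(n_signal_components)
  cfg$n_trait_components <- as.integer(n_trait_components)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: n_train = %d, %d/group longitudinal, %d IDPs (rank %d), seed = %d\n",
    x$n_train, x$n_longitudinal, x$n_idps, x$n_signal_components, x$seed
  ))
  invisible(x)
}

# Structural parameters (feature loadings, confound loadings, noise scale)
# are drawn from their own child seed so the training and longitudinal
# cohorts share the identical generative mapping.
structural_params <- function(config) {
  withr_seed(child_seed(config$seed, "structure_"), function() {
    q <- config$n_signal_components
    qt <- q + config$n_trait_components
    m <- config$n_idps
    L <- if (qt > 0) {
      qr.Q(qr(matrix(stats::rnorm(m * qt), m, qt)))
    } else {
      matrix(0, m, 0)
    }
    B <- if (config$n_confounds > 0) {
      matrix(stats::rnorm(config$n_confounds * m), config$n_confounds, m) /
        sqrt(config$n_confounds)
    } else {
      matrix(0, 0, m)
    }
    mean_signal_var <- if (qt > 0) qt / m else 0
    noise_sd <- if (qt == 0) {
      1
    } else if (is.infinite(config$signal_to_noise)) {
      0
    } else if (config$signal_to_noise == 0) {
      1
    } else {
      sqrt(mean_signal_var / config$signal_to_noise)
    }
    list(L = L, B = B, noise_sd = noise_sd)
  })
}

rtrunc_norm <- function(n, mean, sd, range) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < range[1] | out > range[2]
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < range[1] | out > range[2]
  }
  out
}

# latent component scores: the first n_signal_components load on the
# standardised effective age; trait components are age-orthogonal
component_scores <- function(age_std, eta, w, q) {
  if (ncol(eta) == 0) {
    return(eta)
  }
  Z <- eta
  if (q > 0) {
    Z[, seq_len(q)] <- w * age_std + sqrt(1 - w^2) * eta[, seq_len(q), drop = FALSE]
  }
  Z
}

# assemble an IDP block from component scores and confounds
idp_block <- function(Z, C, sp, config) {
  n <- if (ncol(Z) > 0) nrow(Z) else nrow(C)
  X <- matrix(0, n, config$n_idps)
  if (ncol(Z) > 0) X <- X + Z %*% t(sp$L)
  if (config$n_confounds > 0) {
    X <- X + config$confound_strength * (C %*% sp$B)
  }
  if (sp$noise_sd > 0) {
    X <- X + matrix(
      stats::rnorm(n * config$n_idps, sd = sp$noise_sd),
      n, config$n_idps
    )
  }
  colnames(X) <- sprintf("idp_%03d", seq_len(config$n_idps))
  X
}

conf_block <- function(n, config) {
  C <- matrix(stats::rnorm(n * max(config$n_confounds, 1)), n)[
    , seq_len(config$n_confounds),
    drop = FALSE
  ]
  if (config$n_confounds > 0) {
    colnames(C) <- sprintf("conf_%02d", seq_len(config$n_confounds))
  }
  C
}

#' Generate the cross-sectional training cohort
#'
#' One pre-pandemic scan per participant: ages drawn truncated-Gaussian,
#' IDPs built as (age-driven low-rank signal) + (confound contamination) +
#' iid Gaussian noise at the configured signal-to-noise ratio. Fully
#' reproducible from the config seed; the same structural loadings are used
#' by [generate_longitudinal_cohort()], so a model trained here applies to
#' the longitudinal cohort.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per participant: `participant_id`, `sex`,
#'   `age`, confound columns `conf_*`, and IDP columns `idp_*`.
#' @export
generate_training_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- structural_params(config)
  withr_seed(child_seed(config$seed, "training"), function() {
    n <- config$n_train
    age <- rtrunc_norm(n, config$age_mean, config$age_sd, config$age_range)
    sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
    C <- conf_block(n, config)
    qt <- config$n_signal_components + config$n_trait_components
    eta <- matrix(stats::rnorm(n * qt), n, qt)
    age_std <- (age - config$age_mean) / config$age_sd
    Z <- component_scores(age_std, eta, config$age_loading, config$n_signal_components)
    X <- idp_block(Z, C, sp, config)
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = sprintf("T%05d", seq_len(n)),
        sex = sex, age = age
      ),
      tibble::as_tibble(C),
      tibble::as_tibble(X)
    )
  })
}

#' Generate the longitudinal (unseen) cohort with ground truth
#'
#' Two scans per participant. Control participants have both scans before
#' the pandemic onset with narrowly Gaussian inter-scan intervals; Pandemic
#' participants have exactly one scan after onset with intervals uniform
#' over a wider range. Each participant carries a true baseline BAG and a
#' true BAG rate composed of: a common drift, an age-dependent drift
#' (`rbag_age_slope`), the Pandemic group offset (`true_rbag_effect`), an
#' extra offset for deprived (employment score below the cohort's 30th
#' percentile) Pandemic participants (`deprivation_interaction`), and
#' Gaussian participant-level noise. Second-session IDPs encode the
#' resulting true BAG increment through the same structural loadings as the
#' training cohort; the non-age part of the latent scores is carried over
#' between sessions with correlation `within_subject_cor`, emulating high
#' scan-rescan stability.
#'
#' @param config A [simulation_config()].
#' @return A list with `cohort` (tibble, two rows per participant: id, sex,
#'   `session`, `age`, `scan_date`, `isi`, `covid_status`, deprivation
#'   scores `dep_*`, confounds, IDPs) and `truth` (one row per participant:
#'   group assignment, all injected offsets, true BAG at both scans and the
#'   true rate).
#' @export
generate_longitudinal_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- structural_params(config)
  if (max(config$isi_range_pandemic) < 2 || max(config$isi_range_control) < 2) {
    warning("an ISI range lies entirely below the 2-year follow-up filter; downstream filtering may remove a whole group",
      call. = FALSE
    )
  }
  withr_seed(child_seed(config$seed, "longitudinal"), function() {
    n_g <- config$n_longitudinal
    n <- 2L * n_g
    onset <- as.Date(config$onset_date)
    pandemic <- rep(c(FALSE, TRUE), each = n_g)
    covid <- pandemic & stats::runif(n) < config$covid_fraction
    sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
    age_t1 <- rtrunc_norm(
      n, config$age_mean_longitudinal,
      config$age_sd_longitudinal, config$age_range
    )

    isi <- numeric(n)
    isi[!pandemic] <- rtrunc_norm(
      n_g, config$isi_control_mean, config$isi_control_sd,
      config$isi_range_control
    )
    isi[pandemic] <- stats::runif(
      n_g, config$isi_range_pandemic[1], config$isi_range_pandemic[2]
    )

    # scan dates: Controls fully pre-onset; Pandemic t2 after onset, t1 before
    t2_offset <- numeric(n) # years of t2 relative to onset
    t2_offset[!pandemic] <- -stats::runif(n_g, 0.1, 3.0)
    t2_offset[pandemic] <- isi[pandemic] * stats::runif(n_g, 0.05, 0.95)
    date_t2 <- onset + round(t2_offset * DAYS_PER_YEAR)
    date_t1 <- date_t2 - round(isi * DAYS_PER_YEAR)

    dep <- matrix(stats::rnorm(n * 5), n, 5)
    colnames(dep) <- paste0(
      "dep_", c("health", "employment", "education", "income", "housing")
    )
    # deprived = employment score below the cohort 30th percentile
    deprived <- dep[, "dep_employment"] <
      stats::quantile(dep[, "dep_employment"], 0.30, names = FALSE)

    bag_t1 <- stats::rnorm(n, 0, config$bag_sd)
    avg_age <- age_t1 + isi / 2
    offset_pandemic <- ifelse(pandemic, config$true_rbag_effect, 0)
    offset_deprivation <- ifelse(
      pandemic & deprived, config$deprivation_interaction, 0
    )
    drift <- config$rbag_drift_mean +
      config$rbag_age_slope * (avg_age - config$age_mean_longitudinal)
    noise_r <- stats::rnorm(n, 0, config$rbag_sd)
    r_true <- drift + offset_pandemic + offset_deprivation + noise_r
    bag_t2 <- bag_t1 + r_true * isi
    age_t2 <- age_t1 + isi

    q <- config$n_signal_components
    qt <- q + config$n_trait_components
    eta1 <- matrix(stats::rnorm(n * qt), n, qt)
    rho <- config$within_subject_cor
    eta2 <- rho * eta1 + sqrt(1 - rho^2) * matrix(stats::rnorm(n * qt), n, qt)
    std <- function(a) (a - config$age_mean) / config$age_sd
    Z1 <- component_scores(std(age_t1 + bag_t1), eta1, config$age_loading, q)
    Z2 <- component_scores(std(age_t2 + bag_t2), eta2, config$age_loading, q)
    C1 <- conf_block(n, config)
    rho_c <- config$confound_stability
    C2 <- rho_c * C1 + sqrt(1 - rho_c^2) * conf_block(n, config)
    X1 <- idp_block(Z1, C1, sp, config)
    X2 <- idp_block(Z2, C2, sp, config)

    id <- sprintf("L%05d", seq_len(n))
    session_tbl <- function(s, age, date, C, X) {
      dplyr::bind_cols(
        tibble::tibble(
          participant_id = id, sex = sex, session = s,
          age = age, scan_date = date, isi = isi,
          covid_status = covid
        ),
        tibble::as_tibble(dep),
        tibble::as_tibble(C),
        tibble::as_tibble(X)
      )
    }
    cohort <- dplyr::bind_rows(
      session_tbl("t1", age_t1, date_t1, C1, X1),
      session_tbl("t2", age_t2, date_t2, C2, X2)
    ) |>
      dplyr::arrange(.data$participant_id, .data$session)

    truth <- tibble::tibble(
      participant_id = id,
      pandemic = pandemic, covid_status = covid, deprived = deprived,
      sex = sex, age_t1 = age_t1, age_t2 = age_t2, isi = isi,
      avg_age = avg_age,
      bag_t1 = bag_t1, bag_t2 = bag_t2,
      offset_pandemic = offset_pandemic,
      offset_deprivation = offset_deprivation,
      drift = drift, r_bag_true = r_true
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Attach synthetic cognitive scores to a longitudinal cohort
#'
#' Per participant, a positive baseline completion time (seconds, Trail
#' Making Test style) and a follow-up score
#' `baseline * (1 + (drift + coupling * true R_BAG * infected + noise)/100)`,
#' where the coupling applies only to infected participants. Non-positive
#' draws are resampled (baseline) or clipped (follow-up) with a logged count
#' in the [qc_report()] attribute; all returned scores are strictly
#' positive.
#'
#' @param cohort Longitudinal cohort tibble (rows per participant-session).
#' @param truth Ground-truth tibble from [generate_longitudinal_cohort()].
#' @param config A [simulation_config()].
#' @param test Column prefix for the scores (default `"tmt_a"`).
#' @param baseline_mean,baseline_sd Baseline score distribution (seconds).
#' @return The cohort with `<test>_t1` and `<test>_t2` columns joined on
#'   (identical on both session rows, as score change is a per-participant
#'   quantity).
#' @export
generate_cognitive_scores <- function(cohort, truth, config, test = "tmt_a",
                                      baseline_mean = 40, baseline_sd = 10) {
  stopifnot(inherits(config, "simulation_config"))
  withr_seed(child_seed(config$seed, "cognition"), function() {
    n <- nrow(truth)
    base <- rtrunc_norm(n, baseline_mean, baseline_sd, c(1e-3, Inf))
    pct <- config$cognition_drift +
      config$cognition_coupling * truth$r_bag_true * truth$covid_status +
      stats::rnorm(n, 0, config$cognition_noise)
    follow <- base * (1 + pct / 100)
    n_clipped <- sum(follow <= 0)
    follow[follow <= 0] <- 1e-3
    scores <- tibble::tibble(
      participant_id = truth$participant_id,
      !!paste0(test, "_t1") := base,
      !!paste0(test, "_t2") := follow
    )
    out <- dplyr::left_join(tibble::as_tibble(cohort), scores,
      by = "participant_id"
    )
    attr(out, "qc_report") <- tibble::tibble(
      rule = "nonpositive_followup_clipped", n_excluded = n_clipped,
      n_input = n, n_retained = n
    )
    out
  })
}

#' Write and read simulation configurations and cohort tables
#'
#' Configurations round-trip through JSON; cohort, ground-truth and result
#' tables through CSV (one row per participant-session for cohorts, header
#' row of feature names for IDP columns).
#'
#' @param config A [simulation_config()] (for writing).
#' @param path File path.
#' @return `read_simulation_config()` returns a validated
#'   `simulation_config`; the writers return the path invisibly.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- unclass(config)
  cfg$signal_to_noise <- ifelse(is.infinite(cfg$signal_to_noise),
    "Inf", cfg$signal_to_noise
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(cfg$signal_to_noise, "Inf")) cfg$signal_to_noise <- Inf
  do.call(simulation_config, cfg)
}

#' @rdname write_simulation_config
#' @param data A data frame to serialise.
#' @export
write_cohort_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
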