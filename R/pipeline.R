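#' Run the full longitudinal brain-ageing analysis on a synthetic cohort
#'
#' End-to-end orchestration: simulate (training + longitudinal cohorts) ->
#' QC (IDP outliers, ISI filter, group assignment) -> fit sex-stratified
#' brain-age models on the training set -> predict both sessions of the
#' longitudinal set -> BAG rates -> group statistics (pairwise tests with
#' Cohen's d and FDR, 2x2 permutation ANOVA for pandemic x sex, deprivation
#' stratification and clocks) -> cognition (percentage change, group tests,
#' R_BAG association). Stage outputs are returned as tibbles and optionally
#' written as CSVs with a JSON manifest (seeds, settings, row accounting).
#'
#' @param config A [simulation_config()]; its seed drives every stage.
#' @param k,folds,repeats Model hyperparameters; `repeats`/`folds` control
#'   the optional cross-validation (skipped when `repeats = 0`).
#' @param n_perm Permutations for the 2x2 tests.
#' @param out_dir Optional directory for CSV outputs and `manifest.json`.
#' @param tissue Label recorded with the fitted models (the generator
#'   produces one feature set per run; run twice with different seeds for a
#'   GM/WM pair).
#' @return A list of class `bagrate_run`: `models` (per sex),
#'   `cv` (or NULL), `bag_records`, `rbag`, `reproducibility`,
#'   `group_tests` (paper-style measured scale), `recovery` (the
#'   Pandemic-Control difference on the deattenuated true-BAG scale, for
#'   comparison with injected effects), `perm_sex`, `age_effects`,
#'   `deprivation`, `cognition_tests`, `cognition_association`, `qc`,
#'   `truth`, `manifest`.
#' @export
run_pipeline <- function(config = simulation_config(), k = 50, folds = 20,
                         repeats = 0, n_perm = 5000, out_dir = NULL,
                         tissue = "GM") {
  stopifnot(inherits(config, "simulation_config"))
  qc_log <- list()

  train <- generate_training_cohort(config)
  lon <- generate_longitudinal_cohort(config)
  cohort <- generate_cognitive_scores(lon$cohort, lon$truth, config)
  qc_log$cognition_scores <- qc_report(cohort)

  # QC: technical outliers on each table, ISI filter, group assignment
  train_q <- flag_idp_outliers(train)
  train_kept <- dplyr::filter(train_q, !.data$qc_outlier)
  cohort_q <- flag_idp_outliers(cohort)
  cohort_kept <- dplyr::filter(cohort_q, !.data$qc_outlier)
  qc_log$idp_outliers <- tibble::tibble(
    table = c("training", "longitudinal"),
    n_excluded = c(
      sum(train_q$qc_outlier),
      dplyr::n_distinct(cohort_q$participant_id[cohort_q$qc_outlier])
    )
  )
  # drop participants who lost a session to outlier QC
  cohort_kept <- cohort_kept |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::filter(dplyr::n() == 2L) |>
    dplyr::ungroup()

  participants <- dplyr::distinct(
    cohort_kept, .data$participant_id, .data$isi
  )
  kept_ids <- filter_interscan_interval(participants)
  qc_log$isi_filter <- qc_report(kept_ids)
  cohort_kept <- dplyr::semi_join(cohort_kept, kept_ids, by = "participant_id")

  cohort_g <- assign_groups(cohort_kept, onset_date = config$onset_date)
  qc_log$group_assignment <- qc_report(cohort_g)

  # fit per sex; tissue is a label (one feature set per generator run)
  sexes <- sort(unique(train_kept$sex))
  models <- lapply(sexes, function(s) {
    fit_brain_age_model(
      dplyr::filter(train_kept, .data$sex == s),
      k = k, stratum = c(sex = s, tissue = tissue)
    )
  })
  names(models) <- sexes

  cv <- NULL
  if (repeats > 0) {
    cv <- crossvalidate_brain_age(
      train_kept,
      k = k, folds = folds, repeats = repeats,
      seed = child_seed(config$seed, "cv")
    )
  }

  bag_records <- dplyr::bind_rows(lapply(sexes, function(s) {
    predict(models[[s]], dplyr::filter(cohort_g, .data$sex == s))
  }))
  # deattenuated copies for effect-size recovery (true-BAG scale)
  bag_records_adj <- dplyr::bind_rows(lapply(sexes, function(s) {
    predict(models[[s]], dplyr::filter(cohort_g, .data$sex == s),
      deattenuate = TRUE
    )
  }))

  rbag <- compute_rbag(bag_records) |>
    dplyr::mutate(
      pandemic = .data$group_main == "G1",
      pandemic_label = ifelse(.data$pandemic, "Pandemic", "Control")
    )
  rbag <- dplyr::inner_join(
    rbag,
    dplyr::distinct(
      cohort_g, .data$participant_id,
      dplyr::across(dplyr::starts_with("dep_"))
    ),
    by = "participant_id"
  )

  # scan-rescan reproducibility per main group
  wide_pred <- bag_records |>
    dplyr::select(
      "participant_id", "group_main", "session", "age", "brain_age"
    ) |>
    tidyr::pivot_wider(
      names_from = "session", values_from = c("age", "brain_age")
    ) |>
    dplyr::filter(!is.na(.data$brain_age_t1), !is.na(.data$brain_age_t2))
  reproducibility <- wide_pred |>
    dplyr::group_by(.data$group_main) |>
    dplyr::group_map(~ dplyr::mutate(
      reproducibility_stats(
        .x,
        yb_t1 = "brain_age_t1", yb_t2 = "brain_age_t2",
        age_t1 = "age_t1", age_t2 = "age_t2"
      ),
      group_main = .y[[1]], .before = 1
    )) |>
    dplyr::bind_rows()

  # pairwise group comparisons of R_BAG (one FDR family per panel)
  pull_group <- function(g) rbag$r_bag[rbag$group %in% g]
  pairs <- list(
    c("G1 vs G2", "G3,G4", "G2"),
    c("G3 vs G2", "G3", "G2"),
    c("G4 vs G2", "G4", "G2"),
    c("G3 vs G4", "G3", "G4")
  )
  group_tests <- dplyr::bind_rows(lapply(pairs, function(p) {
    two_sample_tests(
      pull_group(strsplit(p[2], ",")[[1]]),
      pull_group(strsplit(p[3], ",")[[1]]),
      kind = "t", label = p[1], family = "rbag_pairwise"
    )
  })) |> adjust_family()

  # recovery summary on the deattenuated (true-BAG) scale: the measured
  # group difference shrinks by the model's age-response gain, so dividing
  # it back out makes the estimate comparable to a true injected effect
  rbag_adj <- compute_rbag(bag_records_adj) |>
    dplyr::mutate(pandemic = .data$group_main == "G1")
  ht_adj <- stats::t.test(
    rbag_adj$r_bag[rbag_adj$pandemic], rbag_adj$r_bag[!rbag_adj$pandemic]
  )
  recovery <- tibble::tibble(
    estimate = unname(ht_adj$estimate[1] - ht_adj$estimate[2]),
    se = unname(ht_adj$stderr),
    conf_low = ht_adj$conf.int[1], conf_high = ht_adj$conf.int[2],
    scale = "deattenuated"
  )

  perm_sex <- permutation_anova_2x2(
    rbag, "r_bag", "pandemic_label", "sex",
    n_perm = n_perm, seed = child_seed(config$seed, "permutation")
  )

  age_effects <- age_effect_regression(rbag, by = "pandemic_label")

  # deprivation stratification, clocks, and 2x2 tests per index
  dep_cols <- grep("^dep_", names(rbag), value = TRUE)
  deprivation <- dplyr::bind_rows(lapply(dep_cols, function(dc) {
    strat <- rbag |>
      dplyr::mutate(stratum = stratify_by_percentile(.data[[dc]])) |>
      dplyr::filter(.data$stratum %in% c("low", "high"))
    clocks <- strat |>
      dplyr::group_by(.data$pandemic_label) |>
      dplyr::group_map(~ dplyr::mutate(
        deprivation_clock(.x, "r_bag", "stratum"),
        group = .y[[1]], .before = 1
      )) |>
      dplyr::bind_rows()
    pa <- permutation_anova_2x2(
      strat, "r_bag", "pandemic_label", "stratum",
      n_perm = n_perm,
      seed = child_seed(config$seed, "permutation") + match(dc, dep_cols)
    )
    dplyr::mutate(clocks,
      index = dc,
      p_perm_index = pa$result$p[pa$result$effect == "factor_b"],
      p_perm_interaction = pa$result$p[pa$result$effect == "interaction"]
    )
  }))

  # cognition: percentage change, group tests, association with R_BAG
  cog_participant <- cohort_g |>
    dplyr::filter(.data$session == "t1") |>
    dplyr::select(
      "participant_id", "group", "isi",
      dplyr::starts_with("tmt_")
    )
  cog <- cognitive_change(cog_participant, test = "tmt_a")
  cog_pairs <- list(c("G3 vs G2", "G3", "G2"), c("G3 vs G4", "G3", "G4"))
  cognition_tests <- dplyr::bind_rows(lapply(cog_pairs, function(p) {
    two_sample_tests(
      cog$pct_change[cog$group == p[2]],
      cog$pct_change[cog$group == p[3]],
      kind = "t", label = p[1], family = "tmt_a_pct_change"
    )
  })) |> adjust_family()
  cog_joined <- dplyr::inner_join(
    dplyr::select(rbag, "participant_id", "group", "r_bag", "avg_age"),
    dplyr::select(cog, "participant_id", "pct_change"),
    by = "participant_id"
  )
  cognition_association <- rbag_cognition_association(cog_joined, by = "group")

  manifest <- list(
    package_version = as.character(utils::packageVersion("bagrate")),
    seed = config$seed,
    settings = list(
      k = k, folds = folds, repeats = repeats, n_perm = n_perm,
      tissue = tissue
    ),
    config_hash = rlang::hash(unclass(config)),
    rows = list(
      training = nrow(train), training_kept = nrow(train_kept),
      longitudinal_participants = nrow(lon$truth),
      after_qc = dplyr::n_distinct(cohort_g$participant_id)
    )
  )

  run <- structure(
    list(
      models = models, cv = cv, bag_records = bag_records, rbag = rbag,
      reproducibility = reproducibility, group_tests = group_tests,
      perm_sex = perm_sex, age_effects = age_effects, recovery = recovery,
      deprivation = deprivation, cognition_tests = cognition_tests,
      cognition_association = cognition_association,
      qc = qc_log, truth = lon$truth, manifest = manifest
    ),
    class = "bagrate_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c(
      "bag_records", "rbag", "reproducibility", "group_tests",
      "age_effects", "deprivation", "cognition_tests",
      "cognition_association", "truth"
    )
    for (tb in tables) {
      write_cohort_csv(run[[tb]], file.path(out_dir, paste0(tb, ".csv")))
    }
    write_cohort_csv(perm_sex$result, file.path(out_dir, "perm_sex.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  run
}

#' @export
print.bagrate_run <- function(x, ...) {
  cat("bagrate pipeline run\n")
  cat(sprintf(
    "  participants after QC: %d\n", x$manifest$rows$after_qc
  ))
  cat("  Pandemic vs Control R_BAG comparisons:\n")
  print(dplyr::select(
    x$group_tests, "label", "estimate", "cohen_d", "p", "p_fdr"
  ))
  cat("  pandemic x sex permutation ANOVA:\n")
  print(x$perm_sex$result)
  invisible(x)
}
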