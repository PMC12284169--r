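test_that("invalid configuration errors name the offending field", {
  expect_error(simulation_config(n_train = 0), "n_train")
  expect_error(simulation_config(age_sd = -1), "age_sd")
  expect_error(simulation_config(isi_range_control = c(3, 2)), "isi_range_control")
  expect_error(
    simulation_config(n_idps = 10, n_signal_components = 11),
    "n_signal_components"
  )
  expect_error(
    simulation_config(n_idps = 10, n_signal_components = 5, n_trait_components = 6),
    "n_trait_components"
  )
})

test_that("generation is byte-identical under a repeated seed", {
  cfg <- tiny_config()
  expect_identical(generate_training_cohort(cfg), generate_training_cohort(cfg))
  l1 <- generate_longitudinal_cohort(cfg)
  l2 <- generate_longitudinal_cohort(cfg)
  expect_identical(l1, l2)
  c1 <- generate_cognitive_scores(l1$cohort, l1$truth, cfg)
  c2 <- generate_cognitive_scores(l2$cohort, l2$truth, cfg)
  expect_identical(c1, c2)
  # different seed changes the draw
  expect_false(identical(
    generate_training_cohort(cfg)$age,
    generate_training_cohort(tiny_config(seed = 43))$age
  ))
})

test_that("age marginals match the configured truncated Gaussian", {
  cfg <- simulation_config(
    n_train = 4000, n_idps = 20, n_signal_components = 2,
    n_trait_components = 4, n_confounds = 0, seed = 9
  )
  tr <- generate_training_cohort(cfg)
  # oracle: truncated-normal moments by numerical integration
  dens <- function(x) dnorm(x, cfg$age_mean, cfg$age_sd)
  z_mass <- integrate(dens, 45, 82)$value
  mu_t <- integrate(function(x) x * dens(x), 45, 82)$value / z_mass
  v_t <- integrate(function(x) (x - mu_t)^2 * dens(x), 45, 82)$value / z_mass
  se_mean <- sqrt(v_t / cfg$n_train)
  expect_lt(abs(mean(tr$age) - mu_t), 3 * se_mean)
  expect_lt(abs(sd(tr$age) - sqrt(v_t)), 3 * sqrt(v_t) / sqrt(2 * cfg$n_train))
  expect_true(all(tr$age >= cfg$age_range[1] & tr$age <= cfg$age_range[2]))
})

test_that("noise-free features give near-perfect age prediction", {
  # all stochastic terms off: fully age-loaded components, no measurement
  # noise, no confound contamination
  cfg <- tiny_config(
    signal_to_noise = Inf, confound_strength = 0,
    age_loading = 1, n_confounds = 0
  )
  tr <- generate_training_cohort(cfg)
  # fully loaded signal components coincide, so the structured rank is
  # 1 (age) + 15 (traits); retain exactly that
  cv <- crossvalidate_brain_age(tr, k = 16, folds = 5, repeats = 2, seed = 1)
  expect_gt(mean(cv$metrics$r), 0.99)
  expect_lt(mean(cv$metrics$mae), 0.5)
})

test_that("age-signal-free features give null out-of-fold correlation", {
  cfg <- tiny_config(n_signal_components = 0, n_trait_components = 0, n_confounds = 0)
  tr <- generate_training_cohort(cfg)
  cv <- crossvalidate_brain_age(tr, k = 20, folds = 5, repeats = 3, seed = 1)
  expect_lt(abs(mean(cv$metrics$r)), 2 / sqrt(cfg$n_train))
})

test_that("realised injected group effect matches the configured offset", {
  cfg <- simulation_config(
    n_longitudinal = 500, n_idps = 20, n_signal_components = 2,
    n_trait_components = 4, n_confounds = 0,
    true_rbag_effect = 0.458, deprivation_interaction = 0, seed = 5
  )
  lon <- generate_longitudinal_cohort(cfg)
  tru <- lon$truth
  # the deliberate offsets are exact by construction
  expect_equal(unique(tru$offset_pandemic[tru$pandemic]), 0.458)
  expect_true(all(tru$offset_pandemic[!tru$pandemic] == 0))
  # realised mean difference in the true rate = offset within sampling error
  realised <- mean(tru$r_bag_true[tru$pandemic]) - mean(tru$r_bag_true[!tru$pandemic])
  se <- sqrt(2) * cfg$rbag_sd / sqrt(cfg$n_longitudinal)
  expect_lt(abs(realised - 0.458), 4 * se)
})

test_that("cohort structure: paired sessions, positive intervals, group-consistent dates", {
  cfg <- tiny_config()
  lon <- generate_longitudinal_cohort(cfg)
  coh <- lon$cohort
  counts <- table(coh$participant_id)
  expect_true(all(counts == 2))
  wide <- tidyr::pivot_wider(
    dplyr::select(coh, participant_id, session, age, scan_date),
    names_from = session, values_from = c(age, scan_date)
  )
  expect_true(all(wide$age_t2 > wide$age_t1))
  onset <- as.Date(cfg$onset_date)
  pand <- lon$truth$pandemic[match(wide$participant_id, lon$truth$participant_id)]
  n_after <- (wide$scan_date_t1 >= onset) + (wide$scan_date_t2 >= onset)
  expect_true(all(n_after[pand] == 1))
  expect_true(all(n_after[!pand] == 0))
})

test_that("an ISI range entirely below the follow-up floor warns rather than errors", {
  cfg <- tiny_config(
    isi_range_pandemic = c(0.5, 1.5),
    isi_control_mean = 1, isi_range_control = c(0.5, 1.5)
  )
  expect_warning(generate_longitudinal_cohort(cfg), "2-year")
})

test_that("confound contamination is visible raw and gone after deconfounding", {
  cfg <- tiny_config(
    n_signal_components = 0, n_trait_components = 0,
    confound_strength = 1
  )
  tr <- generate_training_cohort(cfg)
  X <- as.matrix(dplyr::select(tr, dplyr::starts_with("idp_")))
  C <- as.matrix(dplyr::select(tr, dplyr::starts_with("conf_")))
  raw_cor <- max(abs(cor(X, C)))
  expect_gt(raw_cor, 0.3)
  dec <- fit_deconfounder(X, C)
  expect_lt(max(abs(cor(dec$residuals, C))), 1e-10)
})

test_that("cognitive scores follow the generative formula and stay positive", {
  cfg <- tiny_config(
    cognition_coupling = 0, cognition_drift = 0,
    cognition_noise = 0
  )
  lon <- generate_longitudinal_cohort(cfg)
  coh <- generate_cognitive_scores(lon$cohort, lon$truth, cfg)
  expect_true(all(coh$tmt_a_t2 == coh$tmt_a_t1)) # zero drift/coupling/noise
  expect_true(all(coh$tmt_a_t1 > 0))

  # infected-only coupling orders the realised group means
  cfg2 <- tiny_config(
    n_longitudinal = 400, cognition_coupling = 40,
    cognition_drift = 0, cognition_noise = 5, seed = 8
  )
  lon2 <- generate_longitudinal_cohort(cfg2)
  coh2 <- generate_cognitive_scores(lon2$cohort, lon2$truth, cfg2)
  d <- dplyr::distinct(coh2, participant_id, tmt_a_t1, tmt_a_t2) |>
    dplyr::inner_join(lon2$truth, by = "participant_id") |>
    dplyr::mutate(pct = (tmt_a_t2 - tmt_a_t1) * 100 / tmt_a_t1)
  m_inf <- mean(d$pct[d$covid_status])
  m_noninf <- mean(d$pct[d$pandemic & !d$covid_status])
  m_ctl <- mean(d$pct[!d$pandemic])
  # mean true rate in the infected subgroup is positive, so coupling > 0
  # pushes infected change above both uncoupled groups
  expect_gt(m_inf, m_noninf + 2)
  expect_gt(m_inf, m_ctl + 2)
  expect_lt(abs(m_noninf - m_ctl), 2)
})

test_that("configurations round-trip through JSON", {
  cfg <- tiny_config(signal_to_noise = Inf)
  path <- withr::local_tempfile(fileext = ".json")
  write_simulation_config(cfg, path)
  cfg2 <- read_simulation_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})
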