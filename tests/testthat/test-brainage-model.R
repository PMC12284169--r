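test_that("deconfounder removes confounds exactly on training rows", {
  set.seed(2)
  n <- 80
  X <- matrix(rnorm(n * 12), n, 12)
  C <- matrix(rnorm(n * 3), n, 3)

  # intercept-only: residuals are mean-centred features
  dec0 <- fit_deconfounder(X, NULL)
  expect_equal(dec0$residuals, scale(X, scale = FALSE), ignore_attr = TRUE)

  # exact linear function of the confounds: residuals vanish
  Xlin <- cbind(1, C) %*% matrix(rnorm(4 * 12), 4, 12)
  dec_lin <- fit_deconfounder(Xlin, C)
  expect_lt(max(abs(dec_lin$residuals)), 1e-10)

  # random data: residual-confound correlations at machine precision
  dec <- fit_deconfounder(X, C)
  expect_lt(max(abs(cor(dec$residuals, C))), 1e-10)

  # rank-deficient confounds: pseudo-inverse path with a warning
  C_dup <- cbind(C, C[, 1])
  expect_warning(dec_pi <- fit_deconfounder(X, C_dup), "rank-deficient")
  expect_lt(max(abs(cor(dec_pi$residuals, C))), 1e-10)
})

test_that("svd reduction tracks rank and variance, matching an eigen oracle", {
  set.seed(3)
  # exact rank 3: cumulative variance-explained is 1
  A <- matrix(rnorm(40 * 3), 40, 3) %*% matrix(rnorm(3 * 15), 3, 15)
  sv3 <- fit_svd(A, k = 3)
  expect_equal(sum(sv3$variance_explained), 1, tolerance = 1e-12)
  expect_error(fit_svd(A, k = 4), "rank")

  # projection + reconstruction at full rank recovers the matrix
  recon <- (A %*% sv3$basis) %*% t(sv3$basis)
  expect_equal(recon, A, tolerance = 1e-10)

  # variance fractions agree with a dense eigendecomposition of X'X
  X <- matrix(rnorm(60 * 10), 60, 10)
  sv <- fit_svd(X, k = 1)
  ev <- eigen(crossprod(X), symmetric = TRUE)$values
  expect_equal(sv$variance_explained[1], ev[1] / sum(ev), tolerance = 1e-10)
})

test_that("corrected training deltas are orthogonal to the age basis", {
  cfg <- tiny_config()
  tr <- generate_training_cohort(cfg)
  m <- fit_brain_age_model(tr, k = 20)
  d <- m$training$delta
  expect_lt(abs(cor(d, tr$age)), 1e-10)
  expect_lt(abs(cor(d, tr$age^2)), 1e-10)
  expect_lt(abs(mean(d)), 1e-10)

  # a saturated quadratic fit (3 ages, 3 parameters) zeroes any delta
  B <- bagrate:::age_basis(c(50, 60, 70), "quadratic")
  resid3 <- stats::lm.fit(B, c(2.3, -1.1, 0.7))$residuals
  expect_lt(max(abs(resid3)), 1e-10)
})

test_that("age perfectly encoded in the features leaves no raw delta", {
  cfg <- tiny_config(
    signal_to_noise = Inf, confound_strength = 0,
    age_loading = 1, n_trait_components = 0, n_confounds = 0
  )
  tr <- generate_training_cohort(cfg)
  m <- fit_brain_age_model(tr, k = 1) # all signal components coincide
  expect_lt(max(abs(m$training$delta_raw)), 1e-8)
  expect_lt(max(abs(m$bias_coef)), 1e-8)
})

test_that("prediction applies frozen training parameters", {
  cfg <- tiny_config()
  tr <- generate_training_cohort(cfg)
  m <- fit_brain_age_model(tr, k = 20)

  # predicting the training table reproduces the in-sample deltas
  p_tr <- predict(m, tr)
  expect_equal(p_tr$delta, m$training$delta, tolerance = 1e-10)
  expect_lt(abs(mean(p_tr$delta)), 1e-10)

  # duplicated row: identical records
  two <- tr[c(5, 5), ]
  p2 <- predict(m, two)
  expect_identical(p2[1, ], p2[2, ])
  expect_equal(p2$delta_raw, p2$brain_age - p2$age)

  # schema errors for missing columns
  expect_error(predict(m, dplyr::select(tr, -idp_010)), "feature columns")
  expect_error(predict(m, dplyr::select(tr, -conf_01)), "confound columns")
})

test_that("unseen-cohort corrected deltas carry no age bias", {
  cfg <- simulation_config(n_longitudinal = 498, seed = 21) # 996 scans group-wide
  tr <- generate_training_cohort(cfg)
  lon <- generate_longitudinal_cohort(cfg)
  pred <- dplyr::bind_rows(lapply(c("F", "M"), function(s) {
    m <- fit_brain_age_model(dplyr::filter(tr, sex == s), k = 50)
    predict(m, dplyr::filter(lon$cohort, sex == s, session == "t1"))
  }))
  n <- nrow(pred)
  expect_gte(n, 900)
  expect_lt(abs(cor(pred$delta, pred$age)), 2 / sqrt(n))
})

test_that("shifting all ages by a constant leaves corrected deltas unchanged", {
  cfg <- tiny_config()
  tr <- generate_training_cohort(cfg)
  m1 <- fit_brain_age_model(tr, k = 20)
  tr_shift <- dplyr::mutate(tr, age = age + 7)
  m2 <- fit_brain_age_model(tr_shift, k = 20)
  expect_equal(m2$training$brain_age, m1$training$brain_age + 7, tolerance = 1e-8)
  expect_equal(m2$training$delta, m1$training$delta, tolerance = 1e-8)
})

test_that("cross-validation matches an independent fold-by-fold oracle", {
  cfg <- tiny_config(n_train = 150, n_idps = 30, n_confounds = 3)
  tr <- generate_training_cohort(cfg)
  k <- 10
  folds <- 5
  seed <- 99
  cv <- crossvalidate_brain_age(tr,
    k = k, folds = folds, repeats = 1,
    seed = seed, stratify_age = FALSE
  )

  # oracle: replay the fold assignment, then rebuild each fold's pipeline
  # from primitive matrix operations only
  y <- tr$age
  X <- as.matrix(dplyr::select(tr, dplyr::starts_with("idp_")))
  C <- as.matrix(dplyr::select(tr, dplyr::starts_with("conf_")))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(y)))
  pred <- numeric(length(y))
  for (f in seq_len(folds)) {
    te <- fold_of == f
    Cd <- cbind(1, C[!te, ])
    W <- solve(crossprod(Cd), crossprod(Cd, X[!te, ]))
    R_tr <- X[!te, ] - Cd %*% W
    mu <- colMeans(R_tr)
    sdv <- apply(R_tr, 2, sd)
    S_tr <- sweep(sweep(R_tr, 2, mu), 2, sdv, "/")
    V <- svd(S_tr)$v[, 1:k]
    U_tr <- S_tr %*% V
    beta <- solve(crossprod(cbind(1, U_tr)), crossprod(cbind(1, U_tr), y[!te]))
    R_te <- X[te, ] - cbind(1, C[te, ]) %*% W
    S_te <- sweep(sweep(R_te, 2, mu), 2, sdv, "/")
    pred[te] <- cbind(1, S_te %*% V) %*% beta
  }
  expect_equal(cv$predictions$brain_age, pred, tolerance = 1e-8)
  expect_equal(cv$metrics$r, cor(pred, y), tolerance = 1e-10)
  expect_equal(cv$metrics$mae, mean(abs(pred - y)), tolerance = 1e-10)
})

test_that("every subject is predicted exactly once per repetition", {
  cfg <- tiny_config(n_train = 120)
  tr <- generate_training_cohort(cfg)
  cv <- crossvalidate_brain_age(tr, k = 10, folds = 6, repeats = 2, seed = 4)
  expect_equal(sort(unique(cv$predictions$fold)), 1:6)
  expect_equal(length(cv$predictions$brain_age), nrow(tr))
  expect_error(
    crossvalidate_brain_age(tr, k = 10, folds = 1, repeats = 1),
    "folds"
  )
})

test_that("cross-validated accuracy is monotone in the signal-to-noise ratio", {
  rs <- vapply(c(0.25, 1, 4, Inf), function(snr) {
    cfg <- tiny_config(signal_to_noise = snr, n_train = 200)
    tr <- generate_training_cohort(cfg)
    cv <- crossvalidate_brain_age(tr, k = 20, folds = 5, repeats = 2, seed = 17)
    mean(cv$metrics$r)
  }, numeric(1))
  expect_true(all(diff(rs) > -0.01))
  expect_gt(rs[4], rs[1] + 0.1)
})

test_that("performance metrics match hand-computed cases", {
  pm <- performance_metrics(c(1, 2, 3), c(3, 2, 1))
  expect_equal(pm$r, -1)
  expect_equal(pm$mae, 4 / 3)
  pm2 <- performance_metrics(1:10 + 1, 1:10)
  expect_equal(pm2$r, 1)
  expect_equal(pm2$mae, 1)
  pm3 <- performance_metrics(rep(1, 5), 1:5)
  expect_true(is.na(pm3$r))
  expect_equal(pm3$mae, mean(abs(1 - 1:5)))
})

test_that("tidiers expose model and CV summaries", {
  cfg <- tiny_config()
  tr <- generate_training_cohort(cfg)
  m <- fit_brain_age_model(tr, k = 15, stratum = c(sex = "F", tissue = "GM"))
  td <- generics::tidy(m)
  expect_equal(nrow(td), (15 + 1) + 3)
  gl <- generics::glance(m)
  expect_equal(gl$k, 15)
  expect_equal(gl$sex, "F")
  cv <- crossvalidate_brain_age(tr, k = 10, folds = 5, repeats = 2, seed = 1)
  expect_equal(nrow(generics::tidy(cv)), 2)
  expect_named(
    generics::glance(cv),
    c("r_mean", "r_sd", "mae_mean", "mae_sd", "folds", "repeats", "n")
  )
})
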