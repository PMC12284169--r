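# Unbiased brain-age model: deconfound -> standardise -> SVD -> linear age
# regression -> quadratic age-bias correction. All parameters are estimated
# on training rows only and frozen for prediction, so unseen data never
# leaks into deconfounder weights, feature scaling, the SVD basis, or the
# bias-correction curve.

#' Fit confound-removal weights on training data
#'
#' Least-squares weights mapping confounds (plus intercept) to each IDP.
#' Residualised training IDPs are exactly uncorrelated with every confound;
#' at prediction time the same weights are applied to unseen rows, so test
#' measures are deconfounded with training-set weights, never refit.
#' Age-derived variables must not appear among the confounds, otherwise the
#' age signal itself is removed.
#'
#' @param X Numeric matrix (rows = participants, columns = IDPs).
#' @param C Numeric confound matrix with the same number of rows, or `NULL`
#'   for intercept-only (mean-centring).
#' @return A list with `weights` ((1 + n_confounds) x n_idps) and
#'   `residuals` (training residuals).
#' @export
fit_deconfounder <- function(X, C = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  Cd <- if (is.null(C)) matrix(1, n, 1) else cbind(1, as.matrix(C))
  stopifnot(nrow(Cd) == n)
  qr_c <- qr(Cd)
  if (qr_c$rank < ncol(Cd)) {
    warning("rank-deficient confound matrix; using minimum-norm (pseudo-inverse) weights",
      call. = FALSE
    )
    sv <- svd(Cd)
    pos <- sv$d > max(dim(Cd)) * .Machine$double.eps * sv$d[1]
    W <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% X / sv$d[pos])
  } else {
    W <- qr.coef(qr_c, X)
  }
  list(weights = W, residuals = X - Cd %*% W)
}

apply_deconfounder <- function(X, C, weights) {
  X <- as.matrix(X)
  Cd <- if (is.null(C)) matrix(1, nrow(X), 1) else cbind(1, as.matrix(C))
  stopifnot(ncol(Cd) == nrow(weights))
  X - Cd %*% weights
}

#' SVD basis of a standardised IDP matrix
#'
#' Orthonormal basis of the top-`k` right singular vectors, with the
#' fraction of variance carried by each retained component. Retaining ~50
#' components of a standardised IDP table balances variance capture against
#' overfitting in downstream age regression.
#'
#' @param X Numeric matrix, already deconfounded and standardised.
#' @param k Number of components (<= min(nrow, ncol) and <= numerical rank).
#' @return A list with `basis` (n_idps x k), `variance_explained` (length-k
#'   fractions, non-increasing), and `rank`.
#' @export
fit_svd <- function(X, k = 50) {
  X <- as.matrix(X)
  assert_count(k, "k")
  stopifnot(k <= min(dim(X)))
  sv <- svd(X, nu = 0)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (k > rank) {
    stop(sprintf("k = %d exceeds the numerical rank %d of the matrix", k, rank),
      call. = FALSE
    )
  }
  list(
    basis = sv$v[, seq_len(k), drop = FALSE],
    variance_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
    rank = rank
  )
}

# Stage-2 bias correction: least squares of raw delta on [1, Y, Y^2] (or
# [1, Y]); corrected training deltas are the residuals, orthogonal to the
# age basis by construction.
age_basis <- function(y, bias_basis) {
  if (bias_basis == "quadratic") cbind(1, y, y^2) else cbind(1, y)
}

#' Fit the unbiased brain-age model for one stratum
#'
#' Runs the full training pipeline on a data frame holding one stratum (one
#' sex x tissue combination): confound removal ([fit_deconfounder()]),
#' per-feature z-scoring with training mean/SD, SVD reduction
#' ([fit_svd()]), least-squares regression of chronological age on the
#' component scores, and a second-stage fit of the raw brain-age gap
#' (predicted minus chronological age) on the age basis \[1, Y, Y^2\]. The
#' corrected training gap is orthogonal to chronological age and its square
#' at machine precision.
#'
#' @param data A data frame with one row per participant(-session).
#' @param age Column holding chronological age in years (unquoted or string).
#' @param idps,confounds <[`tidy-select`][dplyr::dplyr_tidy_select]> feature
#'   and confound columns; defaults select `idp_*` and `conf_*` prefixes.
#'   Use `confounds = NULL` for no deconfounding beyond mean-centring.
#' @param k Number of SVD components (default 50).
#' @param bias_basis `"quadratic"` (default) or `"linear"` age basis for the
#'   gap correction.
#' @param stratum Optional named character vector recorded in the model
#'   (e.g. `c(sex = "F", tissue = "GM")`).
#' @return An object of class `brain_age_model`.
#' @export
fit_brain_age_model <- function(data, age = "age",
                                idps = dplyr::starts_with("idp_"),
                                confounds = dplyr::starts_with("conf_"),
                                k = 50, bias_basis = c("quadratic", "linear"),
                                stratum = NULL) {
  bias_basis <- match.arg(bias_basis)
  y <- dplyr::pull(data, {{ age }})
  X <- as.matrix(dplyr::select(data, {{ idps }}))
  C <- dplyr::select(data, {{ confounds }})
  C <- if (ncol(C) == 0) NULL else as.matrix(C)
  n <- nrow(X)
  stopifnot(n == length(y), !anyNA(X), !anyNA(y))
  if (stats::sd(y) == 0) stop("chronological age is constant; cannot fit", call. = FALSE)
  if (n < k + 3) stop("need at least k + 3 training rows", call. = FALSE)

  dec <- fit_deconfounder(X, C)
  mu <- colMeans(dec$residuals)
  sdev <- apply(dec$residuals, 2, stats::sd)
  sdev[sdev == 0] <- 1 # constant residual feature carries no information
  Xs <- sweep(sweep(dec$residuals, 2, mu, "-"), 2, sdev, "/")

  sv <- fit_svd(Xs, k = k)
  U <- Xs %*% sv$basis
  fit1 <- stats::lm.fit(cbind(1, U), y)
  y_b <- y - fit1$residuals
  delta_raw <- y_b - y

  B <- age_basis(y, bias_basis)
  fit2 <- stats::lm.fit(B, delta_raw)
  delta <- fit2$residuals

  # age-response gain: the slope of predicted on true age (= in-sample R^2).
  # A true brain-age offset passes through the same feature->age channel as
  # chronological age, so measured deltas are attenuated by this factor;
  # predict(..., deattenuate = TRUE) divides it back out.
  gain <- stats::cov(y_b, y) / stats::var(y)

  structure(
    list(
      feature_names = colnames(X),
      confound_names = colnames(C),
      deconfounder = dec$weights,
      center = mu, scale = sdev,
      svd_basis = sv$basis, k = k,
      variance_explained = sv$variance_explained,
      age_coef = fit1$coefficients,
      gain = gain,
      bias_basis = bias_basis,
      bias_coef = fit2$coefficients,
      stratum = stratum,
      n_train = n,
      training = tibble::tibble(
        age = y, brain_age = y_b,
        delta_raw = delta_raw, delta = delta
      )
    ),
    class = "brain_age_model"
  )
}

#' @export
print.brain_age_model <- function(x, ...) {
  cat(sprintf(
    "Unbiased brain-age model: %d IDPs -> %d SVD components (%.1f%% variance), n = %d\n",
    length(x$feature_names), x$k, 100 * sum(x$variance_explained), x$n_train
  ))
  if (!is.null(x$stratum)) {
    cat("stratum:", paste(names(x$stratum), x$stratum, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict brain age and bias-corrected BAG for new data
#'
#' Applies, in order and without refitting anything: the training
#' deconfounder weights, the training standardisation, the SVD basis, the
#' age regression, and the training-derived bias correction evaluated at
#' each new subject's chronological age. Set `refit_bias = TRUE` to instead
#' re-estimate the bias-correction curve on the new cohort (off by default;
#' the default honours the train-once contract).
#'
#' @param object A `brain_age_model`.
#' @param data A data frame carrying the same IDP and confound columns as
#'   the training data plus an age column.
#' @param age Column holding chronological age (default `"age"`).
#' @param id Optional column name copied into the output (default
#'   `"participant_id"` when present).
#' @param refit_bias Re-estimate the bias-correction coefficients on the new
#'   cohort instead of using the training fit.
#' @param deattenuate Divide the corrected gap by the model's age-response
#'   gain (the training slope of predicted on true age). Measured gaps are
#'   shrunk by this factor because a true brain-age offset is read through
#'   the same noisy feature channel as chronological age; deattenuation
#'   makes group differences unbiased estimates of true BAG effects, at the
#'   price of leaving the paper-style measured scale. Off by default.
#' @param ... Unused.
#' @return A tibble of BAG records: optional id/session columns carried
#'   over, `age`, `brain_age`, `delta_raw` (= brain_age - age exactly) and
#'   `delta` (bias-corrected BAG, years).
#' @export
predict.brain_age_model <- function(object, data, age = "age",
                                    id = "participant_id",
                                    refit_bias = FALSE, deattenuate = FALSE,
                                    ...) {
  y <- dplyr::pull(data, {{ age }})
  missing_feat <- setdiff(object$feature_names, names(data))
  if (length(missing_feat) > 0) {
    stop(
      "data lacks trained feature columns: ",
      paste(utils::head(missing_feat, 5), collapse = ", "),
      if (length(missing_feat) > 5) ", ...",
      call. = FALSE
    )
  }
  X <- as.matrix(data[, object$feature_names, drop = FALSE])
  C <- if (is.null(object$confound_names)) {
    NULL
  } else {
    missing_conf <- setdiff(object$confound_names, names(data))
    if (length(missing_conf) > 0) {
      stop("data lacks trained confound columns: ",
        paste(missing_conf, collapse = ", "),
        call. = FALSE
      )
    }
    as.matrix(data[, object$confound_names, drop = FALSE])
  }
  Xd <- apply_deconfounder(X, C, object$deconfounder)
  Xs <- sweep(sweep(Xd, 2, object$center, "-"), 2, object$scale, "/")
  U <- Xs %*% object$svd_basis
  y_b <- as.vector(cbind(1, U) %*% object$age_coef)
  delta_raw <- y_b - y
  if (refit_bias) {
    B <- age_basis(y, object$bias_basis)
    delta <- stats::lm.fit(B, delta_raw)$residuals
  } else {
    B <- age_basis(y, object$bias_basis)
    delta <- delta_raw - as.vector(B %*% object$bias_coef)
  }
  if (deattenuate) delta <- delta / object$gain
  out <- tibble::tibble(age = y, brain_age = y_b, delta_raw = delta_raw, delta = delta)
  carry <- intersect(c(id, "session", "sex", "group", "group_main"), names(data))
  if (length(carry) > 0) {
    out <- dplyr::bind_cols(tibble::as_tibble(data[, carry, drop = FALSE]), out)
  }
  out
}

#' Prediction accuracy metrics
#'
#' Pearson correlation between predicted and true ages (with Fisher-z 95%
#' confidence interval) and the mean absolute error in years.
#'
#' @param pred,true Numeric vectors of equal length >= 3.
#' @param conf Confidence level for the Fisher-z interval.
#' @return A one-row tibble: `r`, `r_lower`, `r_upper`, `mae`, `n`. `r` and
#'   its CI are `NA` when either vector has zero variance.
#' @export
performance_metrics <- function(pred, true, conf = 0.95) {
  stopifnot(length(pred) == length(true), length(pred) >= 3)
  n <- length(pred)
  mae <- mean(abs(pred - true))
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    return(tibble::tibble(
      r = NA_real_, r_lower = NA_real_, r_upper = NA_real_,
      mae = mae, n = n
    ))
  }
  r <- stats::cor(pred, true)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  tibble::tibble(
    r = r, r_lower = tanh(z - zc * se), r_upper = tanh(z + zc * se),
    mae = mae, n = n
  )
}

# Age-decile-stratified fold assignment: deciles are sliced round-robin so
# every fold spans the age range (stabilises small-fold age regressions).
make_folds <- function(y, folds, stratify_age = TRUE) {
  n <- length(y)
  assignment <- integer(n)
  if (stratify_age) {
    dec <- dplyr::ntile(y, 10)
    for (d in unique(dec)) {
      idx <- which(dec == d)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- (seq_along(idx) - 1L) %% folds + 1L
    }
    # rotate so fold sizes balance across deciles
    assignment <- (assignment + sample.int(folds, 1L)) %% folds + 1L
  } else {
    assignment <- sample(rep_len(seq_len(folds), n))
  }
  assignment
}

#' Repeated k-fold cross-validation of the brain-age model
#'
#' Per repetition, rows are randomly assigned to `folds` folds (stratified
#' by age decile by default); for each fold the entire pipeline —
#' deconfounder, standardisation, SVD, age regression, bias correction — is
#' refit on the remaining folds and applied to the held-out fold, so every
#' subject is predicted exactly once per repetition. Pearson r and MAE are
#' computed on the pooled out-of-fold predictions of each repetition, then
#' summarised as mean and SD across repetitions.
#'
#' @inheritParams fit_brain_age_model
#' @param folds Number of folds (default 20).
#' @param repeats Number of random re-assignments (default 100).
#' @param seed Integer seed for fold assignment.
#' @param stratify_age Stratify folds by age decile (default TRUE).
#' @return An object of class `brain_age_cv`: list with `metrics` (tibble,
#'   one row per repetition: `repetition`, `r`, `mae`), `predictions`
#'   (out-of-fold predictions of the last repetition), `summary` (mean/sd),
#'   and the protocol settings.
#' @export
crossvalidate_brain_age <- function(data, age = "age",
                                    idps = dplyr::starts_with("idp_"),
                                    confounds = dplyr::starts_with("conf_"),
                                    k = 50, folds = 20, repeats = 100,
                                    seed = NULL, stratify_age = TRUE,
                                    bias_basis = "quadratic") {
  assert_count(folds, "folds", min = 2L)
  assert_count(repeats, "repeats", min = 1L)
  y <- dplyr::pull(data, {{ age }})
  n <- length(y)
  stopifnot(n >= folds)
  X <- as.matrix(dplyr::select(data, {{ idps }}))
  Cdf <- dplyr::select(data, {{ confounds }})
  has_conf <- ncol(Cdf) > 0
  if (!is.null(seed)) set.seed(seed)

  run_rep <- function(rep_i) {
    fold_of <- make_folds(y, folds, stratify_age)
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      test <- fold_of == f
      d_train <- data[!test, , drop = FALSE]
      m <- fit_brain_age_model(
        d_train,
        age = {{ age }}, idps = {{ idps }},
        confounds = {{ confounds }}, k = k, bias_basis = bias_basis
      )
      p <- predict(m, data[test, , drop = FALSE], age = {{ age }})
      pred[test] <- p$brain_age
    }
    list(
      metrics = dplyr::mutate(performance_metrics(pred, y), repetition = rep_i),
      pred = pred, fold_of = fold_of
    )
  }

  reps <- lapply(seq_len(repeats), run_rep)
  metrics <- dplyr::bind_rows(lapply(reps, `[[`, "metrics")) |>
    dplyr::select("repetition", dplyr::everything())
  last <- reps[[repeats]]
  structure(
    list(
      metrics = metrics,
      predictions = tibble::tibble(
        age = y, brain_age = last$pred, fold = last$fold_of
      ),
      summary = tibble::tibble(
        r_mean = mean(metrics$r), r_sd = stats::sd(metrics$r),
        mae_mean = mean(metrics$mae), mae_sd = stats::sd(metrics$mae),
        folds = folds, repeats = repeats, n = n
      ),
      folds = folds, repeats = repeats, seed = seed, k = k
    ),
    class = "brain_age_cv"
  )
}

#' @export
print.brain_age_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "%d-fold CV x %d repeats (n = %d): r = %.3f +/- %.3f, MAE = %.2f +/- %.2f years\n",
    x$folds, x$repeats, s$n, s$r_mean, s$r_sd, s$mae_mean, s$mae_sd
  ))
  invisible(x)
}
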