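test_that("Cohen's d matches hand computation and its invariances", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2) # pooled SD = 1
  x <- rnorm(20)
  expect_equal(cohens_d(x, x), 0)
  y <- rnorm(15, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_equal(cohens_d(3 * x + 2, 3 * y + 2), cohens_d(x, y), tolerance = 1e-12)
  # zero pooled SD with unequal means: signed overflow sentinel
  expect_identical(cohens_d(c(1, 1), c(2, 2)), -Inf)
  expect_identical(cohens_d(c(1, 1), c(1, 1)), 0)
})

test_that("two-sample tests cover the t and Mann-Whitney conventions", {
  x <- c(1.2, 3.4, 2.2, 4.8, 0.5)
  same <- two_sample_tests(x, x, kind = "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # affine transforms leave the t p-value unchanged
  y <- rnorm(12, 1)
  p1 <- two_sample_tests(x, y, kind = "t")$p
  p2 <- two_sample_tests(2 * x - 5, 2 * y - 5, kind = "t")$p
  expect_equal(p1, p2, tolerance = 1e-12)

  # U = 0 with exact two-sided p = 0.1 = 2/choose(6,3)*... by enumeration
  mw <- two_sample_tests(c(1, 2, 3), c(4, 5, 6), kind = "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1)

  # all observations tied: p = 1 by convention
  tied <- two_sample_tests(rep(2, 5), rep(2, 6), kind = "mann_whitney")
  expect_equal(tied$p, 1)
})

test_that("Mann-Whitney exact p agrees with full enumeration for n <= 8", {
  set.seed(12)
  for (i in 1:10) {
    n1 <- sample(3:4, 1)
    n2 <- sample(3:4, 1)
    x1 <- round(rnorm(n1), 2)
    x2 <- round(rnorm(n2, 0.5), 2)
    if (anyDuplicated(c(x1, x2))) next # exact path requires no ties
    got <- two_sample_tests(x1, x2, kind = "mann_whitney")$p
    expect_equal(got, mw_exact_enum(x1, x2), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(fdr_bh(numeric(0)), numeric(0))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  # family-wise adjustment preserves row order and the p_fdr >= p invariant
  res <- dplyr::bind_rows(
    two_sample_tests(rnorm(10), rnorm(10, 2), label = "a", family = "f1"),
    two_sample_tests(rnorm(10), rnorm(10), label = "b", family = "f1"),
    two_sample_tests(rnorm(10), rnorm(10), label = "c", family = "f2")
  ) |> adjust_family()
  expect_equal(res$label, c("a", "b", "c"))
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  expect_equal(res$p_fdr[3], res$p[3]) # singleton family unchanged
})

test_that("Wilson interval reproduces its closed form and boundary cases", {
  ci <- wilson_ci(0.05, 5000)
  expect_equal(unname(round(ci, 4)), c(0.0443, 0.0564))
  expect_equal(wilson_ci(0, 100)[["lower"]], 0)

  # independent root-solving oracle: interval ends solve
  # (p_hat - p)^2 = z^2 p (1 - p) / n
  z <- qnorm(0.975)
  roots <- sort(Re(polyroot(c(
    0.5^2, -(2 * 0.5 + z^2 / 100), 1 + z^2 / 100
  ))))
  expect_equal(unname(wilson_ci(0.5, 100)), roots, tolerance = 1e-10)
  expect_equal(unname(round(wilson_ci(0.5, 100), 3)), c(0.404, 0.596))
})

test_that("percentile stratification uses strict 30/70 cuts", {
  lab <- stratify_by_percentile(1:10)
  expect_equal(which(lab == "low"), 1:3) # 30th percentile = 3.7
  expect_equal(which(lab == "high"), 8:10) # 70th percentile = 7.3
  expect_equal(sum(lab == "unassigned"), 4)

  # invariant under monotone transforms
  expect_equal(
    stratify_by_percentile(exp(1:10)),
    stratify_by_percentile(1:10)
  )
  expect_warning(lab_eq <- stratify_by_percentile(rep(2, 12)), "degenerate")
  expect_true(all(lab_eq == "unassigned"))
  # external reference population shifts the cuts
  lab_ref <- stratify_by_percentile(1:10, reference = rep(c(0, 100), 10))
  expect_true(all(lab_ref == "unassigned"))
})

test_that("deprivation clocks render month-and-day differences", {
  d <- tibble::tibble(
    r_bag = c(rep(0.5861, 4), rep(0.1, 4)),
    stratum = rep(c("low", "high"), each = 4)
  )
  ck <- deprivation_clock(d, r_bag, stratum)
  expect_equal(ck$difference, 0.4861)
  expect_equal(ck$months_days, "5 months and 25 days")

  # identical strata: zero clock
  d0 <- dplyr::mutate(d, r_bag = 0.2)
  expect_equal(deprivation_clock(d0, r_bag, stratum)$difference, 0)

  # antisymmetry under swapping the labels
  d_swap <- dplyr::mutate(d, stratum = ifelse(stratum == "low", "high", "low"))
  expect_equal(
    deprivation_clock(d_swap, r_bag, stratum)$difference,
    -ck$difference
  )
  expect_error(
    deprivation_clock(dplyr::filter(d, stratum == "low"), r_bag, stratum),
    "non-empty"
  )
})

test_that("2x2 permutation ANOVA handles degenerate and strong-effect cases", {
  d_const <- data.frame(
    y = rep(1, 24),
    a = rep(c("x", "y"), 12), b = rep(c("u", "v"), each = 12)
  )
  pa_const <- permutation_anova_2x2(d_const, y, a, b, n_perm = 199, seed = 1)
  expect_equal(pa_const$result$p, rep(1, 3))

  set.seed(2)
  d_eff <- data.frame(
    a = rep(c("x", "y"), each = 100),
    b = rep(rep(c("u", "v"), each = 50), 2)
  )
  d_eff$y <- rnorm(200) + 10 * (d_eff$a == "y")
  pa <- permutation_anova_2x2(d_eff, y, a, b, n_perm = 999, seed = 3)
  expect_equal(pa$result$p[pa$result$effect == "factor_a"], 1 / 1000)
  expect_gt(pa$result$p[pa$result$effect == "interaction"], 0.01)

  # p-values live on the add-one lattice
  expect_true(all(pa$result$p >= 1 / 1000 & pa$result$p <= 1))

  # determinism under a repeated seed
  pa2 <- permutation_anova_2x2(d_eff, y, a, b, n_perm = 999, seed = 3)
  expect_identical(pa$result, pa2$result)

  d_hole <- d_eff[!(d_eff$a == "y" & d_eff$b == "v"), ]
  expect_error(
    permutation_anova_2x2(d_hole, y, a, b, n_perm = 199),
    "non-empty"
  )
  expect_warning(
    permutation_anova_2x2(d_eff, y, a, b, n_perm = 99, seed = 1),
    "resolution"
  )
  gl <- generics::glance(pa)
  expect_equal(gl$n_perm, 999)
  expect_equal(gl$n, 200)
})

test_that("Freedman-Lane with intercept nuisance equals exhaustive label permutation", {
  set.seed(6)
  y <- c(rnorm(3), rnorm(3, 2))
  g <- rep(c(0, 1), each = 3)

  # exhaustive: all 6! orderings fed through the same machinery
  perms <- do.call(rbind, combinat_perms(6))
  fl <- freedman_lane(y, target = g, perms = perms)

  # oracle: enumerate the 20 distinct assignments, score with anova()
  f_of <- function(lab) {
    fit <- lm(y ~ lab)
    anova(fit)["lab", "F value"]
  }
  assigns <- utils::combn(6, 3)
  f_enum <- apply(assigns, 2, function(ix) {
    lab <- rep(0, 6)
    lab[ix] <- 1
    f_of(factor(lab))
  })
  p_oracle <- mean(f_enum >= f_of(factor(g)) - 1e-12)
  # identical up to the add-one convention in the permutation p-value
  expect_lt(abs(fl$p - p_oracle), 0.005)
})

test_that("permutation p-values are valid under a simulated null", {
  set.seed(44)
  n_rep <- 150
  pvals <- replicate(n_rep, {
    d <- data.frame(
      y = rnorm(24),
      a = rep(c("x", "y"), 12), b = rep(c("u", "v"), each = 12)
    )
    permutation_anova_2x2(d, y, a, b,
      n_perm = 199,
      seed = sample.int(1e6, 1)
    )$result$p[3]
  })
  for (alpha in c(0.05, 0.1)) {
    band <- wilson_ci(alpha, n_rep)
    expect_lt(mean(pvals <= alpha), band[["upper"]] + 0.03)
  }
})
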