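# Small configurations used across tests: fast to generate and fit, with
# enough structure for the model to have signal where a test needs it.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_train = 300, n_longitudinal = 120, n_idps = 60,
      n_signal_components = 5, n_trait_components = 15,
      n_confounds = 5, seed = 42
    ),
    list(...)
  )
  do.call(simulation_config, args)
}

# longitudinal records joined with ground truth, after the standard >= 2y
# interval filter, predicted with per-sex models trained on `cfg`'s cohort
recover_rbag <- function(cfg, k = 20, deattenuate = FALSE) {
  tr <- generate_training_cohort(cfg)
  lon <- generate_longitudinal_cohort(cfg)
  pred <- dplyr::bind_rows(lapply(c("F", "M"), function(s) {
    m <- fit_brain_age_model(dplyr::filter(tr, sex == s), k = k)
    predict(m, dplyr::filter(lon$cohort, sex == s), deattenuate = deattenuate)
  }))
  compute_rbag(pred) |>
    dplyr::inner_join(
      dplyr::select(
        lon$truth, "participant_id", "pandemic", "deprived",
        "r_bag_true", "isi"
      ),
      by = "participant_id"
    ) |>
    dplyr::filter(isi >= 2)
}

# exact two-sided Mann-Whitney p by enumerating every group assignment
mw_exact_enum <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  n <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  us <- apply(utils::combn(n, n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  # two-sided: assignments at least as extreme (|U - mean| >= observed)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# all permutations of 1..n as a list of integer vectors (n small)
combinat_perms <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  smaller <- combinat_perms(n - 1)
  out <- vector("list", n * length(smaller))
  i <- 0L
  for (p in smaller) {
    for (pos in 0:(n - 1)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

# Benjamini-Hochberg step-up written directly from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- running_min
  }
  pmin(adj, 1)
}
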