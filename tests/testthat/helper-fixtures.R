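# Shared in-code fixtures for the test suite.

# A deterministic binary-outcome table built from arm-level counts.
counts_table <- function(ctl_no, ctl_yes, int_no, int_yes,
                         n_compliers_yes = NULL, n_compliers_no = NULL) {
  n_ctl <- ctl_no + ctl_yes
  n_int <- int_no + int_yes
  tab <- tibble::tibble(
    trial_id = "fix",
    participant_id = sprintf("p%04d", seq_len(n_ctl + n_int)),
    arm = rep(c("control", "intervention"), c(n_ctl, n_int)),
    baseline = 30,
    followup = NA_real_,
    responder = c(rep(0L, ctl_no), rep(1L, ctl_yes),
                  rep(0L, int_no), rep(1L, int_yes)),
    adhered = NA_integer_
  )
  tab$adhered[tab$arm == "intervention"] <- 1L
  tab
}

# Intervention arm with an explicit complier / never-taker split:
# counts are (responders, non-responders) within each stratum.
mixture_table <- function(ctl_yes, ctl_no,
                          comp_yes, comp_no, never_yes, never_no) {
  n <- ctl_yes + ctl_no + comp_yes + comp_no + never_yes + never_no
  tab <- tibble::tibble(
    trial_id = "mix",
    participant_id = sprintf("p%05d", seq_len(n)),
    arm = rep(c("control", "intervention"),
              c(ctl_yes + ctl_no, comp_yes + comp_no + never_yes + never_no)),
    baseline = 30, followup = NA_real_,
    responder = c(rep(1L, ctl_yes), rep(0L, ctl_no),
                  rep(1L, comp_yes), rep(0L, comp_no),
                  rep(1L, never_yes), rep(0L, never_no)),
    adhered = c(rep(NA_integer_, ctl_yes + ctl_no),
                rep(1L, comp_yes + comp_no),
                rep(0L, never_yes + never_no))
  )
  tab
}

# Restricted log-likelihood of the random-effects model, for grid oracles.
reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

# Independent tau2 oracle: coarse grid bracket + golden-section refinement.
grid_reml_tau2 <- function(yi, vi, upper = NULL) {
  if (is.null(upper)) upper <- max(10 * var(yi), 1)
  grid <- seq(0, upper, length.out = 200)
  ll <- vapply(grid, reml_loglik, numeric(1), yi = yi, vi = vi)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (i == 1 && ll[1] >= ll[2]) {
    # check the boundary against a refined interior search
    opt <- optimize(reml_loglik, c(0, grid[2]), yi = yi, vi = vi,
                    maximum = TRUE, tol = 1e-12)
    return(if (reml_loglik(0, yi, vi) >= opt$objective) 0 else opt$maximum)
  }
  optimize(reml_loglik, c(lo, hi), yi = yi, vi = vi,
           maximum = TRUE, tol = 1e-12)$maximum
}

# A small two-trial collaboration used by pipeline tests.
tiny_collab <- function(seed = 11) {
  simulate_collaboration(list(
    trial_config("T1", n_per_arm = 120, compliance_prob = 0.7,
                 cace_effect = -5, seed = seed),
    trial_config("T2", n_per_arm = 120, compliance_prob = 0.85,
                 cace_effect = -3, scale = "PHQ9", baseline_mean = 15,
                 baseline_sd = 5, control_change_mean = -4,
                 residual_sd = 5, seed = seed + 1)
  ))
}
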