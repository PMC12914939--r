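toy_exact <- tibble::tibble(
  trial_id = "toy",
  participant_id = paste0("p", 1:4),
  arm = c("control", "control", "intervention", "intervention"),
  baseline = c(30, 20, 30, 20),
  followup = c(25, 15, 23, 13),
  adhered = c(NA, NA, 1L, 1L)
)

test_that("the continuous ITT fit recovers an exact two-point contrast", {
  rec <- suppressWarnings(fit_itt_continuous(toy_exact))  # perfect-fit lm
  expect_equal(rec$estimate, -2, tolerance = 1e-10)
  expect_lt(rec$se, 1e-8)  # perfect fit, zero residual
  expect_identical(rec$n_analysed, 4L)
})

test_that("estimation errors are informative", {
  empty_arm <- toy_exact[toy_exact$arm == "control", ]
  expect_error(fit_itt_continuous(empty_arm), "per arm")
  col <- toy_exact
  col$dup <- col$baseline
  expect_error(fit_itt_continuous(col, c("baseline", "dup")), "collinear")
  sep <- toy_exact
  sep$responder <- c(0L, 0L, 1L, 1L)
  expect_error(fit_itt_binary(sep, character()), "separation")
})

test_that("the unadjusted binary ITT equals the 2x2 cross-product", {
  # COBALT-like counts: control 167 non-responders / 46 responders,
  # intervention 111 / 95
  tab <- counts_table(167, 46, 111, 95)
  rec <- fit_itt_binary(tab, covariate_names = character())
  expect_equal(exp(rec$estimate), (95 * 167) / (46 * 111), tolerance = 1e-8)
  balanced <- counts_table(100, 50, 100, 50)
  expect_equal(exp(fit_itt_binary(balanced, character())$estimate), 1,
               tolerance = 1e-8)
})

test_that("the per-protocol restriction keeps controls and adherers only", {
  sim <- simulate_trial(trial_config("pp", n_per_arm = 234,
                                     compliance_prob = 144 / 234, seed = 10))
  pp <- make_pp_table(sim$ipd)
  expect_identical(sum(pp$arm == "control"), sum(sim$ipd$arm == "control"))
  expect_true(all(pp$adhered[pp$arm == "intervention"] == 1))
  n_adh <- sum(sim$ipd$adhered == 1, na.rm = TRUE)
  expect_identical(sum(pp$arm == "intervention"), n_adh)
  # missing adherence rows are unclassifiable and dropped
  miss <- apply_missingness(sim$ipd, 0, 0.3, seed = 2)
  pp2 <- make_pp_table(miss)
  expect_true(all(!is.na(pp2$adhered[pp2$arm == "intervention"])))
  all_na <- sim$ipd
  all_na$adhered[all_na$arm == "intervention"] <- NA_integer_
  expect_error(make_pp_table(all_na), "entirely missing")
})

test_that("2SLS satisfies the Wald identity and collapses under full compliance", {
  sim <- simulate_trial(trial_config("w", n_per_arm = 400,
                                     compliance_prob = 0.65,
                                     cace_effect = -5, seed = 21))
  itt <- fit_itt_continuous(sim$ipd, character())
  cace <- fit_cace_continuous(sim$ipd, character())
  pihat <- compliance_rate(sim$ipd)
  expect_equal(cace$estimate, itt$estimate / pihat, tolerance = 1e-10)
  # full compliance: instrument equals exposure, all three estimands agree
  full <- simulate_trial(trial_config("fc", n_per_arm = 300,
                                      compliance_prob = 1, cace_effect = -5,
                                      seed = 22))$ipd
  itt_f <- fit_itt_continuous(full)
  expect_equal(fit_cace_continuous(full)$estimate, itt_f$estimate,
               tolerance = 1e-8)
  expect_equal(fit_pp_continuous(full)$estimate, itt_f$estimate,
               tolerance = 1e-10)
  # no compliers at all: the instrument carries no information
  none <- full
  none$adhered[none$arm == "intervention"] <- 0L
  expect_error(fit_cace_continuous(none), "instrument")
})

test_that("binary CACE matches the closed-form mixture moments", {
  # control responds at 0.34; never-takers at 0.20; 60% compliers:
  # complier control rate = (0.34 - 0.4 * 0.20) / 0.6 = 0.43333
  tab <- mixture_table(ctl_yes = 1700, ctl_no = 3300,
                       comp_yes = 1500, comp_no = 1500,
                       never_yes = 400, never_no = 1600)
  rec <- fit_cace_binary(tab, n_bootstrap = 59, seed = 1)
  p_c0 <- (0.34 - 0.4 * 0.20) / 0.6
  expect_equal(p_c0, 0.43333, tolerance = 1e-4)
  expect_equal(rec$estimate, qlogis(0.5) - qlogis(p_c0), tolerance = 1e-10)
  expect_equal(rec$compliance_rate, 0.6, tolerance = 1e-10)
})

test_that("binary CACE point estimate maximises the joint mixture likelihood", {
  sim <- simulate_trial(trial_config("ml", n_per_arm = 2000,
                                     compliance_prob = 0.7, cace_effect = -6,
                                     seed = 31))
  rec <- fit_cace_binary(sim$ipd, n_bootstrap = 19, seed = 1)
  df <- sim$ipd[!is.na(sim$ipd$responder), ]
  int <- df$arm == "intervention"
  y_c1 <- df$responder[int & df$adhered == 1]
  y_n <- df$responder[int & df$adhered == 0]
  y_0 <- df$responder[df$arm == "control"]
  n_int <- sum(int)
  nll <- function(par) {
    pi_c <- plogis(par[1]); p_c1 <- plogis(par[2])
    p_n <- plogis(par[3]); p_c0 <- plogis(par[4])
    p_mix <- pi_c * p_c0 + (1 - pi_c) * p_n
    -(sum(dbinom(y_c1, 1, p_c1, log = TRUE)) +
      sum(dbinom(y_n, 1, p_n, log = TRUE)) +
      sum(dbinom(y_0, 1, p_mix, log = TRUE)) +
      length(y_c1) * log(pi_c) + length(y_n) * log(1 - pi_c))
  }
  opt <- optim(rep(0, 4), nll, method = "BFGS")
  ml_log_or <- opt$par[2] - opt$par[4]
  expect_equal(rec$estimate, ml_log_or, tolerance = 1e-3)
  # recovered probabilities agree with the numeric ML to < 1e-3
  expect_equal(plogis(opt$par[1]), rec$compliance_rate, tolerance = 1e-3)
})

test_that("full compliance reduces the binary CACE to the ITT odds ratio", {
  sim <- simulate_trial(trial_config("fb", n_per_arm = 600,
                                     compliance_prob = 1, cace_effect = -6,
                                     seed = 33))
  rec <- fit_cace_binary(sim$ipd, n_bootstrap = 19, seed = 1)
  itt <- fit_itt_binary(sim$ipd, character())
  expect_equal(rec$estimate, itt$estimate, tolerance = 1e-8)
})

test_that("Hedges' g applies the small-sample correction and scaling", {
  # published COBALT regime: B = -5.68, follow-up SDs 13 / 14, ns 213 / 206
  sd_pool <- sqrt((212 * 13^2 + 205 * 14^2) / 417)
  hg <- hedges_g(-5.68, sd_pool, 213, 206)
  expect_equal(hg$g, -0.42, tolerance = 0.005)
  expect_equal(hedges_g(0, 10, 50, 50)$g, 0)
  expect_equal(hedges_g(1, 1, 2, 2)$J, 1 - 3 / 7, tolerance = 1e-12)
  expect_error(hedges_g(1, 0, 10, 10), "positive")
  hg_se <- hedges_g(-5.68, sd_pool, 213, 206, se_B = 1.158)
  expect_equal(hg_se$se_g, hg_se$J * 1.158 / sd_pool, tolerance = 1e-12)
})

test_that("compliance summaries reproduce the published percentages", {
  t1 <- depgp_table1()$trials
  per_trial <- round(100 * t1$compliers_n /
                     (t1$n_intervention - t1$missing_adherence_n))
  expect_identical(as.integer(per_trial), c(62L, 80L, 72L, 61L, 72L, 94L, 57L))
  overall <- depgp_overall_rates()
  expect_equal(overall$adherence_pct, 100 * 1186 / (1733 - 104),
               tolerance = 1e-10)
  sim <- simulate_trial(trial_config("cr", n_per_arm = 50,
                                     compliance_prob = 1, seed = 3))
  expect_identical(compliance_rate(sim$ipd), 1)
})

test_that("within-trial standardisation yields unit-variance columns", {
  cc <- tiny_collab()
  z <- standardise_within_trial(cc$ipd)
  for (id in unique(z$trial_id)) {
    f <- z$followup_z[z$trial_id == id]
    expect_equal(mean(f, na.rm = TRUE), 0, tolerance = 1e-12)
    expect_equal(sd(f, na.rm = TRUE), 1, tolerance = 1e-12)
  }
  # scale-free: multiplying one trial's raw scores leaves z unchanged
  scaled <- cc$ipd
  idx <- scaled$trial_id == "T1"
  scaled$followup[idx] <- scaled$followup[idx] * 7
  scaled$baseline[idx] <- scaled$baseline[idx] * 7
  z2 <- standardise_within_trial(scaled)
  expect_equal(z2$followup_z, z$followup_z, tolerance = 1e-12)
  const <- cc$ipd
  const$followup <- 5
  expect_error(standardise_within_trial(const), "zero variance")
})

test_that("stage-one estimation covers every trial, method and scale", {
  cc <- tiny_collab()
  est <- estimate_all(cc$ipd, n_bootstrap = 29, seed = 5)
  expect_identical(nrow(est), 2L * 9L)  # 2 trials x 3 methods x 3 scales
  expect_setequal(unique(est$scale),
                  c("raw_mean_diff", "smd_g", "log_odds_ratio"))
  expect_true(all(est$se > 0))
  expect_true(all(est$ci_low <= est$estimate & est$estimate <= est$ci_high))
})
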