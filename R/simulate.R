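#' Score ranges of the supported symptom scales
#'
#' @format Named list with `min` and `max` per scale.
#' @keywords internal
.scale_ranges <- list(
  BDI  = c(min = 0, max = 63),
  PHQ9 = c(min = 0, max = 27)
)

#' Configure one synthetic two-arm trial
#'
#' Builds a validated configuration for [simulate_trial()]. The generator
#' emulates a primary-care depression trial with one-sided non-adherence:
#' control participants can never access the intervention, so the population
#' contains only compliers and never-takers (monotonicity holds by design,
#' there are no always-takers).
#'
#' @param trial_id Character label, unique within a collaboration.
#' @param n_control,n_intervention Arm sizes (each >= 2). `n_per_arm` is a
#'   shorthand setting both.
#' @param n_per_arm Optional common arm size.
#' @param compliance_prob Probability that an intervention-arm participant
#'   belongs to the complier stratum.
#' @param scale `"BDI"` (0-63) or `"PHQ9"` (0-27).
#' @param baseline_mean,baseline_sd Baseline score distribution (score units),
#'   clamped and rounded to the scale range.
#' @param control_change_mean Expected change from baseline under control
#'   (negative = improvement).
#' @param cace_effect True effect of treatment receipt among compliers
#'   (score units, negative = improvement). This is the estimand the CACE
#'   analysis targets.
#' @param never_taker_assignment_effect Effect of assignment on never-takers;
#'   0 (default) means the exclusion restriction holds.
#' @param confounding_strength Loading of a latent prognosis variable on both
#'   complier membership and follow-up score; 0 (default) makes the
#'   per-protocol contrast unbiased, positive values give compliers a better
#'   prognosis so PP overstates benefit.
#' @param baseline_followup_cor Within-arm correlation between baseline and
#'   follow-up score (default 0.5).
#' @param residual_sd Residual SD of the follow-up score (score units).
#' @param responder_rule Dichotomisation rule, see [dichotomise()].
#' @param missing_outcome_prob,missing_adherence_prob Missingness
#'   probabilities (MCAR); adherence missingness only applies to the
#'   intervention arm.
#' @param strat_factors Named list of character vectors: categorical
#'   stratification covariates and their levels, sampled uniformly.
#' @param seed Integer seed; the seed fully determines the generated table.
#' @return An object of class `trial_config`.
#' @examples
#' cfg <- trial_config("toy", n_per_arm = 50, compliance_prob = 0.7,
#'                     cace_effect = -4, seed = 1)
#' @export
trial_config <- function(trial_id,
                         n_control = NULL, n_intervention = NULL,
                         n_per_arm = NULL,
                         compliance_prob = 0.75,
                         scale = c("BDI", "PHQ9"),
                         baseline_mean = 32, baseline_sd = 10,
                         control_change_mean = -10,
                         cace_effect = -4,
                         never_taker_assignment_effect = 0,
                         confounding_strength = 0,
                         baseline_followup_cor = 0.5,
                         residual_sd = 10,
                         responder_rule = c("half_reduction", "below10",
                                            "below10_and_minus5"),
                         missing_outcome_prob = 0,
                         missing_adherence_prob = 0,
                         strat_factors = list(),
                         seed = 1L) {
  scale <- match.arg(scale)
  responder_rule <- match.arg(responder_rule)
  if (!is.null(n_per_arm)) {
    n_control <- n_intervention <- n_per_arm
  }
  if (is.null(n_control) || is.null(n_intervention)) {
    stop("trial_config: supply either `n_per_arm` or both `n_control` and `n_intervention`")
  }
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 2 || x != round(x)) {
      stop(sprintf("trial_config: `%s` must be an integer >= 2", nm))
    }
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("trial_config: `%s` must be a probability in [0, 1]", nm))
    }
  }
  chk_count(n_control, "n_control"); chk_count(n_intervention, "n_intervention")
  chk_prob(compliance_prob, "compliance_prob")
  chk_prob(missing_outcome_prob, "missing_outcome_prob")
  chk_prob(missing_adherence_prob, "missing_adherence_prob")
  if (!is.numeric(residual_sd) || residual_sd <= 0) {
    stop("trial_config: `residual_sd` must be positive")
  }
  if (abs(baseline_followup_cor) > 1) {
    stop("trial_config: `baseline_followup_cor` must lie in [-1, 1]")
  }
  if (length(strat_factors) &&
      (is.null(names(strat_factors)) || any(names(strat_factors) == ""))) {
    stop("trial_config: `strat_factors` must be a named list")
  }
  structure(list(
    trial_id = as.character(trial_id),
    n_control = as.integer(n_control),
    n_intervention = as.integer(n_intervention),
    compliance_prob = compliance_prob,
    scale = scale,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    control_change_mean = control_change_mean,
    cace_effect = cace_effect,
    never_taker_assignment_effect = never_taker_assignment_effect,
    confounding_strength = confounding_strength,
    baseline_followup_cor = baseline_followup_cor,
    residual_sd = residual_sd,
    responder_rule = responder_rule,
    missing_outcome_prob = missing_outcome_prob,
    missing_adherence_prob = missing_adherence_prob,
    strat_factors = strat_factors,
    seed = as.integer(seed)
  ), class = "trial_config")
}

# Intercept of the complier-membership logit such that the marginal complier
# fraction equals pi_c when membership is plogis(alpha + lambda * U), U ~ N(0,1).
.complier_intercept <- function(pi_c, lambda) {
  if (pi_c <= 0) return(-Inf)
  if (pi_c >= 1) return(Inf)
  if (abs(lambda) < 1e-12) return(qlogis(pi_c))
  f <- function(a) {
    integrate(function(u) plogis(a + lambda * u) * exp(-u^2 / 2) / sqrt(2 * pi),
              -8, 8, rel.tol = 1e-10)$value - pi_c
  }
  uniroot(f, c(-20, 20), tol = 1e-10)$root
}

# E[U | complier] under the same membership model (standard normal prognosis).
.complier_mean_prognosis <- function(pi_c, lambda) {
  if (abs(lambda) < 1e-12 || pi_c <= 0 || pi_c >= 1) return(0)
  a <- .complier_intercept(pi_c, lambda)
  num <- integrate(function(u) u * plogis(a + lambda * u) * exp(-u^2 / 2) / sqrt(2 * pi),
                   -8, 8, rel.tol = 1e-10)$value
  num / pi_c
}

.clamp_score <- function(x, scale) {
  rng <- .scale_ranges[[scale]]
  pmin(pmax(round(x), rng[["min"]]), rng[["max"]])
}

#' Simulate one trial with principal-stratum non-adherence
#'
#' Generates individual participant data for a two-arm trial. Every
#' participant has a latent stratum (complier / never-taker) and a latent
#' standard-normal prognosis variable; with positive `confounding_strength`
#' compliers have systematically better prognosis (lower follow-up scores),
#' which biases the per-protocol contrast while leaving the IV CACE
#' estimator consistent. Follow-up scores are baseline-anchored Gaussian,
#' then rounded and clamped to the scale range. Adherence is observed only
#' in the intervention arm; control participants never receive the
#' intervention.
#'
#' The returned table carries a hidden `.stratum` column (and `.prognosis`)
#' for validation; [write_ipd()] strips them from the analysis CSV and
#' writes them to a sidecar so estimators cannot use them.
#'
#' @param config A [trial_config()].
#' @return A list with elements `ipd` (tibble, one row per participant) and
#'   `truth` (one-row tibble: `trial_id`, `true_cace`, `true_itt`,
#'   `true_pp_bias`, `pi_c`).
#' @examples
#' sim <- simulate_trial(trial_config("toy", n_per_arm = 100, seed = 7))
#' head(sim$ipd)
#' sim$truth
#' @export
simulate_trial <- function(config) {
  if (!inherits(config, "trial_config")) {
    stop("simulate_trial: `config` must be built by trial_config()")
  }
  cf <- config
  n <- cf$n_control + cf$n_intervention
  rng <- .scale_ranges[[cf$scale]]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cf$seed)

  arm <- rep(c("control", "intervention"), c(cf$n_control, cf$n_intervention))
  lambda <- 2 * cf$confounding_strength
  alpha <- .complier_intercept(cf$compliance_prob, lambda)
  prognosis <- rnorm(n)
  stratum <- ifelse(runif(n) < plogis(alpha + lambda * prognosis),
                    "complier", "never_taker")

  baseline_raw <- rnorm(n, cf$baseline_mean, cf$baseline_sd)
  baseline <- .clamp_score(baseline_raw, cf$scale)

  received <- arm == "intervention" & stratum == "complier"
  assigned_nt <- arm == "intervention" & stratum == "never_taker"

  conf_load <- cf$confounding_strength * cf$residual_sd
  mu_fup <- cf$baseline_mean + cf$control_change_mean +
    cf$baseline_followup_cor * (baseline - cf$baseline_mean) +
    received * cf$cace_effect +
    assigned_nt * cf$never_taker_assignment_effect -
    conf_load * prognosis
  followup <- .clamp_score(rnorm(n, mu_fup, cf$residual_sd), cf$scale)

  adhered <- rep(NA_integer_, n)
  adhered[arm == "intervention"] <-
    as.integer(stratum[arm == "intervention"] == "complier")

  covs <- lapply(cf$strat_factors, function(lv) sample(lv, n, replace = TRUE))

  ipd <- tibble::tibble(
    trial_id = cf$trial_id,
    participant_id = sprintf("%s_%04d", cf$trial_id, seq_len(n)),
    arm = arm,
    baseline = as.numeric(baseline),
    followup = as.numeric(followup),
    adhered = adhered
  )
  for (nm in names(covs)) ipd[[nm]] <- covs[[nm]]
  ipd$.stratum <- stratum
  ipd$.prognosis <- prognosis

  ipd <- dichotomise(ipd, cf$responder_rule)
  ipd <- apply_missingness(ipd, cf$missing_outcome_prob,
                           cf$missing_adherence_prob,
                           seed = cf$seed + 1L)

  eu_c <- .complier_mean_prognosis(cf$compliance_prob, lambda)
  truth <- tibble::tibble(
    trial_id = cf$trial_id,
    true_cace = cf$cace_effect,
    true_itt = cf$compliance_prob * cf$cace_effect +
      (1 - cf$compliance_prob) * cf$never_taker_assignment_effect,
    # PP compares intervention compliers with the whole control arm; the
    # selection term is the prognosis gap between compliers and everyone.
    true_pp_bias = -conf_load * eu_c,
    pi_c = cf$compliance_prob
  )
  list(ipd = ipd, truth = truth)
}

# Save/restore the global RNG state so simulate_* are seed-local.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a multi-trial collaboration
#'
#' @param configs List of [trial_config()] objects with distinct `trial_id`s.
#' @return A list with `ipd` (stacked tibble) and `truth` (one row per trial).
#' @examples
#' cc <- simulate_collaboration(list(
#'   trial_config("A", n_per_arm = 30, seed = 1),
#'   trial_config("B", n_per_arm = 30, seed = 2)))
#' table(cc$ipd$trial_id)
#' @export
simulate_collaboration <- function(configs) {
  if (!length(configs)) stop("simulate_collaboration: need at least one config")
  ids <- vapply(configs, function(cf) cf$trial_id, character(1))
  if (anyDuplicated(ids)) {
    stop("simulate_collaboration: duplicate trial_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sims <- lapply(configs, simulate_trial)
  list(
    ipd = dplyr::bind_rows(lapply(sims, `[[`, "ipd")),
    truth = dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  )
}

#' Dichotomise a continuous follow-up score into treatment response
#'
#' Applies a trial-specific responder definition: `half_reduction` (>= 50%
#' reduction from baseline), `below10` (follow-up score < 10 regardless of
#' baseline), or `below10_and_minus5` (follow-up < 10 *and* a reduction of
#' >= 5 points from baseline). Missing follow-up yields a missing responder
#' flag.
#'
#' @param table An IPD tibble with `baseline` and `followup` columns.
#' @param rule Rule name.
#' @return The table with a `responder` column in \{0, 1, NA\}.
#' @examples
#' df <- tibble::tibble(baseline = c(30, 30), followup = c(15, 16))
#' dichotomise(df, "half_reduction")$responder
#' @export
dichotomise <- function(table, rule = c("half_reduction", "below10",
                                        "below10_and_minus5")) {
  rule <- match.arg(rule)
  if (!all(c("baseline", "followup") %in% names(table))) {
    stop("dichotomise: table must contain `baseline` and `followup`")
  }
  b <- table$baseline; f <- table$followup
  resp <- switch(rule,
    half_reduction = as.integer((b - f) >= 0.5 * b),
    below10 = as.integer(f < 10),
    below10_and_minus5 = as.integer(f < 10 & (b - f) >= 5)
  )
  resp[is.na(f)] <- NA_integer_
  table$responder <- resp
  table
}

#' Impose missing-completely-at-random missingness
#'
#' Follow-up scores (and the responder flag derived from them) are set to
#' missing with probability `outcome_prob`; adherence flags are set to
#' missing with probability `adherence_prob`, in the intervention arm only
#' (control-arm adherence is undefined by design).
#'
#' @param table IPD tibble.
#' @param outcome_prob,adherence_prob Probabilities in [0, 1].
#' @param seed Integer seed.
#' @return The table with missingness applied.
#' @export
apply_missingness <- function(table, outcome_prob = 0, adherence_prob = 0,
                              seed = 1L) {
  for (p in c(outcome_prob, adherence_prob)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("apply_missingness: probabilities must lie in [0, 1]")
    }
  }
  if (outcome_prob == 0 && adherence_prob == 0) return(table)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(table)
  if (outcome_prob > 0) {
    drop <- runif(n) < outcome_prob
    table$followup[drop] <- NA_real_
    if ("responder" %in% names(table)) table$responder[drop] <- NA_integer_
  }
  if (adherence_prob > 0) {
    drop_a <- runif(n) < adherence_prob & table$arm == "intervention"
    table$adhered[drop_a] <- NA_integer_
  }
  table
}

#' Default seven-trial scenario emulating the Dep-GP collaboration
#'
#' Builds trial configurations matching the published structure of the seven
#' Dep-GP primary-care depression trials: arm sizes, complier fractions,
#' outcome scales, baseline means/SDs, control-arm change, per-trial
#' responder rules, follow-up retention, and missing-adherence rates, with
#' the true complier effect set to the published per-trial CACE point
#' estimate on the score scale.
#'
#' @param seed Base seed; trial `i` uses `seed + i`.
#' @param confounding_strength Shared confounding knob (default 0.3, a
#'   moderate complier-prognosis association).
#' @return List of [trial_config()] objects.
#' @examples
#' cc <- simulate_collaboration(depgp_scenario(seed = 1))
#' nrow(cc$ipd)  # 3467 participants across seven trials
#' @export
depgp_scenario <- function(seed = 20260101L, confounding_strength = 0.3) {
  tr <- depgp_table1()$trials
  eff <- depgp_table1()$effects
  cace <- eff[eff$outcome == "continuous" & eff$method == "CACE", ]
  cace <- setNames(cace$estimate, cace$trial)
  lapply(seq_len(nrow(tr)), function(i) {
    r <- tr[i, ]
    trial_config(
      trial_id = r$trial,
      n_control = r$n_control, n_intervention = r$n_intervention,
      compliance_prob = r$compliers_n /
        (r$n_intervention - r$missing_adherence_n),
      scale = if (r$outcome_scale == "PHQ9") "PHQ9" else "BDI",
      baseline_mean = (r$baseline_mean_control + r$baseline_mean_intervention) / 2,
      baseline_sd = (r$baseline_sd_control + r$baseline_sd_intervention) / 2,
      control_change_mean = r$fup_mean_control - r$baseline_mean_control,
      cace_effect = unname(cace[r$trial]),
      confounding_strength = confounding_strength,
      residual_sd = r$fup_sd_control * sqrt(1 - 0.5^2),
      responder_rule = r$responder_rule,
      missing_outcome_prob =
        1 - (r$n_fup_control + r$n_fup_intervention) /
            (r$n_control + r$n_intervention),
      missing_adherence_prob = r$missing_adherence_n / r$n_intervention,
      seed = seed + i
    )
  })
}
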