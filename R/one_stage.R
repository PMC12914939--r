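#' Specify a one-stage analysis
#'
#' @param outcome_scale `"z_continuous"` (within-trial standardised score)
#'   or `"binary"`.
#' @param method `"ITT"`, `"PP"` or `"CACE"`.
#' @param random_effects `"intercept_plus_treatment"` (default) or
#'   `"intercept_only"`.
#' @return List of class `one_stage_spec`.
#' @export
one_stage_spec <- function(outcome_scale = c("z_continuous", "binary"),
                           method = c("ITT", "PP", "CACE"),
                           random_effects = c("intercept_plus_treatment",
                                              "intercept_only")) {
  structure(list(outcome_scale = match.arg(outcome_scale),
                 method = match.arg(method),
                 random_effects = match.arg(random_effects)),
            class = "one_stage_spec")
}

.prep_one_stage <- function(ipd, spec) {
  if (length(unique(ipd$trial_id)) < 2) {
    stop("one-stage analysis needs >= 2 trials")
  }
  # standardise on the full trial populations, then restrict
  if (spec$outcome_scale == "z_continuous" && !"followup_z" %in% names(ipd)) {
    ipd <- standardise_within_trial(ipd)
  }
  if (spec$method == "PP") ipd <- make_pp_table(ipd)
  ipd$arm <- factor(ipd$arm, levels = c("control", "intervention"))
  ipd
}

.lmm_pooled <- function(fit, term) {
  b <- lme4::fixef(fit)[[term]]
  se <- sqrt(as.matrix(vcov(fit))[term, term])
  z <- qnorm(0.975)
  out <- list(mu = b, se = se, ci_low = b - z * se, ci_high = b + z * se,
              p = 2 * pnorm(-abs(b / se)), tau2 = NA_real_, i2 = NA_real_,
              q = NA_real_, q_p = NA_real_,
              k = length(unique(lme4::getME(fit, "flist")[[1]])))
  class(out) <- "pooled_estimate"
  out
}

#' One-stage random-effects IPD analysis
#'
#' Fits a single hierarchical model to the stacked participant data:
#' a linear mixed model of the within-trial standardised follow-up score
#' (adjusted for standardised baseline) or a logistic mixed model of
#' treatment response (adjusted for baseline), with a random trial
#' intercept and, by default, a random treatment effect. A singular
#' random-slope fit falls back to the intercept-only structure with a
#' recorded downgrade. The CACE variant replaces the mixed model with
#' stacked two-stage least squares: trial fixed effects, randomisation
#' instrumenting receipt, and a trial-cluster-robust sandwich variance.
#'
#' @param ipd Multi-trial IPD tibble (>= 2 trials).
#' @param spec A [one_stage_spec()].
#' @return A `pooled_estimate` (the fixed treatment effect); attribute
#'   `"downgraded"` is `TRUE` when the random-slope fit was singular and
#'   the intercept-only model was used, and attribute `"ranef_sd"` carries
#'   the estimated random-effect SDs.
#' @export
fit_one_stage <- function(ipd, spec = one_stage_spec()) {
  ipd <- .prep_one_stage(ipd, spec)
  if (spec$method == "CACE") return(.one_stage_cace(ipd, spec))
  re <- spec$random_effects
  downgraded <- FALSE
  ipd$treat <- as.numeric(ipd$arm == "intervention")
  fit_with <- function(re_term) {
    if (spec$outcome_scale == "z_continuous") {
      fm <- as.formula(paste("followup_z ~ baseline_z + treat +", re_term))
      lme4::lmer(fm, data = ipd[!is.na(ipd$followup_z), ], REML = TRUE)
    } else {
      fm <- as.formula(paste("responder ~ baseline + treat +", re_term))
      lme4::glmer(fm, data = ipd[!is.na(ipd$responder), ], family = binomial())
    }
  }
  slope_sd <- function(f) {
    vc <- as.data.frame(lme4::VarCorr(f))
    max(c(0, vc$sdcor[!is.na(vc$var1) & vc$var1 == "treat"]))
  }
  fit <- if (re == "intercept_plus_treatment") {
    # uncorrelated intercept and slope: standardised outcomes often leave no
    # between-trial intercept variance, which must not force the downgrade
    f <- suppressMessages(suppressWarnings(fit_with("(1 + treat || trial_id)")))
    if (lme4::isSingular(f, tol = 1e-4) && slope_sd(f) < 1e-4) {
      downgraded <- TRUE
      suppressMessages(suppressWarnings(fit_with("(1 | trial_id)")))
    } else f
  } else {
    suppressMessages(suppressWarnings(fit_with("(1 | trial_id)")))
  }
  out <- .lmm_pooled(fit, "treat")
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(out, "ranef_sd") <- setNames(vc$sdcor, paste(vc$grp, vc$var1, vc$var2))
  attr(out, "downgraded") <- downgraded
  out
}

# Stacked 2SLS with trial fixed effects; cluster-robust (trial) sandwich.
.one_stage_cace <- function(ipd, spec) {
  if (spec$outcome_scale == "binary") return(.one_stage_cace_binary(ipd))
  df <- as.data.frame(ipd[!is.na(ipd$followup_z), ])
  df <- .receipt_frame(df, "drop")
  z <- as.numeric(df$arm == "intervention")
  Xex <- model.matrix(~ baseline_z + factor(trial_id), df)
  iv <- .tsls(df$followup_z, df$received, z, Xex)
  V <- .cluster_vcov_tsls(iv, df$followup_z, df$received, z, Xex,
                          cluster = df$trial_id)
  b <- iv$beta; se <- sqrt(V[1, 1]); zq <- qnorm(0.975)
  out <- list(mu = b, se = se, ci_low = b - zq * se, ci_high = b + zq * se,
              p = 2 * pnorm(-abs(b / se)), tau2 = NA_real_, i2 = NA_real_,
              q = NA_real_, q_p = NA_real_,
              k = length(unique(df$trial_id)))
  class(out) <- "pooled_estimate"
  out
}

.cluster_vcov_tsls <- function(iv, y, endog, instr, exog, cluster) {
  W <- cbind(endog = endog, exog)
  Z <- cbind(instr = instr, exog)
  Zi <- solve(crossprod(Z, W))
  e <- iv$residuals
  Ze <- rowsum(Z * e, group = cluster)      # cluster score sums
  meat <- crossprod(Ze)
  Zi %*% meat %*% t(Zi)
}

# Two-stage predictor substitution for the binary one-stage CACE: the
# first-stage receipt probability (trial-specific compliance x assignment)
# replaces receipt in the logistic mixed model. Approximate (noncollapsible),
# documented as a reconstruction.
.one_stage_cace_binary <- function(ipd) {
  df <- ipd[!is.na(ipd$responder), , drop = FALSE]
  df <- .receipt_frame(as.data.frame(df), "drop")
  comp <- tapply(df$received[df$arm == "intervention"],
                 df$trial_id[df$arm == "intervention"], mean)
  df$receipt_hat <- ifelse(df$arm == "intervention",
                           comp[as.character(df$trial_id)], 0)
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(responder ~ baseline + receipt_hat + (1 | trial_id),
                data = df, family = binomial())))
  .lmm_pooled(fit, "receipt_hat")
}

#' One-stage comparison of two estimation methods
#'
#' Estimates the within-participant divergence between two methods in a
#' single joint model: each method's analysis population is stacked with a
#' method indicator, the model carries trial fixed effects and an
#' arm-by-method interaction, and the variance is the trial-cluster-robust
#' sandwich, honouring the fact that the two copies share participants.
#' For the CACE the exposure column of its copy is treatment receipt
#' instrumented by randomisation (stacked two-stage least squares).
#'
#' Orientation matches [difference_meta()]: positive delta-SMD (or
#' log-ROR > 0, ROR > 1) means `method_b` claims the larger benefit.
#'
#' @param ipd Multi-trial IPD tibble.
#' @param method_a,method_b `"ITT"`, `"PP"` or `"CACE"`; `method_a` is the
#'   reference.
#' @param outcome_scale `"z_continuous"` or `"binary"`.
#' @return A `difference_result` with a degenerate `per_trial` slot (the
#'   contrast is estimated jointly, not per trial).
#' @export
one_stage_difference <- function(ipd, method_a = "ITT", method_b = "PP",
                                 outcome_scale = c("z_continuous", "binary")) {
  outcome_scale <- match.arg(outcome_scale)
  stopifnot(method_a %in% c("ITT", "PP", "CACE"),
            method_b %in% c("ITT", "PP", "CACE"))
  mk_copy <- function(method, tag) {
    sp <- one_stage_spec(outcome_scale, method)
    d <- as.data.frame(.prep_one_stage(ipd, sp))
    # exposure: assignment for ITT/PP, actual receipt for CACE (whose copy
    # drops intervention rows with unclassifiable adherence)
    if (method == "CACE") {
      d <- .receipt_frame(d, "drop")
      d$exposure <- d$received
    } else {
      d$exposure <- as.numeric(d$arm == "intervention")
    }
    d$instr <- as.numeric(d$arm == "intervention")
    d$method_tag <- tag
    d
  }
  da <- mk_copy(method_a, 0); db <- mk_copy(method_b, 1)
  df <- rbind(da[intersect(names(da), names(db))],
              db[intersect(names(da), names(db))])
  ycol <- if (outcome_scale == "z_continuous") "followup_z" else "responder"
  df <- df[!is.na(df[[ycol]]), ]
  bcol <- if (outcome_scale == "z_continuous") "baseline_z" else "baseline"
  Xex <- model.matrix(as.formula(paste("~", bcol, "+ factor(trial_id) + method_tag")), df)
  if (outcome_scale == "z_continuous") {
    # stacked 2SLS: endogenous columns exposure and exposure:method;
    # instruments assignment and assignment:method
    W <- cbind(x = df$exposure, xm = df$exposure * df$method_tag, Xex)
    Z <- cbind(z = df$instr, zm = df$instr * df$method_tag, Xex)
    y <- df[[ycol]]
    beta <- drop(solve(crossprod(Z, W), crossprod(Z, y)))
    names(beta) <- colnames(W)
    e <- drop(y - W %*% beta)
    Zi <- solve(crossprod(Z, W))
    Ze <- rowsum(Z * e, group = df$trial_id)
    V <- Zi %*% crossprod(Ze) %*% t(Zi)
    b <- beta[["xm"]]; se <- sqrt(max(V[2, 2], 0))  # guard exact-zero contrasts
    # benefit is negative on the score scale; positive delta = larger benefit
    delta <- -b
  } else {
    fm <- as.formula(paste("responder ~", bcol,
                           "+ factor(trial_id) + method_tag + exposure + exposure:method_tag"))
    fit <- glm(fm, data = df, family = binomial())
    V <- sandwich::vcovCL(fit, cluster = df$trial_id)
    term <- grep(":", names(coef(fit)), value = TRUE)  # arm-by-method
    b <- coef(fit)[[term]]
    se <- sqrt(max(V[term, term], 0))
    delta <- b  # log ROR: positive favours method_b
  }
  zq <- qnorm(0.975)
  pooled <- list(mu = delta, se = se, ci_low = delta - zq * se,
                 ci_high = delta + zq * se,
                 p = 2 * pnorm(-abs(delta / se)), tau2 = NA_real_,
                 i2 = NA_real_, q = NA_real_, q_p = NA_real_,
                 k = length(unique(df$trial_id)))
  class(pooled) <- "pooled_estimate"
  out <- list(pooled = pooled, r = NA_real_,
              scale = if (outcome_scale == "z_continuous") "delta_smd" else "log_ror",
              orientation = "magnitude",
              per_trial = tibble::tibble(trial_id = character(),
                                         delta = numeric(), v_delta = numeric()),
              floored = 0L)
  if (out$scale == "log_ror") {
    out$ror <- exp(delta)
    out$ror_ci <- exp(c(pooled$ci_low, pooled$ci_high))
  }
  class(out) <- "difference_result"
  out
}
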