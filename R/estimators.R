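#' Construct an estimate record
#'
#' One method's effect for one trial on one analysis scale, the stage-one
#' unit of the two-stage meta-analysis.
#'
#' @param trial_id,method,scale Identifiers; `scale` is one of
#'   `"raw_mean_diff"`, `"smd_g"`, `"log_odds_ratio"`.
#' @param estimate,se Point estimate and standard error (`se > 0`).
#' @param ci_low,ci_high 95% interval; must bracket the estimate.
#' @param n_analysed Analysed sample size.
#' @param compliance_rate Estimated complier fraction (may be `NA`).
#' @param notes Character vector of warnings accrued during estimation.
#' @return A one-row tibble of class `estimate_record`.
#' @export
estimate_record <- function(trial_id, method, scale, estimate, se,
                            ci_low, ci_high, n_analysed,
                            compliance_rate = NA_real_, notes = character()) {
  stopifnot(method %in% c("ITT", "PP", "CACE"),
            scale %in% c("raw_mean_diff", "smd_g", "log_odds_ratio"))
  # se = 0 is tolerated for exactly saturated toy fits
  if (!is.na(se) && se < 0) stop("estimate_record: se must be non-negative")
  if (!is.na(ci_low) && !(ci_low <= estimate && estimate <= ci_high)) {
    stop("estimate_record: CI must bracket the estimate")
  }
  out <- tibble::tibble(
    trial_id = trial_id, method = method, scale = scale,
    estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
    n_analysed = as.integer(n_analysed), compliance_rate = compliance_rate,
    notes = paste(notes, collapse = "; ")
  )
  class(out) <- c("estimate_record", class(out))
  out
}

# Complete-case analysis table: observed outcome, model columns present.
.analysis_frame <- function(table, outcome, covariate_names) {
  missing_cols <- setdiff(c("arm", outcome, covariate_names), names(table))
  if (length(missing_cols)) {
    stop("columns not found in IPD table: ", paste(missing_cols, collapse = ", "))
  }
  keep <- !is.na(table[[outcome]]) & !is.na(table$arm)
  for (cv in covariate_names) keep <- keep & !is.na(table[[cv]])
  df <- as.data.frame(table[keep, , drop = FALSE])
  df$arm <- factor(df$arm, levels = c("control", "intervention"))
  if (any(table(df$arm) < 2)) {
    stop("estimation requires >= 2 participants with observed outcome per arm")
  }
  df
}

.check_collinear <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("collinear model columns: ", paste(bad, collapse = ", "))
  }
}

#' Intention-to-treat effect on a continuous outcome
#'
#' Linear model of follow-up score on arm plus covariates, estimated on
#' complete cases (the ITT population here is everyone randomised whose
#' outcome was observed). The estimate is the arm coefficient: the
#' unstandardised mean difference B, negative = intervention benefit.
#' Baseline adjustment is obtained by keeping `"baseline"` in
#' `covariate_names` (the default).
#'
#' @param table IPD tibble (see [simulate_trial()] for the schema).
#' @param covariate_names Character vector of adjustment columns.
#' @return An [estimate_record()] on the `raw_mean_diff` scale, with a 95%
#'   normal-theory Wald interval.
#' @export
fit_itt_continuous <- function(table, covariate_names = "baseline") {
  df <- .analysis_frame(table, "followup", covariate_names)
  fm <- as.formula(paste("followup ~ arm",
                         paste(c("", covariate_names), collapse = " + ")))
  X <- model.matrix(fm, df)
  .check_collinear(X)
  fit <- lm(fm, data = df)
  b <- coef(fit)[["armintervention"]]
  se <- sqrt(vcov(fit)["armintervention", "armintervention"])
  z <- qnorm(0.975)
  estimate_record(
    trial_id = .trial_label(df), method = "ITT", scale = "raw_mean_diff",
    estimate = b, se = se, ci_low = b - z * se, ci_high = b + z * se,
    n_analysed = nrow(df), compliance_rate = .safe_compliance(table)
  )
}

#' Intention-to-treat effect on a binary responder outcome
#'
#' Logistic model of treatment response on arm plus covariates; the estimate
#' is the log odds ratio of response (OR > 1 favours the intervention).
#'
#' @inheritParams fit_itt_continuous
#' @return An [estimate_record()] on the `log_odds_ratio` scale.
#' @export
fit_itt_binary <- function(table, covariate_names = "baseline") {
  df <- .analysis_frame(table, "responder", covariate_names)
  rates <- tapply(df$responder, df$arm, mean)
  if (any(rates %in% c(0, 1))) {
    stop("separation: responder is constant within an arm (rates ",
         paste(sprintf("%s=%.2f", names(rates), rates), collapse = ", "), ")")
  }
  fm <- as.formula(paste("responder ~ arm",
                         paste(c("", covariate_names), collapse = " + ")))
  X <- model.matrix(fm, df)
  .check_collinear(X)
  fit <- glm(fm, data = df, family = binomial())
  b <- coef(fit)[["armintervention"]]
  se <- sqrt(vcov(fit)["armintervention", "armintervention"])
  z <- qnorm(0.975)
  estimate_record(
    trial_id = .trial_label(df), method = "ITT", scale = "log_odds_ratio",
    estimate = b, se = se, ci_low = b - z * se, ci_high = b + z * se,
    n_analysed = nrow(df), compliance_rate = .safe_compliance(table)
  )
}

.trial_label <- function(df) {
  if ("trial_id" %in% names(df)) as.character(df$trial_id[1]) else "trial"
}
.safe_compliance <- function(table) {
  tryCatch(compliance_rate(table), error = function(e) NA_real_)
}

#' Restrict a table to the per-protocol population
#'
#' Keeps every control-arm row and the intervention-arm rows that adhered to
#' protocol; intervention rows with missing adherence cannot be classified
#' and are dropped. When the table has an `active_control_adhered` column
#' (an active-control adherence flag), the same restriction is applied to
#' the control arm.
#'
#' @param table IPD tibble with an `adhered` column.
#' @return The restricted tibble.
#' @export
make_pp_table <- function(table) {
  if (!"adhered" %in% names(table)) stop("make_pp_table: no `adhered` column")
  int <- table$arm == "intervention"
  if (all(is.na(table$adhered[int]))) {
    stop("make_pp_table: adherence entirely missing in the intervention arm")
  }
  keep_int <- int & !is.na(table$adhered) & table$adhered == 1
  keep_ctl <- table$arm == "control"
  if ("active_control_adhered" %in% names(table)) {
    keep_ctl <- keep_ctl & !is.na(table$active_control_adhered) &
      table$active_control_adhered == 1
  }
  out <- table[keep_int | keep_ctl, , drop = FALSE]
  if (!any(out$arm == "intervention")) {
    stop("make_pp_table: no adherent intervention participants")
  }
  out
}

#' Per-protocol effects
#'
#' Convenience wrappers: [make_pp_table()] followed by the corresponding ITT
#' fit on the restricted population.
#' @inheritParams fit_itt_continuous
#' @return An [estimate_record()] with `method = "PP"`.
#' @export
fit_pp_continuous <- function(table, covariate_names = "baseline") {
  rec <- fit_itt_continuous(make_pp_table(table), covariate_names)
  rec$method <- "PP"
  rec$compliance_rate <- .safe_compliance(table)
  rec
}

#' @rdname fit_pp_continuous
#' @export
fit_pp_binary <- function(table, covariate_names = "baseline") {
  rec <- fit_itt_binary(make_pp_table(table), covariate_names)
  rec$method <- "PP"
  rec$compliance_rate <- .safe_compliance(table)
  rec
}

#' Estimated complier fraction
#'
#' Adherent intervention-arm participants divided by intervention-arm
#' participants with observed adherence.
#'
#' @param table IPD tibble.
#' @return Probability in [0, 1].
#' @export
compliance_rate <- function(table) {
  a <- table$adhered[table$arm == "intervention"]
  if (!length(a)) stop("compliance_rate: intervention arm is empty")
  a <- a[!is.na(a)]
  if (!length(a)) stop("compliance_rate: adherence entirely missing")
  mean(a)
}

# Treatment receipt under one-sided noncompliance: adherent intervention
# participants received, everyone else (including all controls) did not.
# Rows with missing adherence are dropped (default) or counted as
# non-receipt when `missing_adherence = "non_complier"`.
.receipt_frame <- function(df, missing_adherence) {
  rec <- ifelse(df$arm == "intervention" & !is.na(df$adhered) & df$adhered == 1,
                1, 0)
  drop <- df$arm == "intervention" & is.na(df$adhered)
  if (missing_adherence == "drop") {
    df <- df[!drop, , drop = FALSE]
    rec <- rec[!drop]
  }
  df$received <- rec
  df
}

#' CACE on a continuous outcome by two-stage least squares
#'
#' Randomisation instruments treatment receipt: with one binary instrument
#' and one endogenous binary exposure the just-identified IV estimator
#' targets the complier average causal effect under monotonicity (one-sided
#' noncompliance guarantees it) and the exclusion restriction. Covariates
#' enter as exogenous regressors in both stages. The standard error is the
#' heteroskedasticity-robust IV sandwich.
#'
#' Without covariates the estimate equals the Wald ratio: the unadjusted ITT
#' mean difference divided by the observed compliance rate.
#'
#' @inheritParams fit_itt_continuous
#' @param missing_adherence `"drop"` (default) removes intervention rows with
#'   unknown adherence; `"non_complier"` counts them as not having received
#'   treatment (sensitivity analysis).
#' @return An [estimate_record()] with `method = "CACE"` on the raw score
#'   scale.
#' @export
fit_cace_continuous <- function(table, covariate_names = "baseline",
                                missing_adherence = c("drop", "non_complier")) {
  missing_adherence <- match.arg(missing_adherence)
  df <- .analysis_frame(table, "followup", covariate_names)
  df <- .receipt_frame(df, missing_adherence)
  pihat <- mean(df$received[df$arm == "intervention"])
  if (pihat == 0) stop("fit_cace_continuous: zero instrument strength (no compliers)")
  z <- as.numeric(df$arm == "intervention")
  Xex <- if (length(covariate_names)) {
    model.matrix(as.formula(paste("~", paste(covariate_names, collapse = "+"))), df)
  } else {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  .check_collinear(cbind(Xex, z))
  iv <- .tsls(y = df$followup, endog = df$received, instr = z, exog = Xex)
  zq <- qnorm(0.975)
  estimate_record(
    trial_id = .trial_label(df), method = "CACE", scale = "raw_mean_diff",
    estimate = iv$beta, se = iv$se,
    ci_low = iv$beta - zq * iv$se, ci_high = iv$beta + zq * iv$se,
    n_analysed = nrow(df), compliance_rate = pihat
  )
}

# Just-identified 2SLS with one endogenous column, returning the endogenous
# coefficient and its robust (HC0) sandwich SE.
.tsls <- function(y, endog, instr, exog) {
  W <- cbind(endog = endog, exog)          # structural regressors
  Z <- cbind(instr = instr, exog)          # instruments
  ZtW <- crossprod(Z, W)
  A <- solve(ZtW, crossprod(Z, y))
  beta <- drop(A)
  names(beta) <- colnames(W)
  e <- drop(y - W %*% beta)
  Zi <- solve(ZtW)                          # (Z'W)^{-1}
  meat <- crossprod(Z * e, Z * e)           # sum z_i z_i' e_i^2
  V <- Zi %*% meat %*% t(Zi)
  list(beta = beta[["endog"]], se = sqrt(V[1, 1]),
       coef = beta, vcov = V, residuals = e)
}

#' CACE on a binary outcome by principal-stratification maximum likelihood
#'
#' Under one-sided noncompliance, the exclusion restriction and
#' monotonicity, four parameters are identified: the complier fraction
#' (from intervention-arm adherence), the complier and never-taker response
#' rates under intervention (adherers / non-adherers in the intervention
#' arm), and the complier response rate under control, recovered from the
#' control-arm mixture because never-takers respond at the same rate in
#' both arms. The estimate is the log odds ratio of complier response,
#' intervention versus control; the interval is a seeded nonparametric
#' bootstrap percentile interval over participants.
#'
#' The model is just-identified, so the joint ML solution coincides with the
#' closed-form moment estimator whenever the recovered complier control rate
#' lies inside (0, 1); when it falls outside it is clamped to the boundary
#' (within a small tolerance) and a boundary note is recorded.
#'
#' @inheritParams fit_cace_continuous
#' @param n_bootstrap Number of bootstrap resamples (>= 999 recommended;
#'   smaller values are accepted for quick checks).
#' @param seed Seed for the bootstrap.
#' @return An [estimate_record()] on the `log_odds_ratio` scale. Failed
#'   bootstrap resamples (degenerate mixtures) are counted in `notes`.
#' @export
fit_cace_binary <- function(table, covariate_names = character(),
                            n_bootstrap = 999, seed = 1L,
                            missing_adherence = c("drop", "non_complier")) {
  missing_adherence <- match.arg(missing_adherence)
  if (length(covariate_names)) {
    warning("fit_cace_binary: the mixture-ML estimator is unadjusted; ",
            "covariates are ignored")
  }
  df <- .analysis_frame(table, "responder", character())
  df <- .receipt_frame(df, missing_adherence)
  est <- .cace_binary_point(df)
  if (is.na(est$log_or)) stop("fit_cace_binary: degenerate mixture, no estimate")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boots <- vapply(seq_len(n_bootstrap), function(i) {
    idx <- sample.int(nrow(df), replace = TRUE)
    .cace_binary_point(df[idx, , drop = FALSE])$log_or
  }, numeric(1))
  failed <- sum(!is.finite(boots))
  boots <- boots[is.finite(boots)]
  ci <- quantile(boots, c(0.025, 0.975), names = FALSE)
  notes <- c(
    if (est$boundary) "complier control rate clamped to boundary",
    if (failed) sprintf("%d/%d bootstrap resamples failed", failed, n_bootstrap)
  )
  se <- sd(boots)
  estimate_record(
    trial_id = .trial_label(df), method = "CACE", scale = "log_odds_ratio",
    estimate = est$log_or, se = se,
    ci_low = min(ci[1], est$log_or), ci_high = max(ci[2], est$log_or),
    n_analysed = nrow(df), compliance_rate = est$pi_c, notes = notes
  )
}

# Closed-form just-identified ML / moment solution for the binary CACE.
.cace_binary_point <- function(df, tol = 1e-6) {
  int <- df$arm == "intervention"
  pi_c <- mean(df$received[int])
  p_c1 <- mean(df$responder[int & df$received == 1])
  p_n  <- if (pi_c < 1) mean(df$responder[int & df$received == 0]) else NA_real_
  p_ctl <- mean(df$responder[df$arm == "control"])
  p_c0 <- if (pi_c == 1) p_ctl else (p_ctl - (1 - pi_c) * p_n) / pi_c
  boundary <- FALSE
  if (is.na(p_c0) || is.na(p_c1) || pi_c == 0) {
    return(list(log_or = NA_real_, pi_c = pi_c, boundary = FALSE))
  }
  if (p_c0 <= 0 || p_c0 >= 1) {
    boundary <- TRUE
    p_c0 <- min(max(p_c0, tol), 1 - tol)
  }
  if (p_c1 <= 0 || p_c1 >= 1) {
    boundary <- TRUE
    p_c1 <- min(max(p_c1, tol), 1 - tol)
  }
  list(log_or = qlogis(p_c1) - qlogis(p_c0), pi_c = pi_c,
       boundary = boundary, p_c0 = p_c0, p_c1 = p_c1, p_n = p_n)
}

#' Hedges' g standardised mean difference
#'
#' Converts an unstandardised mean difference B to Hedges' g with the
#' small-sample correction J = 1 - 3 / (4 (n1 + n2 - 2) - 1); a standard
#' error supplied on the B scale is propagated by the same factor.
#'
#' @param B Unstandardised mean difference.
#' @param sd_pooled Pooled follow-up SD across arms (> 0).
#' @param n1,n2 Arm sample sizes.
#' @param se_B Optional standard error of B.
#' @return A list with `g`, `J`, and (when `se_B` is given) `se_g`.
#' @examples
#' hedges_g(-5.68, 13.5, 213, 206)$g  # about -0.42
#' @export
hedges_g <- function(B, sd_pooled, n1, n2, se_B = NULL) {
  if (sd_pooled <= 0) stop("hedges_g: sd_pooled must be positive")
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * B / sd_pooled
  out <- list(g = g, J = J)
  if (!is.null(se_B)) out$se_g <- J * se_B / sd_pooled
  out
}

#' Large-sample standard error of Hedges' g
#'
#' The standard analytic variance of a standardised mean difference:
#' (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2)).
#'
#' @param g Standardised mean difference.
#' @param n1,n2 Analysed sample sizes per arm.
#' @return Standard error.
#' @export
hedges_g_se <- function(g, n1, n2) {
  if (any(c(n1, n2) < 2)) stop("hedges_g_se: need n >= 2 per arm")
  sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

#' Standardise scores to z-scores within each trial
#'
#' Adds `followup_z` and `baseline_z` columns computed over the observed
#' values of each trial, so that trials measured on different instruments
#' (BDI-II, PHQ-9) are comparable in one-stage models.
#'
#' @param table Multi-trial IPD tibble with a `trial_id` column.
#' @return The table with the standardised columns appended.
#' @export
standardise_within_trial <- function(table) {
  if (!"trial_id" %in% names(table)) stop("standardise_within_trial: no trial_id")
  zcol <- function(x) {
    obs <- x[!is.na(x)]
    if (length(obs) < 2) stop("standardise_within_trial: < 2 observed values in a trial")
    s <- sd(obs)
    if (s == 0) stop("standardise_within_trial: zero variance in a trial")
    (x - mean(obs)) / s
  }
  dplyr::mutate(dplyr::group_by(table, .data$trial_id),
                followup_z = zcol(.data$followup),
                baseline_z = zcol(.data$baseline)) |>
    dplyr::ungroup()
}

#' Estimate all three estimands for every trial in a collaboration
#'
#' Stage one of the two-stage IPD meta-analysis: for each trial, fits ITT,
#' PP and CACE on the continuous score (raw mean difference, converted to
#' Hedges' g) and on the binary responder outcome (log odds ratio).
#'
#' @param ipd Multi-trial IPD tibble.
#' @param covariate_names Adjustment columns for the continuous and binary
#'   models (intersected with the available columns per trial).
#' @param n_bootstrap Bootstrap resamples for the binary CACE.
#' @param seed Seed for the bootstrap.
#' @return A tibble of estimate records (one row per trial x method x scale),
#'   with Hedges' g rows appended for the continuous fits.
#' @export
estimate_all <- function(ipd, covariate_names = "baseline",
                         n_bootstrap = 199, seed = 1L) {
  out <- list()
  for (id in unique(ipd$trial_id)) {
    tab <- ipd[ipd$trial_id == id, , drop = FALSE]
    covs <- intersect(covariate_names, names(tab))
    fits <- list(
      fit_itt_continuous(tab, covs),
      fit_pp_continuous(tab, covs),
      fit_cace_continuous(tab, covs),
      fit_itt_binary(tab, covs),
      fit_pp_binary(tab, covs),
      fit_cace_binary(tab, n_bootstrap = n_bootstrap, seed = seed)
    )
    cont <- dplyr::bind_rows(fits[1:3])
    nn <- table(tab$arm[!is.na(tab$followup)])
    sdp <- sqrt(((nn[["control"]] - 1) * var(tab$followup[tab$arm == "control"], na.rm = TRUE) +
                 (nn[["intervention"]] - 1) * var(tab$followup[tab$arm == "intervention"], na.rm = TRUE)) /
                (sum(nn) - 2))
    grows <- lapply(seq_len(nrow(cont)), function(i) {
      hg <- hedges_g(cont$estimate[i], sdp, nn[["control"]], nn[["intervention"]],
                     se_B = cont$se[i])
      z <- qnorm(0.975)
      estimate_record(id, cont$method[i], "smd_g", hg$g, hg$se_g,
                      hg$g - z * hg$se_g, hg$g + z * hg$se_g,
                      cont$n_analysed[i], cont$compliance_rate[i])
    })
    out[[id]] <- dplyr::bind_rows(c(fits, grows))
  }
  dplyr::bind_rows(out)
}
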