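#' Assemble stage-two input
#'
#' @param trial_id Trial labels.
#' @param yi Effects on the analysis scale (Hedges' g or log odds ratio).
#' @param vi Within-trial sampling variances (> 0).
#' @param moderators Optional data frame of trial-level moderators.
#' @return A tibble of class `meta_input`.
#' @export
meta_input <- function(trial_id, yi, vi, moderators = NULL) {
  if (length(yi) < 2) stop("meta_input: need k >= 2 trials")
  if (any(vi <= 0)) stop("meta_input: all vi must be positive")
  out <- tibble::tibble(trial_id = trial_id, yi = yi, vi = vi)
  if (!is.null(moderators)) out <- dplyr::bind_cols(out, moderators)
  class(out) <- c("meta_input", class(out))
  out
}

#' REML between-trial variance
#'
#' Restricted-maximum-likelihood estimate of tau-squared for the
#' random-effects model yi ~ N(mu, vi + tau2), floored at zero.
#'
#' @param yi,vi Effects and within-trial variances.
#' @param tol Convergence tolerance.
#' @param maxiter Iteration cap; non-convergence is an error.
#' @return Non-negative tau-squared.
#' @export
reml_tau2 <- function(yi, vi, tol = 1e-10, maxiter = 100) {
  if (length(yi) < 2) stop("reml_tau2: need k >= 2")
  fit <- tryCatch(
    metafor::rma.uni(yi = yi, vi = vi, method = "REML",
                     control = list(threshold = tol, maxiter = maxiter)),
    error = function(e) stop("reml_tau2: REML did not converge: ",
                             conditionMessage(e))
  )
  fit$tau2
}

.pooled_estimate <- function(fit) {
  out <- list(
    mu = as.numeric(fit$b[1]), se = fit$se[1],
    ci_low = fit$ci.lb, ci_high = fit$ci.ub, p = fit$pval[1],
    tau2 = fit$tau2, i2 = fit$I2, q = fit$QE, q_p = fit$QEp, k = fit$k
  )
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate (k = %d): %.4f (95%% CI %.4f to %.4f), p = %.4g\n",
    x$k, x$mu, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  tau2 = %.4f, I2 = %.2f%%, Q = %.2f (p = %.4g)\n",
              x$tau2, x$i2, x$q, x$q_p))
  invisible(x)
}

#' Random-effects pooling with inverse-variance weights
#'
#' REML random-effects meta-analysis: weights 1/(vi + tau2), normal-theory
#' 95% interval and two-sided p by default (a Knapp-Hartung t interval is
#' available via `knha = TRUE`). I-squared follows the
#' tau2 / (tau2 + typical-within-variance) convention; Cochran's Q is
#' computed on fixed-effect weights.
#'
#' @param yi,vi Effects and variances.
#' @param tau2 Optional fixed between-trial variance; `NULL` (default)
#'   estimates it by REML.
#' @param knha Use the Knapp-Hartung small-sample adjustment.
#' @return A `pooled_estimate`: `mu`, `se`, `ci_low`, `ci_high`, `p`,
#'   `tau2`, `i2` (percent), `q`, `k`.
#' @export
pool <- function(yi, vi, tau2 = NULL, knha = FALSE) {
  if (length(yi) < 2) stop("pool: need k >= 2")
  if (any(vi <= 0)) stop("pool: all vi must be positive")
  if (!is.null(tau2)) {
    # fixed, user-supplied tau2: weighted fixed-effect fit on inflated variances
    fit <- metafor::rma.uni(yi = yi, vi = vi + tau2, method = "FE",
                            test = if (knha) "knha" else "z")
    out <- .pooled_estimate(fit)
    out$tau2 <- tau2
    return(out)
  }
  fit <- metafor::rma.uni(yi = yi, vi = vi, method = "REML",
                          test = if (knha) "knha" else "z")
  .pooled_estimate(fit)
}

#' Standard error back-derived from a reported confidence interval
#'
#' @param low,high Interval bounds (`high > low`).
#' @param level Coverage (default 0.95).
#' @param log_scale If `TRUE`, bounds are transformed to the log scale first
#'   (for ratio measures such as odds ratios); bounds must then be positive.
#' @return Standard error on the (possibly log) analysis scale.
#' @examples
#' se_from_ci(2.12, 5.13, log_scale = TRUE)  # about 0.225
#' @export
se_from_ci <- function(low, high, level = 0.95, log_scale = FALSE) {
  if (any(high <= low)) stop("se_from_ci: need high > low")
  if (log_scale) {
    if (any(low <= 0)) stop("se_from_ci: bounds must be positive on the log scale")
    low <- log(low); high <- log(high)
  }
  (high - low) / (2 * qnorm(1 - (1 - level) / 2))
}

#' Pool within-trial differences between two estimation methods
#'
#' The core contrast of the analysis: ITT, PP and CACE estimates come from
#' the same participants on the same outcome, so their within-trial
#' difference has variance v_a + v_b - 2 r sqrt(v_a v_b) under an assumed
#' within-study correlation r. Per-trial differences are REML-pooled as a
#' random-effects meta-analysis.
#'
#' For the standardised-mean-difference scale the default orientation is the
#' difference in magnitudes |y_b| - |y_a|, so a positive pooled value means
#' method b claims a larger benefit; for log odds ratios the signed
#' difference y_b - y_a (the log ratio of odds ratios) is used and the
#' exponentiated pooled value is the ROR.
#'
#' @param records_a,records_b Data frames with columns `trial_id`, `yi`,
#'   `vi` (e.g. built by [table1_meta_input()]), covering identical trial
#'   sets on the same scale. Method a is the reference (typically ITT).
#' @param r Assumed within-study correlation in [0, 1] (default 1, "strong").
#' @param scale `"delta_smd"` or `"log_ror"`.
#' @param orientation `"magnitude"` (|y_b| - |y_a|) or `"signed"`
#'   (y_b - y_a); defaults to magnitude for `delta_smd`, signed for
#'   `log_ror`.
#' @param var_floor Non-degeneracy floor for the difference variance; at
#'   r = 1 with equal variances the formula collapses to 0 and is floored
#'   here (flagged in the result), letting the REML heterogeneity absorb
#'   the dispersion.
#' @param knha Knapp-Hartung adjustment for the pooled difference.
#' @return A `difference_result`: `pooled` (a `pooled_estimate`), `ror`
#'   (exp(mu), log_ror scale only), `r`, `scale`, `per_trial` tibble
#'   (deltas and variances), `floored` count.
#' @export
difference_meta <- function(records_a, records_b, r = 1,
                            scale = c("delta_smd", "log_ror"),
                            orientation = NULL, var_floor = 1e-8,
                            knha = FALSE) {
  scale <- match.arg(scale)
  if (is.null(orientation)) {
    orientation <- if (scale == "delta_smd") "magnitude" else "signed"
  }
  orientation <- match.arg(orientation, c("magnitude", "signed"))
  if (r < 0 || r > 1) stop("difference_meta: r must lie in [0, 1]")
  a <- records_a[order(records_a$trial_id), ]
  b <- records_b[order(records_b$trial_id), ]
  if (!identical(as.character(a$trial_id), as.character(b$trial_id))) {
    stop("difference_meta: trial sets differ between the two record sets")
  }
  delta <- if (orientation == "magnitude") abs(b$yi) - abs(a$yi) else b$yi - a$yi
  vdelta <- a$vi + b$vi - 2 * r * sqrt(a$vi * b$vi)
  floored <- sum(vdelta <= var_floor)
  vdelta <- pmax(vdelta, var_floor)
  pooled <- pool(delta, vdelta, knha = knha)
  out <- list(
    pooled = pooled, r = r, scale = scale, orientation = orientation,
    per_trial = tibble::tibble(trial_id = a$trial_id, delta = delta,
                               v_delta = vdelta),
    floored = floored
  )
  if (scale == "log_ror") {
    out$ror <- exp(pooled$mu)
    out$ror_ci <- exp(c(pooled$ci_low, pooled$ci_high))
  }
  class(out) <- "difference_result"
  out
}

#' @export
print.difference_result <- function(x, ...) {
  lbl <- if (x$scale == "log_ror") "log-ROR" else "delta-SMD"
  cat(sprintf("Pooled method difference (%s, r = %.2f):\n", lbl, x$r))
  print(x$pooled)
  if (!is.null(x$ror)) {
    cat(sprintf("  ROR = %.3f (95%% CI %.3f to %.3f)\n",
                x$ror, x$ror_ci[1], x$ror_ci[2]))
  }
  if (x$floored > 0) {
    cat(sprintf("  note: %d difference variance(s) floored at the degeneracy bound\n",
                x$floored))
  }
  invisible(x)
}

#' Correlation sensitivity grid for a method difference
#'
#' Re-pools the within-trial differences under each assumed correlation and
#' reports how the pooled estimate, its significance classification at the
#' 5% level, and the residual I-squared respond.
#'
#' @inheritParams difference_meta
#' @param r_values Correlations in [0, 1].
#' @return A tibble with one row per r: `r`, `estimate`, `ci_low`,
#'   `ci_high`, `p`, `significant`, `i2`, `tau2`.
#' @export
sensitivity_r_grid <- function(records_a, records_b,
                               r_values = seq(0.5, 1, by = 0.1),
                               scale = c("delta_smd", "log_ror"), ...) {
  scale <- match.arg(scale)
  if (any(r_values < 0 | r_values > 1)) {
    stop("sensitivity_r_grid: r values must lie in [0, 1]")
  }
  rows <- lapply(r_values, function(r) {
    d <- difference_meta(records_a, records_b, r = r, scale = scale, ...)
    tibble::tibble(r = r, estimate = d$pooled$mu, ci_low = d$pooled$ci_low,
                   ci_high = d$pooled$ci_high, p = d$pooled$p,
                   significant = d$pooled$p < 0.05,
                   i2 = d$pooled$i2, tau2 = d$pooled$tau2)
  })
  dplyr::bind_rows(rows)
}

#' Subgroup random-effects analysis with a between-group test
#'
#' Pools each subgroup separately by REML and tests equality of subgroup
#' means with a Q statistic on the inverse-variance weights of the pooled
#' means (chi-squared with G - 1 degrees of freedom). With two singleton
#' groups this reduces to a z-test of the difference between the two trials.
#'
#' @param mi A [meta_input()].
#' @param grouping Factor/character vector aligned with the rows of `mi`.
#' @return List with `groups` (tibble of per-group pooled estimates),
#'   `q_between`, `df`, `p`.
#' @export
subgroup_analysis <- function(mi, grouping) {
  g <- as.character(grouping)
  if (length(g) != nrow(mi)) stop("subgroup_analysis: grouping length mismatch")
  if (length(unique(g)) < 2) stop("subgroup_analysis: need >= 2 groups")
  per <- lapply(split(seq_len(nrow(mi)), g), function(idx) {
    if (length(idx) == 1) {
      list(mu = mi$yi[idx], se = sqrt(mi$vi[idx]), k = 1L,
           tau2 = NA_real_, i2 = NA_real_)
    } else {
      p <- pool(mi$yi[idx], mi$vi[idx])
      list(mu = p$mu, se = p$se, k = p$k, tau2 = p$tau2, i2 = p$i2)
    }
  })
  groups <- tibble::tibble(
    group = names(per),
    mu = vapply(per, `[[`, numeric(1), "mu"),
    se = vapply(per, `[[`, numeric(1), "se"),
    k = vapply(per, function(x) as.integer(x$k), integer(1)),
    tau2 = vapply(per, `[[`, numeric(1), "tau2"),
    i2 = vapply(per, `[[`, numeric(1), "i2")
  )
  w <- 1 / groups$se^2
  mbar <- sum(w * groups$mu) / sum(w)
  q_b <- sum(w * (groups$mu - mbar)^2)
  df <- nrow(groups) - 1
  list(groups = groups, q_between = q_b, df = df,
       p = stats::pchisq(q_b, df, lower.tail = FALSE))
}

#' Random-effects meta-regression on trial-level moderators
#'
#' Weighted regression of the per-trial effects on trial-level covariates
#' (non-adherence rate, duration, intervention type, ...) with REML residual
#' heterogeneity, via the standard mixed-effects meta-analytic model.
#'
#' @param mi A [meta_input()] carrying the moderator columns.
#' @param moderator_names Column names to include as moderators.
#' @return List with `coefficients` (tibble: term, estimate, se, z, p),
#'   `tau2` (residual), `r2` (heterogeneity accounted for, percent).
#' @export
meta_regression <- function(mi, moderator_names) {
  miss <- setdiff(moderator_names, names(mi))
  if (length(miss)) stop("meta_regression: moderators not found: ",
                         paste(miss, collapse = ", "))
  if (nrow(mi) <= length(moderator_names) + 1) {
    stop("meta_regression: need k > #moderators + 1")
  }
  mods <- as.data.frame(mi[, moderator_names, drop = FALSE])
  X <- model.matrix(as.formula(paste("~", paste(moderator_names, collapse = "+"))),
                    mods)
  if (qr(X)$rank < ncol(X)) {
    stop("meta_regression: rank-deficient moderator matrix (constant or ",
         "collinear moderators)")
  }
  fit <- metafor::rma.uni(yi = mi$yi, vi = mi$vi, mods = X[, -1, drop = FALSE],
                          method = "REML")
  list(
    coefficients = tibble::tibble(
      term = rownames(fit$b), estimate = as.numeric(fit$b),
      se = fit$se, z = fit$zval, p = fit$pval),
    tau2 = fit$tau2, r2 = fit$R2
  )
}

#' Egger's regression test for small-study effects
#'
#' The classic funnel-asymmetry regression: the standardised effect
#' yi / sei is regressed on precision 1 / sei by ordinary least squares and
#' the intercept is tested against zero (two-sided t test). A non-zero
#' intercept indicates association between effect size and precision, as
#' seen with publication/small-study bias.
#'
#' @param yi,vi Effects and variances, k >= 3.
#' @return List: `intercept`, `se`, `t`, `df`, `p`, `slope`.
#' @export
eggers_test <- function(yi, vi) {
  if (length(yi) < 3) stop("eggers_test: need k >= 3")
  sei <- sqrt(vi)
  if (sd(1 / sei) < 1e-12) {
    stop("eggers_test: constant precision, funnel regression undefined")
  }
  fit <- lm(I(yi / sei) ~ I(1 / sei))
  sm <- summary(fit)$coefficients
  list(intercept = sm[1, 1], se = sm[1, 2], t = sm[1, 3],
       df = fit$df.residual, p = sm[1, 4], slope = sm[2, 1])
}

#' Two-sided variance-ratio (F) test
#'
#' Compares two sample variances, e.g. the outcome spread of the ITT and PP
#' analysis sets of the same trial; similar variances support the strong
#' within-study correlation assumption behind [difference_meta()].
#'
#' @param sd1,sd2 Sample standard deviations (> 0).
#' @param n1,n2 Sample sizes (>= 2).
#' @return List: `f` (sd1^2/sd2^2), `df1`, `df2`, `p` (two-sided).
#' @export
variance_ratio_test <- function(sd1, n1, sd2, n2) {
  if (min(n1, n2) < 2) stop("variance_ratio_test: need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("variance_ratio_test: zero variance")
  f <- sd1^2 / sd2^2
  p_low <- pf(f, n1 - 1, n2 - 1)
  p <- 2 * min(p_low, 1 - p_low)
  list(f = f, df1 = n1 - 1, df2 = n2 - 1, p = min(p, 1))
}
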