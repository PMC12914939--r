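#' Write / read the analysis IPD CSV and its truth sidecar
#'
#' The analysis CSV carries the fixed header (`trial_id`, `participant_id`,
#' `arm`, `baseline`, `followup`, `responder`, `adhered`, plus declared
#' covariates); hidden truth columns (latent stratum and prognosis) are
#' stripped and written to a `*_truth.csv` sidecar so estimators cannot use
#' them.
#'
#' @param ipd IPD tibble from [simulate_trial()] / [simulate_collaboration()].
#' @param path Output CSV path.
#' @param truth Optional truth ledger tibble written next to `path`.
#' @return Invisibly, the analysis path.
#' @export
write_ipd <- function(ipd, path, truth = NULL) {
  hidden <- grep("^\\.", names(ipd), value = TRUE)
  analysis <- ipd[, setdiff(names(ipd), hidden), drop = FALSE]
  write.csv(analysis, path, row.names = FALSE)
  side <- sub("\\.csv$", "_truth.csv", path)
  if (length(hidden)) {
    write.csv(ipd[, c("trial_id", "participant_id", hidden)], side,
              row.names = FALSE)
  }
  if (!is.null(truth)) {
    write.csv(truth, sub("\\.csv$", "_ledger.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  if (!file.exists(path)) stop("read_ipd: file not found: ", path)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate an IPD table against the schema
#'
#' Checks column presence, arm labels, one-sided adherence (undefined in the
#' control arm), score ranges for the declared scale, and consistency of the
#' responder flag with a declared dichotomisation rule.
#'
#' @param x IPD tibble or path to a CSV.
#' @param scale Score scale for range checks (`"BDI"` or `"PHQ9"`), or
#'   `NULL` to skip.
#' @param responder_rule Declared rule for consistency checks, or `NULL`.
#' @return List with `ok` (logical) and `violations` (tibble: `rule`,
#'   `rows`, `message`).
#' @export
validate_ipd <- function(x, scale = NULL, responder_rule = NULL) {
  ipd <- if (is.character(x)) read_ipd(x) else x
  v <- list()
  flag <- function(rule, rows, message) {
    if (length(rows)) {
      v[[length(v) + 1]] <<- tibble::tibble(
        rule = rule, rows = paste(head(rows, 10), collapse = ","),
        n = length(rows), message = message)
    }
  }
  need <- c("trial_id", "participant_id", "arm", "baseline", "followup",
            "adhered")
  miss <- setdiff(need, names(ipd))
  if (length(miss)) {
    flag("schema", integer(0), "")
    return(list(ok = FALSE, violations = tibble::tibble(
      rule = "schema", rows = "", n = length(miss),
      message = paste("missing columns:", paste(miss, collapse = ", ")))))
  }
  flag("arm_values", which(!ipd$arm %in% c("control", "intervention")),
       "arm must be 'control' or 'intervention'")
  flag("adherence_one_sided",
       which(ipd$arm == "control" & !is.na(ipd$adhered)),
       "adherence must be undefined in the control arm")
  if (!is.null(scale)) {
    rng <- .scale_ranges[[match.arg(scale, names(.scale_ranges))]]
    bad <- function(col) which(!is.na(ipd[[col]]) &
                               (ipd[[col]] < rng[["min"]] | ipd[[col]] > rng[["max"]]))
    flag("baseline_range", bad("baseline"),
         sprintf("baseline outside [%d, %d]", rng[["min"]], rng[["max"]]))
    flag("followup_range", bad("followup"),
         sprintf("followup outside [%d, %d]", rng[["min"]], rng[["max"]]))
  }
  if (!is.null(responder_rule) && "responder" %in% names(ipd)) {
    expect <- dichotomise(ipd[, c("baseline", "followup")], responder_rule)$responder
    flag("responder_rule",
         which(!is.na(ipd$responder) & !is.na(expect) & ipd$responder != expect),
         sprintf("responder inconsistent with rule '%s'", responder_rule))
  }
  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(rule = character(), rows = character(), n = integer(),
                   message = character())
  list(ok = nrow(violations) == 0, violations = violations)
}

#' Run the full pipeline end to end
#'
#' Drives the package from a single configuration list. Commands:
#' \describe{
#'   \item{`simulate`}{generate a collaboration from `configs` (a list of
#'     [trial_config()]; default [depgp_scenario()]) and write the IPD CSV,
#'     truth sidecars and a run manifest.}
#'   \item{`estimate`}{stage one: per-trial ITT / PP / CACE estimates from
#'     an IPD table (path or tibble) written as a tidy estimate CSV.}
#'   \item{`pool`}{stage two on simulated estimates: REML pools and
#'     correlated-difference models per scale.}
#'   \item{`replay-table1`}{the published-summary replay:
#'     [replay_table2()] written as a pooled-comparison CSV.}
#' }
#' Every output directory receives a `manifest.json` recording the command,
#' seed, correlation settings and package version, so each numeric result
#' can be re-derived by calling the underlying functions with the
#' manifest's configuration.
#'
#' @param command One of `"simulate"`, `"estimate"`, `"pool"`,
#'   `"replay-table1"`.
#' @param out_dir Output directory (created if needed).
#' @param ipd Input IPD (tibble or CSV path) for `estimate` / `pool`.
#' @param configs Trial configurations for `simulate`.
#' @param r_base Within-study correlation for difference models.
#' @param seed Seed recorded in the manifest and used wherever randomness
#'   enters (simulation, bootstrap).
#' @param n_bootstrap Bootstrap resamples for the binary CACE.
#' @param smd_se Replay SMD standard-error derivation (see
#'   [table1_meta_input()]).
#' @return The main result of the command (tibble), invisibly for
#'   `simulate`.
#' @export
run_pipeline <- function(command = c("simulate", "estimate", "pool",
                                     "replay-table1"),
                         out_dir = tempfile("cacemeta_run_"),
                         ipd = NULL, configs = NULL, r_base = 1,
                         seed = 1L, n_bootstrap = 199,
                         smd_se = "sample_size") {
  command <- match.arg(command)
  if (r_base < 0 || r_base > 1) stop("run_pipeline: r_base must lie in [0, 1]")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = command, seed = seed, r_base = r_base,
                   n_bootstrap = n_bootstrap, smd_se = smd_se,
                   package_version = as.character(utils::packageVersion("cacemeta")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  get_ipd <- function() {
    if (is.null(ipd)) stop("run_pipeline: `ipd` required for this command")
    if (is.character(ipd)) read_ipd(ipd) else ipd
  }
  result <- switch(command,
    "simulate" = {
      if (is.null(configs)) configs <- depgp_scenario(seed = seed)
      cc <- simulate_collaboration(configs)
      write_ipd(cc$ipd, file.path(out_dir, "ipd.csv"), truth = cc$truth)
      manifest$n_trials <- length(configs)
      manifest$n_participants <- nrow(cc$ipd)
      invisible(cc$ipd)
    },
    "estimate" = {
      est <- estimate_all(get_ipd(), n_bootstrap = n_bootstrap, seed = seed)
      write.csv(est, file.path(out_dir, "estimates.csv"), row.names = FALSE)
      est
    },
    "pool" = {
      est <- estimate_all(get_ipd(), n_bootstrap = n_bootstrap, seed = seed)
      res <- pool_estimates(est, r = r_base)
      write.csv(res, file.path(out_dir, "pooled.csv"), row.names = FALSE)
      res
    },
    "replay-table1" = {
      res <- replay_table2(r = r_base, smd_se = smd_se)
      write.csv(res, file.path(out_dir, "table2_replay.csv"), row.names = FALSE)
      res
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result
}

#' Stage-two pooling of a tidy estimate table
#'
#' Pools per-trial estimate records (as produced by [estimate_all()]) by
#' REML on the Hedges' g and log-odds-ratio scales, and fits the
#' correlated-difference models for each method pair.
#'
#' @param est Estimate-record tibble.
#' @param r Within-study correlation for the difference models.
#' @return Tibble shaped like [replay_table2()] output.
#' @export
pool_estimates <- function(est, r = 1) {
  mk <- function(method, scale) {
    e <- est[est$method == method & est$scale == scale, ]
    meta_input(e$trial_id, e$estimate, e$se^2)
  }
  row_pool <- function(analysis, outcome, pe, expo = FALSE) {
    tibble::tibble(analysis = analysis, outcome = outcome,
                   estimate = if (expo) exp(pe$mu) else pe$mu,
                   ci_low = if (expo) exp(pe$ci_low) else pe$ci_low,
                   ci_high = if (expo) exp(pe$ci_high) else pe$ci_high,
                   p = pe$p, i2 = pe$i2, tau2 = pe$tau2, k = pe$k)
  }
  rows <- list()
  for (m in c("ITT", "PP", "CACE")) {
    rows[[paste(m, "g")]] <- row_pool(paste("pooled", m), "SMD",
                                      with(mk(m, "smd_g"), pool(yi, vi)))
    rows[[paste(m, "or")]] <- row_pool(paste("pooled", m), "OR",
                                       with(mk(m, "log_odds_ratio"), pool(yi, vi)),
                                       expo = TRUE)
  }
  for (pr in list(c("ITT", "PP"), c("ITT", "CACE"), c("PP", "CACE"))) {
    dg <- difference_meta(mk(pr[1], "smd_g"), mk(pr[2], "smd_g"), r = r,
                          scale = "delta_smd")
    db <- difference_meta(mk(pr[1], "log_odds_ratio"),
                          mk(pr[2], "log_odds_ratio"), r = r, scale = "log_ror")
    rows[[paste(pr, collapse = "g")]] <-
      row_pool(sprintf("%s vs %s", pr[2], pr[1]), "delta_SMD", dg$pooled)
    rows[[paste(pr, collapse = "b")]] <-
      row_pool(sprintf("%s vs %s", pr[2], pr[1]), "ROR", db$pooled, expo = TRUE)
  }
  dplyr::bind_rows(rows)
}
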