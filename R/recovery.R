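# Simulation-recovery harness: repeated generate -> fit -> standardize
# cycles against generator truth, for bias and CI-calibration studies.

#' Parameter-recovery and coverage harness
#'
#' Repeatedly generates a population from `config` (with per-replicate
#' derived seeds), runs the outcome's analysis-window selection and the
#' scenario, fits `spec`, and (optionally) standardizes at horizon 0.
#' Used for bias checks on the immediate-effect and slope-change
#' coefficients and for delta-method CI calibration against the
#' generator-truth marginal rate ratio.
#'
#' @param config a [population_config()]; its `true_beta` holds the truth
#'   being recovered.
#' @param spec a [model_spec()].
#' @param n_seeds number of replicates.
#' @param base_seed replicate seeds are derived from this.
#' @param scenario an [exposure_scenario()].
#' @param standardize also compute the standardized RR at `horizon` with
#'   a delta-method CI (requires `se = TRUE`).
#' @param horizon horizon for the standardized RR.
#' @param se compute covariance (needed for CIs).
#' @param control optional [mpits_control()] override.
#' @param window_months override the outcome's standard recall window
#'   (60 delivery / 120 mortality); e.g. the full observation span for
#'   recovery studies of the segmented-regression coefficients, which are
#'   weakly identified when the pre-policy period is short.
#' @return data frame with one row per replicate: `seed`, `converged`,
#'   `beta_subsidy`, `beta_post_time`, `psi_intercept`, and when
#'   `standardize` is TRUE `rr`, `rr_lo`, `rr_hi`.
#' @export
recovery_harness <- function(config, spec, n_seeds = 10, base_seed = 1,
                             scenario = exposure_scenario("primary"),
                             standardize = FALSE, horizon = 0,
                             se = standardize, control = NULL,
                             window_months = NULL) {
  control <- control %||% mpits_control(se = se)
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, 100L + i)
    rec <- suppressWarnings(generate_population(cfg))
    win <- if (is.null(window_months))
      select_window(rec, spec$outcome, cfg$survey_month)
    else rec[cfg$survey_month - rec$birth_month < window_months, ,
             drop = FALSE]
    if (spec$outcome == "delivery") win <- collapse_deliveries(win)
    fit <- mpits(win, spec, scenario, control)
    out <- data.frame(
      seed = cfg$seed, converged = fit$converged,
      beta_subsidy = unname(fit$beta["subsidy"]),
      beta_post_time = unname(fit$beta["post_time"]),
      psi_intercept = if (!is.null(fit$psi) &&
                          "intercept" %in% rownames(fit$psi))
        fit$psi["intercept", "intercept"] else 0,
      rr = NA_real_, rr_lo = NA_real_, rr_hi = NA_real_)
    if (standardize && fit$converged) {
      g <- standardize_rates(fit, horizons = horizon)
      out$rr <- g$rr; out$rr_lo <- g$rr_lo; out$rr_hi <- g$rr_hi
    }
    out
  })
  do.call(rbind, rows)
}

#' Summarize a recovery run against generator truth
#'
#' @param runs result of [recovery_harness()].
#' @param config the generating [population_config()].
#' @param outcome outcome whose truth to compare against.
#' @return list with mean estimates, bias on the subsidy and post-time
#'   coefficients, and (when present) CI coverage of the generator-truth
#'   marginal RR at horizon 0.
#' @export
recovery_summary <- function(runs, config, outcome = "delivery") {
  ok <- runs[runs$converged, , drop = FALSE]
  truth <- config$true_beta[[outcome]]
  out <- list(
    n_converged = nrow(ok), n_total = nrow(runs),
    mean_beta_subsidy = mean(ok$beta_subsidy),
    mean_beta_post_time = mean(ok$beta_post_time),
    bias_subsidy = mean(ok$beta_subsidy) - truth[["subsidy"]],
    bias_post_time = mean(ok$beta_post_time) - truth[["post_time"]])
  if (any(is.finite(ok$rr_lo))) {
    tme <- true_marginal_effect(config, 0, outcome)
    cov <- ok$rr_lo <= tme$rr & tme$rr <= ok$rr_hi
    out$true_rr <- tme$rr
    out$coverage <- mean(cov, na.rm = TRUE)
    out$n_covered <- sum(cov, na.rm = TRUE)
  }
  out
}
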