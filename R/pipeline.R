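# End-to-end analysis pipeline: window selection, interaction testing and
# stratification, model fitting with the model-building rules, and
# standardization, per outcome and exposure scenario.

#' Select an outcome's analysis window
#'
#' Births in the 60 (delivery) or 120 (mortality) months before the
#' survey month.
#'
#' @param records birth records.
#' @param outcome `"delivery"` or `"mortality"`.
#' @param survey_month month index of the survey.
#' @export
select_window <- function(records, outcome, survey_month) {
  age_m <- survey_month - records$birth_month
  span <- if (outcome == "delivery") 60 else 120
  records[age_m >= 0 & age_m < span, , drop = FALSE]
}

#' Collapse multiple births to one delivery record
#'
#' Keeps one record per (woman, birth month) pair, the delivery unit of
#' the birthplace analysis.
#'
#' @param records birth records.
#' @export
collapse_deliveries <- function(records) {
  records[!duplicated(records[, c("woman_id", "birth_month")]), ,
          drop = FALSE]
}

#' Test the subsidy interactions and decide on stratification
#'
#' Likelihood-ratio tests of the subsidy-by-rural, subsidy-by-wealth and
#' subsidy-by-education interactions, jointly and separately, at the 0.05
#' threshold. For the delivery outcome a significant subsidy-by-rural
#' interaction triggers separate urban and rural analyses.
#'
#' @param records analysis-window records.
#' @param spec a [model_spec()] without interactions.
#' @param scenario an [exposure_scenario()].
#' @param control a [mpits_control()].
#' @param alpha significance threshold.
#' @return list with `joint` and per-interaction LRTs, and `stratify_rural`.
#' @export
interaction_analysis <- function(records, spec,
                                 scenario = exposure_scenario("primary"),
                                 control = mpits_control(se = FALSE),
                                 alpha = 0.05) {
  if (length(spec$interactions))
    stop("supply the base spec; interactions are added internally")
  base <- mpits(records, spec, scenario, control)
  # the fixed-effect LRTs must compare fits with a common random
  # structure: adopt the base fit's post-boundary structure and keep it
  # fixed (no further boundary collapse) for the interaction fits
  spec <- base$spec
  ctrl_fix <- control
  ctrl_fix$boundary_tol <- 0
  all_ints <- c("subsidy:rural", "subsidy:wealth", "subsidy:education")
  usable <- all_ints[c("rural" %in% spec$covariates, TRUE, TRUE)]
  fits <- list()
  tests <- list()
  spec_j <- spec; spec_j$interactions <- usable
  fit_j <- mpits(records, spec_j, scenario, ctrl_fix)
  tests$joint <- lrt(base, fit_j, boundary = FALSE)
  for (ia in usable) {
    spec_i <- spec; spec_i$interactions <- ia
    fits[[ia]] <- mpits(records, spec_i, scenario, ctrl_fix)
    tests[[ia]] <- lrt(base, fits[[ia]], boundary = FALSE)
  }
  stratify <- spec$outcome == "delivery" &&
    "subsidy:rural" %in% usable &&
    is.finite(tests[["subsidy:rural"]]$p_value) &&
    tests[["subsidy:rural"]]$p_value < alpha
  list(joint = tests$joint,
       separate = tests[setdiff(names(tests), "joint")],
       stratify_rural = stratify, alpha = alpha)
}

#' Analysis configuration
#'
#' @param population a [population_config()] (used by `simulate`-style
#'   runs and recorded for traceability).
#' @param survey_month month of the survey (recall windows count back
#'   from it).
#' @param scenarios scenario names to run.
#' @param horizons standardization horizons in months.
#' @param random cluster-level random terms for the fitted models.
#' @param woman_intercept_mortality use a woman-level intercept (3-level
#'   model) for the mortality outcome.
#' @param seasonality_screen,overdispersion_screen run the corresponding
#'   diagnostics (each costs an extra fit per cell).
#' @param agq_nodes,se passed to [mpits_control()].
#' @param verbose print stage-by-stage progress.
#' @param seed master seed recorded in the report.
#' @export
analysis_config <- function(population = population_config(),
                            survey_month = NULL,
                            scenarios = c("primary", "shift_april",
                                          "exclude_q1"),
                            horizons = seq(0, 42, by = 6),
                            random = c("intercept", "subsidy"),
                            woman_intercept_mortality = FALSE,
                            seasonality_screen = FALSE,
                            overdispersion_screen = FALSE,
                            agq_nodes = NULL,
                            se = TRUE,
                            verbose = FALSE,
                            seed = 1L) {
  structure(list(population = population,
                 survey_month = survey_month %||% population$survey_month,
                 scenarios = scenarios, horizons = horizons,
                 random = random,
                 woman_intercept_mortality = woman_intercept_mortality,
                 seasonality_screen = seasonality_screen,
                 overdispersion_screen = overdispersion_screen,
                 agq_nodes = agq_nodes, se = se, verbose = verbose,
                 seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognized blocks: `population` (fields of [population_config()]),
#' and top-level fields of [analysis_config()].
#'
#' @param path YAML file.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  pop_args <- y$population %||% list()
  if (!is.null(pop_args$true_beta))
    pop_args$true_beta <- lapply(pop_args$true_beta, unlist)
  if (!is.null(pop_args$true_psi))
    pop_args$true_psi <- lapply(pop_args$true_psi, unlist)
  pop <- do.call(population_config, pop_args)
  args <- y[setdiff(names(y), "population")]
  args$population <- pop
  do.call(analysis_config, args)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(lapply(unclass(config), unclass), tf)
  unname(tools::md5sum(tf))
}

# fit + diagnostics + standardization for one stratum
run_stratum <- function(records, spec, scenario, config, control) {
  fit <- mpits(records, spec, scenario, control)
  out <- list(fit = fit)
  if (!fit$converged) return(out)
  if (config$seasonality_screen) {
    spec_s <- spec; spec_s$seasonal <- TRUE
    fit_s <- mpits(records, spec_s, scenario,
                   mpits_control(se = FALSE, agq_nodes = control$agq_nodes))
    scr <- confounder_screen(fit_s, fit)
    out$seasonality <- scr
    if (isTRUE(scr$keep)) {
      fit <- mpits(records, spec_s, scenario, control)
      out$fit <- fit
    }
  }
  if (config$overdispersion_screen && !spec$woman_intercept) {
    out$overdispersion <- tryCatch(
      overdispersion_check(records, out$fit$spec, scenario,
                           mpits_control(se = FALSE,
                                         agq_nodes = control$agq_nodes)),
      error = function(e) list(error = conditionMessage(e)))
  }
  out$vif <- vif(out$fit)
  out$grid <- tryCatch(
    standardize_rates(out$fit, config$horizons, ci = config$se),
    error = function(e) { warning(conditionMessage(e)); NULL })
  out
}

#' Run the full analysis pipeline
#'
#' For each outcome (delivery: 5-year window, multiples collapsed to one
#' delivery, time origin June 2005; mortality: 10-year window, all births,
#' time origin January 2000) and each exposure scenario: select the
#' window, apply the scenario, test the subsidy interactions (pooled
#' model), stratify by residence if the subsidy-by-rural interaction is
#' significant for delivery, fit the final model(s), and standardize.
#' Stage failures are recorded per cell; the run continues.
#'
#' @param records birth-record data frame.
#' @param config an [analysis_config()].
#' @return object of class `analysis_report`.
#' @export
run_analysis <- function(records, config = analysis_config()) {
  control <- mpits_control(se = config$se, agq_nodes = config$agq_nodes)
  ctrl_fast <- mpits_control(se = FALSE, agq_nodes = config$agq_nodes)
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 cells = list())
  report$flow <- flow_accounting(records, config$survey_month)
  for (outcome in c("delivery", "mortality")) {
    winrec <- select_window(records, outcome, config$survey_month)
    if (outcome == "delivery") winrec <- collapse_deliveries(winrec)
    for (sc_name in config$scenarios) {
      scenario <- exposure_scenario(sc_name)
      cell_id <- paste(outcome, sc_name, sep = ".")
      if (isTRUE(config$verbose))
        message(sprintf("[run_analysis] %s (%s)", cell_id,
                        format(Sys.time(), "%H:%M:%S")))
      cell <- tryCatch({
        ap <- apply_scenario(winrec, scenario)
        spec <- model_spec(outcome, random = config$random,
                           woman_intercept = outcome == "mortality" &&
                             config$woman_intercept_mortality)
        ia <- interaction_analysis(ap$records, spec, scenario, ctrl_fast)
        if (isTRUE(config$verbose))
          message(sprintf("[run_analysis]   interactions done, stratify=%s (%s)",
                          ia$stratify_rural, format(Sys.time(), "%H:%M:%S")))
        chars <- characteristics_table(winrec, scenario)
        strata <- list()
        if (ia$stratify_rural) {
          spec_st <- spec
          spec_st$covariates <- setdiff(spec_st$covariates, "rural")
          for (st in c("urban", "rural")) {
            sub <- ap$records[ap$records$rural == (st == "rural"), ,
                              drop = FALSE]
            strata[[st]] <- if (length(unique(sub$cluster_id)) < 2L)
              list(skipped = "stratum too small")
            else run_stratum(sub, spec_st, scenario, config, control)
          }
        } else {
          strata$pooled <- run_stratum(ap$records, spec, scenario, config,
                                       control)
        }
        list(outcome = outcome, scenario = sc_name,
             n_included = nrow(ap$records), n_excluded = ap$n_excluded,
             interactions = ia, characteristics = chars, strata = strata)
      }, error = function(e) list(outcome = outcome, scenario = sc_name,
                                  error = conditionMessage(e)))
      report$cells[[cell_id]] <- cell
    }
  }
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Subsidy impact analysis report (config", substr(x$config_hash, 1, 8),
      ", seed", x$seed, ")\n")
  for (cell in x$cells) {
    cat(sprintf("\n== %s / %s ==\n", cell$outcome, cell$scenario))
    if (!is.null(cell$error)) { cat("  failed:", cell$error, "\n"); next }
    cat(sprintf("  births: %d included, %d excluded\n", cell$n_included,
                cell$n_excluded))
    for (st in names(cell$strata)) {
      s <- cell$strata[[st]]
      if (!is.null(s$skipped)) { cat("  ", st, ": ", s$skipped, "\n"); next }
      if (!s$fit$converged) { cat("  ", st, ": fit failed\n"); next }
      cat(sprintf("  %s: subsidy = %.4f, psi = (%s)\n", st,
                  s$fit$beta["subsidy"],
                  if (is.null(s$fit$psi)) "none"
                  else paste(sprintf("%.4f", diag(s$fit$psi)),
                             collapse = ", ")))
      if (!is.null(s$grid)) {
        h0 <- s$grid[s$grid$horizon == min(s$grid$horizon), ]
        cat(sprintf("      RR at h=%d: %.3f\n", h0$horizon, h0$rr))
      }
    }
  }
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report an [run_analysis()] result.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  ser_cell <- function(cell) {
    if (!is.null(cell$error)) return(cell)
    list(outcome = cell$outcome, scenario = cell$scenario,
         n_included = cell$n_included, n_excluded = cell$n_excluded,
         stratified = cell$interactions$stratify_rural,
         interaction_p = lapply(cell$interactions$separate,
                                function(t) t$p_value),
         strata = lapply(cell$strata, function(s) {
           if (!is.null(s$skipped)) return(s)
           if (!s$fit$converged) return(list(failed = TRUE))
           list(beta = as.list(s$fit$beta),
                psi = if (!is.null(s$fit$psi)) diag(s$fit$psi),
                sd_woman = s$fit$sd_woman,
                loglik = s$fit$loglik,
                robust_se = if (!is.null(s$fit$vcov_robust))
                  sqrt(diag(s$fit$vcov_robust)),
                boundary_dropped = s$fit$boundary_dropped,
                grid = if (!is.null(s$grid)) as.data.frame(s$grid))
         }))
  }
  jsonlite::write_json(
    list(config_hash = report$config_hash, seed = report$seed,
         flow = unclass(report$flow),
         cells = lapply(report$cells, ser_cell)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
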