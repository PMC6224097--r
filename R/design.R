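# Model specification and design construction for the segmented
# multilevel modified-Poisson model.

#' Specify a segmented multilevel modified-Poisson model
#'
#' Fixed part: intercept, secular time trend `time` (months since the
#' outcome's time origin), immediate subsidy effect `subsidy`, post-policy
#' slope change `post_time` (months since introduction, 0 before), plus
#' covariates and optional subsidy interactions. Random part: cluster-level
#' intercept and, optionally, cluster-level coefficients on subsidy, time
#' and post-time; a woman-level random intercept gives the three-level
#' variant.
#'
#' @param outcome `"delivery"` (facility delivery, 5-year window, time
#'   origin June 2005) or `"mortality"` (neonatal death, 10-year window,
#'   time origin January 2000).
#' @param covariates character vector drawn from `"rural"`, `"literacy"`,
#'   `"education"`, `"wealth"`, `"multiple"`, `"age"`, `"birth_order"`,
#'   `"interval"`, `"sex"`, `"worked"`. `"literacy"` and `"education"` are
#'   mutually exclusive (they are near-collinear codings of the same
#'   trait), as are `"birth_order"` and `"interval"` jointly with their
#'   shared first-birth category. Defaults depend on the outcome.
#' @param interactions subset of `"subsidy:rural"`, `"subsidy:wealth"`,
#'   `"subsidy:education"` (the last interacts subsidy with whichever of
#'   literacy/education is in the model).
#' @param random character subset of `"intercept"`, `"subsidy"`, `"time"`,
#'   `"post_time"`: the cluster-level random terms. `character(0)` gives a
#'   fixed-effects-only Poisson model.
#' @param woman_intercept logical; add a woman-level random intercept
#'   (three-level model).
#' @param seasonal logical; add calendar-month-of-birth dummies
#'   (reference January).
#' @param covariance `"unstructured"` or `"diagonal"` cluster random-effect
#'   covariance.
#' @param time_origin override the outcome's standard time origin (month
#'   index, 0 = Jan 2000).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("delivery", "mortality"),
                       covariates = NULL,
                       interactions = character(0),
                       random = c("intercept", "subsidy"),
                       woman_intercept = FALSE,
                       seasonal = FALSE,
                       covariance = c("unstructured", "diagonal"),
                       time_origin = NULL) {
  outcome <- match.arg(outcome)
  covariance <- match.arg(covariance)
  if (is.null(covariates)) {
    covariates <- if (outcome == "delivery")
      c("rural", "literacy", "wealth", "multiple", "age", "birth_order",
        "worked")
    else
      c("rural", "literacy", "wealth", "multiple", "age", "interval",
        "sex", "worked")
  }
  valid <- c("rural", "literacy", "education", "wealth", "multiple", "age",
             "birth_order", "interval", "sex", "worked")
  if (length(bad <- setdiff(covariates, valid)))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  if (all(c("literacy", "education") %in% covariates))
    stop("'literacy' and 'education' are mutually exclusive")
  if (all(c("birth_order", "interval") %in% covariates))
    stop(paste("'birth_order' and 'interval' share the first-birth",
               "category and are jointly aliased; include one"))
  valid_int <- c("subsidy:rural", "subsidy:wealth", "subsidy:education")
  if (length(bad <- setdiff(interactions, valid_int)))
    stop("unknown interaction(s): ", paste(bad, collapse = ", "))
  if ("subsidy:rural" %in% interactions && !("rural" %in% covariates))
    stop("subsidy:rural requires the rural covariate")
  random <- unique(random)
  if (length(bad <- setdiff(random, c("intercept", "subsidy", "time",
                                      "post_time"))))
    stop("unknown random term(s): ", paste(bad, collapse = ", "))
  if (length(random) && !("intercept" %in% random))
    stop("random coefficients require a random intercept")
  time_origin <- as.integer(time_origin %||%
    if (outcome == "delivery") MONTH_JUN2005 else MONTH_JAN2000)
  structure(list(outcome = outcome, covariates = covariates,
                 interactions = interactions, random = random,
                 woman_intercept = woman_intercept, seasonal = seasonal,
                 covariance = covariance, time_origin = time_origin),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Segmented modified-Poisson model spec\n")
  cat("  outcome:     ", x$outcome, " (time origin ",
      month_label(x$time_origin), ")\n", sep = "")
  cat("  covariates:  ", paste(x$covariates, collapse = ", "), "\n")
  if (length(x$interactions))
    cat("  interactions:", paste(x$interactions, collapse = ", "), "\n")
  cat("  random (cluster):", if (length(x$random))
    paste(x$random, collapse = ", ") else "none", "\n")
  if (x$woman_intercept) cat("  woman-level random intercept (3-level)\n")
  if (x$seasonal) cat("  seasonal calendar-month terms\n")
  invisible(x)
}

# Canonical model frame: one row per birth, canonical covariate codings.
design_frame <- function(records, spec, scenario) {
  if (!is.null(scenario$exclusion_window)) {
    ew <- scenario$exclusion_window
    if (any(records$birth_month >= ew[1] & records$birth_month <= ew[2]))
      stop("records inside the scenario exclusion window; apply_scenario() first")
  }
  exposed <- if (!is.null(records$exposed)) records$exposed
             else if (scenario$name == "oracle") as.integer(records$true_exposed)
             else as.integer(records$birth_month >= scenario$cutoff_month)
  data.frame(
    y = if (spec$outcome == "delivery") records$facility_delivery
        else records$neonatal_death,
    time = records$birth_month - spec$time_origin,
    subsidy = exposed,
    post_time = pmax(0L, records$birth_month - scenario$cutoff_month),
    rural = records$rural,
    illiterate = 1L - records$literate,
    education = factor(records$education, BIRTH_LEVELS$education),
    wealth = factor(c("poorest", "poorer", "middle", "richer",
                      "richest")[records$wealth_quintile],
                    c("poorest", "poorer", "middle", "richer", "richest")),
    multiple = records$multiple_birth,
    age = factor(records$mother_age_group, BIRTH_LEVELS$mother_age_group),
    birth_order = factor(records$birth_order_cat, BIRTH_LEVELS$birth_order_cat),
    interval = factor(records$preceding_interval_cat,
                      c("ge36", "lt36", "first")),
    female = records$newborn_female,
    worked = records$mother_worked,
    season = factor(records$calendar_month_of_year, levels = 1:12),
    cluster = records$cluster_id,
    woman = records$woman_id,
    region = records$region_id
  )
}

# Fixed-effects design matrix from a canonical frame. Reference categories:
# literate, no education, poorest, single, 15-19, first birth, >=36-month
# interval, male, not worked, January.
fixed_matrix <- function(df, spec) {
  cols <- list("(Intercept)" = rep(1, nrow(df)),
               time = df$time, subsidy = df$subsidy,
               post_time = df$post_time)
  for (cv in spec$covariates) {
    switch(cv,
      rural = { cols$rural <- df$rural },
      literacy = { cols$illiterate <- df$illiterate },
      education = {
        cols$educ_primary <- as.numeric(df$education == "primary")
        cols$educ_secondary <- as.numeric(df$education == "secondary+")
      },
      wealth = {
        for (lv in c("poorer", "middle", "richer", "richest"))
          cols[[paste0("wealth_", lv)]] <- as.numeric(df$wealth == lv)
      },
      multiple = { cols$multiple <- df$multiple },
      age = {
        for (lv in c("20-24", "25-29", "30-34", "35-39", "40-49"))
          cols[[paste0("age_", gsub("-", "_", lv))]] <-
            as.numeric(df$age == lv)
      },
      birth_order = {
        cols$order_2_4 <- as.numeric(df$birth_order == "2-4")
        cols$order_5p <- as.numeric(df$birth_order == "5+")
      },
      interval = {
        cols$interval_lt36 <- as.numeric(df$interval == "lt36")
        cols$interval_first <- as.numeric(df$interval == "first")
      },
      sex = { cols$female <- df$female },
      worked = { cols$worked <- df$worked })
  }
  for (ia in spec$interactions) {
    switch(ia,
      "subsidy:rural" = { cols$subsidy_rural <- df$subsidy * df$rural },
      "subsidy:wealth" = {
        for (lv in c("poorer", "middle", "richer", "richest"))
          cols[[paste0("subsidy_wealth_", lv)]] <-
            df$subsidy * as.numeric(df$wealth == lv)
      },
      "subsidy:education" = {
        if ("literacy" %in% spec$covariates) {
          cols$subsidy_illiterate <- df$subsidy * df$illiterate
        } else {
          cols$subsidy_educ_primary <-
            df$subsidy * as.numeric(df$education == "primary")
          cols$subsidy_educ_secondary <-
            df$subsidy * as.numeric(df$education == "secondary+")
        }
      })
  }
  if (spec$seasonal) {
    for (mm in 2:12)
      cols[[paste0("season_", mm)]] <- as.numeric(df$season == mm)
  }
  do.call(cbind, cols)
}

# Cluster-level random-effects design (columns in fixed order).
random_matrix <- function(df, spec) {
  if (!length(spec$random)) return(NULL)
  ord <- c("intercept", "time", "subsidy", "post_time")
  terms <- ord[ord %in% spec$random]
  Z <- sapply(terms, function(t)
    switch(t, intercept = rep(1, nrow(df)), time = df$time,
           subsidy = df$subsidy, post_time = df$post_time))
  Z <- matrix(Z, nrow = nrow(df), dimnames = list(NULL, terms))
  Z
}

#' Build the estimation design bundle
#'
#' Computes the segmented-regression time variables (`time` = months since
#' the outcome's origin; `post_time` = months since the scenario cutoff, 0
#' before it), assigns exposure per the scenario, and assembles the fixed
#' and random design matrices with the standard reference categories.
#'
#' @param records birth records (already scenario-filtered if the scenario
#'   excludes a window; an `exposed` column from [apply_scenario()] is
#'   honoured, otherwise exposure is derived from the cutoff).
#' @param spec a [model_spec()].
#' @param scenario an [exposure_scenario()].
#' @return an object of class `mpits_design`: list with `y`, `X`, `Z`,
#'   integer grouping vectors `cluster`, `woman`, `region`, the canonical
#'   frame `df`, and metadata.
#' @export
build_design <- function(records, spec, scenario) {
  stopifnot(inherits(spec, "model_spec"), inherits(scenario, "exposure_scenario"))
  df <- design_frame(records, spec, scenario)
  X <- fixed_matrix(df, spec)
  Z <- random_matrix(df, spec)
  structure(list(
    y = df$y,
    X = X,
    Z = Z,
    cluster = match(df$cluster, sort(unique(df$cluster))),
    cluster_ids = sort(unique(df$cluster)),
    woman = if (spec$woman_intercept)
      match(df$woman, sort(unique(df$woman))) else NULL,
    woman_ids = if (spec$woman_intercept) sort(unique(df$woman)) else NULL,
    region = df$region,
    df = df,
    spec = spec,
    scenario = scenario,
    n = nrow(df)
  ), class = "mpits_design")
}
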