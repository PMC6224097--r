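# Synthetic DHS-like population generator.
#
# Records emulate a women's-recode birth history: live births nested in
# women, households, enumeration clusters and regions, with facility-delivery
# and neonatal-death outcomes drawn from a segmented log-rate model with
# cluster-level random intercepts and random coefficients.

#' Default covariate margins for the synthetic population
#'
#' Target category proportions for the directly assigned covariates, chosen
#' to match the published descriptive profile of live births in Burkina Faso
#' 2000-2010 (about 79% rural, 86-89% illiterate mothers, near-uniform
#' wealth quintiles, 3.5% multiple births, 51% boys).
#'
#' @return a named list of proportion vectors.
#' @export
default_margins <- function() {
  list(
    rural = 0.793,
    wealth = c(poorest = 0.206, poorer = 0.213, middle = 0.217,
               richer = 0.214, richest = 0.150),
    education = c(none = 0.857, primary = 0.099, `secondary+` = 0.044),
    # P(literate | education); implies a marginal literacy of about 12%
    literate_by_education = c(none = 0.035, primary = 0.50,
                              `secondary+` = 0.95),
    worked = 0.809,
    male = 0.512,
    multiple = 0.035
  )
}

#' Default generative coefficients for the two outcomes
#'
#' Log-rate model coefficients for facility delivery and neonatal death.
#' The delivery values are motivated by published stratum fits (urban
#' intercept about -0.54, rural deficit -0.38, immediate subsidy effect
#' 0.039 urban and 0.139 rural, i.e. a subsidy-by-rural interaction of
#' 0.100); the mortality values encode a baseline neonatal mortality near
#' 4%, a gentle secular decline and a modest immediate subsidy effect
#' (rate ratio about 0.93) that grows with time since introduction.
#'
#' @return a list with elements `delivery` and `mortality`, each a named
#'   numeric vector of generator coefficients.
#' @export
default_true_beta <- function() {
  list(
    delivery = c(
      intercept = -0.5405, time = 0.0040, subsidy = 0.0386,
      post_time = 0.0025, rural = -0.3829, illiterate = -0.08,
      wealth_poorer = 0.15, wealth_middle = 0.22, wealth_richer = 0.28,
      wealth_richest = 0.33, multiple = 0.08,
      age_20_24 = -0.02, age_25_29 = -0.02, age_30_34 = -0.01,
      age_35_39 = 0.00, age_40_49 = 0.00,
      order_2_4 = -0.07, order_5p = -0.10, interval_lt36 = 0.00,
      worked = 0.08, female = 0.00,
      subsidy_rural = 0.1002, subsidy_wealth = 0.00,
      subsidy_illiterate = 0.00),
    mortality = c(
      intercept = -3.35, time = -0.0030, subsidy = -0.073,
      post_time = -0.0064, rural = 0.15, illiterate = 0.15,
      wealth_poorer = -0.05, wealth_middle = -0.08, wealth_richer = -0.10,
      wealth_richest = -0.15, multiple = 1.00,
      age_20_24 = -0.25, age_25_29 = -0.25, age_30_34 = -0.15,
      age_35_39 = 0.00, age_40_49 = 0.25,
      order_2_4 = -0.20, order_5p = 0.00, interval_lt36 = 0.25,
      worked = 0.00, female = -0.10,
      subsidy_rural = 0.00, subsidy_wealth = 0.00,
      subsidy_illiterate = 0.00)
  )
}

#' Default random-effect variances for the two outcomes
#'
#' Cluster-level variances for the random intercept, random subsidy
#' coefficient and random time slope, plus a woman-level intercept
#' variance. Delivery defaults follow the published rural random parts
#' (intercept 0.7682, subsidy 0.0819) with no woman-level variance (none
#' was found in the source analysis); the per-month time-slope variance
#' defaults to zero because heterogeneity of the printed magnitude
#' degenerates under a log link over a five-year horizon. Mortality
#' defaults are modest cluster and woman intercept variances.
#'
#' @return list with elements `delivery` and `mortality`, each a named
#'   vector `c(intercept, subsidy, time, woman)` of variances.
#' @export
default_true_psi <- function() {
  list(
    delivery  = c(intercept = 0.7682, subsidy = 0.0819, time = 0,
                  woman = 0),
    mortality = c(intercept = 0.15, subsidy = 0, time = 0, woman = 0.20)
  )
}

#' Configuration of the synthetic population
#'
#' Collects every knob of the generative model. The defaults describe the
#' emulated survey: roughly 550 clusters in 13 regions observed January
#' 2000 - December 2010, about 12,500 women bearing around 32,000 live
#' births (1-8 per woman, median 3), subsidy introduced January 2007 with
#' an optional staggered rollout of up to 3 months.
#'
#' @param n_regions,n_clusters counts of regions and enumeration clusters.
#' @param mean_households_per_cluster Poisson mean of households sampled
#'   per cluster.
#' @param women_per_household_probs probabilities for 1,2,... women with a
#'   birth history per household.
#' @param births_per_woman_probs probabilities for 1..8 in-window births
#'   per woman; the default has median 3.
#' @param prior_parity_probs probabilities for 0,1,... births a woman had
#'   before the observation window (drives the birth-order mix).
#' @param observation_window integer months `c(start, end)` (0 = Jan 2000).
#' @param survey_month month the survey is taken (defines the 5- and
#'   10-year recall windows).
#' @param subsidy_month official introduction month of the subsidy.
#' @param rollout_spread_months 0-3; with a positive spread each cluster's
#'   actual introduction month is drawn uniformly from
#'   `subsidy_month + 0:rollout_spread_months`, so calendar-based exposure
#'   misclassifies some births near the cutoff.
#' @param seasonal_multipliers length-12 positive weights modulating the
#'   month-of-year of first births (default flat).
#' @param covariate_margins see [default_margins()].
#' @param true_beta see [default_true_beta()].
#' @param true_psi see [default_true_psi()].
#' @param psi_correlation correlation between the cluster random intercept
#'   and random subsidy coefficient; the default -0.9 encodes the finding
#'   that low-uptake clusters gained most from the subsidy (a correlation
#'   near -1). Exactly -1 yields a rank-deficient but valid covariance.
#' @param time_origin named integer vector: month at which the secular
#'   time variable is zero for each outcome (delivery counts from June
#'   2005, mortality from January 2000).
#' @param interval_shape,interval_scale gamma parameters of the
#'   (9 months + gamma) inter-birth interval distribution.
#' @param age_first_birth_shape,age_first_birth_scale gamma parameters of
#'   the (15 years + gamma) maternal age at first birth.
#' @param twin_prob probability a delivery is a twin delivery.
#' @param max_truncation_fraction generation uses a log link, so implied
#'   rates above 1 are truncated before the Bernoulli draw; a warning is
#'   issued when the truncated fraction exceeds this threshold.
#' @param seed master integer seed; all internal streams derive from it.
#' @return an object of class `population_config` (a validated list).
#' @export
population_config <- function(n_regions = 13L,
                              n_clusters = 550L,
                              mean_households_per_cluster = 15.3,
                              women_per_household_probs = c(0.82, 0.13, 0.04, 0.01),
                              births_per_woman_probs = c(0.18, 0.27, 0.22, 0.14,
                                                         0.09, 0.05, 0.03, 0.02),
                              prior_parity_probs = c(0.60, 0.12, 0.10, 0.08,
                                                     0.06, 0.04),
                              observation_window = c(0L, 131L),
                              survey_month = 131L,
                              subsidy_month = 84L,
                              rollout_spread_months = 0L,
                              seasonal_multipliers = rep(1, 12),
                              covariate_margins = default_margins(),
                              true_beta = default_true_beta(),
                              true_psi = default_true_psi(),
                              psi_correlation = -0.9,
                              time_origin = c(delivery = 65L, mortality = 0L),
                              interval_shape = 1.9,
                              interval_scale = 19,
                              age_first_birth_shape = 4.6,
                              age_first_birth_scale = 1.05,
                              twin_prob = 0.0178,
                              max_truncation_fraction = 0.25,
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "population_config")
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  stopifnot(cfg$n_regions >= 1, cfg$n_clusters >= cfg$n_regions)
  for (nm in c("women_per_household_probs", "births_per_woman_probs",
               "prior_parity_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("'%s' must be non-negative and sum to 1", nm))
  }
  m <- cfg$covariate_margins
  for (nm in c("wealth", "education")) {
    if (abs(sum(m[[nm]]) - 1) > 1e-9)
      stop(sprintf("covariate margin '%s' must sum to 1", nm))
  }
  for (nm in c("rural", "worked", "male", "multiple")) {
    if (m[[nm]] < 0 || m[[nm]] > 1)
      stop(sprintf("covariate margin '%s' must be in [0,1]", nm))
  }
  if (any(m$literate_by_education < 0) || any(m$literate_by_education > 1))
    stop("literate_by_education must be probabilities")
  w <- cfg$observation_window
  stopifnot(length(w) == 2L, w[1] < w[2])
  if (cfg$subsidy_month < w[1] || cfg$subsidy_month > w[2])
    stop("subsidy_month must lie inside the observation window")
  if (cfg$rollout_spread_months < 0)
    stop("rollout_spread_months must be >= 0")
  if (abs(cfg$psi_correlation) > 1)
    stop("psi_correlation must be in [-1, 1]")
  for (oc in c("delivery", "mortality")) {
    psi <- cfg$true_psi[[oc]]
    if (any(psi < 0)) stop("variance components must be non-negative")
    if (!is_psd(psi_matrix(psi, cfg$psi_correlation)))
      stop(sprintf("true_psi for '%s' is not positive semi-definite", oc))
  }
  invisible(cfg)
}

# Cluster-level covariance of (intercept, subsidy, time) random effects.
psi_matrix <- function(psi, rho) {
  s <- sqrt(psi[c("intercept", "subsidy", "time")])
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- rho
  diag(s) %*% S %*% diag(s)
}

# Draw from N(0, Sigma) allowing rank-deficient Sigma (eigen square root).
rmvnorm_psd <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  M <- e$vectors %*% (t(e$vectors) * sqrt(ev))
  matrix(rnorm(n * ncol(Sigma)), n) %*% t(M)
}

#' Generate a synthetic hierarchical birth-record table
#'
#' Draws the full nested structure (region > cluster > household > woman >
#' birth), assigns covariates to match the configured margins, and
#' generates both outcomes from the segmented log-rate model
#' \eqn{\log \mu = (\beta_0+\gamma_{0jk}+\gamma_{00k}) +
#' (\beta_1+\gamma_{1k}) T + (\beta_2+\gamma_{2k}) I +
#' (\beta_3+\gamma_{3k}) \mathrm{posttime} + \beta' X}
#' with per-birth rates truncated into (0,1) before the Bernoulli draw.
#'
#' @param config a [population_config()].
#' @return a data frame of birth records (one row per live birth) with the
#'   documented column contract plus the generator-only column
#'   `true_exposed`. Generator truth (coefficients, random effects,
#'   truncation counts, seed) is attached as attribute `"truth"`.
#' @export
generate_population <- function(config) {
  validate_population_config(config)
  set.seed(derive_seed(config$seed, 1L))
  m <- config$covariate_margins
  win <- config$observation_window
  win_len <- win[2] - win[1] + 1L

  ## --- clusters ---------------------------------------------------------
  K <- config$n_clusters
  region_id <- sort(rep_len(seq_len(config$n_regions), K))
  rural_k <- integer(K)
  for (r in seq_len(config$n_regions)) {
    idx <- which(region_id == r)
    rural_k[idx] <- as.integer(
      sample_composition(length(idx), c("1", "0"),
                         c(m$rural, 1 - m$rural)))
  }
  rollout_k <- config$subsidy_month +
    sample.int(config$rollout_spread_months + 1L, K, replace = TRUE) - 1L

  ## --- households and women --------------------------------------------
  n_hh_k <- pmax(1L, rpois(K, config$mean_households_per_cluster))
  H <- sum(n_hh_k)
  hh_cluster <- rep(seq_len(K), n_hh_k)
  hh_wealth <- as.integer(sample_composition(H, as.character(1:5), m$wealth))
  n_w_h <- sample.int(length(config$women_per_household_probs), H,
                      replace = TRUE, prob = config$women_per_household_probs)
  W <- sum(n_w_h)
  w_household <- rep(seq_len(H), n_w_h)
  w_cluster <- hh_cluster[w_household]

  w_educ <- sample_composition(W, names(m$education), m$education)
  w_lit <- integer(W)
  for (ed in names(m$education)) {
    idx <- which(w_educ == ed)
    p <- m$literate_by_education[[ed]]
    w_lit[idx] <- as.integer(
      sample_composition(length(idx), c("1", "0"), c(p, 1 - p)))
  }
  w_worked <- as.integer(
    sample_composition(W, c("1", "0"), c(m$worked, 1 - m$worked)))

  ## --- birth histories ---------------------------------------------------
  n_b_w <- sample.int(8L, W, replace = TRUE,
                      prob = config$births_per_woman_probs)
  prior_parity <- sample.int(length(config$prior_parity_probs), W,
                             replace = TRUE,
                             prob = config$prior_parity_probs) - 1L
  age_ffb <- 15 + rgamma(W, config$age_first_birth_shape,
                         scale = config$age_first_birth_scale)

  seas <- config$seasonal_multipliers / sum(config$seasonal_multipliers)

  B <- sum(n_b_w)
  b_woman <- rep(seq_len(W), n_b_w)
  b_index <- sequence(n_b_w)              # 1..B_w within woman
  # inter-birth intervals (months); first slot of each woman unused
  gaps <- 9 + rgamma(B, config$interval_shape, scale = config$interval_scale)
  gaps[b_index == 1L] <- 0
  span_w <- rowsum(gaps, b_woman)[, 1]
  # compress histories that do not fit into the window
  too_long <- span_w > (win_len - 1)
  if (any(too_long)) {
    shrink <- (win_len - 1) / span_w
    gaps <- gaps * ifelse(too_long[b_woman], shrink[b_woman], 1)
    span_w <- pmin(span_w, win_len - 1)
  }
  # month-of-year weights for the first birth placement
  slack <- floor(win_len - 1 - span_w)
  first_month <- integer(W)
  u <- runif(W)
  for (wi in seq_len(W)) {
    cand <- win[1] + 0:slack[wi]
    wt <- seas[cand %% 12L + 1L]
    first_month[wi] <- cand[findInterval(u[wi] * sum(wt), cumsum(wt)) + 1L]
  }
  cum_gap <- ave(gaps, b_woman, FUN = cumsum)
  birth_month <- as.integer(round(first_month[b_woman] + cum_gap))
  birth_month <- pmin(pmax(birth_month, win[1]), win[2])

  # maternal age: one date of birth per mother drives every birth's age
  pre_gap_years <- prior_parity * (9 + config$interval_shape *
                                     config$interval_scale) / 12
  age_fib <- age_ffb + pre_gap_years          # age at first in-window birth
  mother_dob <- first_month - age_fib * 12
  age_at_birth <- (birth_month - mother_dob[b_woman]) / 12
  age_grp <- cut(pmin(pmax(age_at_birth, 15), 49.99),
                 breaks = c(15, 20, 25, 30, 35, 40, 50),
                 labels = c("15-19", "20-24", "25-29", "30-34", "35-39",
                            "40-49"),
                 right = FALSE, include.lowest = TRUE)

  birth_order <- prior_parity[b_woman] + b_index
  order_cat <- cut(birth_order, c(0, 1, 4, Inf), labels = c("first", "2-4", "5+"))
  # preceding interval category; first in-window birth of a parous woman
  # gets an imputed (unobserved) pre-window interval
  gap_prev <- gaps
  parous_first <- b_index == 1L & prior_parity[b_woman] > 0L
  gap_prev[parous_first] <- 9 + rgamma(sum(parous_first),
                                       config$interval_shape,
                                       scale = config$interval_scale)
  interval_cat <- ifelse(birth_order == 1L, "first",
                         ifelse(gap_prev < 36, "lt36", "ge36"))

  ## --- twins -------------------------------------------------------------
  is_twin_delivery <- runif(B) < config$twin_prob
  rep_idx <- rep(seq_len(B), times = 1L + is_twin_delivery)
  multiple <- as.integer(is_twin_delivery[rep_idx])
  n <- length(rep_idx)

  rec <- data.frame(
    region_id = region_id[w_cluster[b_woman[rep_idx]]],
    cluster_id = w_cluster[b_woman[rep_idx]],
    household_id = w_household[b_woman[rep_idx]],
    woman_id = b_woman[rep_idx],
    birth_id = seq_len(n),
    birth_month = birth_month[rep_idx],
    calendar_month_of_year = birth_month[rep_idx] %% 12L + 1L,
    rural = rural_k[w_cluster[b_woman[rep_idx]]],
    wealth_quintile = hh_wealth[w_household[b_woman[rep_idx]]],
    education = w_educ[b_woman[rep_idx]],
    literate = w_lit[b_woman[rep_idx]],
    mother_age_group = as.character(age_grp[rep_idx]),
    multiple_birth = multiple,
    birth_order_cat = as.character(order_cat[rep_idx]),
    preceding_interval_cat = interval_cat[rep_idx],
    mother_worked = w_worked[b_woman[rep_idx]],
    newborn_female = as.integer(runif(n) >= m$male),
    stringsAsFactors = FALSE
  )

  ## --- exposure under the (possibly staggered) rollout --------------------
  roll <- rollout_k[rec$cluster_id]
  rec$true_exposed <- as.integer(rec$birth_month >= roll)
  post_true <- pmax(0L, rec$birth_month - roll)

  ## --- outcomes ----------------------------------------------------------
  re <- list()
  trunc_counts <- c(delivery = 0L, mortality = 0L)
  set.seed(derive_seed(config$seed, 2L))
  for (oc in c("delivery", "mortality")) {
    psi <- config$true_psi[[oc]]
    G <- rmvnorm_psd(K, psi_matrix(psi, config$psi_correlation))
    colnames(G) <- c("intercept", "subsidy", "time")
    u_w <- rnorm(W, 0, sqrt(psi[["woman"]]))
    re[[oc]] <- list(cluster = G, woman = u_w)

    beta <- config$true_beta[[oc]]
    Tm <- rec$birth_month - config$time_origin[[oc]]
    eta <- beta[["intercept"]] + G[rec$cluster_id, "intercept"] +
      u_w[rec$woman_id] +
      (beta[["time"]] + G[rec$cluster_id, "time"]) * Tm +
      (beta[["subsidy"]] + G[rec$cluster_id, "subsidy"]) * rec$true_exposed +
      beta[["post_time"]] * post_true +
      beta[["rural"]] * rec$rural +
      beta[["illiterate"]] * (1 - rec$literate) +
      c(0, beta[["wealth_poorer"]], beta[["wealth_middle"]],
        beta[["wealth_richer"]], beta[["wealth_richest"]])[rec$wealth_quintile] +
      beta[["multiple"]] * rec$multiple_birth +
      unname(c(`15-19` = 0, `20-24` = beta[["age_20_24"]],
               `25-29` = beta[["age_25_29"]], `30-34` = beta[["age_30_34"]],
               `35-39` = beta[["age_35_39"]], `40-49` = beta[["age_40_49"]]
               )[rec$mother_age_group]) +
      unname(c(first = 0, `2-4` = beta[["order_2_4"]],
               `5+` = beta[["order_5p"]])[rec$birth_order_cat]) +
      beta[["interval_lt36"]] * (rec$preceding_interval_cat == "lt36") +
      beta[["worked"]] * rec$mother_worked +
      beta[["female"]] * rec$newborn_female +
      beta[["subsidy_rural"]] * rec$true_exposed * rec$rural +
      beta[["subsidy_wealth"]] * rec$true_exposed * (rec$wealth_quintile - 1) +
      beta[["subsidy_illiterate"]] * rec$true_exposed * (1 - rec$literate)

    rate <- exp(eta)
    n_trunc <- sum(rate > 1 - 1e-9)
    trunc_counts[[oc]] <- n_trunc
    rate <- pmin(rate, 1 - 1e-9)
    y <- rbinom(n, 1L, rate)
    if (oc == "delivery") {
      # twins are one delivery: both records share the delivery outcome
      first_of_delivery <- !duplicated(rep_idx)
      y <- y[first_of_delivery][match(rep_idx, rep_idx[first_of_delivery])]
    }
    rec[[if (oc == "delivery") "facility_delivery" else "neonatal_death"]] <- y
    if (n_trunc / n > config$max_truncation_fraction)
      warning(sprintf(
        "%s: %d of %d implied rates (%.1f%%) exceeded 1 and were truncated",
        oc, n_trunc, n, 100 * n_trunc / n))
  }

  ord <- c("region_id", "cluster_id", "household_id", "woman_id", "birth_id",
           "birth_month", "calendar_month_of_year", "facility_delivery",
           "neonatal_death", "rural", "wealth_quintile", "education",
           "literate", "mother_age_group", "multiple_birth",
           "birth_order_cat", "preceding_interval_cat", "mother_worked",
           "newborn_female", "true_exposed")
  rec <- rec[, ord]
  attr(rec, "truth") <- list(
    seed = config$seed,
    true_beta = config$true_beta,
    true_psi = config$true_psi,
    psi_correlation = config$psi_correlation,
    time_origin = config$time_origin,
    subsidy_month = config$subsidy_month,
    rollout_month = rollout_k,
    random_effects = re,
    truncated = trunc_counts,
    margins = m
  )
  rec
}

#' Generator-truth marginal effect of the subsidy
#'
#' Monte-Carlo oracle for the standardization machinery: regenerates a
#' population from `config` on an independent random stream, computes each
#' birth's generator-truth rate at the given post-policy horizon with the
#' subsidy switched on and off (time set to the policy-timeline value,
#' post-time to the horizon), and averages. No model fitting is involved.
#'
#' @param config a [population_config()].
#' @param horizon_months months since introduction, 0-42.
#' @param outcome `"delivery"` or `"mortality"`.
#' @param stream sub-stream offset; use different values for independent
#'   replications.
#' @return list with `rr`, `rd`, `rate1`, `rate0`, Monte-Carlo standard
#'   errors `rr_se` and `rd_se` (delta method over the paired per-birth
#'   rates), and `n` births used.
#' @export
true_marginal_effect <- function(config, horizon_months, outcome,
                                 stream = 11L) {
  stopifnot(horizon_months >= 0, horizon_months <= 42)
  outcome <- match.arg(outcome, c("delivery", "mortality"))
  cfg <- config
  cfg$seed <- derive_seed(config$seed, stream)
  rec <- generate_population(cfg)
  truth <- attr(rec, "truth")
  G <- truth$random_effects[[outcome]]$cluster
  u_w <- truth$random_effects[[outcome]]$woman
  beta <- config$true_beta[[outcome]]

  Tstar <- (config$subsidy_month - config$time_origin[[outcome]]) +
    horizon_months
  base <- beta[["intercept"]] + G[rec$cluster_id, "intercept"] +
    u_w[rec$woman_id] +
    (beta[["time"]] + G[rec$cluster_id, "time"]) * Tstar +
    beta[["rural"]] * rec$rural +
    beta[["illiterate"]] * (1 - rec$literate) +
    c(0, beta[["wealth_poorer"]], beta[["wealth_middle"]],
      beta[["wealth_richer"]], beta[["wealth_richest"]])[rec$wealth_quintile] +
    beta[["multiple"]] * rec$multiple_birth +
    unname(c(`15-19` = 0, `20-24` = beta[["age_20_24"]],
             `25-29` = beta[["age_25_29"]], `30-34` = beta[["age_30_34"]],
             `35-39` = beta[["age_35_39"]], `40-49` = beta[["age_40_49"]]
             )[rec$mother_age_group]) +
    unname(c(first = 0, `2-4` = beta[["order_2_4"]],
             `5+` = beta[["order_5p"]])[rec$birth_order_cat]) +
    beta[["interval_lt36"]] * (rec$preceding_interval_cat == "lt36") +
    beta[["worked"]] * rec$mother_worked +
    beta[["female"]] * rec$newborn_female

  eff1 <- (beta[["subsidy"]] + G[rec$cluster_id, "subsidy"]) +
    beta[["post_time"]] * horizon_months +
    beta[["subsidy_rural"]] * rec$rural +
    beta[["subsidy_wealth"]] * (rec$wealth_quintile - 1) +
    beta[["subsidy_illiterate"]] * (1 - rec$literate)

  r1 <- pmin(exp(base + eff1), 1 - 1e-9)
  r0 <- pmin(exp(base), 1 - 1e-9)
  n <- length(r1)
  m1 <- mean(r1); m0 <- mean(r0)
  # births within a cluster share random effects, so the Monte-Carlo
  # variance of the means is taken over cluster totals (iid units)
  s1 <- drop(rowsum(r1, rec$cluster_id))
  s0 <- drop(rowsum(r0, rec$cluster_id))
  Kc <- length(s1)
  v1 <- Kc * var(s1) / n^2; v0 <- Kc * var(s0) / n^2
  cv <- Kc * cov(s1, s0) / n^2
  rr <- m1 / m0
  # the bracket is exactly zero (up to rounding) when the subsidy scales
  # every rate by the same factor, so clamp before the square root
  rr_se <- rr * sqrt(max(0, v1 / m1^2 + v0 / m0^2 - 2 * cv / (m1 * m0)))
  rd_se <- sqrt(max(0, v1 + v0 - 2 * cv))
  list(rr = rr, rd = m1 - m0, rate1 = m1, rate0 = m0,
       rr_se = rr_se, rd_se = rd_se, n = n)
}
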