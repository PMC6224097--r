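# Synthetic population generator.

test_that("config validation rejects bad inputs", {
  expect_error(population_config(subsidy_month = 200L), "inside")
  expect_error(population_config(psi_correlation = -1.2), "psi_correlation")
  bad_m <- default_margins(); bad_m$wealth <- c(0.5, 0.5, 0.5, 0.2, 0.1)
  expect_error(population_config(covariate_margins = bad_m), "sum to 1")
  tp <- default_true_psi(); tp$delivery[["intercept"]] <- -1
  expect_error(population_config(true_psi = tp), "non-negative")
})

test_that("an exact -1 intercept-subsidy correlation is accepted (rank-deficient PSD)", {
  cfg <- population_config(n_clusters = 20, n_regions = 2,
                           mean_households_per_cluster = 4,
                           psi_correlation = -1, seed = 2)
  rec <- suppressWarnings(generate_population(cfg))
  tr <- attr(rec, "truth")
  G <- tr$random_effects$delivery$cluster
  # effects lie exactly on a line: correlation -1
  expect_equal(unname(cor(G[, "intercept"], G[, "subsidy"])), -1,
               tolerance = 1e-10)
})

test_that("identical seeds give byte-identical record sets", {
  cfg <- small_config(seed = 7)
  r1 <- suppressWarnings(generate_population(cfg))
  r2 <- suppressWarnings(generate_population(cfg))
  expect_identical(r1, r2)
  r3 <- suppressWarnings(generate_population(small_config(seed = 8)))
  expect_false(identical(r1$facility_delivery, r3$facility_delivery))
})

test_that("directly assigned covariate margins are reproduced", {
  cfg <- population_config(seed = 31)   # full scale, ~32k births
  rec <- suppressWarnings(generate_population(cfg))
  m <- cfg$covariate_margins
  n <- nrow(rec)
  bse <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(rec$rural) - m$rural), 0.01)       # table-margin check
  expect_lt(abs(mean(rec$rural) - m$rural), 3 * max(bse(m$rural), 0.004))
  for (q in 1:5)
    expect_lt(abs(mean(rec$wealth_quintile == q) - m$wealth[q]),
              3 * max(bse(m$wealth[q]), 0.004))
  for (ed in names(m$education))
    expect_lt(abs(mean(rec$education == ed) - m$education[ed]),
              3 * max(bse(m$education[ed]), 0.004))
  p_lit <- sum(m$education * m$literate_by_education)
  expect_lt(abs(mean(rec$literate) - p_lit), 3 * max(bse(p_lit), 0.004))
  expect_lt(abs(mean(rec$mother_worked) - m$worked),
            3 * max(bse(m$worked), 0.004))
  expect_lt(abs(mean(rec$newborn_female) - (1 - m$male)), 3 * bse(m$male))
  expect_lt(abs(mean(rec$multiple_birth) - m$multiple),
            3 * max(bse(m$multiple), 0.004))
})

test_that("nesting is strict and ids are conserved", {
  rec <- suppressWarnings(generate_population(small_config(seed = 3)))
  # each woman in exactly one household, each household in one cluster,
  # each cluster in one region
  expect_true(all(tapply(rec$household_id, rec$woman_id,
                         function(x) length(unique(x))) == 1))
  expect_true(all(tapply(rec$cluster_id, rec$household_id,
                         function(x) length(unique(x))) == 1))
  expect_true(all(tapply(rec$region_id, rec$cluster_id,
                         function(x) length(unique(x))) == 1))
  expect_identical(nrow(rec), sum(table(rec$woman_id)))
  # first birth iff first preceding-interval category
  expect_identical(rec$birth_order_cat == "first",
                   rec$preceding_interval_cat == "first")
})

test_that("maternal age group is non-decreasing over a woman's births", {
  rec <- suppressWarnings(generate_population(small_config(seed = 4)))
  lv <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-49")
  ok <- tapply(seq_len(nrow(rec)), rec$woman_id, function(idx) {
    o <- idx[order(rec$birth_month[idx])]
    ages <- match(rec$mother_age_group[o], lv)
    all(diff(ages) >= 0)
  })
  expect_true(all(ok))
})

test_that("null model reproduces exp(beta0) and the secular-trend-only case matches closed form", {
  cfg <- flat_config(seed = 5, n_clusters = 100, n_regions = 10,
                     mean_households_per_cluster = 10)
  rec <- generate_population(cfg)
  p0 <- 0.4
  se <- sqrt(p0 * (1 - p0) / nrow(rec))
  expect_lt(abs(mean(rec$facility_delivery) - p0), 3 * se)

  # beta2 = 0, psi22 = 0, beta3 = 0: pre/post rates differ only via the
  # secular trend exp(beta1 * T)
  cfg2 <- flat_config(seed = 6, delivery = c(time = 0.004),
                      n_clusters = 100, n_regions = 10,
                      mean_households_per_cluster = 10)
  rec2 <- generate_population(cfg2)
  tm <- rec2$birth_month - cfg2$time_origin[["delivery"]]
  expected <- 0.4 * exp(0.004 * tm)
  post <- rec2$birth_month >= cfg2$subsidy_month
  for (grp in list(post, !post)) {
    p_exp <- mean(expected[grp])
    se_g <- sqrt(p_exp * (1 - p_exp) / sum(grp))
    expect_lt(abs(mean(rec2$facility_delivery[grp]) - p_exp), 3.5 * se_g)
  }
})

test_that("staggered rollout misclassifies some cutoff-quarter births and only those", {
  cfg <- population_config(n_clusters = 200, n_regions = 10,
                           mean_households_per_cluster = 8,
                           rollout_spread_months = 3L, seed = 9)
  rec <- suppressWarnings(generate_population(cfg))
  primary <- as.integer(rec$birth_month >= cfg$subsidy_month)
  dis <- rec$true_exposed != primary
  inwin <- rec$birth_month >= cfg$subsidy_month &
    rec$birth_month < cfg$subsidy_month + 3L
  expect_gt(sum(dis), 0)
  expect_true(all(inwin[dis]))                 # disagreements only there
  expect_lte(sum(dis), sum(inwin))
  # no rollout spread: perfect agreement
  cfg0 <- population_config(n_clusters = 50, n_regions = 5,
                            mean_households_per_cluster = 5,
                            rollout_spread_months = 0L, seed = 9)
  rec0 <- suppressWarnings(generate_population(cfg0))
  expect_identical(rec0$true_exposed,
                   as.integer(rec0$birth_month >= cfg0$subsidy_month))
})

test_that("true marginal effect: null and closed-form cases", {
  cfg <- flat_config(seed = 10, n_clusters = 60, n_regions = 6)
  tme <- true_marginal_effect(cfg, 0, "delivery")
  expect_equal(tme$rr, 1.0, tolerance = 1e-12)
  expect_equal(tme$rd, 0.0, tolerance = 1e-12)

  cfg2 <- flat_config(seed = 10, n_clusters = 1, n_regions = 1,
                      delivery = c(subsidy = log(1.12)))
  for (h in c(0, 18, 42)) {
    tme2 <- true_marginal_effect(cfg2, h, "delivery")
    expect_equal(tme2$rr, 1.12, tolerance = 1e-12)
  }
})

test_that("true marginal effect on a heterogeneous config matches an independent replication", {
  tb <- default_true_beta()
  tb$delivery[["subsidy"]] <- 0.14
  tp <- default_true_psi()
  tp$delivery <- c(intercept = 0.2, subsidy = 0.03, time = 0, woman = 0)
  cfg <- population_config(n_clusters = 150, n_regions = 10,
                           mean_households_per_cluster = 10,
                           true_beta = tb, true_psi = tp, seed = 12)
  a <- true_marginal_effect(cfg, 6, "delivery", stream = 11L)
  b <- true_marginal_effect(cfg, 6, "delivery", stream = 77L)
  expect_lt(abs(a$rr - b$rr), 2 * sqrt(a$rr_se^2 + b$rr_se^2) + 1e-9)
})
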