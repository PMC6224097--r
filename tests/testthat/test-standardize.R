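# Model-based standardization and delta-method intervals.

fit_flat <- function(seed = 50, delivery = c(subsidy = log(1.2)),
                     n_clusters = 40) {
  cfg <- flat_config(seed = seed, delivery = delivery,
                     n_clusters = n_clusters, n_regions = 4,
                     mean_households_per_cluster = 8)
  rec <- generate_population(cfg)
  sp <- model_spec("delivery", covariates = character(0),
                   random = character(0))
  mpits(rec, sp, control = mpits_control(se = TRUE))
}

test_that("homogeneous population: standardization equals the closed form", {
  fit <- fit_flat()
  b <- fit$beta
  g <- standardize_rates(fit, horizons = c(0, 12, 42))
  Tstar <- (84 - 65) + c(0, 12, 42)
  r0 <- exp(b[["(Intercept)"]] + b[["time"]] * Tstar)
  r1 <- exp(b[["(Intercept)"]] + b[["time"]] * Tstar + b[["subsidy"]] +
              b[["post_time"]] * c(0, 12, 42))
  expect_equal(g$rate0, unname(r0), tolerance = 1e-12)
  expect_equal(g$rate1, unname(r1), tolerance = 1e-12)
  expect_equal(g$rr, unname(r1 / r0), tolerance = 1e-12)
  expect_equal(g$rd, unname(r1 - r0), tolerance = 1e-12)
  # rates and per-record predictions line up exactly
  pr <- predict_rate(fit, 1, 0)
  expect_lt(max(abs(pr - r1[1])), 1e-12)
})

test_that("per-record counterfactual rate equals hand-computed exp(x'b + z'g)", {
  rec <- suppressWarnings(generate_population(small_config(seed = 51)))
  sp <- model_spec("delivery", covariates = c("rural", "wealth"),
                   random = "intercept")
  fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
  eb <- eb_predict(fit)
  h <- 18
  pr <- predict_rate(fit, 1, h)
  d <- fit$design
  X2 <- d$X
  X2[, "time"] <- (84 - 65) + h
  X2[, "subsidy"] <- 1
  X2[, "post_time"] <- h
  gam <- eb$cluster$intercept[match(d$df$cluster, eb$cluster$cluster_id)]
  by_hand <- pmin(exp(drop(X2 %*% fit$beta) + gam), 1)
  expect_lt(max(abs(pr - by_hand)), 1e-12)
})

test_that("a null subsidy effect predicts identical rates under both scenarios", {
  fit <- fit_flat(seed = 52)
  fit$beta["subsidy"] <- 0
  fit$beta["post_time"] <- 0
  for (h in c(0, 24, 42))
    expect_equal(as.numeric(predict_rate(fit, 1, h)),
                 as.numeric(predict_rate(fit, 0, h)), tolerance = 1e-15)
})

test_that("RR is strictly increasing in the horizon when the slope change is positive", {
  fit <- fit_flat(seed = 53)
  fit$beta["subsidy"] <- 0.05
  fit$beta["post_time"] <- 0.01
  g <- standardize_rates(fit, horizons = seq(0, 42, 6), ci = FALSE)
  expect_identical(sum(g$n_capped), 0)
  expect_true(all(diff(g$rr) > 0))
})

test_that("standardization is deterministic and symmetric under coding swap", {
  fit <- fit_flat(seed = 54)
  g1 <- standardize_rates(fit, horizons = seq(0, 42, 6))
  g2 <- standardize_rates(fit, horizons = seq(0, 42, 6))
  expect_identical(g1, g2)
  for (h in c(0, 30)) {
    r1 <- mean(predict_rate(fit, 1, h))
    r0 <- mean(predict_rate(fit, 0, h))
    gh <- g1[g1$horizon == h, ]
    expect_equal(gh$rr, r1 / r0, tolerance = 1e-12)
    expect_equal(1 / gh$rr, r0 / r1, tolerance = 1e-12)   # swapped coding
    expect_equal(-gh$rd, r0 - r1, tolerance = 1e-12)
  }
  expect_true(all(g1$rr_lo <= g1$rr & g1$rr <= g1$rr_hi))
  expect_true(all(g1$rd_lo <= g1$rd & g1$rd <= g1$rd_hi))
})

test_that("zero coefficient covariance collapses the CI to the point estimate", {
  fit <- fit_flat(seed = 55)
  fit$vcov_robust <- matrix(0, length(fit$beta), length(fit$beta),
                            dimnames = list(names(fit$beta),
                                            names(fit$beta)))
  g <- standardize_rates(fit, horizons = 0)
  expect_equal(g$rr_lo, g$rr, tolerance = 1e-9)
  expect_equal(g$rr_hi, g$rr, tolerance = 1e-9)
  expect_equal(g$rd_lo, g$rd, tolerance = 1e-9)
})

test_that("delta-method SE agrees with a parametric bootstrap on a toy fit", {
  fit <- fit_flat(seed = 56)
  g <- standardize_rates(fit, horizons = 0)
  se_delta <- (log(g$rr_hi) - log(g$rr)) / qnorm(0.975)
  V <- vcov(fit)
  set.seed(99)
  draws <- mpits:::rmvnorm_psd(2000, (V + t(V)) / 2)
  eb <- eb_predict(fit)
  logrr <- apply(draws, 1, function(d) {
    b <- fit$beta + d
    m <- mpits:::std_means(fit, 0, b, "policy", eb)
    log(m[["m1"]] / m[["m0"]])
  })
  expect_lt(abs(sd(logrr) - se_delta) / se_delta, 0.10)
})

test_that("two-level and three-level standardized RRs agree closely", {
  tb <- default_true_beta()
  tb$mortality[["subsidy"]] <- -0.1
  tp <- default_true_psi()
  tp$mortality <- c(intercept = 0.15, subsidy = 0, time = 0, woman = 0.25)
  cfg <- population_config(n_clusters = 50, n_regions = 5,
                           mean_households_per_cluster = 8,
                           true_beta = tb, true_psi = tp, seed = 57)
  rec <- suppressWarnings(generate_population(cfg))
  sp2 <- model_spec("mortality", covariates = c("rural", "sex"),
                    random = "intercept")
  sp3 <- model_spec("mortality", covariates = c("rural", "sex"),
                    random = "intercept", woman_intercept = TRUE)
  ctrl <- mpits_control(se = FALSE)
  f2 <- mpits(rec, sp2, control = ctrl)
  f3 <- mpits(rec, sp3, control = ctrl)
  expect_true(f2$converged && f3$converged)
  g2 <- standardize_rates(f2, horizons = c(0, 42), ci = FALSE)
  g3 <- standardize_rates(f3, horizons = c(0, 42), ci = FALSE)
  expect_lt(max(abs(g2$rr - g3$rr)), 0.02)
})
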