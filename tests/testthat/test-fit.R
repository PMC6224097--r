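# GLMM engine: likelihood, estimation, robust variance, EB, diagnostics.

test_that("marginal likelihood matches brute-force trapezoid integration", {
  b <- toy_bundle(K = 5, nper = 4, seed = 42)
  beta <- c(-0.4, 0.3); psi11 <- 0.5
  ll <- marginal_loglik(b, beta, matrix(psi11, 1, 1), nodes = 25)
  ll_bf <- trapezoid_loglik(b, beta, psi11)
  expect_lt(abs(as.numeric(ll) - ll_bf), 1e-6)
  # deterministic for fixed node count
  expect_identical(as.numeric(ll),
                   as.numeric(marginal_loglik(b, beta, matrix(psi11, 1, 1),
                                              nodes = 25)))
})

test_that("single-birth closed form and the psi->0 limit hold", {
  # one birth, y = 1, eta = 0: log Poisson(1; 1) = -1
  b1 <- list(y = 1L, X = matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")),
             Z = NULL, cluster = 1L, cluster_ids = 1L, woman = NULL,
             region = 1L, n = 1L, spec = list(covariance = "unstructured"))
  expect_equal(as.numeric(marginal_loglik(b1, 0)), -1)

  b <- toy_bundle(seed = 7)
  beta <- c(-0.6, 0.2)
  ll0 <- as.numeric(marginal_loglik(b, beta, matrix(1e-12, 1, 1), nodes = 7))
  eta <- drop(b$X %*% beta)
  expect_lt(abs(ll0 - sum(b$y * eta - exp(eta))), 1e-6)
})

test_that("AGQ is converged at the default node count", {
  rec <- suppressWarnings(generate_population(small_config(seed = 33)))
  sp <- model_spec("delivery", covariates = c("rural", "wealth"),
                   random = "intercept")
  ap <- apply_scenario(rec, exposure_scenario("primary"))
  d <- build_design(ap$records, sp, exposure_scenario("primary"))
  beta <- rep(0, ncol(d$X)); beta[1] <- -0.6
  l7 <- as.numeric(marginal_loglik(d, beta, matrix(0.4, 1, 1), nodes = 7))
  l15 <- as.numeric(marginal_loglik(d, beta, matrix(0.4, 1, 1), nodes = 15))
  expect_lt(abs(l7 - l15) / d$n, 1e-4)
})

test_that("with no random terms the fit equals a standard log-link Poisson GLM", {
  rec <- suppressWarnings(generate_population(small_config(seed = 34)))
  sp <- model_spec("delivery", random = character(0))
  fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
  ap <- apply_scenario(rec, exposure_scenario("primary"))
  d <- build_design(ap$records, sp, exposure_scenario("primary"))
  g <- suppressWarnings(glm.fit(d$X, d$y, family = poisson()))
  expect_lt(max(abs(fit$beta - g$coefficients)), 1e-6)
  ll_glm <- sum(dpois(d$y, g$fitted.values, log = TRUE))
  expect_lt(abs(fit$loglik - ll_glm), 1e-6)

  # single-cluster data: same result, no crash (covariates that vary
  # within a cluster; rural is constant there and would be aliased)
  one <- rec[rec$cluster_id == rec$cluster_id[1], ]
  sp1 <- model_spec("delivery", covariates = "wealth",
                    random = character(0))
  f1 <- mpits(one, sp1, control = mpits_control(se = FALSE))
  d1 <- build_design(apply_scenario(one, exposure_scenario("primary"))$records,
                     sp1, exposure_scenario("primary"))
  g1 <- suppressWarnings(glm.fit(d1$X, d1$y, family = poisson()))
  expect_lt(max(abs(f1$beta - g1$coefficients)), 1e-6)
})

test_that("random-intercept estimates agree with an independent AGQ implementation", {
  skip_if_not_installed("lme4")
  rec <- suppressWarnings(generate_population(
    small_config(seed = 35, n_clusters = 60)))
  sp <- model_spec("delivery", covariates = c("rural", "literacy", "wealth"),
                   random = "intercept")
  fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
  ap <- apply_scenario(rec, exposure_scenario("primary"))
  d <- build_design(ap$records, sp, exposure_scenario("primary"))
  dd <- data.frame(y = d$y, d$X[, -1], cl = ap$records$cluster_id,
                   check.names = FALSE)
  gm <- suppressWarnings(
    lme4::glmer(y ~ . - cl + (1 | cl), data = dd, family = poisson,
                nAGQ = 7))
  expect_lt(max(abs(fit$beta - lme4::fixef(gm))), 5e-4)
  expect_lt(abs(fit$psi[1, 1] - as.numeric(lme4::VarCorr(gm)$cl)), 1e-3)
  # Laplace log-likelihoods are on the same scale
  fitL <- mpits(rec, sp, control = mpits_control(se = FALSE, agq_nodes = 1))
  gmL <- suppressWarnings(
    lme4::glmer(y ~ . - cl + (1 | cl), data = dd, family = poisson, nAGQ = 1))
  expect_lt(abs(fitL$loglik - as.numeric(logLik(gmL))), 0.05)
})

test_that("region-clustered sandwich matches the textbook estimator when clusters are records", {
  rec <- suppressWarnings(generate_population(small_config(seed = 36)))
  rec <- rec[1:400, ]
  sp <- model_spec("delivery", covariates = c("rural", "wealth"),
                   random = character(0))
  fit <- mpits(rec, sp)
  d <- fit$design
  V <- robust_se(fit, cluster_ids = seq_len(d$n))
  mu <- exp(drop(d$X %*% fit$beta))
  A <- crossprod(d$X * sqrt(mu))
  B <- crossprod(d$X * (d$y - mu)) * d$n / (d$n - 1)
  V_ref <- solve(A) %*% B %*% solve(A)
  expect_lt(max(abs(V - V_ref)), 1e-8)
})

test_that("robust covariance is invariant to region relabeling and needs >= 2 regions", {
  rec <- suppressWarnings(generate_population(small_config(seed = 37)))
  sp <- model_spec("delivery", covariates = "rural", random = character(0))
  fit <- mpits(rec, sp)
  V1 <- robust_se(fit)
  perm <- sample(unique(fit$design$region))
  relab <- perm[match(fit$design$region, unique(fit$design$region))]
  V2 <- robust_se(fit, cluster_ids = relab)
  expect_equal(unclass(V1)[, ], unclass(V2)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diag(V1) >= 0))
  expect_error(robust_se(fit, cluster_ids = rep(1L, fit$design$n)),
               ">= 2 regions")
})

test_that("likelihood-ratio test identities and nesting checks", {
  rec <- suppressWarnings(generate_population(small_config(seed = 38)))
  sp <- model_spec("delivery", covariates = "rural", random = character(0))
  fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
  t0 <- lrt(fit, fit)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # larger fixed model nests the smaller; statistic >= 0
  sp2 <- model_spec("delivery", covariates = c("rural", "wealth"),
                    random = character(0))
  fit2 <- mpits(rec, sp2, control = mpits_control(se = FALSE))
  t2 <- lrt(fit, fit2)
  expect_gte(t2$statistic, 0)
  expect_identical(t2$df, length(fit2$theta) - length(fit$theta))
  expect_error(lrt(fit2, fit), "not a subset")
  # different data
  fit3 <- mpits(rec[1:500, ], sp, control = mpits_control(se = FALSE))
  expect_error(lrt(fit3, fit2), "different data")
})

test_that("boundary LRT uses the 50:50 chi-square mixture", {
  rec <- suppressWarnings(generate_population(
    small_config(seed = 39, n_clusters = 50)))
  sp0 <- model_spec("delivery", covariates = "rural", random = character(0))
  sp1 <- model_spec("delivery", covariates = "rural", random = "intercept")
  ctrl <- mpits_control(se = FALSE, boundary_tol = 0)
  f0 <- mpits(rec, sp0, control = ctrl)
  f1 <- mpits(rec, sp1, control = ctrl)
  tb <- lrt(f0, f1)              # auto: same fixed effects -> boundary
  expect_true(tb$boundary)
  expect_gte(tb$statistic, 0)
  expect_equal(tb$p_value,
               0.5 * pchisq(tb$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gte(f1$loglik, f0$loglik - 1e-6)   # nesting monotonicity
})

test_that("empirical-Bayes predictions: zero variance, direction, grid-search oracle", {
  rec <- suppressWarnings(generate_population(small_config(seed = 40)))
  # no random terms: all EB values are zero
  sp0 <- model_spec("delivery", covariates = "rural", random = character(0))
  f0 <- mpits(rec, sp0, control = mpits_control(se = FALSE))
  eb0 <- eb_predict(f0)
  expect_true(all(eb0$cluster[, -1] == 0))

  sp1 <- model_spec("delivery", covariates = "rural", random = "intercept")
  f1 <- mpits(rec, sp1, control = mpits_control(se = FALSE))
  eb1 <- eb_predict(f1)
  d <- f1$design
  rate_k <- tapply(d$y, d$cluster, mean)
  hi <- which.max(rate_k); lo <- which.min(rate_k)
  expect_gt(eb1$cluster$intercept[hi], 0)
  expect_lt(eb1$cluster$intercept[lo], 0)

  # 1-dim posterior mode equals a grid-search argmax
  k <- hi
  idx <- d$cluster == k
  eta0 <- drop(d$X[idx, , drop = FALSE] %*% f1$beta)
  s <- sqrt(f1$psi[1, 1])
  grid <- seq(-4, 4, by = 1e-4)
  gval <- vapply(grid, function(u)
    sum(d$y[idx] * (eta0 + s * u) - exp(eta0 + s * u)) - 0.5 * u^2,
    numeric(1))
  b_grid <- s * grid[which.max(gval)]
  expect_lt(abs(eb1$cluster$intercept[k] - b_grid), 1e-4)
})

test_that("VIF: orthogonal columns, closed form under known correlation, aliasing", {
  n <- 2000
  set.seed(1)
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  dsg <- structure(list(X = cbind(`(Intercept)` = 1, a = x1, b = x2)),
                   class = "mpits_design")
  v <- vif(dsg)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12)

  rho <- 0.6
  z <- rnorm(n)
  a <- z
  b <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  r_emp <- cor(a, b)
  dsg2 <- structure(list(X = cbind(`(Intercept)` = 1, a = a, b = b)),
                    class = "mpits_design")
  v2 <- vif(dsg2)
  expect_equal(unname(v2["a"]), 1 / (1 - r_emp^2), tolerance = 1e-6)

  dsg3 <- structure(list(X = cbind(`(Intercept)` = 1, a = a, b = a)),
                    class = "mpits_design")
  expect_true(all(is.infinite(vif(dsg3))))
})

test_that("over-dispersion screen: non-negative statistic; detects injected frailty", {
  cfg <- flat_config(seed = 41, n_clusters = 40, n_regions = 4,
                     mean_households_per_cluster = 6)
  sp <- model_spec("delivery", covariates = "rural", random = "intercept")
  rejected_plain <- rejected_frail <- logical(3)
  for (i in 1:3) {
    rec <- generate_population(flat_config(seed = 41 + i, n_clusters = 40,
                                           n_regions = 4,
                                           mean_households_per_cluster = 6))
    od <- overdispersion_check(rec, sp)
    expect_gte(od$statistic, 0)
    expect_true(od$p_value >= 0 && od$p_value <= 1)
    rejected_plain[i] <- od$p_value < 0.05

    # birth-level lognormal frailty is a no-op inside a Bernoulli rate
    # (iid mixing changes nothing distributionally), so the frailty arm
    # uses the Poisson-count form of the outcome, where level-1
    # heterogeneity is real over-dispersion
    set.seed(1000 + i)
    fr <- exp(rnorm(nrow(rec), 0, 1))
    rec2 <- rec
    rec2$facility_delivery <- rpois(nrow(rec), 0.4 * fr)
    od2 <- overdispersion_check(rec2, sp)
    rejected_frail[i] <- od2$p_value < 0.05
  }
  expect_lte(sum(rejected_plain), 1)   # Bernoulli data: typically not rejected
  expect_gte(sum(rejected_frail), 2)   # frailty: typically rejected
})

test_that("confounder screen: identical, 20% change, and zero-reference cases", {
  rec <- suppressWarnings(generate_population(small_config(seed = 43)))
  sp <- model_spec("delivery", covariates = "rural", random = character(0))
  fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
  expect_false(confounder_screen(fit, fit)$keep)
  fit_b <- fit; fit_b$beta["subsidy"] <- fit$beta["subsidy"] * 1.2
  expect_true(confounder_screen(fit_b, fit)$keep)
  fit_c <- fit; fit_c$beta["subsidy"] <- 0
  scr <- confounder_screen(fit_b, fit_c)
  expect_true(scr$indeterminate)
  expect_true(scr$keep)
})

test_that("degenerate outcomes fail gracefully, never crash", {
  rec <- suppressWarnings(generate_population(small_config(seed = 44)))
  rec$facility_delivery <- 0L
  sp <- model_spec("delivery", covariates = "rural", random = "intercept")
  fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
  expect_false(fit$converged)
  expect_match(fit$failure, "zero")
  expect_output(print(fit), "NOT CONVERGED")
})

test_that("boundary variance triggers collapse to the simpler model", {
  # no true cluster variance: random intercept should be dropped
  cfg <- flat_config(seed = 45, n_clusters = 50, n_regions = 5,
                     mean_households_per_cluster = 8)
  rec <- generate_population(cfg)
  sp <- model_spec("delivery", covariates = "rural", random = "intercept")
  fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
  if (length(fit$boundary_dropped)) {
    expect_true("intercept" %in% fit$boundary_dropped)
    expect_null(fit$psi)
    # equals the plain Poisson fit after collapse
    sp0 <- model_spec("delivery", covariates = "rural",
                      random = character(0))
    f0 <- mpits(rec, sp0, control = mpits_control(se = FALSE))
    expect_lt(max(abs(fit$beta - f0$beta)), 1e-6)
  } else {
    expect_lt(fit$psi[1, 1], 0.02)   # at worst a tiny estimated variance
  }
})

test_that("non-finite linear predictors and invalid psi are reported", {
  b <- toy_bundle()
  expect_error(marginal_loglik(b, c(Inf, 0), matrix(0.1, 1, 1)),
               "record")
  b2 <- b
  b2$Z <- cbind(intercept = rep(1, b$n), x = b$X[, "x"])
  expect_error(marginal_loglik(b2, c(0, 1), matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})
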