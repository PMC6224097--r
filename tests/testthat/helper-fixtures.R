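# Shared fixtures: small, fast configurations built in code.

# a compact population: ~40 clusters, ~1200 births
small_config <- function(seed = 1, n_clusters = 40, n_regions = 5,
                         mean_households_per_cluster = 8, ...) {
  population_config(n_clusters = n_clusters, n_regions = n_regions,
                    mean_households_per_cluster = mean_households_per_cluster,
                    seed = seed, ...)
}

# a deterministic-rate configuration: no random effects, no covariate
# effects beyond those passed in `delivery` / `mortality`
flat_config <- function(seed = 1, delivery = c(), mortality = c(), ...) {
  tb <- default_true_beta()
  tb$delivery[] <- 0
  tb$delivery[["intercept"]] <- log(0.4)
  tb$mortality[] <- 0
  tb$mortality[["intercept"]] <- log(0.04)
  for (nm in names(delivery)) tb$delivery[[nm]] <- delivery[[nm]]
  for (nm in names(mortality)) tb$mortality[[nm]] <- mortality[[nm]]
  tp <- default_true_psi()
  tp$delivery[] <- 0
  tp$mortality[] <- 0
  population_config(true_beta = tb, true_psi = tp, psi_correlation = 0,
                    seed = seed, ...)
}

# hand-built toy design bundle (bypasses records): K clusters of size nper,
# one covariate, random intercept
toy_bundle <- function(K = 5, nper = 4, seed = 42, psi_diag = 0.5,
                       beta = c(-0.5, 0.4)) {
  set.seed(seed)
  n <- K * nper
  cl <- rep(seq_len(K), each = nper)
  x <- rnorm(n)
  b <- rnorm(K, 0, sqrt(psi_diag))
  eta <- beta[1] + beta[2] * x + b[cl]
  y <- rbinom(n, 1, pmin(exp(eta), 1))
  list(y = y, X = cbind(`(Intercept)` = rep(1, n), x = x),
       Z = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
       cluster = cl, cluster_ids = seq_len(K), woman = NULL,
       region = rep(1L, n), n = n,
       spec = list(covariance = "unstructured"))
}

# brute-force trapezoid marginal log-likelihood for a 1-dim random
# intercept bundle (independent quadrature oracle)
trapezoid_loglik <- function(bundle, beta, psi11, lim = 8, npts = 4001) {
  ug <- seq(-lim, lim, length.out = npts)
  s <- sqrt(psi11)
  total <- 0
  for (k in unique(bundle$cluster)) {
    idx <- bundle$cluster == k
    vals <- vapply(ug, function(u) {
      eta <- drop(bundle$X[idx, , drop = FALSE] %*% beta) + s * u
      sum(bundle$y[idx] * eta - exp(eta)) - 0.5 * u^2
    }, numeric(1))
    m <- max(vals)
    total <- total + log(sum(exp(vals - m)) * (ug[2] - ug[1])) + m -
      0.5 * log(2 * pi)
  }
  total
}
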