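#' @keywords internal
#' @importFrom stats rnorm rbinom rpois runif rgamma rnbinom var cov sd
#'   median pnorm qnorm pchisq optim setNames lm.fit ave coef vcov anova
#'   residuals simulate predict logLik qr.coef
#' @importFrom utils read.table write.table
"_PACKAGE"

# Calendar convention used throughout: birth_month is an integer count of
# months since January 2000 (0 = Jan 2000). Jan 2007 = 84, Apr 2007 = 87,
# Jun 2005 = 65, Dec 2010 = 131.

MONTH_JAN2000 <- 0L
MONTH_JUN2005 <- 65L
MONTH_JAN2007 <- 84L
MONTH_APR2007 <- 87L
MONTH_DEC2010 <- 131L

#' Convert a month index to a printable calendar label
#'
#' @param m integer month index (0 = January 2000).
#' @return character vector like "2007-01".
#' @export
month_label <- function(m) {
  sprintf("%d-%02d", 2000L + m %/% 12L, m %% 12L + 1L)
}

# Derived sub-seeds: every stochastic routine draws its own stream from the
# master seed so modules are independently reproducible. Kept below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * stream) %% 2147483629)
}

# Round half away from zero (base round() rounds half to even); matches the
# one-decimal printing convention of survey descriptive tables.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Exact-composition categorical assignment: returns n labels whose counts are
# the largest-remainder apportionment of n * prob, randomly permuted. Used so
# simulated covariate margins match their targets up to integer rounding
# rather than binomial noise.
sample_composition <- function(n, labels, prob) {
  stopifnot(length(labels) == length(prob), all(prob >= 0))
  if (n == 0L) return(character(0))
  prob <- prob / sum(prob)
  quota <- n * prob
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(labels, times = base))
}

# Positive-semidefiniteness check with a tolerance scaled to the matrix.
is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(1, abs(ev[1])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
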