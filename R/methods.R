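# S3 methods for fitted mpits objects.

#' @export
print.mpits <- function(x, ...) {
  cat("Segmented multilevel modified-Poisson fit\n")
  cat("  outcome:", x$spec$outcome, " scenario:", x$scenario$name, "\n")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$failure %||% "optimizer did not converge", "\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d births, %d clusters, %d regions; logLik = %.2f\n",
              x$n_used["births"], x$n_used["clusters"], x$n_used["regions"],
              x$loglik))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  if (!is.null(x$psi)) {
    cat("  cluster random-effect variances:\n")
    print(round(diag(x$psi), 4))
  }
  if (x$sd_woman > 0)
    cat(sprintf("  woman-level intercept SD: %.4f\n", x$sd_woman))
  if (length(x$boundary_dropped))
    cat("  dropped at boundary:", paste(x$boundary_dropped, collapse = ", "),
        "\n")
  invisible(x)
}

#' Summarize a fitted segmented modified-Poisson model
#'
#' @param object an [mpits()] fit.
#' @param vcov_type `"robust"` (region-clustered sandwich, the default and
#'   the reported flavour) or `"model"` (inverse observed information).
#' @param ... unused.
#' @return a `summary.mpits` object with a coefficient table (estimate,
#'   SE, z, p, and rate ratio with 95% CI).
#' @export
summary.mpits <- function(object, vcov_type = c("robust", "model"), ...) {
  vcov_type <- match.arg(vcov_type)
  if (!object$converged) {
    out <- list(fit = object, table = NULL, vcov_type = vcov_type)
    class(out) <- "summary.mpits"
    return(out)
  }
  V <- vcov(object, type = vcov_type)
  se <- sqrt(pmax(diag(V), 0))
  z <- object$beta / se
  p <- 2 * pnorm(-abs(z))
  tab <- data.frame(
    estimate = object$beta, se = se, z = z, p_value = p,
    rr = exp(object$beta),
    rr_lo = exp(object$beta - qnorm(0.975) * se),
    rr_hi = exp(object$beta + qnorm(0.975) * se))
  out <- list(fit = object, table = tab, vcov_type = vcov_type)
  class(out) <- "summary.mpits"
  out
}

#' @export
print.summary.mpits <- function(x, digits = 4, ...) {
  print(x$fit)
  if (is.null(x$table)) return(invisible(x))
  cat(sprintf("\nCoefficients (%s standard errors):\n", x$vcov_type))
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.mpits <- function(object, ...) object$beta

#' Covariance of the fixed effects
#'
#' @param object an [mpits()] fit (run with `se = TRUE`).
#' @param type `"robust"` for the region-clustered sandwich covariance,
#'   `"model"` for the model-based (inverse information) covariance.
#' @param ... unused.
#' @export
vcov.mpits <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  V <- if (type == "robust") object$vcov_robust else object$vcov_model
  if (is.null(V)) stop("fit was run with se = FALSE; refit with se = TRUE")
  V
}

#' @export
logLik.mpits <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = unname(object$n_used["births"]), class = "logLik")
}

#' Fitted or counterfactual rates for the analysis records
#'
#' Rates are `exp(x'beta + z'gamma)` with the empirical-Bayes random
#' effects included (set `use_eb = FALSE` for the fixed-effects-only
#' rate), capped at 1; the number of capped predictions is attached as
#' attribute `"n_capped"`.
#'
#' @param object an [mpits()] fit.
#' @param type `"rate"` or `"link"` (linear predictor).
#' @param use_eb include empirical-Bayes random-effect values.
#' @param ... unused.
#' @export
predict.mpits <- function(object, type = c("rate", "link"), use_eb = TRUE,
                          ...) {
  type <- match.arg(type)
  eta <- fitted_eta(object, use_eb = use_eb)
  if (type == "link") return(eta)
  r <- exp(eta)
  ncap <- sum(r > 1)
  r <- pmin(r, 1)
  attr(r, "n_capped") <- ncap
  r
}

# linear predictor on the stored design, optionally with EB effects
fitted_eta <- function(fit, use_eb = TRUE) {
  bundle <- fit$design
  eta <- drop(bundle$X %*% fit$beta)
  if (use_eb) {
    eb <- eb_predict(fit)
    if (!is.null(bundle$Z)) {
      Bc <- as.matrix(eb$cluster[, colnames(bundle$Z), drop = FALSE])
      eta <- eta + rowSums(bundle$Z * Bc[bundle$cluster, , drop = FALSE])
    }
    if (!is.null(eb$woman)) {
      wv <- eb$woman$intercept[match(bundle$df$woman, eb$woman$woman_id)]
      eta <- eta + wv
    }
  }
  eta
}

#' @export
residuals.mpits <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- predict(object)
  res <- object$design$y - r
  if (type == "pearson") res <- res / sqrt(pmax(r, 1e-12))
  as.numeric(res)
}

#' Simulate outcomes from a fitted model
#'
#' Draws fresh cluster (and woman) random effects from the estimated
#' covariance and Bernoulli outcomes from the implied (truncated) rates,
#' on the stored design.
#'
#' @param object an [mpits()] fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.mpits <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  bundle <- object$design
  eta0 <- drop(bundle$X %*% object$beta)
  K <- length(bundle$cluster_ids)
  out <- matrix(0L, bundle$n, nsim)
  for (s in seq_len(nsim)) {
    eta <- eta0
    if (!is.null(bundle$Z)) {
      B <- rmvnorm_psd(K, object$psi)
      eta <- eta + rowSums(bundle$Z * B[bundle$cluster, , drop = FALSE])
    }
    if (object$sd_woman > 0) {
      wid <- match(bundle$df$woman, sort(unique(bundle$df$woman)))
      vw <- rnorm(max(wid), 0, object$sd_woman)
      eta <- eta + vw[wid]
    }
    out[, s] <- rbinom(bundle$n, 1L, pmin(exp(eta), 1))
  }
  as.data.frame(out)
}

#' Likelihood-ratio test between nested fits
#'
#' For variance components tested on their boundary (the null pins a
#' variance at zero) the null distribution is the 50:50 mixture
#' chi-square(df-1) : chi-square(df).
#'
#' @param object the nested (smaller) fit.
#' @param ... the nesting (larger) fit.
#' @param boundary `"auto"` (mixture when only random terms differ),
#'   `TRUE`, or `FALSE`.
#' @export
anova.mpits <- function(object, ..., boundary = "auto") {
  fits <- list(...)
  if (!length(fits) || !inherits(fits[[1]], "mpits"))
    stop("supply the nesting model as the second argument")
  lrt(object, fits[[1]], boundary = boundary)
}

#' @rdname anova.mpits
#' @param fit_nested,fit_full nested and full fits on the same data.
#' @return list with `statistic`, `df`, `p_value`, `boundary`.
#' @export
lrt <- function(fit_nested, fit_full, boundary = "auto") {
  stopifnot(inherits(fit_nested, "mpits"), inherits(fit_full, "mpits"))
  n1 <- fit_nested$n_used["births"]; n2 <- fit_full$n_used["births"]
  if (n1 != n2) stop("fits use different data (birth counts differ)")
  if (!setequal(intersect(names(fit_nested$beta), names(fit_full$beta)),
                names(fit_nested$beta)))
    stop("fixed effects of the nested fit are not a subset of the full fit")
  r1 <- fit_nested$spec$random; r2 <- fit_full$spec$random
  if (!all(r1 %in% r2) ||
      (fit_nested$spec$woman_intercept && !fit_full$spec$woman_intercept))
    stop("random structure of the nested fit is not a subset of the full fit")
  df <- length(fit_full$theta) - length(fit_nested$theta)
  if (df <= 0) df <- 0L
  stat <- max(0, 2 * (fit_full$loglik - fit_nested$loglik))
  same_fixed <- identical(names(fit_nested$beta), names(fit_full$beta))
  use_mix <- isTRUE(boundary) ||
    (identical(boundary, "auto") && same_fixed && df > 0)
  if (df == 0) {
    p <- 1
  } else if (use_mix) {
    p_lo <- if (df - 1 == 0) as.numeric(stat <= 0)
            else pchisq(stat, df - 1, lower.tail = FALSE)
    p <- 0.5 * p_lo + 0.5 * pchisq(stat, df, lower.tail = FALSE)
  } else {
    p <- pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p, boundary = use_mix)
}
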