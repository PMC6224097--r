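# The mpits() fitting function: marginal ML estimation, boundary
# handling, and covariance estimation.

#' Fit the segmented multilevel modified-Poisson model
#'
#' Maximizes the marginal likelihood (random effects integrated out by
#' adaptive Gauss-Hermite quadrature / Laplace, see [marginal_loglik()])
#' over the fixed effects, the log-Cholesky-parameterized cluster
#' random-effect covariance and, for three-level models, the woman-level
#' intercept standard deviation, with a quasi-Newton optimizer and
#' perturbed restarts. A cluster-level variance estimated at the boundary
#' (zero) triggers an automatic refit without that random term, mirroring
#' the collapse to a simple Poisson regression when no between-cluster
#' variance is found.
#'
#' @param records birth-record data frame (scenario exclusions are applied
#'   internally).
#' @param spec a [model_spec()].
#' @param scenario an [exposure_scenario()].
#' @param control a [mpits_control()].
#' @return an object of class `mpits`; see [summary.mpits()]. Key fields:
#'   `beta` (named fixed effects), `psi` (cluster random-effect
#'   covariance), `sd_woman`, `loglik`, `vcov_model`, `vcov_robust`
#'   (region-clustered sandwich), `converged`, `boundary_dropped`,
#'   `n_used`.
#' @examples
#' cfg <- population_config(n_clusters = 40, n_regions = 4, seed = 1)
#' rec <- generate_population(cfg)
#' sp <- model_spec("delivery", covariates = "rural", random = "intercept")
#' fit <- mpits(rec, sp, control = mpits_control(se = FALSE))
#' coef(fit)["subsidy"]
#' @export
mpits <- function(records, spec, scenario = exposure_scenario("primary"),
                  control = mpits_control()) {
  ap <- apply_scenario(records, scenario)
  bundle <- build_design(ap$records, spec, scenario)
  fit <- mpits_fit_design(bundle, control)
  fit$n_excluded <- ap$n_excluded
  fit
}

# failure result that downstream code can recognize without crashing
mpits_failure <- function(bundle, message) {
  structure(list(
    beta = setNames(rep(NA_real_, ncol(bundle$X)), colnames(bundle$X)),
    psi = NULL, sd_woman = NA_real_, loglik = -Inf, converged = FALSE,
    failure = message, spec = bundle$spec, scenario = bundle$scenario,
    n_used = mpits_counts(bundle)), class = "mpits")
}

mpits_counts <- function(bundle) {
  c(births = bundle$n,
    women = length(unique(bundle$df$woman)),
    clusters = length(bundle$cluster_ids),
    regions = length(unique(bundle$region)))
}

# Pure fixed-effects Poisson ML by Newton-Raphson (exact, used when no
# random terms remain).
poisson_newton <- function(bundle) {
  X <- bundle$X; y <- bundle$y
  if (qr(X)$rank < ncol(X)) return(NULL)     # aliased columns
  beta <- qr.coef(qr(X), log(pmax(y, 0.05)))
  beta[!is.finite(beta)] <- 0
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - exp(eta) - lfactorial(y))
  }
  ll <- loglik(beta)
  for (i in 1:200) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    sc <- drop(crossprod(X, y - mu))
    if (max(abs(sc)) < 1e-10 && i > 1) break
    H <- crossprod(X * sqrt(mu))
    # ridge-stabilized solve: quasi-separated categories make H nearly
    # singular while their estimates drift to large finite values
    lam <- 0
    repeat {
      step <- tryCatch(solve(H + diag(lam, ncol(X)), sc),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) break
      lam <- if (lam == 0) 1e-8 * max(diag(H), 1) else lam * 100
      if (lam > 1e6) return(NULL)
    }
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    # step halving
    for (h in 1:30) {
      ll_new <- loglik(beta + step)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (h == 30) step <- step * 0
    }
    beta <- beta + step
    ll <- loglik(beta)
  }
  eta <- drop(X %*% beta)
  list(beta = beta, loglik = ll, H = crossprod(X * sqrt(exp(eta))))
}

mpits_fit_design <- function(bundle, control = mpits_control()) {
  dims <- internal_dims(bundle, control)
  if (sum(bundle$y) == 0L)
    return(mpits_failure(bundle, "outcome is identically zero"))

  # starting values from the fixed-effects Poisson fit
  glm0 <- poisson_newton(bundle)
  if (is.null(glm0))
    return(mpits_failure(bundle, "singular fixed-effects design"))

  if (dims$ntheta == dims$p) {
    # no random terms: the Newton fit is the exact ML fit
    fit <- build_mpits(glm0$beta, NULL, 0, glm0$loglik, TRUE, bundle, dims,
                       control, glm_hessian = glm0$H)
    return(fit)
  }

  cache <- new.env(parent = emptyenv())
  negll <- function(theta) {
    v <- -sum(mll_groups(theta, bundle, dims, cache))
    if (!is.finite(v)) v <- 1e10
    v
  }
  grad <- function(theta) {
    g <- numeric(length(theta))
    h <- control$fd_step * pmax(1, abs(theta))
    for (i in seq_along(theta)) {
      tp <- theta; tp[i] <- theta[i] + h[i]
      tm <- theta; tm[i] <- theta[i] - h[i]
      g[i] <- (negll(tp) - negll(tm)) / (2 * h[i])
    }
    g
  }

  psi_start <- function(scale) {
    tp <- log(rep(0.3 * scale, dims$q))
    if (dims$q > 1L) tp[-1] <- log(0.1 * scale)
    if (dims$structure == "unstructured" && dims$q > 1L)
      tp <- c(tp, rep(0, (dims$q * (dims$q - 1L)) %/% 2L))
    tp
  }
  starts <- list()
  scales <- c(1, 0.25, 4)
  for (a in seq_len(1L + control$restarts)) {
    sc <- scales[(a - 1L) %% length(scales) + 1L]
    th <- glm0$beta
    if (dims$npsi > 0L) th <- c(th, psi_start(sc))
    if (dims$has_woman || dims$woman_as_cluster) th <- c(th, log(0.3 * sc))
    starts[[a]] <- th
  }

  best <- NULL
  run_bfgs <- function(th0) {
    opt <- tryCatch(
      stats::optim(th0, negll, grad, method = "BFGS",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol,
                                  trace = as.integer(control$verbose))),
      error = function(e) NULL)
    # iteration cap reached: continue from where the search stopped
    tries <- 0L
    while (!is.null(opt) && opt$convergence == 1L && tries < 2L &&
           all(is.finite(opt$par))) {
      tries <- tries + 1L
      nxt <- tryCatch(
        stats::optim(opt$par, negll, grad, method = "BFGS",
                     control = list(maxit = control$maxit,
                                    reltol = control$reltol)),
        error = function(e) NULL)
      if (is.null(nxt)) break
      opt <- nxt
    }
    opt
  }
  for (th0 in starts) {
    opt <- run_bfgs(th0)
    if (is.null(opt) || any(!is.finite(opt$par)) || !is.finite(opt$value))
      next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best))
    return(mpits_failure(bundle, "optimizer failed on all starts"))

  pars <- split_theta(best$par, dims)

  # --- boundary handling: drop vanished variance components and refit ----
  dropped <- character(0)
  if (dims$q > 0L) {
    vars <- diag(pars$L %*% t(pars$L))
    at_zero <- vars < control$boundary_tol
    if (any(at_zero)) dropped <- colnames(bundle$Z)[at_zero]
  }
  drop_woman <- (dims$has_woman || dims$woman_as_cluster) &&
    pars$sd_w^2 < control$boundary_tol
  if (length(dropped) || drop_woman) {
    spec2 <- bundle$spec
    spec2$random <- setdiff(spec2$random, dropped)
    if (length(spec2$random) && !("intercept" %in% spec2$random))
      spec2$random <- character(0)   # slopes without intercept: collapse
    if (drop_woman) spec2$woman_intercept <- FALSE
    bundle2 <- bundle
    bundle2$spec <- spec2
    bundle2$Z <- random_matrix(bundle$df, spec2)
    bundle2$woman <- if (spec2$woman_intercept) bundle$woman else NULL
    fit <- mpits_fit_design(bundle2, control)
    fit$boundary_dropped <- unique(c(fit$boundary_dropped %||% character(0),
                                     dropped,
                                     if (drop_woman) "woman_intercept"))
    return(fit)
  }

  build_mpits(pars$beta, pars$L, pars$sd_w, -best$value,
              best$convergence == 0, bundle, dims, control,
              theta = best$par, cache = cache)
}

# assemble the fitted object, including covariance estimates
build_mpits <- function(beta, L, sd_w, loglik, converged, bundle, dims,
                        control, theta = NULL, cache = NULL,
                        glm_hessian = NULL) {
  names(beta) <- colnames(bundle$X)
  psi <- if (!is.null(L)) {
    P <- L %*% t(L)
    dimnames(P) <- list(colnames(bundle$Z), colnames(bundle$Z))
    P
  } else NULL
  if (is.null(theta)) theta <- beta
  fit <- structure(list(
    beta = beta, psi = psi, sd_woman = sd_w, loglik = loglik,
    converged = converged, theta = theta, dims = dims,
    boundary_dropped = character(0),
    spec = bundle$spec, scenario = bundle$scenario,
    control = control, design = bundle,
    n_used = mpits_counts(bundle)), class = "mpits")

  if (control$se) {
    if (!is.null(glm_hessian) && dims$ntheta == dims$p) {
      A <- glm_hessian
    } else {
      A <- -numeric_hessian(function(th)
        sum(mll_groups(th, bundle, dims, cache)), theta, control$fd_step)
    }
    Ainv <- safe_solve(A)
    fit$vcov_model <- Ainv[seq_len(dims$p), seq_len(dims$p), drop = FALSE]
    dimnames(fit$vcov_model) <- list(names(beta), names(beta))
    fit$A_full <- A
    fit$vcov_robust <- robust_vcov_theta(fit)
  }
  fit
}

numeric_hessian <- function(f, theta, step) {
  P <- length(theta)
  h <- step * pmax(1, abs(theta))
  g0 <- numeric(P)
  gfun <- function(th) {
    g <- numeric(P)
    for (i in seq_len(P)) {
      tp <- th; tp[i] <- th[i] + h[i]
      tm <- th; tm[i] <- th[i] - h[i]
      g[i] <- (f(tp) - f(tm)) / (2 * h[i])
    }
    g
  }
  g0 <- gfun(theta)
  H <- matrix(0, P, P)
  for (i in seq_len(P)) {
    tp <- theta; tp[i] <- theta[i] + h[i]
    H[, i] <- (gfun(tp) - g0) / h[i]
  }
  (H + t(H)) / 2
}

safe_solve <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, max(abs(e$values)) * 1e-10)
  e$vectors %*% (t(e$vectors) / ev)
}

# Region-clustered sandwich covariance of the full parameter vector.
# Scores are summed within regions; the small-sample factor G/(G-1) is
# applied.
robust_vcov_theta <- function(fit) {
  bundle <- fit$design; dims <- fit$dims
  if (dims$ntheta == dims$p) {
    # no random terms: per-record Poisson scores, summed within regions
    grp_region <- as.integer(factor(bundle$region))
    G <- length(unique(grp_region))
    if (G < 2L) stop("region-clustered robust variance needs >= 2 regions")
    mu <- exp(drop(bundle$X %*% fit$beta))
    S <- rowsum((bundle$y - mu) * bundle$X, grp_region)
  } else {
  grp_region <- group_regions(bundle, dims)
  G <- length(unique(grp_region))
  if (G < 2L) stop("region-clustered robust variance needs >= 2 regions")
  theta <- fit$theta
  P <- length(theta)
  h <- fit$control$fd_step * pmax(1, abs(theta))
  cache <- new.env(parent = emptyenv())
  S <- matrix(0, G, P)
  for (i in seq_len(P)) {
    tp <- theta; tp[i] <- theta[i] + h[i]
    tm <- theta; tm[i] <- theta[i] - h[i]
    lp <- mll_groups(tp, bundle, dims, cache)
    lm_ <- mll_groups(tm, bundle, dims, cache)
    S[, i] <- drop(rowsum((lp - lm_) / (2 * h[i]), grp_region))
  }
  }
  B <- crossprod(S) * G / (G - 1)
  Ainv <- safe_solve(fit$A_full)
  V <- Ainv %*% B %*% Ainv
  Vb <- V[seq_len(dims$p), seq_len(dims$p), drop = FALSE]
  dimnames(Vb) <- list(names(fit$beta), names(fit$beta))
  attr(Vb, "full") <- V
  attr(Vb, "n_regions") <- G
  Vb
}

# region of each likelihood group (cluster, or woman for the
# woman-grouped special case)
group_regions <- function(bundle, dims) {
  if (dims$woman_as_cluster) {
    idx <- !duplicated(bundle$woman)
    reg <- bundle$region[idx][order(bundle$woman[idx])]
  } else {
    idx <- !duplicated(bundle$cluster)
    reg <- bundle$region[idx][order(bundle$cluster[idx])]
  }
  reg
}

#' Region-clustered robust covariance of the fixed effects
#'
#' Sandwich estimator with scores summed within a grouping (region by
#' default) and the small-cluster degrees-of-freedom factor G/(G-1).
#'
#' @param fit an [mpits()] fit.
#' @param cluster_ids optional alternative grouping vector, one value per
#'   analysis record (defaults to the stored region ids).
#' @return covariance matrix of the fixed effects.
#' @export
robust_se <- function(fit, cluster_ids = NULL) {
  stopifnot(inherits(fit, "mpits"))
  if (is.null(cluster_ids)) {
    if (!is.null(fit$vcov_robust)) return(fit$vcov_robust)
    if (is.null(fit$A_full)) stop("fit was run with se = FALSE")
    return(robust_vcov_theta(fit))
  }
  f2 <- fit
  stopifnot(length(cluster_ids) == fit$design$n)
  f2$design$region <- as.integer(factor(cluster_ids))
  if (is.null(f2$A_full)) stop("fit was run with se = FALSE")
  robust_vcov_theta(f2)
}

#' Empirical-Bayes prediction of the random effects
#'
#' Posterior modes of the cluster-level effects (on the natural scale,
#' i.e. the deviations that enter the linear predictor) and, for
#' three-level fits, of the woman-level intercepts, given the estimated
#' parameters. Models without a given term predict 0 for it.
#'
#' @param fit an [mpits()] fit.
#' @return object of class `eb_prediction`: list with data frames
#'   `cluster` (cluster_id plus one column per random term) and `woman`
#'   (woman_id, intercept).
#' @export
eb_predict <- function(fit) {
  stopifnot(inherits(fit, "mpits"))
  bundle <- fit$design; dims <- fit$dims
  K <- length(bundle$cluster_ids)
  terms <- c("intercept", "time", "subsidy", "post_time")
  Bc <- matrix(0, K, length(terms), dimnames = list(NULL, terms))
  wdf <- NULL
  if (dims$q > 0L || dims$has_woman || dims$woman_as_cluster) {
    cache <- new.env(parent = emptyenv())
    mll_groups(fit$theta, bundle, dims, cache)
    pars <- split_theta(fit$theta, dims)
    if (dims$woman_as_cluster) {
      sw <- drop(cache$U) * pars$sd_w
      ids <- sort(unique(bundle$df$woman))
      wdf <- data.frame(woman_id = ids, intercept = sw)
    } else if (dims$q > 0L) {
      Bhat <- cache$U %*% t(pars$L)    # b = L u
      Bc[, colnames(bundle$Z)] <- Bhat
      if (dims$has_woman) {
        ids <- sort(unique(bundle$df$woman))
        wdf <- data.frame(woman_id = ids, intercept = cache$s * pars$sd_w)
      }
    }
  }
  structure(list(
    cluster = data.frame(cluster_id = bundle$cluster_ids, Bc),
    woman = wdf), class = "eb_prediction")
}
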