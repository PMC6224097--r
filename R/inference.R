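# Model-building diagnostics: multicollinearity, over-dispersion,
# confounder/seasonality screening.

#' Variance inflation factors of the fixed-effects design
#'
#' Computed from the covariate columns of the design (intercept, the
#' subsidy interaction columns and seasonal dummies excluded), each column
#' regressed on all the others plus an intercept. Aliased (perfectly
#' collinear) columns are reported as `Inf`.
#'
#' @param x an `mpits_design` bundle or an [mpits()] fit.
#' @return named vector of VIFs (each >= 1, or Inf when aliased).
#' @export
vif <- function(x) {
  bundle <- if (inherits(x, "mpits")) x$design else x
  stopifnot(inherits(bundle, "mpits_design"))
  X <- bundle$X
  drop_cols <- grepl("^\\(Intercept\\)$|^subsidy_|^season_", colnames(X))
  X <- X[, !drop_cols, drop = FALSE]
  out <- setNames(numeric(ncol(X)), colnames(X))
  one <- rep(1, nrow(X))
  for (j in seq_len(ncol(X))) {
    yj <- X[, j]
    Xj <- cbind(one, X[, -j, drop = FALSE])
    fitj <- lm.fit(Xj, yj)
    rss <- sum(fitj$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) { out[j] <- Inf; next }
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Over-dispersion check via a birth-level random intercept
#'
#' Fits the model with and without a random intercept at the birth level
#' (level 1) and compares them with a boundary likelihood-ratio test, the
#' standard screen for extra-Poisson variation in this setting.
#'
#' @param records birth records.
#' @param spec a two-level [model_spec()] (no woman intercept).
#' @param scenario an [exposure_scenario()].
#' @param control a [mpits_control()].
#' @return list with the boundary LRT (`statistic`, `df`, `p_value`) and
#'   the two fits.
#' @export
overdispersion_check <- function(records, spec,
                                 scenario = exposure_scenario("primary"),
                                 control = mpits_control(se = FALSE)) {
  if (spec$woman_intercept)
    stop("over-dispersion check expects a two-level spec")
  control$boundary_tol <- 0   # keep both fits on the same random structure
  ap <- apply_scenario(records, scenario)
  bundle <- build_design(ap$records, spec, scenario)
  fit0 <- mpits_fit_design(bundle, control)
  bundle1 <- bundle
  bundle1$spec$woman_intercept <- TRUE
  bundle1$woman <- seq_len(bundle$n)      # every birth its own group
  fit1 <- mpits_fit_design(bundle1, control)
  # a boundary drop of the level-1 term means the statistic is 0
  if ("woman_intercept" %in% (fit1$boundary_dropped %||% character(0)) ||
      length(fit1$theta) == length(fit0$theta)) {
    test <- list(statistic = 0, df = 1L, p_value = 1, boundary = TRUE)
  } else {
    test <- lrt(fit0, fit1, boundary = TRUE)
  }
  list(statistic = test$statistic, df = test$df, p_value = test$p_value,
       boundary = TRUE, fit_without = fit0, fit_with = fit1)
}

#' Ten-percent change-in-estimate screen
#'
#' Keeps an adjustment (confounder set, or the seasonal terms) if it moves
#' the subsidy coefficient by at least `threshold` in relative terms.
#'
#' @param fit_with,fit_without fits with and without the adjustment.
#' @param threshold relative change threshold (default 0.10).
#' @return list with `keep`, `relative_change`, `indeterminate` (TRUE when
#'   the reference coefficient is zero, in which case the adjustment is
#'   kept by default).
#' @export
confounder_screen <- function(fit_with, fit_without, threshold = 0.10) {
  b_w <- coef(fit_with)["subsidy"]
  b_o <- coef(fit_without)["subsidy"]
  if (is.na(b_w) || is.na(b_o)) stop("fits lack a subsidy coefficient")
  if (b_o == 0) {
    return(list(keep = TRUE, relative_change = NA_real_,
                indeterminate = TRUE))
  }
  rel <- abs(b_w - b_o) / abs(b_o)
  list(keep = rel >= threshold, relative_change = unname(rel),
       indeterminate = FALSE)
}
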