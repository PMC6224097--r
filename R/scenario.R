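#' Exposure-definition scenarios for the subsidy cutoff
#'
#' The subsidy was officially introduced on 1 January 2007 but reached
#' districts over the following months, so the exposure status of births in
#' the first quarter of 2007 is uncertain. Three scenarios operationalize
#' this: the primary analysis dates exposure from January 2007; the first
#' sensitivity analysis shifts the cutoff to April 2007; the second drops
#' births of January-March 2007 altogether.
#'
#' @param name one of `"primary"`, `"shift_april"`, `"exclude_q1"`, or
#'   `"oracle"`. The oracle scenario uses the generator-recorded
#'   `true_exposed` flag (available only for simulated records) and is the
#'   reference point for misclassification analyses.
#' @param cutoff_month,exclusion_window override the scenario's standard
#'   cutoff (month index, 0 = Jan 2000) or exclusion window
#'   (`c(first, last)`, inclusive). Rarely needed.
#' @return an object of class `exposure_scenario` with fields `name`,
#'   `cutoff_month` and `exclusion_window` (NULL when nothing is excluded).
#' @examples
#' exposure_scenario("primary")
#' exposure_scenario("exclude_q1")
#' @export
exposure_scenario <- function(name = c("primary", "shift_april", "exclude_q1",
                                       "oracle"),
                              cutoff_month = NULL,
                              exclusion_window = NULL) {
  name <- match.arg(name)
  std <- switch(name,
    primary     = list(cutoff = MONTH_JAN2007, excl = NULL),
    shift_april = list(cutoff = MONTH_APR2007, excl = NULL),
    exclude_q1  = list(cutoff = MONTH_JAN2007,
                       excl = c(MONTH_JAN2007, MONTH_APR2007 - 1L)),
    oracle      = list(cutoff = MONTH_JAN2007, excl = NULL)
  )
  sc <- structure(
    list(name = name,
         cutoff_month = as.integer(cutoff_month %||% std$cutoff),
         exclusion_window = exclusion_window %||% std$excl),
    class = "exposure_scenario")
  if (!is.null(sc$exclusion_window)) {
    ew <- sc$exclusion_window
    stopifnot(length(ew) == 2L, ew[1] <= ew[2])
    sc$exclusion_window <- as.integer(ew)
  }
  sc
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat("Exposure scenario:", x$name, "\n")
  cat("  cutoff month:", x$cutoff_month,
      sprintf("(%s)", month_label(x$cutoff_month)), "\n")
  if (!is.null(x$exclusion_window)) {
    cat("  excluded births:", month_label(x$exclusion_window[1]), "to",
        month_label(x$exclusion_window[2]), "\n")
  }
  invisible(x)
}

#' Apply an exposure scenario to birth records
#'
#' Assigns the subsidy exposure indicator and removes births falling in the
#' scenario's exclusion window. A birth in the cutoff month itself is coded
#' exposed: month-resolution data cannot split a month.
#'
#' @param records a birth-record data frame (see [read_births()]).
#' @param scenario an [exposure_scenario()].
#' @return a list with `records` (included rows, with an added integer
#'   column `exposed`), `n_excluded`, and `excluded` (the dropped rows).
#' @export
apply_scenario <- function(records, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(scenario$exclusion_window)) {
    ew <- scenario$exclusion_window
    keep <- !(records$birth_month >= ew[1] & records$birth_month <= ew[2])
  }
  out <- records[keep, , drop = FALSE]
  if (scenario$name == "oracle") {
    if (is.null(out$true_exposed))
      stop("oracle scenario requires the generator column 'true_exposed'")
    out$exposed <- as.integer(out$true_exposed)
  } else {
    out$exposed <- as.integer(out$birth_month >= scenario$cutoff_month)
  }
  list(records = out,
       n_excluded = sum(!keep),
       excluded = records[!keep, , drop = FALSE])
}
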