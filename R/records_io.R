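# Birth-record table I/O, sample-flow accounting and the descriptive
# characteristics ledger.

BIRTH_COLUMNS <- c("region_id", "cluster_id", "household_id", "woman_id",
                   "birth_id", "birth_month", "calendar_month_of_year",
                   "facility_delivery", "neonatal_death", "rural",
                   "wealth_quintile", "education", "literate",
                   "mother_age_group", "multiple_birth", "birth_order_cat",
                   "preceding_interval_cat", "mother_worked",
                   "newborn_female")

BIRTH_LEVELS <- list(
  education = c("none", "primary", "secondary+"),
  mother_age_group = c("15-19", "20-24", "25-29", "30-34", "35-39", "40-49"),
  birth_order_cat = c("first", "2-4", "5+"),
  preceding_interval_cat = c("ge36", "lt36", "first")
)

BIRTH_BINARY <- c("facility_delivery", "neonatal_death", "rural", "literate",
                  "multiple_birth", "mother_worked", "newborn_female")

#' Write a birth-record table
#'
#' Plain-text, UTF-8, header row. `birth_month` is an integer month index
#' with 0 = January 2000.
#'
#' @param records birth-record data frame.
#' @param path output file.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_births <- function(records, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  cols <- intersect(c(BIRTH_COLUMNS, "true_exposed"), names(records))
  utils::write.table(records[, cols], path,
                     sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a birth-record table
#'
#' Checks the column contract, coerces types, and canonicalizes category
#' labels; unknown labels are reported with the offending row and column.
#'
#' @param path file written by [write_births()] or conforming to its
#'   column contract.
#' @param dialect `"csv"` or `"tsv"`.
#' @return a validated birth-record data frame.
#' @export
read_births <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "csv") "," else "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          check.names = FALSE)
  validate_births(df)
}

#' Validate an in-memory birth-record table
#'
#' @param df data frame to check against the column contract.
#' @return the validated data frame (integer-coerced ids and binaries).
#' @export
validate_births <- function(df) {
  missing_cols <- setdiff(BIRTH_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in names(BIRTH_LEVELS)) {
    bad <- which(!(df[[col]] %in% BIRTH_LEVELS[[col]]))
    if (length(bad))
      stop(sprintf("unknown label '%s' in column '%s' (first at row %d)",
                   df[[col]][bad[1]], col, bad[1]))
  }
  for (col in BIRTH_BINARY) {
    v <- df[[col]]
    if (!all(v %in% c(0L, 1L)))
      stop(sprintf("column '%s' must be 0/1 (first bad value at row %d)",
                   col, which(!(v %in% c(0L, 1L)))[1]))
    df[[col]] <- as.integer(v)
  }
  for (col in c("region_id", "cluster_id", "household_id", "woman_id",
                "birth_id", "birth_month", "calendar_month_of_year",
                "wealth_quintile")) {
    df[[col]] <- as.integer(df[[col]])
  }
  if (!all(df$wealth_quintile %in% 1:5))
    stop("wealth_quintile must be 1..5")
  if (!all(df$calendar_month_of_year == df$birth_month %% 12L + 1L))
    stop("calendar_month_of_year inconsistent with birth_month")
  if (any((df$birth_order_cat == "first") !=
          (df$preceding_interval_cat == "first")))
    stop("birth_order_cat 'first' must coincide with preceding interval 'first'")
  df
}

#' Sample-flow accounting
#'
#' Reproduces the flow-diagram bookkeeping of a birth-history survey: the
#' 10-year recall window for the mortality analysis, the 5-year window for
#' the birthplace analysis, and the collapse of multiple births into one
#' delivery (same woman, same birth month).
#'
#' @param records birth-record data frame.
#' @param survey_month month index of the survey (all births must precede
#'   it); defaults to the latest birth month present.
#' @param n_households_selected,n_women_identified optional frame totals
#'   for surveys with non-response; default to the observed counts.
#' @return an object of class `flow_counts`.
#' @export
flow_accounting <- function(records, survey_month = NULL,
                            n_households_selected = NULL,
                            n_women_identified = NULL) {
  survey_month <- survey_month %||% max(records$birth_month, 0L)
  if (nrow(records) && survey_month < max(records$birth_month))
    stop("survey_month precedes some birth months")
  age_m <- survey_month - records$birth_month
  in10 <- age_m >= 0 & age_m < 120
  in5 <- age_m >= 0 & age_m < 60
  r5 <- records[in5, , drop = FALSE]
  deliveries <- if (nrow(r5)) nrow(unique(r5[, c("woman_id", "birth_month")]))
                else 0L
  hh_obs <- length(unique(records$household_id))
  w_obs <- length(unique(records$woman_id))
  out <- list(
    households_selected = n_households_selected %||% hh_obs,
    households_surveyed = hh_obs,
    women_identified = n_women_identified %||% w_obs,
    women_responding = w_obs,
    births_10yr = sum(in10),
    births_5yr = sum(in5),
    deliveries_5yr = deliveries,
    women_in_analysis = if (nrow(records)) length(unique(records$woman_id[in10])) else 0L,
    households_in_analysis = if (nrow(records)) length(unique(records$household_id[in10])) else 0L,
    survey_month = survey_month
  )
  stopifnot(out$deliveries_5yr <= out$births_5yr,
            out$births_5yr <= out$births_10yr)
  structure(out, class = "flow_counts")
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("Sample flow (survey month ", month_label(x$survey_month), ")\n", sep = "")
  cat(sprintf("  households: %d selected, %d surveyed\n",
              x$households_selected, x$households_surveyed))
  cat(sprintf("  women:      %d identified, %d responding\n",
              x$women_identified, x$women_responding))
  cat(sprintf("  births, 10-yr window:  %d\n", x$births_10yr))
  cat(sprintf("  births, 5-yr window:   %d\n", x$births_5yr))
  cat(sprintf("  deliveries, 5-yr window (multiples collapsed): %d\n",
              x$deliveries_5yr))
  invisible(x)
}

# Covariates shown in the descriptive ledger, in table order. Each entry is
# a function returning a factor over the records.
ledger_covariates <- function() {
  list(
    "Neonatal deaths" = function(r)
      factor(ifelse(r$neonatal_death == 1, "died", "survived"),
             c("died", "survived")),
    "New-born's sex (male)" = function(r)
      factor(ifelse(r$newborn_female == 0, "male", "female"),
             c("male", "female")),
    "Number of births (multiple)" = function(r)
      factor(ifelse(r$multiple_birth == 1, "multiple", "single"),
             c("multiple", "single")),
    "Woman's age (years)" = function(r)
      factor(r$mother_age_group, BIRTH_LEVELS$mother_age_group),
    "Previous birth interval" = function(r)
      factor(c(ge36 = "36 months or higher", lt36 = "Less than 36 months",
               first = "First birth")[r$preceding_interval_cat],
             c("36 months or higher", "Less than 36 months", "First birth")),
    "Woman's literacy (illiterate)" = function(r)
      factor(ifelse(r$literate == 0, "illiterate", "literate"),
             c("illiterate", "literate")),
    "Woman's education" = function(r)
      factor(r$education, BIRTH_LEVELS$education),
    "Woman's occupation (worked)" = function(r)
      factor(ifelse(r$mother_worked == 1, "worked", "not worked"),
             c("worked", "not worked")),
    "Household wealth" = function(r)
      factor(c("poorest", "poorer", "middle", "richer",
               "richest")[r$wealth_quintile],
             c("poorest", "poorer", "middle", "richer", "richest")),
    "Place of residence (rural)" = function(r)
      factor(ifelse(r$rural == 1, "rural", "urban"), c("rural", "urban")),
    "Birth order" = function(r)
      factor(r$birth_order_cat, BIRTH_LEVELS$birth_order_cat)
  )
}

#' Category percentage at one-decimal survey-table precision
#'
#' Percentages are computed as 100 * count / total and rounded half away
#' from zero to one decimal, the convention of printed survey tables.
#'
#' @param count,total non-negative counts.
#' @return numeric percentage(s) with one decimal.
#' @export
table_percentage <- function(count, total) {
  round_half_up(100 * count / total, 1L)
}

#' Descriptive characteristics ledger by policy period
#'
#' Counts and one-decimal percentages of each covariate category in the
#' pre-subsidy period, the post-subsidy period and overall, with the
#' period split (and any exclusions) defined by an exposure scenario.
#'
#' @param records birth-record data frame.
#' @param scenario an [exposure_scenario()]; under the exclusion scenario,
#'   excluded births are dropped from both periods and reported.
#' @return object of class `characteristics_table`: a list with `table`
#'   (long data frame: covariate, category, period, count, pct),
#'   `totals`, and `n_excluded`.
#' @export
characteristics_table <- function(records, scenario = exposure_scenario("primary")) {
  ap <- apply_scenario(records, scenario)
  r <- ap$records
  period <- factor(ifelse(r$exposed == 1, "post", "pre"), c("pre", "post"))
  covs <- ledger_covariates()
  rows <- list()
  for (nm in names(covs)) {
    f <- covs[[nm]](r)
    for (per in c("pre", "post", "total")) {
      idx <- if (per == "total") rep(TRUE, length(f)) else period == per
      tot <- sum(idx)
      cnt <- table(f[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = nm, category = names(cnt), period = per,
        count = as.integer(cnt),
        pct = table_percentage(as.integer(cnt), tot),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    table = do.call(rbind, rows),
    totals = c(pre = sum(period == "pre"), post = sum(period == "post"),
               total = length(period)),
    n_excluded = ap$n_excluded,
    scenario = scenario$name
  ), class = "characteristics_table")
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat(sprintf("Characteristics of live births (scenario: %s)\n", x$scenario))
  cat(sprintf("  n = %d pre, %d post, %d total (%d excluded)\n\n",
              x$totals["pre"], x$totals["post"], x$totals["total"],
              x$n_excluded))
  tb <- x$table
  for (cv in unique(tb$covariate)) {
    cat(cv, "\n")
    sub <- tb[tb$covariate == cv, ]
    for (cat_ in unique(sub$category)) {
      s <- sub[sub$category == cat_, ]
      pre <- s[s$period == "pre", ]; post <- s[s$period == "post", ]
      tot <- s[s$period == "total", ]
      cat(sprintf("  %-22s %8d (%4.1f) %8d (%4.1f) %8d (%4.1f)\n",
                  cat_, pre$count, pre$pct, post$count, post$pct,
                  tot$count, tot$pct))
    }
  }
  invisible(x)
}

#' Export the ledger (flow counts + characteristics) as JSON
#'
#' @param flow a [flow_accounting()] result.
#' @param chars a [characteristics_table()] result.
#' @param path output JSON file.
#' @export
write_ledger <- function(flow, chars, path) {
  jsonlite::write_json(
    list(flow = unclass(flow),
         characteristics = list(table = chars$table,
                                totals = as.list(chars$totals),
                                n_excluded = chars$n_excluded,
                                scenario = chars$scenario)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
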