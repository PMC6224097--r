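# Birth-record I/O, flow accounting, characteristics ledger.

test_that("write/read round-trips identically in both dialects", {
  rec <- suppressWarnings(generate_population(small_config(seed = 21)))
  for (dialect in c("csv", "tsv")) {
    path <- tempfile(fileext = paste0(".", dialect))
    write_births(rec, path, dialect)
    back <- read_births(path, dialect)
    cols <- setdiff(names(back), "true_exposed")
    ref <- rec[cols]
    attr(ref, "row.names") <- attr(back[cols], "row.names")
    expect_identical(back[cols], ref)
    unlink(path)
  }
  # csv and tsv parse to the same records
  p1 <- tempfile(); p2 <- tempfile()
  write_births(rec, p1, "csv"); write_births(rec, p2, "tsv")
  expect_identical(read_births(p1, "csv"), read_births(p2, "tsv"))
  unlink(c(p1, p2))
})

test_that("validation names the offending label, row and column", {
  rec <- suppressWarnings(generate_population(small_config(seed = 22)))
  bad <- rec
  bad$education[5] <- "tertiary"
  expect_error(validate_births(bad), "tertiary")
  expect_error(validate_births(bad), "education")
  expect_error(validate_births(bad), "row 5")
  bad2 <- rec[, setdiff(names(rec), "wealth_quintile")]
  expect_error(validate_births(bad2), "wealth_quintile")
  bad3 <- rec
  bad3$rural[2] <- 3L
  expect_error(validate_births(bad3), "rural")
})

test_that("flow accounting: windows, twin collapse, degenerate input", {
  # a woman with twins inside the 5-year window
  rec <- suppressWarnings(generate_population(small_config(seed = 23)))
  tw <- rec[rec$multiple_birth == 1 &
              (131 - rec$birth_month) < 60, ]
  expect_gt(nrow(tw), 0)
  fl <- flow_accounting(rec, survey_month = 131)
  in5 <- (131 - rec$birth_month) < 60
  in10 <- (131 - rec$birth_month) < 120
  # independent recount
  expect_identical(fl$births_5yr, sum(in5))
  expect_identical(fl$births_10yr, sum(in10))
  r5 <- rec[in5, ]
  expect_identical(fl$deliveries_5yr,
                   nrow(unique(r5[, c("woman_id", "birth_month")])))
  expect_lt(fl$deliveries_5yr, fl$births_5yr)   # twins present
  expect_lte(fl$births_5yr, fl$births_10yr)

  # two twin records = one delivery
  one <- rec[1:2, ]
  one$woman_id <- 1L; one$birth_month <- 100L; one$multiple_birth <- 1L
  fl1 <- flow_accounting(one, survey_month = 131)
  expect_identical(fl1$births_5yr, 2L)
  expect_identical(fl1$deliveries_5yr, 1L)

  # all births outside both windows
  old <- rec[1:5, ]; old$birth_month <- 3L
  fl0 <- flow_accounting(old, survey_month = 131 + 120)
  expect_identical(fl0$births_10yr, 0L)
  expect_identical(fl0$births_5yr, 0L)
  # empty set: zero counts, no error
  fle <- flow_accounting(rec[0, ], survey_month = 131)
  expect_identical(fle$births_10yr, 0L)
})

test_that("percentages use half-up rounding at one decimal", {
  expect_equal(table_percentage(16811, 20513), 82.0)  # 81.95 -> 82.0
  expect_equal(table_percentage(803, 20513), 3.9)
  expect_equal(table_percentage(1, 1), 100.0)
  expect_equal(round_half_up(0.05, 1), 0.1)           # base round gives 0
  expect_equal(round_half_up(-0.05, 1), -0.1)         # away from zero
})

test_that("characteristics table conserves counts and handles exclusions", {
  rec <- suppressWarnings(generate_population(small_config(seed = 24)))
  ch <- characteristics_table(rec, exposure_scenario("primary"))
  tb <- ch$table
  for (cv in unique(tb$covariate)) {
    for (per in c("pre", "post", "total")) {
      sub <- tb[tb$covariate == cv & tb$period == per, ]
      expect_identical(sum(sub$count), unname(ch$totals[per]))
      expect_equal(sub$pct, table_percentage(sub$count, ch$totals[per]))
    }
  }
  expect_identical(unname(ch$totals["pre"] + ch$totals["post"]),
                   unname(ch$totals["total"]))
  expect_identical(ch$n_excluded, 0L)

  chx <- characteristics_table(rec, exposure_scenario("exclude_q1"))
  q1 <- sum(rec$birth_month >= 84 & rec$birth_month <= 86)
  expect_identical(chx$n_excluded, q1)
  expect_identical(unname(chx$totals["total"]) + q1, nrow(rec))

  # single pre-period record: category shares are 100%
  one <- rec[1, ]
  one$birth_month <- 50L; one$calendar_month_of_year <- 50L %% 12L + 1L
  ch1 <- characteristics_table(one, exposure_scenario("primary"))
  got <- ch1$table
  expect_true(all(got$pct[got$period == "pre" & got$count == 1] == 100.0))
})

test_that("ledger JSON export round-trips", {
  rec <- suppressWarnings(generate_population(small_config(seed = 25)))
  fl <- flow_accounting(rec, 131)
  ch <- characteristics_table(rec)
  path <- tempfile(fileext = ".json")
  write_ledger(fl, ch, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(as.integer(back$flow$births_5yr), fl$births_5yr)
  expect_identical(nrow(back$characteristics$table), nrow(ch$table))
  unlink(path)
})
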