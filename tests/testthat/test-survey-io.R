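make_records <- function(rows) {
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(date = as.Date(r[[1]]), station = r[[2]], region = "r1",
                   taxon = r[[3]], group = r[[4]], count = as.integer(r[[5]]),
                   effort = as.numeric(r[[6]]))
  }))
}

test_that("survey CSV round-trips through write and read without loss", {
  tax <- list(taxon_spec("a", "fish"), taxon_spec("b", "zooplankton"))
  des <- survey_design(years = c(2000, 2004), regions = "r1",
                       stations_per_region = 2, missing_rate = 0.1, seed = 17)
  rec <- generate_survey_data(tax, des)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(rec, path)
  back <- read_survey_table(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
})

test_that("malformed rows are dropped with line numbers; missing columns fail hard", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,station,region,taxon,group,count,effort",
               "2000-01-01,s1,r1,a,fish,3,2.0",
               "2000-02-01,s1,r1,a,fish,4,0",      # effort 0: invariant violated
               "2000-03-01,s1,r1,a,fish,-1,2.0",   # negative count
               "2000-04-01,s1,r1,a,fish,5,1.5"), path)
  expect_warning(rec <- read_survey_table(path), "line\\(s\\): 3, 4")
  expect_equal(nrow(rec), 2)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,station,region,taxon,group,count",
               "2000-01-01,s1,r1,a,fish,3"), path2)
  expect_error(read_survey_table(path2), "effort")
})

test_that("CPUE is averaged across tows then log(x+1)-transformed", {
  rec <- make_records(list(
    list("2000-06-01", "s1", "a", "fish", 10, 2),   # CPUE 5
    list("2000-07-01", "s1", "a", "fish", 0, 2),    # zero catch
    list("2001-06-01", "s1", "a", "fish", 8, 2),    # two tows: CPUE 4 and 6
    list("2001-06-01", "s1", "a", "fish", 12, 2)
  ))
  ser <- compute_cpue_series(rec, start_year = 1995)
  v <- function(m, y) ser$value[ser$month == m & ser$year == y]
  expect_equal(v(6, 2000), log(6))  # ln(5 + 1)
  expect_equal(v(7, 2000), 0)      # ln(0 + 1)
  expect_equal(v(6, 2001), log(6)) # mean CPUE 5 before transform
  expect_false(ser$observed[ser$month == 8 & ser$year == 2000])
})

test_that("compute_cpue_series drops pre-window years and ignores row order", {
  rec <- make_records(list(
    list("1990-06-01", "s1", "a", "fish", 9, 1),
    list("2000-06-01", "s1", "a", "fish", 3, 1),
    list("2001-06-01", "s1", "a", "fish", 4, 1)
  ))
  ser <- compute_cpue_series(rec, start_year = 1995)
  expect_false(1990 %in% ser$year)
  shuffled <- rec[c(3, 1, 2), ]
  expect_equal(as.data.frame(compute_cpue_series(shuffled, 1995)),
               as.data.frame(ser))
})

# series with an exact number of nonzero surveys, spread over the grid
engineered_series <- function(n_nonzero, taxon, group, n_years = 29) {
  grid <- tidyr::expand_grid(month = 1:12, year = seq_len(n_years) + 1994)
  grid$value <- 0
  grid$value[seq_len(n_nonzero)] <- 1.5
  tibble::tibble(taxon = taxon, station = "s1", region = "r1", group = group,
                 month = grid$month, year = grid$year, value = grid$value,
                 observed = TRUE)
}

test_that("detection screening applies inclusive group thresholds", {
  ser <- dplyr::bind_rows(
    engineered_series(49, "f49", "fish"),
    engineered_series(50, "f50", "fish"),
    engineered_series(51, "f51", "fish"),
    engineered_series(0, "z0", "zooplankton"),
    engineered_series(233, "z233", "zooplankton"),
    engineered_series(234, "z234", "zooplankton")
  )
  kept <- filter_by_detections(ser)
  expect_setequal(unique(kept$taxon), c("f50", "f51", "z234"))
  expect_error(filter_by_detections(dplyr::mutate(ser, group = "algae")),
               "unknown group")
  # idempotent
  expect_identical(filter_by_detections(kept), kept)
})

test_that("month splitting partitions a series without loss", {
  tax <- taxon_spec("a", "fish", detection_prob = 1)
  des <- survey_design(years = c(1995, 2023), regions = "r1",
                       stations_per_region = 1, missing_rate = 0, seed = 19)
  ser <- compute_cpue_series(generate_survey_data(list(tax), des), 1995)
  out <- split_months(ser)
  counts <- dplyr::count(out, .data$month)
  expect_equal(nrow(counts), 12)
  expect_true(all(counts$n == 29))  # 12 series of length 29
  # reconstruction: same rows, only the arrangement differs
  key <- function(d) d[order(d$taxon, d$station, d$year, d$month), ]
  expect_equal(as.data.frame(key(out)), as.data.frame(key(ser)))
})

test_that("month splitting flags a skipped survey as unobserved", {
  rec <- make_records(list(
    list("2002-06-01", "s1", "a", "fish", 3, 1),
    list("2004-06-01", "s1", "a", "fish", 4, 1)  # June 2003 never surveyed
  ))
  out <- split_months(compute_cpue_series(rec, 1995))
  june <- out[out$month == 6, ]
  expect_false(june$observed[june$year == 2003])
  expect_true(all(june$observed[june$year %in% c(2002, 2004)]))
})

test_that("month-stratum screening keeps >= 30% presence over observed years", {
  base <- function(n_nonzero, taxon) {
    vals <- c(rep(2, n_nonzero), rep(0, 29 - n_nonzero))
    series_from_values(vals, taxon = taxon)
  }
  ser <- dplyr::bind_rows(base(9, "keep"),   # 9/29 = 31.0%
                          base(8, "drop"),   # 8/29 = 27.6%
                          base(0, "zero"))
  kept <- filter_month_strata(ser)
  expect_setequal(unique(kept$taxon), "keep")
  expect_identical(filter_month_strata(kept), kept)  # idempotent
  # denominator is observed years, not the calendar span
  gappy <- series_from_values(c(rep(2, 3), rep(0, 6), rep(NA, 20)), taxon = "g")
  expect_equal(unique(filter_month_strata(gappy)$taxon), "g")  # 3/9 = 33%
})
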