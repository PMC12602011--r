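#' Read a survey table from the standard CSV layout
#'
#' Parses a long-format survey CSV (columns `date`, `station`, `region`,
#' `taxon`, `group`, `count`, `effort`). Rows violating the record invariants
#' (negative count, non-positive effort, unparseable date, missing fields) are
#' dropped and reported with their line numbers; a missing required column is
#' a hard failure naming the column.
#'
#' @param path Path to the CSV file.
#' @return A tibble of survey records.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop_phenorisk("file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  req <- c("date", "station", "region", "taxon", "group", "count", "effort")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop_phenorisk("survey CSV is missing required column(s): ",
                   paste(missing, collapse = ", "))
  }
  parsed <- tibble::tibble(
    date = as.Date(raw$date, format = "%Y-%m-%d"),
    station = raw$station, region = raw$region,
    taxon = raw$taxon, group = raw$group,
    count = suppressWarnings(as.numeric(raw$count)),
    effort = suppressWarnings(as.numeric(raw$effort))
  )
  bad <- is.na(parsed$date) | is.na(parsed$count) | is.na(parsed$effort) |
    parsed$count < 0 | parsed$count != floor(parsed$count) |
    parsed$effort <= 0 | is.na(parsed$station) | is.na(parsed$taxon)
  if (any(bad)) {
    # +1 for the header: report physical line numbers in the file
    warning(sprintf("dropped %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")),
            call. = FALSE)
    parsed <- parsed[!bad, ]
  }
  parsed$count <- as.integer(parsed$count)
  parsed
}

#' Build log-CPUE month series from survey records
#'
#' For each taxon, station and calendar month, computes catch per unit effort
#' (CPUE = count / effort) per tow, averages CPUE over multiple tows in the
#' same station-month, then applies the `log(x + 1)` transform (natural log).
#' Years before `start_year` are dropped; station-months with no survey are
#' kept in the grid but flagged unobserved.
#'
#' @param records Survey records (from [read_survey_table()] or
#'   [generate_survey_data()]).
#' @param start_year First year retained; earlier surveys are discarded.
#' @return A tibble of month series values with columns `taxon`, `station`,
#'   `region`, `group`, `month`, `year`, `value` (log1p CPUE, `NA` where
#'   unobserved) and `observed`.
#' @export
compute_cpue_series <- function(records, start_year = 1995) {
  if (nrow(records) == 0) stop_phenorisk("`records` is empty")
  rec <- dplyr::mutate(records,
                       year = as.integer(format(.data$date, "%Y")),
                       month = as.integer(format(.data$date, "%m")))
  rec <- dplyr::filter(rec, .data$year >= start_year)
  if (nrow(rec) == 0) stop_phenorisk("no records at or after `start_year`")
  cell <- dplyr::summarise(
    dplyr::group_by(rec, .data$taxon, .data$station, .data$region,
                    .data$group, .data$month, .data$year),
    value = log1p(mean(.data$count / .data$effort)),
    .groups = "drop"
  )
  years <- seq(min(cell$year), max(cell$year))
  out <- tidyr::complete(
    dplyr::group_by(cell, .data$taxon, .data$station, .data$region, .data$group),
    month = 1:12, year = years
  )
  out <- dplyr::ungroup(out)
  out$observed <- !is.na(out$value)
  dplyr::arrange(out, .data$taxon, .data$station, .data$year, .data$month)
}

#' Screen series by nonzero-detection counts
#'
#' A taxon-by-station full monthly series is retained only if its number of
#' nonzero-CPUE surveys reaches the group threshold (inclusive): fish and
#' zooplankton have different thresholds because the two monitoring
#' programmes differ in sampling intensity.
#'
#' @param series Month-series tibble from [compute_cpue_series()].
#' @param min_nonzero_fish Minimum nonzero detections for fish series.
#' @param min_nonzero_zoop Minimum nonzero detections for zooplankton series.
#' @return The retained subset of `series`.
#' @export
filter_by_detections <- function(series, min_nonzero_fish = 50,
                                 min_nonzero_zoop = 234) {
  known <- c(fish = min_nonzero_fish, zooplankton = min_nonzero_zoop)
  bad <- setdiff(unique(series$group), names(known))
  if (length(bad)) {
    stop_phenorisk("unknown group label(s): ", paste(bad, collapse = ", "),
                   " (expected fish or zooplankton)")
  }
  keep <- dplyr::summarise(
    dplyr::group_by(series, .data$taxon, .data$station, .data$group),
    n_nonzero = sum(.data$observed & .data$value > 0),
    .groups = "drop"
  )
  keep <- dplyr::filter(keep, .data$n_nonzero >= known[.data$group])
  dplyr::semi_join(series, keep, by = c("taxon", "station"))
}

#' Split full monthly series into month-specific annual series
#'
#' Re-keys the series so that each (taxon, station, calendar month) holds one
#' annual-scale time series: all the Januaries form one series, all the
#' Februaries another, and so on. The union of the twelve outputs is exactly
#' the input (a partition), so no data are gained or lost.
#'
#' @param series Month-series tibble.
#' @return The same values arranged as month-specific series, sorted by
#'   `taxon`, `station`, `month`, `year`.
#' @export
split_months <- function(series) {
  span <- length(unique(series$year))
  if (span < 2) stop_phenorisk("input series must span at least 2 years")
  dplyr::arrange(series, .data$taxon, .data$station, .data$month, .data$year)
}

#' Screen month strata by historical presence
#'
#' A taxon-by-station-by-month series is retained only if the taxon was
#' present (nonzero value) in at least `min_presence` of the observed
#' (surveyed) years; skipped surveys do not count against a taxon.
#' Strata with zero observed years are dropped with a warning.
#'
#' @param series Month-series tibble from [split_months()].
#' @param min_presence Minimum fraction of observed years with nonzero value.
#' @return The retained subset of `series`.
#' @export
filter_month_strata <- function(series, min_presence = 0.30) {
  tab <- dplyr::summarise(
    dplyr::group_by(series, .data$taxon, .data$station, .data$month),
    n_obs = sum(.data$observed),
    n_nonzero = sum(.data$observed & .data$value > 0),
    .groups = "drop"
  )
  empty <- dplyr::filter(tab, .data$n_obs == 0)
  if (nrow(empty) > 0) {
    warning(sprintf("%d stratum(-a) with zero observed years dropped", nrow(empty)),
            call. = FALSE)
  }
  keep <- dplyr::filter(tab, .data$n_obs > 0,
                        .data$n_nonzero / .data$n_obs >= min_presence)
  dplyr::semi_join(series, keep, by = c("taxon", "station", "month"))
}
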