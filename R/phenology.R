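#' Per-calendar-month mean catch for one taxon and region
#'
#' Averages untransformed CPUE (back-transformed from the stored
#' `log(x + 1)` values) across all observed years and stations, per calendar
#' month. Months never observed contribute a mean of 0 and are flagged via
#' the `"unobserved_months"` attribute.
#'
#' @param series Month-series tibble for one taxon and region.
#' @return Numeric vector of 12 per-month mean CPUE values (January first).
#' @export
monthly_mean_catch <- function(series) {
  obs <- dplyr::filter(series, .data$observed)
  if (nrow(obs) == 0) stop_phenorisk("no observed values in series")
  agg <- dplyr::summarise(dplyr::group_by(obs, .data$month),
                          mean_catch = mean(expm1(.data$value)),
                          .groups = "drop")
  means <- numeric(12)
  means[agg$month] <- agg$mean_catch
  attr(means, "unobserved_months") <- setdiff(1:12, agg$month)
  means
}

# Is a set of calendar months contiguous on the circular calendar?
is_circular_contiguous <- function(months) {
  months <- sort(unique(months))
  if (length(months) >= 12 || length(months) == 1) return(TRUE)
  present <- 1:12 %in% months
  # number of run starts on the circle: a run starts where present & !prev
  starts <- sum(present & !present[c(12, 1:11)])
  starts == 1
}

# Order a circularly contiguous month set along the calendar, starting after
# the largest gap (so Dec-Jan windows print as 12, 1).
order_circular <- function(months) {
  months <- sort(unique(months))
  if (length(months) >= 12) return(1:12)
  present <- 1:12 %in% months
  starts <- which(present & !present[c(12, 1:11)])
  if (length(starts) != 1) return(months)  # non-contiguous: calendar order
  idx <- ((starts - 1 + 0:11) %% 12) + 1
  idx[idx %in% months]
}

#' Detect the high-abundance window from monthly means
#'
#' Months are added in descending order of mean catch (ties broken toward
#' the earlier calendar month) until the cumulative share of the annual total
#' reaches `coverage_target`. Any single-month gap between selected months is
#' then filled so the window is uninterrupted, and coverage is recomputed on
#' the final set. The calendar is treated as circular, so December–January
#' windows are contiguous and a December/February selection has a fillable
#' one-month gap. If gaps wider than `max_gap` months remain, the window is
#' reported unfilled and flagged non-contiguous.
#'
#' @param means 12 per-month mean catch values (January first), at least one
#'   positive.
#' @param coverage_target Fraction of the annual total the window must hold.
#' @param max_gap Widest gap (in months) that may be filled; the screening
#'   rule licenses 1.
#' @param taxon,region Optional labels carried into the result.
#' @return An `abundance_window`: list with `months` (ordered along the
#'   circle), `coverage`, `contiguous`, `taxon`, `region`.
#' @export
#' @examples
#' m <- c(0, 0, 10, 40, 5, 30, 0, 0, 0, 0, 0, 0)
#' high_abundance_window(m)  # April-June, coverage 0.8824
high_abundance_window <- function(means, coverage_target = 0.80, max_gap = 1,
                                  taxon = NA_character_, region = NA_character_) {
  if (length(means) != 12 || any(!is.finite(means)) || any(means < 0)) {
    stop_phenorisk("`means` must be 12 finite non-negative values")
  }
  total <- sum(means)
  if (total <= 0) stop_phenorisk("all-zero monthly means: no window exists")
  if (coverage_target <= 0 || coverage_target > 1) {
    stop_phenorisk("`coverage_target` must lie in (0, 1]")
  }
  ord <- order(-means, 1:12)  # ties toward the earlier calendar month
  cum <- cumsum(means[ord]) / total
  n_sel <- which(cum >= coverage_target - 1e-12)[1]
  selected <- sort(ord[seq_len(n_sel)])

  filled <- selected
  if (length(selected) >= 2 && max_gap >= 1) {
    present <- 1:12 %in% selected
    for (m in setdiff(1:12, selected)) {
      prev <- ((m - 2) %% 12) + 1
      nxt <- (m %% 12) + 1
      if (present[prev] && present[nxt]) filled <- c(filled, m)
    }
    filled <- sort(unique(filled))
  }
  contiguous <- is_circular_contiguous(filled)
  final <- if (contiguous) filled else selected
  structure(
    list(taxon = taxon, region = region,
         months = order_circular(final),
         selected = selected,  # pre-fill greedy selection, calendar order
         coverage = sum(means[final]) / total,
         contiguous = contiguous),
    class = "abundance_window"
  )
}

#' Compact month-range label for a window
#'
#' Contiguous windows print as a circular range (`"4-6"`, `"12-1"`, or a
#' single month `"9"`); non-contiguous selections list every month.
#'
#' @param window An `abundance_window`.
#' @return A character scalar.
#' @export
format_window_months <- function(window) {
  m <- window$months
  if (length(m) == 1) return(as.character(m))
  if (isTRUE(window$contiguous) && length(m) < 12) {
    return(paste0(m[1], "-", m[length(m)]))
  }
  paste(m, collapse = ",")
}

#' @export
print.abundance_window <- function(x, ...) {
  cat("<abundance_window>", x$taxon, "/", x$region, "\n")
  cat(sprintf("  months %s | coverage %.2f%%%s\n",
              paste(x$months, collapse = "-"), 100 * x$coverage,
              if (!x$contiguous) " | NON-CONTIGUOUS (gaps > 1 month)" else ""))
  invisible(x)
}

#' Monthly baseline-risk profile for one taxon and region
#'
#' One baseline decline risk per modeled calendar month; months with no fit
#' (the taxon was too often absent there to model) are flagged unmodeled with
#' `NA` risk, matching the gaps in monitoring-based risk phenologies.
#'
#' @param fits Fits table (rows of [fit_month_strata()]) for one taxon and
#'   region, one row per modeled month.
#' @param query A [risk_query()].
#' @param mean_catch Optional 12 per-month mean CPUE values to carry along
#'   (from [monthly_mean_catch()]).
#' @param q_floor Variance floor.
#' @return A tibble with 12 rows: `taxon`, `region`, `month`, `mean_catch`,
#'   `risk`, `modeled`.
#' @export
monthly_risk_profile <- function(fits, query = risk_query(),
                                 mean_catch = NULL, q_floor = 1e-10) {
  if (nrow(fits) < 1) stop_phenorisk("need at least one monthly fit")
  if (anyDuplicated(fits$month)) stop_phenorisk("multiple fits for one month")
  risk <- rep(NA_real_, 12)
  for (i in seq_len(nrow(fits))) {
    est <- scenario_risks(as_mar_fit(fits[i, ]), query, q_floor = q_floor)
    risk[fits$month[i]] <- est$p_baseline
  }
  mc <- if (is.null(mean_catch)) rep(NA_real_, 12) else as.numeric(mean_catch)
  tibble::tibble(taxon = fits$taxon[1], region = fits$region[1],
                 month = 1:12, mean_catch = mc, risk = risk,
                 modeled = !is.na(risk))
}

#' Correlation between monthly decline risk and mean abundance
#'
#' Pearson correlation across calendar months between baseline risk and mean
#' catch, with the two-sided p-value from the usual t transform on `n - 2`
#' degrees of freedom. A negative correlation would mean high-abundance
#' months are the safer ones.
#'
#' @param profile Profile tibble from [monthly_risk_profile()] (must carry
#'   `mean_catch`).
#' @return A list: `r`, `p_value`, `n_months`, `undefined` (TRUE when either
#'   vector has zero variance, in which case `r` is `NA`).
#' @export
risk_abundance_correlation <- function(profile) {
  ok <- complete.cases(profile[, c("risk", "mean_catch")])
  if (sum(ok) < 3) {
    stop_phenorisk("need >= 3 months with both risk and mean_catch present")
  }
  x <- profile$risk[ok]
  y <- profile$mean_catch[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n_months = sum(ok),
                undefined = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_months = sum(ok),
       undefined = FALSE)
}
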