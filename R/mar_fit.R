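#' Gap-aware differences of a station-replicated month series
#'
#' Under the random walk with drift, the difference of log-CPUE across `k`
#' years is Gaussian with mean `k * U` and variance `k * Q`; missing survey
#' years therefore widen the span of a difference rather than discarding it.
#' One difference is produced per adjacent pair of observed years, per
#' station. Stations with fewer than two observed years contribute nothing.
#'
#' @param series_group Month-series tibble for one taxon, region and calendar
#'   month (one or more stations).
#' @return A tibble with columns `station`, `span_k`, `delta`.
#' @export
extract_differences <- function(series_group) {
  obs <- dplyr::filter(series_group, .data$observed)
  out <- lapply(split(obs, obs$station), function(d) {
    d <- d[order(d$year), ]
    if (nrow(d) < 2) {
      message("station ", d$station[1] %||% "?",
              " has < 2 observed years; contributes no differences")
      return(NULL)
    }
    tibble::tibble(
      station = d$station[-1],
      span_k = diff(d$year),
      delta = diff(d$value)
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(station = character(), span_k = integer(),
                          delta = numeric()))
  }
  res
}

new_mar_fit <- function(taxon = NA_character_, region = NA_character_,
                        month = NA_integer_, U_hat, Q_hat,
                        n_diffs, n_stations, degenerate,
                        U_lo = NA_real_, U_hi = NA_real_,
                        Q_lo = NA_real_, Q_hi = NA_real_,
                        seed = NA_integer_, B = NA_integer_) {
  structure(
    list(taxon = taxon, region = region, month = month,
         U_hat = U_hat, Q_hat = Q_hat,
         U_lo = U_lo, U_hi = U_hi, Q_lo = Q_lo, Q_hi = Q_hi,
         n_diffs = n_diffs, n_stations = n_stations,
         degenerate = degenerate, seed = seed, B = B),
    class = "mar_fit"
  )
}

#' @export
print.mar_fit <- function(x, ...) {
  cat("<mar_fit>", x$taxon, "/", x$region, "/ month", x$month, "\n")
  cat(sprintf("  U_hat = %.5f [%.5f, %.5f]\n", x$U_hat, x$U_lo, x$U_hi))
  cat(sprintf("  Q_hat = %.5g [%.5g, %.5g]%s\n", x$Q_hat, x$Q_lo, x$Q_hi,
              if (isTRUE(x$degenerate)) "  (degenerate: at variance floor)" else ""))
  cat(sprintf("  n_diffs = %d, n_stations = %d\n", x$n_diffs, x$n_stations))
  invisible(x)
}

#' @export
as.data.frame.mar_fit <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

#' Maximum-likelihood drift and process variance from pooled differences
#'
#' Jointly maximises the Gaussian likelihood of the gap-aware differences,
#' `prod N(delta_i | k_i * U, k_i * Q)`, pooled across stations (shared drift,
#' equal variance). The maximisers are closed-form:
#' `U_hat = sum(delta) / sum(k)` and
#' `Q_hat = mean((delta - k * U_hat)^2 / k)` (the `n`-denominator MLE, not
#' `n - 1`). With all spans equal to 1 this is the sample mean and the
#' mean squared deviation of the differences. `Q_hat` is floored at `q_floor`
#' (with the `degenerate` flag raised) so downstream risk formulas stay
#' defined for noise-free series.
#'
#' @param diffs Differences tibble from [extract_differences()] (non-empty).
#' @param q_floor Variance floor on the log^2 scale.
#' @param taxon,region,month Optional stratum labels carried into the fit.
#' @return A `mar_fit` object without confidence intervals (see
#'   [bootstrap_ci()]).
#' @export
#' @examples
#' d <- tibble::tibble(station = "A", span_k = 1, delta = c(0.3, -0.4, 0.5))
#' fit_drift_variance(d)  # U_hat = 0.13333, Q_hat = 0.14889
fit_drift_variance <- function(diffs, q_floor = 1e-10,
                               taxon = NA_character_, region = NA_character_,
                               month = NA_integer_) {
  if (is.null(diffs) || nrow(diffs) == 0) {
    stop_phenorisk("`diffs` is empty: nothing to fit")
  }
  if (any(diffs$span_k < 1) || any(!is.finite(diffs$delta))) {
    stop_phenorisk("differences must have span_k >= 1 and finite delta")
  }
  k <- as.numeric(diffs$span_k)
  delta <- diffs$delta
  U_hat <- sum(delta) / sum(k)
  n <- length(delta)
  Q_raw <- if (n >= 2) mean((delta - k * U_hat)^2 / k) else 0
  degenerate <- n < 2 || Q_raw < q_floor
  Q_hat <- max(Q_raw, q_floor)
  new_mar_fit(taxon = taxon, region = region, month = month,
              U_hat = U_hat, Q_hat = Q_hat,
              n_diffs = n, n_stations = length(unique(diffs$station)),
              degenerate = degenerate)
}

#' Parametric-bootstrap confidence intervals for a drift/variance fit
#'
#' Simulates `B` synthetic station groups from the fitted `(U_hat, Q_hat)`
#' under the random walk with drift, preserving the observation pattern of
#' the data (each difference keeps its span, so missing years are respected),
#' refits each replicate with [fit_drift_variance()], and takes percentile
#' 2.5/97.5 intervals of the replicate estimates.
#'
#' @param fit A `mar_fit` from [fit_drift_variance()].
#' @param series_group The month-series tibble the fit came from (only its
#'   observation pattern is used).
#' @param B Number of bootstrap replicates; values below 100 trigger a
#'   warning because percentile endpoints become unstable.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param q_floor Variance floor applied in each refit.
#' @return The `mar_fit` with `U_lo`, `U_hi`, `Q_lo`, `Q_hi`, `seed`, `B`
#'   filled in.
#' @export
bootstrap_ci <- function(fit, series_group, B = 1000, seed = 1L,
                         q_floor = 1e-10) {
  stopifnot(inherits(fit, "mar_fit"))
  if (B < 100) warning("B < 100: percentile CI endpoints are unstable", call. = FALSE)
  diffs <- extract_differences(series_group)
  if (nrow(diffs) == 0) stop_phenorisk("series group yields no differences")
  k <- as.numeric(diffs$span_k)
  n <- length(k)
  sumk <- sum(k)
  est <- with_seed(seed, {
    # simulate increments delta_i ~ N(k_i U, k_i Q): identical in law to
    # simulating full series on the observed-year grid and differencing
    dmat <- matrix(rnorm(n * B, mean = rep(k, B) * fit$U_hat,
                         sd = sqrt(rep(k, B) * fit$Q_hat)),
                   nrow = n, ncol = B)
    U_b <- colSums(dmat) / sumk
    resid2 <- (dmat - outer(k, U_b))^2 / k
    Q_b <- pmax(colMeans(resid2), q_floor)
    list(U = U_b, Q = Q_b)
  })
  qs <- function(v) unname(quantile(v, c(0.025, 0.975), names = FALSE))
  u_ci <- qs(est$U)
  q_ci <- qs(est$Q)
  fit$U_lo <- min(u_ci[1], fit$U_hat)
  fit$U_hi <- max(u_ci[2], fit$U_hat)
  fit$Q_lo <- min(q_ci[1], fit$Q_hat)
  fit$Q_hi <- max(q_ci[2], fit$Q_hat)
  fit$seed <- as.integer(seed)
  fit$B <- as.integer(B)
  fit
}

#' Fit every taxon-region-month stratum of a screened series set
#'
#' Convenience wrapper running [extract_differences()],
#' [fit_drift_variance()] and (optionally) [bootstrap_ci()] over all strata.
#' Stations within a region are pooled: one shared drift and one process
#' variance per stratum. Strata yielding no differences are skipped.
#'
#' @param series Screened month-series tibble (after [filter_month_strata()]).
#' @param q_floor Variance floor.
#' @param B Bootstrap replicates (see [bootstrap_ci()]).
#' @param seed Top-level seed; each stratum gets a deterministic child seed.
#' @param ci If `FALSE`, skip the bootstrap (CIs collapse to the point
#'   estimate).
#' @return A tibble with one row per fitted stratum.
#' @export
fit_month_strata <- function(series, q_floor = 1e-10, B = 1000, seed = 1L,
                             ci = TRUE) {
  strata <- split(series,
                  list(series$taxon, series$region, series$month), drop = TRUE)
  rows <- lapply(strata, function(grp) {
    diffs <- suppressMessages(extract_differences(grp))
    if (nrow(diffs) == 0) return(NULL)
    fit <- fit_drift_variance(diffs, q_floor = q_floor,
                              taxon = grp$taxon[1], region = grp$region[1],
                              month = grp$month[1])
    if (ci) {
      sseed <- child_seed(seed, paste("boot", grp$taxon[1], grp$region[1],
                                      grp$month[1], sep = ":"))
      fit <- bootstrap_ci(fit, grp, B = B, seed = sseed, q_floor = q_floor)
    } else {
      fit$U_lo <- fit$U_hi <- fit$U_hat
      fit$Q_lo <- fit$Q_hi <- fit$Q_hat
      fit$seed <- as.integer(seed)
      fit$B <- 0L
    }
    tibble::as_tibble(unclass(fit))
  })
  dplyr::bind_rows(rows)
}

#' Rebuild a `mar_fit` object from one row of a fits table
#'
#' @param row A one-row data frame with the `mar_fit` columns (as produced by
#'   [fit_month_strata()]).
#' @return A `mar_fit` object.
#' @export
as_mar_fit <- function(row) {
  row <- as.list(row)
  new_mar_fit(taxon = row$taxon, region = row$region, month = row$month,
              U_hat = row$U_hat, Q_hat = row$Q_hat,
              U_lo = row$U_lo, U_hi = row$U_hi,
              Q_lo = row$Q_lo, Q_hi = row$Q_hi,
              n_diffs = row$n_diffs, n_stations = row$n_stations,
              degenerate = row$degenerate,
              seed = row$seed %||% NA_integer_, B = row$B %||% NA_integer_)
}
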