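#' Specify a decline-risk query
#'
#' @param a Decline threshold distance on the log scale (positive). The
#'   default `log(10)` encodes a 90% decline below the current level.
#' @param T Horizon in years (positive).
#' @return A `risk_query` list.
#' @export
risk_query <- function(a = log(10), T = 10) {
  assert_scalar_number(a, "a")
  assert_scalar_number(T, "T")
  if (a < 0) stop_phenorisk("`a` must be >= 0")
  if (T <= 0) stop_phenorisk("`T` must be > 0")
  structure(list(a = a, T = T), class = "risk_query")
}

#' Quasi-extinction (critical decline) probability
#'
#' First-passage probability that a Brownian motion with drift `U` and
#' infinitesimal variance `Q`, started at the current log-abundance, falls a
#' distance `a` below its starting level within `T` years — the
#' inverse-Gaussian first-passage form
#' \deqn{P_e = \Phi(\mu - V) + e^{2 \mu V} \, \Phi(-\mu - V),}
#' with the standardised intermediates \eqn{\mu = -U T / \sqrt{Q T}} and
#' \eqn{V = a / \sqrt{Q T}} and \eqn{\Phi} the standard normal CDF. The
#' product \eqn{2 \mu V} equals \eqn{-2 U a / Q} (the horizon cancels), and
#' the second term is evaluated in log space so extreme parameters (tiny `Q`,
#' long horizons) cannot overflow.
#'
#' @param U Drift per year on the log scale.
#' @param Q Process variance per year, strictly positive (use the variance
#'   floor for degenerate fits).
#' @param query A [risk_query()] (threshold `a`, horizon `T`).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' quasi_extinction_probability(U = -0.1, Q = 0.04, risk_query(T = 10))
quasi_extinction_probability <- function(U, Q, query = risk_query()) {
  assert_scalar_number(U, "U")
  assert_scalar_number(Q, "Q")
  if (!inherits(query, "risk_query")) stop_phenorisk("`query` must be a risk_query")
  if (Q <= 0) stop_phenorisk("`Q` must be > 0 (floor degenerate fits at q_floor)")
  a <- query$a
  T <- query$T
  s <- sqrt(Q * T)
  mu <- -U * T / s
  V <- a / s
  term1 <- pnorm(mu - V)
  log2muV <- -2 * U * a / Q  # algebraically identical to 2*mu*V, horizon-free
  lp <- pnorm(-mu - V, log.p = TRUE)
  term2 <- if (is.infinite(lp) && lp < 0) 0 else exp(min(log2muV + lp, 709))
  unname(clamp(term1 + term2, 0, 1))
}

new_risk_estimate <- function(taxon, region, month, T, a,
                              p_baseline, p_best, p_worst, mu, V) {
  structure(
    list(taxon = taxon, region = region, month = month, T = T, a = a,
         p_baseline = p_baseline, p_best = p_best, p_worst = p_worst,
         mu = mu, V = V),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat("<risk_estimate>", x$taxon, "/", x$region, "/ month", x$month,
      sprintf("(a = %.4f, T = %g)\n", x$a, x$T))
  cat(sprintf("  baseline %.4f | best %.4f | worst %.4f\n",
              x$p_baseline, x$p_best, x$p_worst))
  invisible(x)
}

#' Baseline, best-case and worst-case decline risk for a fitted stratum
#'
#' Baseline risk uses the maximum-likelihood `(U_hat, Q_hat)`; the best case
#' uses the upper CI endpoint of the drift with the lower CI endpoint of the
#' process variance (strong growth, low stochasticity); the worst case uses
#' the lower drift endpoint with the upper variance endpoint. The scenario
#' ordering `p_best <= p_baseline <= p_worst` usually holds but is not
#' guaranteed: risk is not globally monotone in `Q` (as `Q` shrinks with
#' `-U T > a`, risk tends to 1).
#'
#' @param fit A `mar_fit` carrying bootstrap CIs.
#' @param query A [risk_query()].
#' @param q_floor Variance floor substituted for non-positive scenario `Q`.
#' @return A `risk_estimate` object.
#' @export
scenario_risks <- function(fit, query = risk_query(), q_floor = 1e-10) {
  stopifnot(inherits(fit, "mar_fit"))
  ends <- c(fit$U_lo, fit$U_hi, fit$Q_lo, fit$Q_hi)
  if (any(is.na(ends))) {
    stop_phenorisk("fit has no CI endpoints: run bootstrap_ci() first")
  }
  pb <- quasi_extinction_probability(fit$U_hat, max(fit$Q_hat, q_floor), query)
  best <- quasi_extinction_probability(fit$U_hi, max(fit$Q_lo, q_floor), query)
  worst <- quasi_extinction_probability(fit$U_lo, max(fit$Q_hi, q_floor), query)
  s <- sqrt(max(fit$Q_hat, q_floor) * query$T)
  new_risk_estimate(taxon = fit$taxon, region = fit$region, month = fit$month,
                    T = query$T, a = query$a,
                    p_baseline = pb, p_best = best, p_worst = worst,
                    mu = -fit$U_hat * query$T / s, V = query$a / s)
}

#' Decline-risk trajectory over multiple horizons
#'
#' One scenario triple per horizon. Baseline risk is non-decreasing in the
#' horizon (first-passage monotonicity).
#'
#' @param fit A `mar_fit` with CIs.
#' @param a Decline threshold distance (default `log(10)`, a 90% decline).
#' @param horizons Integer vector of horizons in years, e.g. `1:10`.
#' @param q_floor Variance floor.
#' @return A tibble with one row per horizon: `taxon`, `region`, `month`,
#'   `T`, `a`, `p_baseline`, `p_best`, `p_worst`.
#' @export
risk_trajectory <- function(fit, a = log(10), horizons = 1:10,
                            q_floor = 1e-10) {
  if (length(horizons) < 1 || any(horizons <= 0)) {
    stop_phenorisk("`horizons` must be positive")
  }
  rows <- lapply(horizons, function(T) {
    est <- scenario_risks(fit, risk_query(a = a, T = T), q_floor = q_floor)
    tibble::tibble(taxon = est$taxon, region = est$region, month = est$month,
                   T = T, a = a, p_baseline = est$p_baseline,
                   p_best = est$p_best, p_worst = est$p_worst)
  })
  dplyr::bind_rows(rows)
}
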