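#' Logit transform with boundary clamping
#'
#' Risks of exactly 0 or 1 occur at degenerate process variance, so
#' probabilities are clamped to `[eps, 1 - eps]` before the transform.
#'
#' @param p Probabilities in `[0, 1]` (vectorised).
#' @param eps Clamp width.
#' @return `log(p' / (1 - p'))`; the `"clamped"` attribute marks entries that
#'   were moved by the clamp.
#' @export
#' @examples
#' logit(0.5)  # 0
#' logit(0.1)  # -log(9)
logit <- function(p, eps = 1e-6) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_phenorisk("`p` must lie in [0, 1]")
  }
  pc <- clamp(p, eps, 1 - eps)
  out <- log(pc / (1 - pc))
  attr(out, "clamped") <- pc != p
  out
}

#' Window-averaged decline risk per prey taxon
#'
#' For each prey taxon, the arithmetic mean of its monthly risks over the
#' window months in which it is modeled. Taxa modeled in none of the window
#' months are excluded (with a message); an empty result is an error.
#'
#' @param prey_fits Fits table (rows of [fit_month_strata()]) for the prey
#'   taxa of one region, one row per (taxon, month).
#' @param window An `abundance_window` (the predator's).
#' @param query A [risk_query()].
#' @param q_floor Variance floor.
#' @return A tibble: `taxon`, `p_baseline`, `p_best`, `p_worst`, `n_months`
#'   (window months the taxon is modeled in).
#' @export
prey_window_risk <- function(prey_fits, window, query = risk_query(),
                             q_floor = 1e-10) {
  stopifnot(inherits(window, "abundance_window"))
  rows <- lapply(split(prey_fits, prey_fits$taxon), function(d) {
    d <- d[d$month %in% window$months, ]
    if (nrow(d) == 0) {
      message("prey taxon ", unique(prey_fits$taxon)[1],
              " has no modeled month inside the window; excluded")
      return(NULL)
    }
    ests <- lapply(seq_len(nrow(d)),
                   function(i) scenario_risks(as_mar_fit(d[i, ]), query,
                                              q_floor = q_floor))
    tibble::tibble(
      taxon = d$taxon[1],
      p_baseline = mean(vapply(ests, `[[`, numeric(1), "p_baseline")),
      p_best = mean(vapply(ests, `[[`, numeric(1), "p_best")),
      p_worst = mean(vapply(ests, `[[`, numeric(1), "p_worst")),
      n_months = nrow(d)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop_phenorisk("no prey taxon is modeled inside the window")
  }
  out
}

# Window-averaged scenario trajectory for one taxon's monthly fits.
window_trajectory <- function(fits, window, a, horizons, q_floor) {
  fits <- fits[fits$month %in% window$months, ]
  if (nrow(fits) == 0) return(NULL)
  per_month <- lapply(seq_len(nrow(fits)), function(i) {
    risk_trajectory(as_mar_fit(fits[i, ]), a = a, horizons = horizons,
                    q_floor = q_floor)
  })
  all <- dplyr::bind_rows(per_month)
  dplyr::summarise(dplyr::group_by(all, .data$T),
                   p_baseline = mean(.data$p_baseline),
                   p_best = mean(.data$p_best),
                   p_worst = mean(.data$p_worst), .groups = "drop")
}

#' Pair fish predators with their co-occurring zooplankton prey
#'
#' One pair per (region, predator). No diet filtering is applied: the prey
#' set of a predator is every retained zooplankton taxon in its region,
#' equally weighted, because age-0 forage fishes can consume most common
#' zooplankton. Risks are averaged over the predator's high-abundance window
#' months (both for the predator itself and for each prey taxon) and
#' projected over `horizons`.
#'
#' @param fish_fits Fits table for fish taxa (rows of [fit_month_strata()]).
#' @param windows List of `abundance_window` objects, one per
#'   (fish taxon, region); predators without a window are skipped with a
#'   warning.
#' @param zoop_fits Fits table for zooplankton taxa.
#' @param a Decline threshold distance (default `log(10)`).
#' @param horizons Projection horizons in years.
#' @param q_floor Variance floor.
#' @return A list of `predator_prey_pair` objects, each holding the window,
#'   the prey set, and window-averaged scenario trajectories
#'   (`predator_traj`, `prey_traj`).
#' @export
build_pairs <- function(fish_fits, windows, zoop_fits, a = log(10),
                        horizons = 1:10, q_floor = 1e-10) {
  shared <- intersect(unique(fish_fits$region), unique(zoop_fits$region))
  if (length(shared) == 0) {
    stop_phenorisk("fish and zooplankton share no region")
  }
  win_key <- vapply(windows, function(w) paste(w$taxon, w$region, sep = "\r"),
                    character(1))
  pairs <- list()
  combos <- unique(fish_fits[fish_fits$region %in% shared, c("taxon", "region")])
  for (i in seq_len(nrow(combos))) {
    pred <- combos$taxon[i]
    reg <- combos$region[i]
    w_idx <- match(paste(pred, reg, sep = "\r"), win_key)
    if (is.na(w_idx)) {
      warning(sprintf("predator %s in %s has no abundance window; skipped",
                      pred, reg), call. = FALSE)
      next
    }
    window <- windows[[w_idx]]
    pf <- fish_fits[fish_fits$taxon == pred & fish_fits$region == reg, ]
    zf <- zoop_fits[zoop_fits$region == reg, ]
    pred_traj <- window_trajectory(pf, window, a, horizons, q_floor)
    if (is.null(pred_traj)) {
      warning(sprintf("predator %s in %s has no modeled window month; skipped",
                      pred, reg), call. = FALSE)
      next
    }
    prey_rows <- lapply(split(zf, zf$taxon), function(d) {
      tr <- window_trajectory(d, window, a, horizons, q_floor)
      if (is.null(tr)) return(NULL)
      tr$prey <- d$taxon[1]
      tr
    })
    prey_traj <- dplyr::bind_rows(prey_rows)
    if (nrow(prey_traj) == 0) {
      warning(sprintf("predator %s in %s has no prey modeled in window; skipped",
                      pred, reg), call. = FALSE)
      next
    }
    pairs[[length(pairs) + 1]] <- structure(
      list(region = reg, predator = pred,
           prey_set = unique(prey_traj$prey), window = window,
           predator_traj = pred_traj, prey_traj = prey_traj),
      class = "predator_prey_pair"
    )
  }
  if (length(pairs) == 0) stop_phenorisk("no predator-prey pair could be built")
  pairs
}

#' @export
print.predator_prey_pair <- function(x, ...) {
  cat("<predator_prey_pair>", x$predator, "in", x$region, "\n")
  cat("  window months:", paste(x$window$months, collapse = "-"),
      "| prey:", paste(x$prey_set, collapse = ", "), "\n")
  invisible(x)
}

#' Logit-risk divergence slope between trophic groups
#'
#' Ordinary-least-squares fit of `logit(risk)` on time, group and their
#' interaction (plus region main effect when several regions are present).
#' The group factor is ordered (zooplankton, fish), so the returned
#' interaction coefficient is the fish minus zooplankton slope of logit risk
#' over time: positive values mean fish accumulate risk faster than their
#' prey. Swapping the group labels negates the slope exactly.
#'
#' @param data Tibble with columns `risk` (probability), `time` (years into
#'   the future), `group` (`"fish"`/`"zooplankton"`), optionally `region`.
#' @param eps Logit clamp.
#' @return A list: `slope_gap` (interaction coefficient), `coefficients`
#'   (full OLS coefficient vector), `n`.
#' @export
divergence_slope <- function(data, eps = 1e-6) {
  need <- c("risk", "time", "group")
  if (!all(need %in% names(data))) {
    stop_phenorisk("`data` needs columns risk, time, group")
  }
  lv <- c("zooplankton", "fish")
  missing_lv <- setdiff(lv, unique(data$group))
  if (length(missing_lv)) {
    stop_phenorisk("group level absent from data: ", missing_lv[1])
  }
  d <- data.frame(y = as.numeric(logit(data$risk, eps = eps)),
                  time = data$time,
                  group = factor(data$group, levels = lv))
  multi_region <- "region" %in% names(data) && length(unique(data$region)) > 1
  if (multi_region) {
    d$region <- factor(data$region)
    fit <- lm(y ~ time * group + region, data = d)
  } else {
    fit <- lm(y ~ time * group, data = d)
  }
  co <- coef(fit)
  list(slope_gap = unname(co[["time:groupfish"]]), coefficients = co,
       n = nrow(d))
}

#' Uncertainty width of a risk estimate
#'
#' The worst-case minus best-case scenario risk: how much the bootstrap
#' uncertainty in drift and process variance spreads the projected risk.
#'
#' @param estimate A `risk_estimate`, or any data frame carrying `p_best`
#'   and `p_worst` columns (e.g. a [risk_trajectory()]).
#' @return Non-negative width(s).
#' @export
uncertainty_width <- function(estimate) {
  if (inherits(estimate, "risk_estimate")) {
    return(estimate$p_worst - estimate$p_best)
  }
  if (is.data.frame(estimate) && all(c("p_best", "p_worst") %in% names(estimate))) {
    return(estimate$p_worst - estimate$p_best)
  }
  stop_phenorisk("`estimate` must be a risk_estimate or carry p_best/p_worst")
}

#' Predator-prey risk divergence summaries
#'
#' For each pair: the per-horizon risk gap (predator baseline risk minus the
#' prey-assemblage mean), the logit-risk slope difference between groups
#' (fish minus zooplankton, the OLS interaction coefficient), and per-horizon
#' scenario uncertainty widths for both groups. Community summaries average
#' the pair gaps over predators within each region; the overall model pools
#' all pairs (with a region main effect when several regions are present).
#'
#' @param pairs List of `predator_prey_pair` objects from [build_pairs()].
#' @param eps Logit clamp.
#' @return A list with `per_pair` (tibble: region, predator, horizon, gap,
#'   uncertainty_fish, uncertainty_zoop, slope_gap), `community` (tibble:
#'   region, horizon, mean_gap, n_predators) and `overall` (pooled
#'   [divergence_slope()] result).
#' @export
divergence_model <- function(pairs, eps = 1e-6) {
  if (length(pairs) == 0) stop_phenorisk("`pairs` is empty")
  per_pair <- lapply(pairs, function(p) {
    prey_mean <- dplyr::summarise(
      dplyr::group_by(p$prey_traj, .data$T),
      p_baseline = mean(.data$p_baseline),
      width = mean(.data$p_worst - .data$p_best), .groups = "drop")
    stopifnot(identical(prey_mean$T, p$predator_traj$T))
    long <- dplyr::bind_rows(
      tibble::tibble(risk = p$predator_traj$p_baseline,
                     time = p$predator_traj$T, group = "fish"),
      tibble::tibble(risk = p$prey_traj$p_baseline,
                     time = p$prey_traj$T, group = "zooplankton")
    )
    sl <- divergence_slope(long, eps = eps)
    tibble::tibble(
      region = p$region, predator = p$predator,
      horizon = p$predator_traj$T,
      gap = p$predator_traj$p_baseline - prey_mean$p_baseline,
      uncertainty_fish = p$predator_traj$p_worst - p$predator_traj$p_best,
      uncertainty_zoop = prey_mean$width,
      slope_gap = sl$slope_gap
    )
  })
  per_pair <- dplyr::bind_rows(per_pair)
  community <- dplyr::summarise(
    dplyr::group_by(per_pair, .data$region, .data$horizon),
    mean_gap = mean(.data$gap),
    n_predators = dplyr::n_distinct(.data$predator), .groups = "drop")
  pooled <- dplyr::bind_rows(lapply(pairs, function(p) {
    dplyr::bind_rows(
      tibble::tibble(risk = p$predator_traj$p_baseline,
                     time = p$predator_traj$T, group = "fish",
                     region = p$region),
      tibble::tibble(risk = p$prey_traj$p_baseline,
                     time = p$prey_traj$T, group = "zooplankton",
                     region = p$region)
    )
  }))
  list(per_pair = per_pair, community = community,
       overall = divergence_slope(pooled, eps = eps))
}
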