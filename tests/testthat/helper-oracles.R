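# Independent oracles and fixture builders shared across test files.

# Monte-Carlo first-passage probability for Brownian motion with drift U and
# variance Q crossing a barrier `a` below the start within T years.
# Discrete Gaussian increments with the exact Brownian-bridge within-step
# crossing probability, accumulated as a survival weight per path
# (Rao-Blackwellised: unbiased at any step size, low variance).
mc_first_passage <- function(U, Q, a, T, n_paths = 1e5, dt = 0.25, seed = 42) {
  set.seed(seed)
  n_steps <- max(1L, ceiling(T / dt))
  dt <- T / n_steps
  x <- numeric(n_paths)
  surv <- rep(1, n_paths)
  for (j in seq_len(n_steps)) {
    x_new <- x + rnorm(n_paths, U * dt, sqrt(Q * dt))
    p_cross <- ifelse(x <= -a | x_new <= -a, 1,
                      exp(-2 * (x + a) * (x_new + a) / (Q * dt)))
    surv <- surv * (1 - p_cross)
    x <- x_new
  }
  1 - mean(surv)
}

# Log-likelihood of gap-aware differences under N(k U, k Q): the brute-force
# counterpart of the closed-form MLE.
diff_loglik <- function(U, Q, k, delta) {
  sum(dnorm(delta, mean = k * U, sd = sqrt(k * Q), log = TRUE))
}

# A month-series tibble for one station from a vector of yearly values
# (NA = unobserved year).
series_from_values <- function(values, years = seq_along(values) + 1994,
                               taxon = "t1", station = "s1", region = "r1",
                               group = "fish", month = 6L) {
  tibble::tibble(taxon = taxon, station = station, region = region,
                 group = group, month = month, year = years,
                 value = values, observed = !is.na(values))
}

# Month-series tibble for several stations simulated from the random walk
# with drift, all observed.
simulate_station_group <- function(U, Q, n_years = 29, n_stations = 4,
                                   x0 = 3, taxon = "t1", region = "r1",
                                   month = 6L, group = "fish") {
  dplyr::bind_rows(lapply(seq_len(n_stations), function(s) {
    series_from_values(generate_random_walk(U, Q, n_years, x0),
                       taxon = taxon, station = paste0("s", s),
                       region = region, month = month, group = group)
  }))
}

# Fits-table row with prescribed parameters and (optionally collapsed) CIs,
# for tests that feed known parameters into the risk layer.
fits_row <- function(taxon, region, month, U, Q,
                     U_lo = U, U_hi = U, Q_lo = Q, Q_hi = Q) {
  tibble::tibble(taxon = taxon, region = region, month = as.integer(month),
                 U_hat = U, Q_hat = Q, U_lo = U_lo, U_hi = U_hi,
                 Q_lo = Q_lo, Q_hi = Q_hi, n_diffs = 28L, n_stations = 1L,
                 degenerate = FALSE, seed = 1L, B = 0L)
}

# A small one-region simulate-mode pipeline configuration (1 fish, 2 zoop,
# 2 stations, 29 years) used by the pipeline and determinism tests.
small_config <- function(seed = 1L, out_dir = NULL, B = 120) {
  taxa <- list(
    taxon_spec("fish_a", "fish", drift = -0.12, proc_var = 0.03,
               peak_months = 4:7, detection_prob = 0.9,
               base_log_abundance = 4),
    taxon_spec("zoop_a", "zooplankton", drift = 0, proc_var = 0.04,
               peak_months = 3:8, peak_concentration = 0.7,
               detection_prob = 0.95, base_log_abundance = 6),
    taxon_spec("zoop_b", "zooplankton", drift = -0.03, proc_var = 0.05,
               peak_months = 4:9, peak_concentration = 0.7,
               detection_prob = 0.95, base_log_abundance = 6)
  )
  design <- survey_design(years = c(1995, 2023), regions = "r1",
                          stations_per_region = 2, missing_rate = 0.05,
                          effort_mean = 10, seed = seed)
  pipeline_config(simulate = list(taxa = taxa, design = design), B = B,
                  seed = seed, out_dir = out_dir)
}

# Hand-constructed predator_prey_pair whose baseline trajectories follow
# prescribed logit lines: logit(risk) = b0 + b1 * t.
make_pair <- function(region = "r1", predator = "fish_1",
                      fish_line = c(-1, 0.2), prey_lines = list(c(-1, 0)),
                      horizons = 1:10, width = 0.1) {
  inv <- function(b, t) stats::plogis(b[1] + b[2] * t)
  pred <- tibble::tibble(T = horizons,
                         p_baseline = inv(fish_line, horizons),
                         p_best = pmax(inv(fish_line, horizons) - width / 2, 0),
                         p_worst = pmin(inv(fish_line, horizons) + width / 2, 1))
  prey <- dplyr::bind_rows(lapply(seq_along(prey_lines), function(i) {
    tibble::tibble(T = horizons,
                   p_baseline = inv(prey_lines[[i]], horizons),
                   p_best = pmax(inv(prey_lines[[i]], horizons) - width / 2, 0),
                   p_worst = pmin(inv(prey_lines[[i]], horizons) + width / 2, 1),
                   prey = paste0("zoop_", i))
  }))
  structure(list(region = region, predator = predator,
                 prey_set = unique(prey$prey),
                 window = structure(list(taxon = predator, region = region,
                                         months = 4:6, coverage = 0.9,
                                         contiguous = TRUE),
                                    class = "abundance_window"),
                 predator_traj = pred, prey_traj = prey),
            class = "predator_prey_pair")
}
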