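#' Describe a synthetic taxon
#'
#' A taxon specification bundles the generative parameters of one simulated
#' population: the drift `U` and process variance `Q` of its yearly latent
#' log-abundance random walk, its seasonal phenology (which calendar months
#' concentrate abundance, and how strongly), a detection probability that
#' produces zero inflation, and the starting log-abundance.
#'
#' @param taxon_id Character label, e.g. `"fish_A"`.
#' @param group `"fish"` or `"zooplankton"`.
#' @param drift Per-year change of log-abundance (`U_true`). Negative values
#'   simulate declining populations.
#' @param proc_var Per-year process variance on the log scale (`Q_true`),
#'   must be non-negative.
#' @param peak_months Integer vector of calendar months (1-12) holding the
#'   seasonal abundance peak. Must be non-empty.
#' @param peak_concentration Fraction of annual abundance falling in the peak
#'   months, in `[0, 1]`. The remainder is spread evenly over off-peak months.
#' @param detection_prob Probability that a present taxon yields a nonzero
#'   count in a survey, in `(0, 1]`. Bernoulli thinning, independent across
#'   records: the zero-inflation mechanism.
#' @param base_log_abundance Starting log-abundance `x0` of the latent walk.
#'
#' @return A `taxon_spec` list.
#' @export
#' @examples
#' taxon_spec("herring", "fish", drift = -0.1, proc_var = 0.04,
#'            peak_months = 3:5)
taxon_spec <- function(taxon_id, group = c("fish", "zooplankton"),
                       drift = 0, proc_var = 0.04,
                       peak_months = 4:7, peak_concentration = 0.8,
                       detection_prob = 0.9, base_log_abundance = 3) {
  group <- match.arg(group)
  assert_scalar_number(drift, "drift")
  assert_scalar_number(proc_var, "proc_var")
  if (proc_var < 0) stop_phenorisk("`proc_var` must be >= 0")
  peak_months <- sort(unique(as.integer(peak_months)))
  if (length(peak_months) == 0 || any(peak_months < 1 | peak_months > 12)) {
    stop_phenorisk("`peak_months` must be a non-empty subset of 1:12")
  }
  assert_scalar_number(peak_concentration, "peak_concentration")
  if (peak_concentration < 0 || peak_concentration > 1) {
    stop_phenorisk("`peak_concentration` must lie in [0, 1]")
  }
  assert_scalar_number(detection_prob, "detection_prob")
  if (detection_prob <= 0 || detection_prob > 1) {
    stop_phenorisk("`detection_prob` must lie in (0, 1]")
  }
  assert_scalar_number(base_log_abundance, "base_log_abundance")
  structure(
    list(taxon_id = as.character(taxon_id), group = group, drift = drift,
         proc_var = proc_var, peak_months = peak_months,
         peak_concentration = peak_concentration,
         detection_prob = detection_prob,
         base_log_abundance = base_log_abundance),
    class = "taxon_spec"
  )
}

#' Describe a synthetic survey design
#'
#' The sampling frame of the simulated monitoring programme: which years are
#' surveyed, how stations are laid out in regions, how often a station-month
#' survey is skipped, and the mean sampling effort per tow.
#'
#' @param years Length-2 inclusive year range, e.g. `c(1995, 2023)`.
#' @param regions Character vector of region labels (at least one).
#' @param stations_per_region Number of fixed stations in each region.
#' @param missing_rate Probability a station-month survey is skipped, in
#'   `[0, 1)`. A skipped survey drops all taxa for that station-month.
#' @param effort_mean Mean effort units per tow; effort varies across tows
#'   following a Gamma distribution with this mean.
#' @param seed Integer seed governing all draws of the generator.
#'
#' @return A `survey_design` list.
#' @export
survey_design <- function(years = c(1995, 2023), regions = c("Suisun", "SanPablo"),
                          stations_per_region = 4, missing_rate = 0.05,
                          effort_mean = 10, seed = 1L) {
  if (length(years) != 2 || years[2] < years[1] + 1) {
    stop_phenorisk("`years` must be an inclusive range spanning >= 2 years")
  }
  regions <- as.character(regions)
  if (length(regions) < 1) stop_phenorisk("need at least one region")
  if (stations_per_region < 1) stop_phenorisk("need at least one station per region")
  assert_scalar_number(missing_rate, "missing_rate")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_phenorisk("`missing_rate` must lie in [0, 1)")
  }
  assert_scalar_number(effort_mean, "effort_mean")
  if (effort_mean <= 0) stop_phenorisk("`effort_mean` must be positive")
  structure(
    list(years = as.integer(years), regions = regions,
         stations_per_region = as.integer(stations_per_region),
         missing_rate = missing_rate, effort_mean = effort_mean,
         seed = as.integer(seed)),
    class = "survey_design"
  )
}

#' Simulate a random walk with drift on the log scale
#'
#' Yearly latent log-abundance follows `X_t = X_{t-1} + U + W_t` with
#' `W_t ~ N(0, Q)`. The first element is the starting value `x0`; `n_years - 1`
#' increments are drawn.
#'
#' @param U Drift per year (log scale).
#' @param Q Process variance per year (log^2 scale), `>= 0`.
#' @param n_years Length of the returned series, `>= 1`.
#' @param x0 Starting value.
#' @param seed Optional integer seed; identical seeds give identical paths.
#'
#' @return Numeric vector of length `n_years`.
#' @export
#' @examples
#' generate_random_walk(U = 0.5, Q = 0, n_years = 4, x0 = 0)  # 0 0.5 1.0 1.5
generate_random_walk <- function(U, Q, n_years, x0 = 0, seed = NULL) {
  assert_scalar_number(U, "U")
  assert_scalar_number(Q, "Q")
  if (Q < 0) stop_phenorisk("`Q` must be >= 0: a variance cannot be negative")
  if (n_years < 1) stop_phenorisk("`n_years` must be >= 1")
  with_seed(seed, {
    incr <- if (n_years > 1) rnorm(n_years - 1, mean = U, sd = sqrt(Q)) else numeric(0)
    cumsum(c(x0, incr))
  })
}

# Fraction of annual abundance assigned to each calendar month.
month_shares <- function(spec) {
  shares <- numeric(12)
  np <- length(spec$peak_months)
  if (np == 12) {
    shares[] <- 1 / 12
  } else {
    shares[spec$peak_months] <- spec$peak_concentration / np
    shares[-spec$peak_months] <- (1 - spec$peak_concentration) / (12 - np)
  }
  shares
}

#' Generate a synthetic survey table
#'
#' Simulates the monitoring data the downstream pipeline expects: for each
#' taxon and station, a yearly latent log-abundance random walk (shared drift
#' and variance across stations of a taxon); the yearly abundance
#' `exp(X_t)` is distributed across calendar months by the taxon's phenology
#' profile; counts are Poisson draws proportional to abundance and effort,
#' thinned by the detection probability (zero inflation); whole station-month
#' surveys are skipped at `missing_rate`.
#'
#' All randomness flows from `design$seed` through deterministic stream
#' splitting, so identical inputs give bit-identical tables.
#'
#' @param taxa List of [taxon_spec()] objects (non-empty).
#' @param design A [survey_design()].
#'
#' @return A tibble of survey records with columns `date` (first of month),
#'   `station`, `region`, `taxon`, `group`, `count`, `effort`.
#' @export
generate_survey_data <- function(taxa, design) {
  if (inherits(taxa, "taxon_spec")) taxa <- list(taxa)
  if (length(taxa) == 0) stop_phenorisk("`taxa` must contain at least one taxon_spec")
  ok <- vapply(taxa, inherits, logical(1), "taxon_spec")
  if (!all(ok)) stop_phenorisk("every element of `taxa` must be a taxon_spec")
  if (!inherits(design, "survey_design")) stop_phenorisk("`design` must be a survey_design")

  years <- seq(design$years[1], design$years[2])
  n_years <- length(years)
  stations <- tibble::tibble(
    region = rep(design$regions, each = design$stations_per_region),
    station = paste0(rep(design$regions, each = design$stations_per_region), "-S",
                     rep(seq_len(design$stations_per_region), length(design$regions)))
  )

  # survey grid: one tow per station-month; skip mask and effort drawn per tow
  grid <- tidyr::expand_grid(stations, year = years, month = 1:12)
  n_tows <- nrow(grid)

  grid <- with_seed(child_seed(design$seed, "survey_frame"), {
    grid$skipped <- runif(n_tows) < design$missing_rate
    shape <- 25  # cv = 0.2: moderate tow-to-tow effort variation
    grid$effort <- rgamma(n_tows, shape = shape, rate = shape / design$effort_mean)
    grid
  })

  per_taxon <- lapply(taxa, function(spec) {
    shares <- month_shares(spec)
    with_seed(child_seed(design$seed, paste0("taxon:", spec$taxon_id)), {
      # latent yearly walk per station, independent increments, shared (U, Q)
      walks <- lapply(seq_len(nrow(stations)), function(i) {
        cumsum(c(spec$base_log_abundance,
                 rnorm(n_years - 1, spec$drift, sqrt(spec$proc_var))))
      })
      names(walks) <- stations$station
      lam_latent <- vapply(
        seq_len(nrow(grid)),
        function(i) exp(walks[[grid$station[i]]][match(grid$year[i], years)]) *
          shares[grid$month[i]],
        numeric(1)
      )
      present <- rbinom(nrow(grid), 1L, spec$detection_prob)
      count <- rpois(nrow(grid), lam_latent * grid$effort) * present
      tibble::tibble(
        date = as.Date(sprintf("%d-%02d-01", grid$year, grid$month)),
        station = grid$station, region = grid$region,
        taxon = spec$taxon_id, group = spec$group,
        count = as.integer(count), effort = grid$effort,
        skipped = grid$skipped
      )
    })
  })

  out <- dplyr::bind_rows(per_taxon)
  out <- out[!out$skipped, setdiff(names(out), "skipped")]
  out <- dplyr::arrange(out, .data$taxon, .data$station, .data$date)
  tibble::as_tibble(out)
}

#' Ground-truth parameter table for a set of synthetic taxa
#'
#' Companion to [generate_survey_data()]: the true drift, process variance and
#' peak months of each simulated taxon, for parameter-recovery checks.
#'
#' @param taxa List of [taxon_spec()] objects.
#' @return A tibble with columns `taxon`, `group`, `U_true`, `Q_true`,
#'   `peak_months` (dash-separated string).
#' @export
ground_truth_table <- function(taxa) {
  if (inherits(taxa, "taxon_spec")) taxa <- list(taxa)
  dplyr::bind_rows(lapply(taxa, function(s) {
    tibble::tibble(taxon = s$taxon_id, group = s$group,
                   U_true = s$drift, Q_true = s$proc_var,
                   peak_months = paste(s$peak_months, collapse = "-"))
  }))
}

#' Write a survey table to the standard CSV layout
#'
#' @param records Survey records as returned by [generate_survey_data()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(records, path) {
  req <- c("date", "station", "region", "taxon", "group", "count", "effort")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop_phenorisk("records lack required columns: ", paste(missing, collapse = ", "))
  }
  readr::write_csv(records[req], path)
  invisible(path)
}
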