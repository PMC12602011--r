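test_that("logit transform clamps boundary probabilities and flags them", {
  expect_equal(as.numeric(logit(0.5)), 0)
  expect_equal(as.numeric(logit(0.1)), -log(9), tolerance = 1e-12)
  l1 <- logit(1.0)
  expect_equal(as.numeric(l1), log((1 - 1e-6) / 1e-6), tolerance = 1e-9)
  expect_true(attr(l1, "clamped"))
  expect_false(any(attr(logit(c(0.2, 0.8)), "clamped")))
  expect_error(logit(1.5), "\\[0, 1\\]")
})

test_that("prey window risk averages monthly baseline risks inside the window", {
  win <- high_abundance_window(c(0, 0, 0, 10, 10, 10, 0, 0, 0, 0, 0, 0),
                               taxon = "f", region = "r")  # months 4:6
  q <- risk_query(T = 10)
  p_of <- function(U) quasi_extinction_probability(U, 0.04, q)

  one <- fits_row("z1", "r", 5, U = -0.15, Q = 0.04)
  expect_equal(prey_window_risk(one, win, q)$p_baseline, p_of(-0.15),
               tolerance = 1e-12)

  two <- dplyr::bind_rows(fits_row("z1", "r", 4, U = -0.2, Q = 0.04),
                          fits_row("z1", "r", 5, U = -0.1, Q = 0.04))
  expect_equal(prey_window_risk(two, win, q)$p_baseline,
               mean(c(p_of(-0.2), p_of(-0.1))), tolerance = 1e-12)

  # 3 prey x 3 window months: per-taxon means equal direct arithmetic
  us <- list(z1 = c(-0.2, -0.1, 0.0), z2 = c(0.1, 0.0, -0.1),
             z3 = c(-0.3, -0.3, -0.3))
  tbl <- dplyr::bind_rows(lapply(names(us), function(z)
    dplyr::bind_rows(lapply(1:3, function(i)
      fits_row(z, "r", 3 + i, U = us[[z]][i], Q = 0.04)))))
  got <- prey_window_risk(tbl, win, q)
  for (z in names(us)) {
    expect_equal(got$p_baseline[got$taxon == z],
                 mean(vapply(us[[z]], p_of, numeric(1))), tolerance = 1e-12)
  }

  outside <- fits_row("z9", "r", 11, U = 0, Q = 0.04)
  expect_error(suppressMessages(prey_window_risk(outside, win, q)),
               "no prey taxon")
})

test_that("pair assembly crosses predators with all co-occurring prey", {
  win_r1 <- high_abundance_window(c(rep(0, 3), 10, 10, 10, rep(0, 6)),
                                  taxon = "f1", region = "r1")
  fish <- dplyr::bind_rows(lapply(4:6, function(m)
    fits_row("f1", "r1", m, U = -0.15, Q = 0.04)))
  zoop <- dplyr::bind_rows(lapply(c("z1", "z2", "z3"), function(z)
    dplyr::bind_rows(lapply(4:6, function(m)
      fits_row(z, "r1", m, U = 0, Q = 0.04)))))
  pairs <- build_pairs(fish, list(win_r1), zoop)
  expect_length(pairs, 1)
  expect_setequal(pairs[[1]]$prey_set, c("z1", "z2", "z3"))
  expect_equal(nrow(pairs[[1]]$predator_traj), 10)

  # a predator present in two regions yields two pairs
  fish2 <- dplyr::bind_rows(fish, dplyr::mutate(fish, region = "r2"))
  zoop2 <- dplyr::bind_rows(zoop, dplyr::mutate(zoop, region = "r2"))
  win_r2 <- win_r1; win_r2$region <- "r2"
  pairs2 <- build_pairs(fish2, list(win_r1, win_r2), zoop2)
  expect_length(pairs2, 2)
  expect_setequal(vapply(pairs2, `[[`, character(1), "region"), c("r1", "r2"))

  # predator without a window is skipped with a warning
  fish3 <- dplyr::bind_rows(fish2, dplyr::mutate(fish, taxon = "f_nowin"))
  expect_warning(p3 <- build_pairs(fish3, list(win_r1, win_r2), zoop2),
                 "no abundance window")
  expect_length(p3, 2)

  expect_error(build_pairs(fish, list(win_r1),
                           dplyr::mutate(zoop, region = "elsewhere")),
               "share no region")
})

test_that("divergence slope is exact on noise-free logit lines and anti-symmetric", {
  h <- 1:10
  lines_df <- function(b_fish, b_zoop) dplyr::bind_rows(
    tibble::tibble(risk = stats::plogis(-1 + b_fish * h), time = h,
                   group = "fish"),
    tibble::tibble(risk = stats::plogis(-1 + b_zoop * h), time = h,
                   group = "zooplankton"))
  expect_equal(divergence_slope(lines_df(0.2, 0))$slope_gap, 0.2,
               tolerance = 1e-9)
  expect_equal(divergence_slope(lines_df(0.1, 0.1))$slope_gap, 0,
               tolerance = 1e-9)

  d <- lines_df(0.25, -0.05)
  swapped <- dplyr::mutate(d, group = ifelse(group == "fish", "zooplankton",
                                             "fish"))
  expect_equal(divergence_slope(swapped)$slope_gap,
               -divergence_slope(d)$slope_gap, tolerance = 1e-12)

  expect_error(divergence_slope(d[d$group == "fish", ]),
               "zooplankton")
})

test_that("divergence summaries recover prescribed per-region slopes and aggregate consistently", {
  p1 <- make_pair(region = "rA", predator = "f1", fish_line = c(-1, 0.30),
                  prey_lines = list(c(-1, 0.10), c(-1, 0.10)))
  p2 <- make_pair(region = "rB", predator = "f2", fish_line = c(-0.5, 0.05),
                  prey_lines = list(c(-0.5, 0.25)))
  dm <- divergence_model(list(p1, p2))

  s1 <- dm$per_pair$slope_gap[dm$per_pair$predator == "f1"][1]
  s2 <- dm$per_pair$slope_gap[dm$per_pair$predator == "f2"][1]
  expect_equal(s1, 0.20, tolerance = 1e-9)   # 0.30 - 0.10, exact OLS
  expect_equal(s2, -0.20, tolerance = 1e-9)  # 0.05 - 0.25

  # identical trajectories: zero gap and zero slope difference
  p0 <- make_pair(region = "rC", predator = "f0", fish_line = c(-1, 0.1),
                  prey_lines = list(c(-1, 0.1)))
  dm0 <- divergence_model(list(p0))
  expect_equal(dm0$per_pair$gap, rep(0, 10), tolerance = 1e-12)
  expect_equal(dm0$per_pair$slope_gap[1], 0, tolerance = 1e-9)

  # community mean gap equals the mean of constituent pair gaps
  p3 <- make_pair(region = "rA", predator = "f3", fish_line = c(-2, 0.2),
                  prey_lines = list(c(-1, 0)))
  dm2 <- divergence_model(list(p1, p3))
  at10 <- dm2$per_pair[dm2$per_pair$horizon == 10, ]
  comm10 <- dm2$community[dm2$community$region == "rA" &
                            dm2$community$horizon == 10, ]
  expect_equal(comm10$mean_gap, mean(at10$gap), tolerance = 1e-12)
  expect_equal(comm10$n_predators, 2)
})

test_that("uncertainty width is worst minus best and ordered by CI width", {
  est <- structure(list(taxon = "t", region = "r", month = 6, T = 10,
                        a = log(10), p_baseline = 0.4, p_best = 0.2,
                        p_worst = 0.6, mu = 0, V = 1),
                   class = "risk_estimate")
  expect_equal(uncertainty_width(est), 0.4)

  wide <- as_mar_fit(fits_row("t", "r", 6, U = -0.1, Q = 0.04,
                              U_lo = -0.3, U_hi = 0.1,
                              Q_lo = 0.01, Q_hi = 0.20))
  narrow <- as_mar_fit(fits_row("t", "r", 6, U = -0.1, Q = 0.04,
                                U_lo = -0.15, U_hi = -0.05,
                                Q_lo = 0.03, Q_hi = 0.06))
  collapsed <- as_mar_fit(fits_row("t", "r", 6, U = -0.1, Q = 0.04))
  tw <- uncertainty_width(risk_trajectory(wide, horizons = 1:10))
  tn <- uncertainty_width(risk_trajectory(narrow, horizons = 1:10))
  tc <- uncertainty_width(risk_trajectory(collapsed, horizons = 1:10))
  expect_true(all(tw >= tn - 1e-12))  # wider parameter CIs, wider risk bands
  expect_equal(tc, rep(0, 10), tolerance = 1e-12)
  expect_true(all(tw >= 0))
})
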