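test_that("nonrectangular hyperbola matches its quadratic-root oracle and limits", {
  expect_equal(nrh_gpp(0, 0.05, 30, 0.7), 0)
  # Blackman limit at theta = 1
  expect_equal(nrh_gpp(1000, 0.05, 30, 1), 30)  # min(50, 30)
  expect_equal(nrh_gpp(400, 0.05, 30, 1), 20)   # min(20, 30)
  # quadratic-root oracle over a parameter grid
  for (theta in c(0.2, 0.7, 0.95)) {
    q <- seq(0, 2110, length.out = 25)
    expect_equal(nrh_gpp(q, 0.03, 25, theta), nrh_oracle(q, 0.03, 25, theta),
                 tolerance = 1e-10)
  }
  expect_equal(nrh_gpp(2110, 0.03, 25, 0.7), 21.63122, tolerance = 1e-5)
  expect_error(nrh_gpp(100, 0.05, 30, 1.2), "theta")
  expect_error(nrh_gpp(-5, 0.05, 30, 0.5), ">= 0")
})

test_that("Michaelis-Menten model is the theta -> 0 limit", {
  expect_equal(mm_gpp(30 / 0.05, 0.05, 30), 15) # half-saturation at Q = Amax/alpha
  expect_lt(abs(mm_gpp(1e9, 0.05, 30) - 30) / 30, 1e-6)
  q <- seq(0, 2110, length.out = 200)
  expect_lt(max(abs(nrh_gpp(q, 0.05, 30, 1e-6) - mm_gpp(q, 0.05, 30))), 1e-4)
  expect_equal(nrh_gpp(q, 0.04, 22, 0), mm_gpp(q, 0.04, 22))
})

test_that("light response is nondecreasing in Q and in Amax", {
  q <- seq(0, 2500, length.out = 100)
  for (theta in c(0, 0.5, 1)) {
    g <- nrh_gpp(q, 0.04, 28, theta)
    expect_true(all(diff(g) >= -1e-12))
    expect_true(all(g <= pmin(0.04 * q, 28) + 1e-9))
  }
  amaxes <- seq(5, 60, length.out = 50)
  g_at_q <- vapply(amaxes, function(a) nrh_gpp(1500, 0.04, a, 0.7), numeric(1))
  expect_true(all(diff(g_at_q) >= -1e-12))
})

test_that("R2 of fit follows the 1 - SSE/SST definition", {
  obs <- c(1, 2, 3)
  expect_equal(r2_of_fit(obs, obs), 1)
  expect_equal(r2_of_fit(obs, rep(mean(obs), 3)), 0)
  expect_equal(r2_of_fit(obs, c(1, 2, 5)), -1) # worse than the mean
  expect_error(r2_of_fit(c(2, 2, 2), c(1, 2, 3)), "variance")
})

test_that("window fitting recovers known parameters and honours contracts", {
  recs <- make_window_records(0.04, 28, 0.6, n = 240)
  fit <- fit_window(recs, as.Date("2001-07-15"), "PAR")
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 0.04) / 0.04, 1e-3)
  expect_lt(abs(fit$amax - 28) / 28, 1e-3)
  expect_lt(abs(fit$theta - 0.6) / 0.6, 1e-3)
  expect_gt(fit$r2, 0.999)

  # too few points: no exception, converged = FALSE
  small <- make_window_records(0.04, 28, 0.6, n = 10)
  expect_false(fit_window(small, as.Date("2001-07-15"), "PAR")$converged)
  empty <- make_window_records(0.04, 28, 0.6, n = 50)
  expect_false(fit_window(empty, as.Date("2011-01-01"), "PAR")$converged)

  # fitted objective is no worse than plausible feasible parameter guesses
  day <- as.Date(recs$timestamp, tz = "UTC")
  q <- recs$par; g <- recs$gpp
  rss_at <- function(p) sum((g - nrh_gpp(q, p[1], p[2], p[3]))^2)
  for (p in list(c(0.03, 30, 0.5), c(0.04, 28, 0.6), c(0.1, 50, 0.9))) {
    expect_lte(fit$rss, rss_at(p) + 1e-9)
  }
})

test_that("low-light-only windows flag a poorly constrained plateau", {
  # radiation never approaches saturation: Amax is unreliable, and the
  # q_max diagnostic exposes it
  recs <- make_window_records(0.04, 28, 0.6, n = 120, q_max = 190,
                              noise_sd = 0.1, seed = 5)
  fit <- fit_window(recs, as.Date("2001-07-15"), "PAR")
  expect_lt(fit$q_max, 200)
  amaxes <- vapply(1:20, function(s) {
    r <- make_window_records(0.04, 28, 0.6, n = 120, q_max = 190,
                             noise_sd = 0.1, seed = s)
    fit_window(r, as.Date("2001-07-15"), "PAR")$amax
  }, numeric(1))
  expect_gt(sd(amaxes) / 28, 0.2) # wide spread relative to truth
})

test_that("daily derivation: saturating-light value, integral, retention", {
  fit <- fit_window(make_window_records(0.05, 30, 1, n = 240, q_max = 2110),
                    as.Date("2001-07-15"), "PAR")
  d <- derive_daily(fit)
  # closed-form Blackman integral: alpha Q^2/2 up to Q* = Amax/alpha, then flat
  expect_equal(d$gpp_cum, 54300, tolerance = 1e-3)
  expect_equal(d$gpp_sat, 30, tolerance = 1e-4)
  expect_true(d$retained)

  fit2 <- fit_window(make_window_records(0.03, 25, 0.7, n = 240),
                     as.Date("2001-07-15"), "PAR")
  d2 <- derive_daily(fit2)
  expect_lte(d2$gpp_sat, d2$amax + 1e-9)
  oracle <- trapz_oracle(function(qq) nrh_gpp(qq, fit2$alpha, fit2$amax, fit2$theta),
                         0, 2110)
  expect_lt(abs(d2$gpp_cum - oracle) / oracle, 1e-4)

  # APAR variant saturates at 2000
  fit3 <- fit_window(make_window_records(0.03, 25, 0.7, n = 240), center_date = as.Date("2001-07-15"),
                     radiation_kind = "PAR")
  fit3$radiation_kind <- "APAR"
  d3 <- derive_daily(fit3)
  expect_equal(d3$gpp_sat, nrh_gpp(2000, fit3$alpha, fit3$amax, fit3$theta))

  bad <- fit_window(make_window_records(0.04, 28, 0.6, n = 10),
                    as.Date("2001-07-15"), "PAR")
  expect_error(derive_daily(bad), "converge")
})

test_that("series fitting steps one day at a time and degrades gracefully", {
  cfg <- site_sim_config(noise_scale = 0.1, gap_fraction = 0.1, seed = 21)
  sim <- simulate_site_fluxes(cfg)
  qc <- filter_daytime_measured(sim$fluxes)
  centers <- seq(as.Date("2001-07-01"), as.Date("2001-07-10"), by = "day")
  daily <- fit_lrc_series(qc, centers, "PAR")
  expect_equal(nrow(daily), 10)
  expect_true(all(diff(daily$center_date) == 1))
  expect_true(all(daily$retained == (!is.na(daily$r2) & daily$r2 > 0.6)))
  # mid-winter centers have too few daytime points and yield NA rows
  win <- fit_lrc_series(qc, as.Date("2001-01-05"), "PAR", min_obs = 500L)
  expect_false(win$retained)
  expect_true(is.na(win$gpp_sat))
})
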