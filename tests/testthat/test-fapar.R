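test_that("distance correlation matches the brute-force oracle and its axioms", {
  set.seed(1)
  for (n in c(20, 50, 100)) {
    x <- rnorm(n); y <- x^2 + rnorm(n, 0, 0.2)
    expect_equal(distance_correlation(x, y), dcor_brute(x, y), tolerance = 1e-12)
  }
  x <- rnorm(40)
  expect_equal(distance_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, -3 * x + 7), 1, tolerance = 1e-10)
  # affine invariance in either argument
  y <- rnorm(40)
  expect_equal(distance_correlation(2 * x - 5, y),
               distance_correlation(x, y), tolerance = 1e-10)
  # nonlinear dependence is detected where Pearson is ~ 0
  xg <- seq(-3, 3, length.out = 60)
  expect_lt(abs(cor(xg, xg^2)), 1e-10)
  expect_gt(distance_correlation(xg, xg^2), 0.4)
  expect_error(distance_correlation(rep(1, 10), rnorm(10)), "constant")
})

test_that("neighbour screen ranks donors by correlation above a strict 0.75", {
  set.seed(2)
  central <- fapar_series(runif(30, 0.2, 0.8))
  copies <- list(
    exact = central,
    noisy = fapar_series(pmin(1, pmax(0, central$fapar + rnorm(30, 0, 0.05)))),
    indep = fapar_series(runif(30, 0.2, 0.8)))
  ranked <- neighbor_screen(central, copies)
  expect_equal(ranked$pixel_id[1], "exact")
  expect_equal(ranked$correlation[1], 1, tolerance = 1e-12)
  expect_false("indep" %in% ranked$pixel_id)
  expect_true(all(diff(ranked$correlation) <= 0))
  expect_true(all(ranked$correlation > 0.75))
  # candidates with too few paired steps are skipped
  short <- list(few = fapar_series(c(central$fapar[1:5], rep(NA, 25))))
  expect_equal(nrow(neighbor_screen(central, short)), 0)
  all_na <- central; all_na$fapar <- NA_real_
  expect_error(neighbor_screen(all_na, copies), "all missing")
})

test_that("gap-filling uses the best-ranked donor and never alters observations", {
  set.seed(3)
  truth <- 0.3 + 0.4 * sin(seq(0, 2 * pi, length.out = 40))^2
  central <- fapar_series(truth)
  central$fapar[c(10, 25)] <- NA
  donor_best <- fapar_series(truth)                        # dcor 1
  donor_ok <- fapar_series(pmin(1, pmax(0, truth + rnorm(40, 0, 0.02))))
  donor_best$fapar[25] <- NA # forces gap 25 to fall through to the next donor
  donors <- neighbor_screen(central, list(best = donor_best, ok = donor_ok))
  filled <- gapfill_central(central, donors)
  expect_equal(filled$fapar[-c(10, 25)], central$fapar[-c(10, 25)])
  expect_equal(filled$provenance[10], "best")  # highest-ranked donor with data
  expect_equal(filled$provenance[25], "ok")    # fallback to next-ranked donor
  expect_equal(filled$fapar[10], truth[10], tolerance = 1e-9) # affine-corrected copy
  # a gap no donor covers stays flagged
  central2 <- central
  donor_best2 <- donor_best; donor_best2$fapar[10] <- NA
  donor_ok2 <- donor_ok; donor_ok2$fapar[10] <- NA
  donors2 <- neighbor_screen(central2, list(best = donor_best2, ok = donor_ok2))
  filled2 <- gapfill_central(central2, donors2)
  expect_true(is.na(filled2$fapar[10]))
  expect_equal(filled2$provenance[10], "unfilled")
})

test_that("fallback fill uses climatology first, then interpolation, clamped", {
  # three years on a 16-day grid; gap in year 2 at a slot other years observe
  dates <- seq(as.Date("2001-01-01"), by = 16, length.out = 69) # exactly 3 years
  vals <- rep(0.5, 69)
  slot <- (as.integer(format(dates, "%j")) - 1) %/% 16
  yr <- as.integer(format(dates, "%Y"))
  vals[slot == 6 & yr == 2001] <- 0.5
  vals[slot == 6 & yr == 2003] <- 0.7
  gap_i <- which(slot == 6 & yr == 2002)[1]
  vals[gap_i] <- NA
  filled <- fallback_fill(data.frame(date = dates, fapar = vals))
  expect_equal(filled$fapar[gap_i], 0.6) # mean of 0.5 and 0.7
  expect_equal(filled$provenance[gap_i], "climatology")

  # single year: interior gap -> linear midpoint
  one <- fapar_series(c(0.2, 0.4, NA, 0.6, 0.8))
  f1 <- fallback_fill(one)
  expect_equal(f1$fapar[3], 0.5)
  expect_equal(f1$provenance[3], "interpolated")
  expect_true(all(f1$fapar >= 0 & f1$fapar <= 1))
  expect_error(fallback_fill(fapar_series(rep(NA_real_, 5))), "non-missing")
})

test_that("daily smoothing reproduces constants and tracks smooth phenology", {
  const <- fapar_series(rep(0.6, 20))
  sm <- smooth_to_daily(const)
  expect_true(all(sm$fapar == 0.6))
  expect_equal(nrow(sm), as.integer(diff(range(const$date))) + 1L)

  # noiseless double-logistic truth sampled 16-daily: daily RMSE < 0.02
  doy <- 1:365
  truth <- 0.1 + 0.8 / (1 + exp(-0.15 * (doy - 120))) / (1 + exp(0.15 * (doy - 280)))
  knots <- seq(1, 365, by = 16)
  series <- data.frame(date = as.Date("2001-01-01") + knots - 1,
                       fapar = truth[knots])
  sm2 <- smooth_to_daily(series)
  daily_truth <- truth[seq(knots[1], max(knots))]
  expect_lt(sqrt(mean((sm2$fapar - daily_truth)^2)), 0.02)
  expect_true(all(sm2$fapar >= 0 & sm2$fapar <= 1))
  expect_error(smooth_to_daily(fapar_series(c(0.1, 0.2, 0.3))), "4 knots")
  expect_error(smooth_to_daily(fapar_series(c(0.1, NA, 0.3, 0.4, 0.5))), "gaps")
})

test_that("spline fit at the knots is never rougher than the raw series", {
  set.seed(8)
  vals <- pmin(1, pmax(0, 0.5 + 0.3 * sin((1:30) / 3) + rnorm(30, 0, 0.08)))
  series <- fapar_series(vals)
  sm <- smooth_to_daily(series)
  at_knots <- sm$fapar[match(series$date, sm$date)]
  rough <- function(v) sum(diff(diff(v))^2)
  expect_lte(rough(at_knots), rough(series$fapar))
})

test_that("annual maximum LAI is the 90th percentile of the year's retrievals", {
  dates <- seq(as.Date("2004-01-01"), by = 16, length.out = 23)
  expect_equal(annual_max_lai(data.frame(date = dates, lai = rep(3, 23)), 2004), 3)
  lai <- data.frame(date = dates, lai = as.numeric(1:23))
  expect_equal(annual_max_lai(lai, 2004), pctl_oracle(1:23, 0.9))
  expect_error(annual_max_lai(data.frame(date = dates[1:4], lai = rep(1, 4)), 2004),
               ">= 5")
  expect_error(annual_max_lai(data.frame(date = dates, lai = c(-1, rep(2, 22))), 2004),
               "negative")
})
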