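test_that("config validation rejects out-of-range parameters", {
  expect_error(site_sim_config(rg_max_summer = -5), "rg_max_summer")
  expect_error(site_sim_config(theta_true = 1.2), "theta_true")
  expect_error(site_sim_config(gap_fraction = 1.5), "gap_fraction")
  expect_error(site_sim_config(alpha_peak = 0), "alpha_peak")
  expect_error(simulate_fapar_pixels(site_sim_config(), neighbor_noise = -0.1),
               "neighbor_noise")
  expect_error(simulate_trait_sites(5, relation = list(intercept = 1, slope = 1,
                                                       noise_sd = -1)),
               "noise_sd")
})

test_that("radiation is seeded-deterministic, non-negative, zero at night", {
  cfg <- site_sim_config(seed = 42)
  r1 <- simulate_radiation(cfg)
  r2 <- simulate_radiation(cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$rg >= 0))
  hour <- as.integer(format(r1$timestamp, "%H"))
  expect_true(all(r1$rg[hour %in% c(0, 1, 2, 23)] == 0))
})

test_that("noise-free midsummer noon reaches the configured clear-sky peak", {
  cfg <- site_sim_config(noise_scale = 0, rg_max_summer = 800)
  r <- simulate_radiation(cfg)
  noon <- r$rg[format(r$timestamp, "%m-%d %H:%M") == "06-21 12:00"]
  expect_equal(noon, 800, tolerance = 1e-12)
})

test_that("annual daylight fraction matches the configured day fraction", {
  for (lat in c(0.2, 0.4)) {
    cfg <- site_sim_config(latitude_proxy = lat, noise_scale = 0)
    r <- simulate_radiation(cfg)
    frac <- mean(r$rg > 10)
    expect_lt(abs(frac - attr(r, "day_fraction")), 0.02)
  }
})

test_that("flux generator: truth recovery, gap fraction, year effects", {
  cfg <- site_sim_config(noise_scale = 0, gap_fraction = 0, seed = 3)
  sim <- simulate_site_fluxes(cfg)
  expect_identical(sim, simulate_site_fluxes(cfg)) # bit-identical regeneration
  # modelled GPP is zero where radiation is zero, even before noise
  expect_true(all(sim$fluxes$gpp[sim$fluxes$rg == 0] == 0))

  # noiseless, gapless window fit recovers the generating parameters
  qc <- filter_daytime_measured(sim$fluxes)
  fit <- fit_window(qc, as.Date("2001-07-19"), "PAR")
  truth <- sim$truth$daily[sim$truth$daily$date == as.Date("2001-07-19"), ]
  expect_lt(abs(fit$alpha - truth$alpha) / truth$alpha, 1e-3)
  expect_lt(abs(fit$amax - truth$amax) / truth$amax, 1e-3)
  expect_lt(abs(fit$theta - truth$theta) / truth$theta, 1e-3)

  # realized gap fraction within +/- 1% of the target
  cfg2 <- site_sim_config(gap_fraction = 0.2, seed = 11)
  sim2 <- simulate_site_fluxes(cfg2)
  expect_lt(abs(mean(!sim2$fluxes$measured) - 0.2), 0.01)

  # no interannual variation when the year effect is off
  cfg3 <- site_sim_config(n_years = 3, year_effect_sd = 0, seed = 5)
  sim3 <- simulate_site_fluxes(cfg3)
  expect_equal(length(unique(sim3$truth$gppsat_true)), 1L)
})

test_that("laplace noise option keeps the zero-radiation invariant", {
  cfg <- site_sim_config(noise_scale = 0.1, seed = 9)
  sim <- simulate_site_fluxes(cfg, noise_family = "laplace")
  expect_true(all(sim$fluxes$gpp[sim$fluxes$rg == 0] == 0))
})

test_that("fapar pixels: bounds, exact copies at zero noise, central gaps", {
  cfg <- site_sim_config(n_years = 2, seed = 7)
  fp <- simulate_fapar_pixels(cfg, n_neighbors = 3, neighbor_noise = 0,
                              n_independent = 1, gap_fraction = 0.2)
  all_vals <- c(fp$central$fapar, unlist(lapply(fp$neighbors, `[[`, "fapar")))
  expect_true(all(all_vals >= 0 & all_vals <= 1, na.rm = TRUE))
  # correlated neighbour with zero noise is an exact copy where central observed
  obs <- !is.na(fp$central$fapar)
  expect_equal(fp$neighbors$nb02$fapar[obs], fp$central$fapar[obs])
  expect_lt(abs(mean(is.na(fp$central$fapar)) - 0.2), 0.02)
  # no gaps requested -> gap-filling is a no-op
  fp0 <- simulate_fapar_pixels(cfg, n_neighbors = 2, gap_fraction = 0)
  donors <- neighbor_screen(fp0$central, fp0$neighbors)
  expect_identical(gapfill_central(fp0$central, donors)$fapar, fp0$central$fapar)
})

test_that("independent neighbour pixels decorrelate from the central series", {
  cfg <- site_sim_config(n_years = 9, seed = 13) # ~200 16-day steps
  fp <- simulate_fapar_pixels(cfg, n_neighbors = 1, n_independent = 1,
                              gap_fraction = 0)
  expect_lt(distance_correlation(fp$central$fapar, fp$neighbors$nb01$fapar), 0.5)
})

test_that("trait sites: exact relation arithmetic and abundance closure", {
  tr <- simulate_trait_sites(3, relation = list(intercept = 15.67, slope = 7.25,
                                                noise_sd = 0),
                             seed = 1, n_pct = 2)
  expect_equal(tr$truth$gppsat_true, rep(30.17, 3), tolerance = 1e-12)
  for (s in split(tr$in_situ, tr$in_situ$site)) {
    expect_lt(abs(sum(s$abundance) - 1), 1e-12)
    # abundance-weighted species N% reproduces the site CWM exactly
    expect_equal(sum(s$abundance * s$n_mass) / 10,
                 tr$truth$n_pct_cwm[tr$truth$site == s$site[1]],
                 tolerance = 1e-9)
  }
})

test_that("noiseless trait relation is recovered exactly by regression", {
  tr <- simulate_trait_sites(12, relation = list(intercept = 15.67, slope = 7.25,
                                                 noise_sd = 0), seed = 4)
  m <- ols(tr$truth$gppsat_true, data.frame(n_pct = tr$truth$n_pct_cwm))
  expect_equal(m$coefficients$estimate, c(15.67, 7.25), tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)
})

test_that("recovered trait-capacity slope is unbiased at moderate noise", {
  # simulation study: over many seeds the slope estimate stays within 2 SE
  slopes <- ses <- numeric(200)
  for (s in 1:200) {
    tr <- simulate_trait_sites(20, relation = list(intercept = 15.67,
                                                   slope = 7.25, noise_sd = 4.5),
                               seed = s)
    m <- ols(tr$truth$gppsat_true, data.frame(n_pct = tr$truth$n_pct_cwm),
             loocv = FALSE)
    slopes[s] <- m$coefficients$estimate[2]
    ses[s] <- m$coefficients$se[2]
  }
  expect_gt(mean(abs(slopes - 7.25) <= 2 * ses), 0.90)
})
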