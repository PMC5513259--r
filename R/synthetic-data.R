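# Synthetic flux, FAPAR and trait inputs with known ground truth.
# Every downstream stage of the pipeline can be exercised against these
# generators without access to restricted flux or trait databases. One
# integer seed drives separate sub-streams (radiation, noise, gaps,
# FAPAR, traits, year effects), so each stage regenerates independently
# and bit-identically.

#' Configuration for one simulated flux site
#'
#' @param site_id Site label.
#' @param n_years Number of simulated calendar years (starting 2001).
#' @param latitude_proxy Seasonal daylength amplitude in `[0, 1)`: day
#'   length ranges `12 * (1 - latitude_proxy)` to `12 * (1 + latitude_proxy)`
#'   hours.
#' @param rg_max_summer Clear-sky noon Rg at midsummer, W m-2.
#' @param alpha_peak Peak-season initial slope of the light response,
#'   umol CO2 per umol photons.
#' @param amax_peak Peak-season plateau, umol CO2 m-2 s-1.
#' @param theta_true Curvature in `[0, 1]`.
#' @param season_shape Double-logistic phenology: list `start`, `end`
#'   (days of year), `steepness` (d-1), `base` (off-season fraction).
#' @param noise_scale Flux noise as a fraction of the modelled flux
#'   (heteroscedastic); also the amplitude of the multiplicative
#'   radiation clearness noise. Default 0.1.
#' @param gap_fraction Fraction of half-hours flagged gap-filled.
#' @param year_effect_sd Log-normal interannual multiplier sd applied to
#'   `amax_peak`.
#' @param seed Integer seed for all of the site's random streams.
#' @return A validated list of class `"site_sim_config"`.
#' @export
site_sim_config <- function(site_id = "SYN-001", n_years = 1L,
                            latitude_proxy = 0.3, rg_max_summer = 800,
                            alpha_peak = 0.04, amax_peak = 28,
                            theta_true = 0.7,
                            season_shape = list(start = 120, end = 280,
                                                steepness = 0.15, base = 0.05),
                            noise_scale = 0.1, gap_fraction = 0.1,
                            year_effect_sd = 0.08, seed = 1L) {
  if (rg_max_summer <= 0) stop("site_sim_config: rg_max_summer must be > 0", call. = FALSE)
  stopifnot_scalar(theta_true, "theta_true", 0, 1)
  stopifnot_scalar(gap_fraction, "gap_fraction", 0, 1)
  stopifnot_scalar(latitude_proxy, "latitude_proxy", 0, 0.99)
  if (alpha_peak <= 0 || amax_peak <= 0) {
    stop("site_sim_config: alpha_peak and amax_peak must be > 0", call. = FALSE)
  }
  if (noise_scale < 0 || year_effect_sd < 0) {
    stop("site_sim_config: noise scales must be >= 0", call. = FALSE)
  }
  if (n_years < 1L) stop("site_sim_config: n_years must be >= 1", call. = FALSE)
  cfg <- list(site_id = site_id, n_years = as.integer(n_years),
              latitude_proxy = latitude_proxy, rg_max_summer = rg_max_summer,
              alpha_peak = alpha_peak, amax_peak = amax_peak,
              theta_true = theta_true, season_shape = season_shape,
              noise_scale = noise_scale, gap_fraction = gap_fraction,
              year_effect_sd = year_effect_sd, seed = as.integer(seed))
  class(cfg) <- "site_sim_config"
  cfg
}

# Double-logistic phenology on day-of-year, normalised to peak 1.
phenology <- function(doy, shape) {
  raw <- function(d) {
    1 / (1 + exp(-shape$steepness * (d - shape$start))) *
      1 / (1 + exp(shape$steepness * (d - shape$end)))
  }
  peak <- max(raw(1:366))
  shape$base + (1 - shape$base) * raw(doy) / peak
}

# Day length in hours for a day of year.
day_length <- function(doy, latitude_proxy) {
  12 * (1 + latitude_proxy * cos(2 * pi * (doy - 172) / 365.25))
}

sim_timestamps <- function(n_years, first_year = 2001L) {
  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", first_year), tz = "UTC")
  end <- as.POSIXct(sprintf("%d-12-31 23:30:00", first_year + n_years - 1L), tz = "UTC")
  seq(start, end, by = 1800)
}

#' Simulate half-hourly global radiation
#'
#' A sinusoidal daytime arc whose length (day length) and amplitude vary
#' seasonally: midsummer noon reaches `rg_max_summer` exactly when noise
#' is off. Multiplicative clearness noise `exp(-noise_scale * |N(0,1)|)`
#' (bounded in `(0, 1]`) emulates cloudiness; nights are exactly zero.
#'
#' @param config A [site_sim_config()].
#' @return Data frame `timestamp` (POSIXct UTC, half-hourly), `rg`
#'   (W m-2), plus attribute `day_fraction` (mean day length / 24).
#' @export
simulate_radiation <- function(config) {
  stopifnot(inherits(config, "site_sim_config"))
  ts <- sim_timestamps(config$n_years)
  doy <- as.integer(format(ts, "%j"))
  hour <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
  L <- day_length(doy, config$latitude_proxy)
  sunrise <- 12 - L / 2
  u <- (hour - sunrise) / L
  season <- (1 + cos(2 * pi * (doy - 172) / 365.25)) / 2
  rg_peak <- config$rg_max_summer * (0.4 + 0.6 * season)
  rg <- ifelse(u > 0 & u < 1, rg_peak * sin(pi * u), 0)
  if (config$noise_scale > 0) {
    clear <- with_seed(stream_seed(config$seed, "radiation"),
                       exp(-config$noise_scale * abs(stats::rnorm(length(rg)))))
    rg <- rg * clear
  }
  out <- data.frame(timestamp = ts, rg = rg)
  attr(out, "day_fraction") <- mean(day_length(1:365, config$latitude_proxy)) / 24
  out
}

# Gap mask: mixture of singleton gaps and geometric-length blocks hitting
# the target count exactly.
gap_mask <- function(n, fraction, seed) {
  gap <- logical(n)
  target <- round(fraction * n)
  if (target == 0L) return(gap)
  with_seed(seed, {
    guard <- 0L
    while (sum(gap) < target && guard < 100000L) {
      guard <- guard + 1L
      len <- if (stats::runif(1) < 0.5) 1L else stats::rgeom(1, 1 / 6) + 1L
      pos <- sample.int(n, 1L)
      gap[pos:min(n, pos + len - 1L)] <- TRUE
    }
    excess <- sum(gap) - target
    if (excess > 0L) {
      on_idx <- which(gap)
      gap[sample(on_idx, excess)] <- FALSE
    }
  })
  gap
}

#' Simulate a site's half-hourly GPP record with known truth
#'
#' Radiation comes from [simulate_radiation()]; PAR = 2.11 x Rg; GPP is
#' the nonrectangular hyperbola driven by a seasonal (double-logistic)
#' trajectory of `alpha(t)` and `Amax(t)` plus heteroscedastic noise with
#' standard deviation `noise_scale x modelled GPP` (Gaussian by default,
#' Laplace optional). A fraction `gap_fraction` of half-hours is flagged
#' gap-filled (random singletons plus contiguous blocks). Year-to-year
#' variation multiplies `amax_peak` by `exp(N(0, year_effect_sd))`.
#'
#' @param config A [site_sim_config()].
#' @param noise_family `"gaussian"` (default) or `"laplace"`.
#' @return List: `fluxes` (data frame `timestamp`, `gpp`, `rg`, `par`,
#'   `measured`) and `truth` (list: daily `alpha`, `amax`, `theta`,
#'   per-year `gppsat_true` at Qsat = 2110, `year_multiplier`).
#' @export
simulate_site_fluxes <- function(config, noise_family = c("gaussian", "laplace")) {
  stopifnot(inherits(config, "site_sim_config"))
  noise_family <- match.arg(noise_family)
  rad <- simulate_radiation(config)
  ts <- rad$timestamp
  doy <- as.integer(format(ts, "%j"))
  yr <- as.integer(format(ts, "%Y"))
  years <- sort(unique(yr))
  mult <- if (config$year_effect_sd > 0) {
    with_seed(stream_seed(config$seed, "years"),
              exp(stats::rnorm(length(years), 0, config$year_effect_sd)))
  } else rep(1, length(years))
  names(mult) <- years

  phen <- phenology(doy, config$season_shape)
  alpha_t <- config$alpha_peak * phen
  amax_t <- config$amax_peak * mult[as.character(yr)] * phen
  par <- par_from_rg(rad$rg)
  s <- alpha_t * par + amax_t
  disc <- pmax(s * s - 4 * config$theta_true * alpha_t * par * amax_t, 0)
  gpp_model <- if (config$theta_true == 0) {
    ifelse(par == 0, 0, alpha_t * par * amax_t / (alpha_t * par + amax_t))
  } else (s - sqrt(disc)) / (2 * config$theta_true)

  gpp <- gpp_model
  if (config$noise_scale > 0) {
    gpp <- with_seed(stream_seed(config$seed, "noise"), {
      sdv <- config$noise_scale * gpp_model
      if (noise_family == "gaussian") gpp_model + stats::rnorm(length(gpp_model), 0, sdv)
      else {
        # Laplace with sd = sdv: scale b = sdv / sqrt(2)
        u <- stats::runif(length(gpp_model)) - 0.5
        gpp_model - sdv / sqrt(2) * sign(u) * log(1 - 2 * abs(u))
      }
    })
  }
  measured <- !gap_mask(length(ts), config$gap_fraction,
                        stream_seed(config$seed, "gaps"))

  day_grid <- unique(as.Date(ts, tz = "UTC"))
  doy_grid <- as.integer(format(day_grid, "%j"))
  yr_grid <- as.integer(format(day_grid, "%Y"))
  phen_grid <- phenology(doy_grid, config$season_shape)
  truth <- list(
    daily = data.frame(date = day_grid,
                       alpha = config$alpha_peak * phen_grid,
                       amax = config$amax_peak * mult[as.character(yr_grid)] * phen_grid,
                       theta = config$theta_true),
    gppsat_true = stats::setNames(
      vapply(mult, function(m) nrh_gpp(2110, config$alpha_peak,
                                       config$amax_peak * m,
                                       config$theta_true), numeric(1)),
      names(mult)),
    year_multiplier = mult,
    theta = config$theta_true)
  list(fluxes = data.frame(timestamp = ts, gpp = gpp, rg = rad$rg,
                           par = par, measured = measured),
       truth = truth)
}

#' Simulate 16-day FAPAR for a central pixel and its neighbours
#'
#' The central pixel follows the site's double-logistic phenology scaled
#' into `[0.1, 0.9]`. Correlated neighbours are the central series plus
#' Gaussian noise of sd `neighbor_noise` (exact copies when 0);
#' `n_independent` of the neighbours are instead generated from an
#' independent AR(1) process, to exercise the donor screen. Gaps are
#' injected into the central pixel only. An LAI series on the same grid
#' is returned along with the gap-free daily FAPAR truth.
#'
#' @param config A [site_sim_config()].
#' @param n_neighbors Total neighbour pixels (`>= 0`).
#' @param neighbor_noise Noise sd of correlated neighbours (`>= 0`).
#' @param n_independent How many of the neighbours are independent of the
#'   central pixel (default 1, capped at `n_neighbors`).
#' @param gap_fraction Fraction of central steps set missing (default 0.15).
#' @param lai_max Peak LAI, m2 m-2 (default 5).
#' @return List: `central` (data frame `date`, `fapar`), `neighbors`
#'   (named list of data frames), `lai` (`date`, `lai`), `truth`
#'   (daily `date`, `fapar` without gaps or noise).
#' @export
simulate_fapar_pixels <- function(config, n_neighbors = 4L, neighbor_noise = 0.02,
                                  n_independent = 1L, gap_fraction = 0.15,
                                  lai_max = 5) {
  stopifnot(inherits(config, "site_sim_config"))
  if (n_neighbors < 0L) stop("simulate_fapar_pixels: n_neighbors must be >= 0", call. = FALSE)
  if (neighbor_noise < 0) stop("simulate_fapar_pixels: neighbor_noise must be >= 0", call. = FALSE)
  n_independent <- min(n_independent, n_neighbors)
  first_year <- 2001L
  dates <- seq(as.Date(sprintf("%d-01-01", first_year)),
               as.Date(sprintf("%d-12-31", first_year + config$n_years - 1L)),
               by = 16)
  doy <- as.integer(format(dates, "%j"))
  central_true <- 0.1 + 0.8 * phenology(doy, config$season_shape)
  out <- with_seed(stream_seed(config$seed, "fapar"), {
    neighbors <- list()
    if (n_neighbors > 0L) {
      for (i in seq_len(n_neighbors)) {
        id <- sprintf("nb%02d", i)
        if (i <= n_independent) {
          # independent AR(1), scaled into [0, 1]
          e <- stats::rnorm(length(dates), 0, 0.05)
          v <- Reduce(function(prev, eps) 0.8 * prev + eps, e,
                      accumulate = TRUE, init = 0)[-1]
          neighbors[[id]] <- data.frame(date = dates, fapar = clamp01(0.5 + v))
        } else {
          neighbors[[id]] <- data.frame(
            date = dates,
            fapar = clamp01(central_true +
                              stats::rnorm(length(dates), 0, neighbor_noise)))
        }
      }
    }
    central <- central_true
    if (gap_fraction > 0) {
      n_gap <- round(gap_fraction * length(central))
      if (n_gap > 0L) central[sample.int(length(central), n_gap)] <- NA_real_
    }
    list(central = central, neighbors = neighbors)
  })
  daily_dates <- seq(min(dates), max(dates), by = "day")
  truth <- data.frame(date = daily_dates,
                      fapar = 0.1 + 0.8 * phenology(
                        as.integer(format(daily_dates, "%j")), config$season_shape))
  list(central = data.frame(date = dates, fapar = out$central),
       neighbors = out$neighbors,
       lai = data.frame(date = dates, lai = lai_max * phenology(doy, config$season_shape)),
       truth = truth)
}

#' Simulate multi-site species trait tables tied to a known capacity
#'
#' Site community-weighted mean leaf nitrogen (N%, g per 100 g) is drawn
#' uniformly and the site's true photosynthetic capacity follows
#' `GPPsat = intercept + slope * N% + N(0, noise_sd)`. Species tables are
#' constructed so the abundance-weighted species values reproduce the
#' site CWM exactly; other traits (P, C, SLA, delta13C) are generated
#' with realistic ranges and an N-P coupling of configurable tightness.
#' A second, "database" table perturbs the species values to emulate
#' looking traits up rather than measuring them in situ.
#'
#' @param n_sites Number of sites (`>= 3`).
#' @param relation List `slope`, `intercept` (GPPsat per N% units) and
#'   `noise_sd` (`>= 0`). Defaults: intercept 15.67, slope 7.25, sd 3.
#' @param seed Integer seed.
#' @param n_pct Optional fixed vector of site CWM N% values (recycled to
#'   `n_sites`); drawn `U(1, 3.2)` when `NULL`.
#' @param np_ratio,np_sd N:P mass ratio and its log-scale spread.
#' @param db_noise_sd Relative sd of the database-table perturbation.
#' @return List: `in_situ` and `database` species tables (`site`,
#'   `species`, `abundance`, `n_mass`, `p_mass`, `c_mass`, `sla`,
#'   `delta13c`, `source`), `truth` (`site`, `n_pct_cwm`,
#'   `gppsat_true`), `relation`.
#' @export
simulate_trait_sites <- function(n_sites, relation = list(intercept = 15.67,
                                                          slope = 7.25,
                                                          noise_sd = 3),
                                 seed = 1L, n_pct = NULL,
                                 np_ratio = 12, np_sd = 0.15,
                                 db_noise_sd = 0.1) {
  if (n_sites < 3L) stop("simulate_trait_sites: need n_sites >= 3", call. = FALSE)
  if (relation$noise_sd < 0) stop("simulate_trait_sites: noise_sd must be >= 0", call. = FALSE)
  with_seed(stream_seed(seed, "traits"), {
    sites <- sprintf("SYN-%03d", seq_len(n_sites))
    cwm_n_pct <- if (is.null(n_pct)) stats::runif(n_sites, 1, 3.2)
                 else rep_len(n_pct, n_sites)
    gppsat_true <- relation$intercept + relation$slope * cwm_n_pct +
      stats::rnorm(n_sites, 0, relation$noise_sd)
    tabs <- lapply(seq_len(n_sites), function(i) {
      k <- sample(3:6, 1)
      ab <- stats::rgamma(k, 2)
      ab <- ab / sum(ab)
      dev <- stats::rnorm(k, 0, 2)
      dev <- dev - sum(ab * dev) # abundance-weighted deviations sum to zero
      n_mass <- pmax(cwm_n_pct[i] * 10 + dev, 3) # mg g-1; N% = n_mass / 10
      n_mass <- n_mass + (cwm_n_pct[i] * 10 - sum(ab * n_mass)) # re-centre after floor
      p_mass <- n_mass / np_ratio * exp(stats::rnorm(k, 0, np_sd))
      data.frame(site = sites[i], species = sprintf("sp%02d", seq_len(k)),
                 abundance = ab, n_mass = n_mass, p_mass = p_mass,
                 c_mass = stats::rnorm(k, 470, 15),
                 sla = exp(stats::rnorm(k, log(12), 0.3)),
                 delta13c = stats::rnorm(k, -28, 1.5),
                 source = "in_situ")
    })
    in_situ <- do.call(rbind, tabs)
    database <- in_situ
    for (col in c("n_mass", "p_mass", "c_mass", "sla")) {
      database[[col]] <- database[[col]] *
        exp(stats::rnorm(nrow(database), 0, db_noise_sd))
    }
    database$delta13c <- database$delta13c + stats::rnorm(nrow(database), 0, db_noise_sd * 5)
    database$source <- "database"
    list(in_situ = in_situ, database = database,
         truth = data.frame(site = sites, n_pct_cwm = cwm_n_pct,
                            gppsat_true = gppsat_true),
         relation = relation)
  })
}
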