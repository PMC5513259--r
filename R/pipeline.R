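# File formats, configuration and the end-to-end pipeline runner:
# simulate -> flux QC -> FAPAR gap-fill/smooth -> light-response fitting
# -> annual capacity extraction and estimator comparison -> community
# traits -> trait linking.

#' Read a half-hourly flux CSV
#'
#' Expected columns: `timestamp` (ISO 8601), `gpp`, `rg`, `measured`
#' (logical or 0/1). The sentinel `-9999` is parsed as missing;
#' duplicated timestamps are an error. A `par` column is derived.
#'
#' @param path CSV path.
#' @return Data frame `timestamp` (POSIXct UTC), `gpp`, `rg`, `par`,
#'   `measured`.
#' @export
read_flux_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "gpp", "rg", "measured")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("read_flux_csv: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(x$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) stop("read_flux_csv: unparseable timestamp(s)", call. = FALSE)
  dup <- duplicated(ts)
  if (any(dup)) {
    stop("read_flux_csv: duplicated timestamp: ",
         format(ts[dup][1], "%Y-%m-%dT%H:%M:%S"), call. = FALSE)
  }
  num <- function(v) {
    v <- as.numeric(v)
    v[v == -9999] <- NA_real_
    v
  }
  steps <- diff(as.numeric(ts))
  if (length(steps) > 0L && any(steps != 1800)) {
    warning(sprintf("read_flux_csv: %d irregular time step(s)", sum(steps != 1800)),
            call. = FALSE)
  }
  data.frame(timestamp = ts, gpp = num(x$gpp), rg = num(x$rg),
             par = par_from_rg(pmax(num(x$rg), 0)),
             measured = as.logical(x$measured))
}

#' Write a flux table in the dialect [read_flux_csv()] reads
#'
#' @param fluxes Data frame with `timestamp`, `gpp`, `rg`, `measured`.
#' @param path Output path.
#' @export
write_flux_csv <- function(fluxes, path) {
  out <- data.frame(timestamp = format(fluxes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    gpp = fluxes$gpp, rg = fluxes$rg,
                    measured = as.integer(fluxes$measured))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated
#' object; all numeric rules applied downstream trace back to these
#' fields.
#'
#' @param n_sites,n_years Synthetic study dimensions (defaults 20 sites,
#'   8 years).
#' @param rg_daytime Daytime Rg threshold, W m-2 (strict; default 10).
#' @param day_gap Per-day gap fraction above which a day is bad (0.80).
#' @param year_bad Bad-day fraction above which a site-year is dropped
#'   (0.25).
#' @param half_width Fitting window half-width, days (2 = 5-day window).
#' @param r2_threshold Daily retention threshold on fit R2 (0.6).
#' @param qsat_par,qsat_apar Saturating light, umol m-2 s-1 (2110 / 2000).
#' @param percentile Annual extraction percentile for linking (0.9).
#' @param percentiles Extraction set for the estimator comparison.
#' @param min_years Minimum years per site for the comparison (5).
#' @param min_days Minimum retained days per annual value (10).
#' @param exclude_sites,exclude_site_years Exclusion lists (site ids /
#'   `"site:year"` strings), e.g. for disturbance or extreme years.
#' @param relation Trait-capacity generator truth (intercept, slope,
#'   noise_sd).
#' @param resampling_B Permutations for the year-resampling test (199).
#' @param seed Master seed.
#' @param sim Named list of overrides passed to [site_sim_config()]
#'   (e.g. `noise_scale`, `gap_fraction`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_sites = 20L, n_years = 8L, rg_daytime = 10,
                            day_gap = 0.80, year_bad = 0.25, half_width = 2L,
                            r2_threshold = 0.6, qsat_par = 2110, qsat_apar = 2000,
                            percentile = 0.9,
                            percentiles = list("max", 0.9, 0.85, 0.8, 0.75, 0.7, 0.6),
                            min_years = 5L, min_days = 10L,
                            exclude_sites = character(),
                            exclude_site_years = character(),
                            relation = list(intercept = 15.67, slope = 7.25,
                                            noise_sd = 3),
                            resampling_B = 199L, seed = 1L, sim = list()) {
  stopifnot_scalar(day_gap, "day_gap", 0, 1)
  stopifnot_scalar(year_bad, "year_bad", 0, 1)
  stopifnot_scalar(r2_threshold, "r2_threshold", -Inf, 1)
  stopifnot_scalar(percentile, "percentile", 0, 1)
  cfg <- list(n_sites = as.integer(n_sites), n_years = as.integer(n_years),
              rg_daytime = rg_daytime, day_gap = day_gap, year_bad = year_bad,
              half_width = as.integer(half_width), r2_threshold = r2_threshold,
              qsat_par = qsat_par, qsat_apar = qsat_apar,
              percentile = percentile, percentiles = percentiles,
              min_years = as.integer(min_years), min_days = as.integer(min_days),
              exclude_sites = exclude_sites,
              exclude_site_years = exclude_site_years,
              relation = relation, resampling_B = as.integer(resampling_B),
              seed = as.integer(seed), sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Invert the light response: the amax giving gpp at radiation q.
amax_for_gppsat <- function(gpp, q, alpha, theta) {
  aq <- alpha * q
  gpp * (aq - theta * gpp) / (aq - gpp)
}

percentile_label <- function(p) if (identical(p, "max")) "max" else sprintf("%d", round(100 * p))

#' Run the full pipeline on synthetic inputs
#'
#' Executes, for `config$n_sites` simulated sites: flux QC (daytime /
#' measured filter and site-year gap screening), FAPAR neighbour
#' gap-filling with climatology fallback and daily smoothing, 5-day
#' moving-window light-response fits against PAR and APAR, annual
#' extraction of the six capacity estimators at the configured
#' percentiles, the interannual-variability estimator comparison,
#' community-weighted trait aggregation, the three trait-capacity
#' synchronisation scenarios with ANCOVA, the year-resampling test, and
#' stepwise AIC trait selection. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every output table is
#'   written as CSV plus a JSON run manifest.
#' @return List of data frames: `screening`, `daily_efp`, `annual_efp`,
#'   `site_iav`, `estimator_comparison`, `traits_cwm`, `scenarios`,
#'   `ancova`, `year_resampling`, `stepwise`, `truth`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  warnings_log <- character()
  sites <- sprintf("SYN-%03d", seq_len(config$n_sites))
  traits_sim <- simulate_trait_sites(config$n_sites, relation = config$relation,
                                     seed = config$seed)
  sampling_year <- 2000L + config$n_years # last simulated year

  theta0 <- config$sim$theta_true %||% 0.7
  alpha0 <- config$sim$alpha_peak %||% 0.04
  screening <- list(); daily_all <- list(); annual_all <- list()
  iav_all <- list(); efp_site <- list()
  estimators <- c("amax", "gpp_sat", "gpp_cum")

  for (i in seq_len(config$n_sites)) {
    site <- sites[i]
    if (site %in% config$exclude_sites) next
    amax_i <- amax_for_gppsat(traits_sim$truth$gppsat_true[i], config$qsat_par,
                              alpha0, theta0)
    amax_i <- min(max(amax_i, 5), 90)
    sim_args <- utils::modifyList(
      list(site_id = site, n_years = config$n_years, alpha_peak = alpha0,
           theta_true = theta0, amax_peak = amax_i,
           seed = config$seed * 1000L + i),
      config$sim[setdiff(names(config$sim), c("alpha_peak", "theta_true"))])
    site_cfg <- do.call(site_sim_config, sim_args)
    sim <- simulate_site_fluxes(site_cfg)

    fap <- simulate_fapar_pixels(site_cfg)
    donors <- neighbor_screen(fap$central, fap$neighbors)
    filled <- fallback_fill(gapfill_central(fap$central, donors))
    daily_fapar <- smooth_to_daily(filled[, c("date", "fapar")])

    flux <- compute_apar(sim$fluxes, daily_fapar)
    years <- 2001:(2000 + config$n_years)
    keep_years <- c()
    for (y in years) {
      scr <- screen_site_year(flux, y, config$day_gap, config$year_bad)
      scr$site <- site
      excluded <- paste0(site, ":", y) %in% config$exclude_site_years
      scr$keep <- scr$keep && !excluded
      screening[[length(screening) + 1L]] <-
        data.frame(site = site, year = y, n_bad_days = scr$n_bad_days,
                   bad_fraction = scr$bad_fraction, keep = scr$keep,
                   status = scr$status)
      if (scr$keep) keep_years <- c(keep_years, y)
    }
    if (length(keep_years) == 0L) next
    qc <- filter_daytime_measured(flux, config$rg_daytime)

    for (kind in c("PAR", "APAR")) {
      centers <- do.call(c, lapply(keep_years, function(y) {
        seq(as.Date(sprintf("%d-04-01", y)), as.Date(sprintf("%d-09-30", y)), by = "day")
      }))
      daily <- fit_lrc_series(qc, centers, kind,
                              qsat_par = config$qsat_par,
                              qsat_apar = config$qsat_apar,
                              r2_threshold = config$r2_threshold,
                              half_width = config$half_width)
      daily$site <- site
      daily_all[[length(daily_all) + 1L]] <- daily
      suffix <- if (kind == "APAR") ".structure" else ""
      for (est in estimators) {
        for (p in config$percentiles) {
          vals <- vapply(keep_years, function(y) {
            annual_extract(daily, y, p, est, config$min_days)$value
          }, numeric(1))
          annual_all[[length(annual_all) + 1L]] <-
            data.frame(site = site, year = keep_years,
                       estimator = paste0(est, suffix),
                       percentile = percentile_label(p), value = vals)
          v <- vals[!is.na(vals)]
          if (length(v) >= 2L && mean(v) > 0) {
            cv <- iav_cv(v)
            iav_all[[length(iav_all) + 1L]] <-
              data.frame(site = site, estimator = paste0(est, suffix),
                         percentile = percentile_label(p), cv = cv$cv,
                         n_years = cv$n_years)
          }
        }
      }
    }
  }
  screening <- do.call(rbind, screening)
  daily_efp <- do.call(rbind, daily_all)
  annual_efp <- do.call(rbind, annual_all)
  site_iav <- if (length(iav_all)) do.call(rbind, iav_all) else
    stop("run_pipeline: no qualifying site-years after screening", call. = FALSE)

  comparison <- tryCatch(compare_estimators(site_iav, config$min_years),
                         error = function(e) {
                           warnings_log <<- c(warnings_log, conditionMessage(e))
                           NULL
                         })

  # community traits (in situ and database pathways)
  cwm_tab <- lapply(c("in_situ", "database"), function(src) {
    tab <- derive_stoichiometry(traits_sim[[src]])
    rows <- lapply(split(tab, tab$site), function(g) {
      v <- site_species_mean(g)
      data.frame(site = g$site[1], source = src, n_pct = v$n_mass / 10,
                 p_mass = v$p_mass, c_mass = v$c_mass, sla = v$sla,
                 delta13c = v$delta13c, cn = v$cn, n_area = v$n_area,
                 p_area = v$p_area)
    })
    do.call(rbind, rows)
  })
  traits_cwm <- do.call(rbind, cwm_tab)
  rownames(traits_cwm) <- NULL

  # site-level capacity scalars for the linking stage (90th pct GPPsat, PAR)
  lbl <- percentile_label(config$percentile)
  ann_sat <- annual_efp[annual_efp$estimator == "gpp_sat" &
                          annual_efp$percentile == lbl, ]
  efp_mean <- vapply(sites, function(s) {
    a <- ann_sat[ann_sat$site == s, ]
    if (nrow(a) == 0L) NA_real_ else select_site_efp(a, "multiyear_mean")$value
  }, numeric(1))
  efp_year <- vapply(sites, function(s) {
    a <- ann_sat[ann_sat$site == s, ]
    if (nrow(a) == 0L) NA_real_
    else select_site_efp(a, "specific_year", year = sampling_year)$value
  }, numeric(1))

  insitu_n <- traits_cwm$n_pct[traits_cwm$source == "in_situ"][match(sites, traits_cwm$site[traits_cwm$source == "in_situ"])]
  db_n <- traits_cwm$n_pct[traits_cwm$source == "database"][match(sites, traits_cwm$site[traits_cwm$source == "database"])]

  scenario_defs <- list(
    list(name = "mean_database", efp = efp_mean, n_pct = db_n),
    list(name = "mean_insitu", efp = efp_mean, n_pct = insitu_n),
    list(name = "year_insitu", efp = efp_year, n_pct = insitu_n))
  scen_rows <- list(); scen_points <- list()
  for (sc in scenario_defs) {
    ok <- !is.na(sc$efp) & !is.na(sc$n_pct)
    if (sum(ok) < 5L) next
    m <- ols(sc$efp[ok], data.frame(n_pct = sc$n_pct[ok]))
    scen_rows[[sc$name]] <- data.frame(
      scenario = sc$name, n = m$n, intercept = m$coefficients$estimate[1],
      intercept_se = m$coefficients$se[1], slope = m$coefficients$estimate[2],
      slope_se = m$coefficients$se[2], r2 = m$r2, adj_r2 = m$adj_r2,
      p = m$p, dcor = m$dcor, ef = m$ef, rrmse = m$rrmse)
    scen_points[[sc$name]] <- data.frame(scenario = sc$name,
                                         efp = sc$efp[ok], n_pct = sc$n_pct[ok])
  }
  scenarios <- do.call(rbind, scen_rows)
  rownames(scenarios) <- NULL

  anc <- NULL
  if (length(scen_points) >= 2L) {
    pts <- do.call(rbind, scen_points)
    a <- ancova(pts$efp, pts$n_pct, pts$scenario)
    anc <- data.frame(interaction_F = a$interaction_F,
                      interaction_p = a$interaction_p,
                      group_F = a$group_F, group_p = a$group_p)
  }

  resamp <- NULL
  ok_tr <- !is.na(insitu_n)
  resamp_try <- tryCatch(
    year_resampling_test(ann_sat,
                         data.frame(site = sites[ok_tr], trait = insitu_n[ok_tr],
                                    sampling_year = sampling_year),
                         B = config$resampling_B, seed = config$seed),
    error = function(e) {
      warnings_log <<- c(warnings_log, conditionMessage(e))
      NULL
    })
  if (!is.null(resamp_try)) {
    resamp <- data.frame(observed_r2 = resamp_try$observed_r2,
                         null_r2_mean = mean(resamp_try$null_r2),
                         p = resamp_try$p, B = config$resampling_B)
  }

  insitu_cwm <- traits_cwm[traits_cwm$source == "in_situ", ]
  insitu_cwm <- insitu_cwm[match(sites, insitu_cwm$site), ]
  ok_sw <- !is.na(efp_year) & stats::complete.cases(insitu_cwm[, c("cn", "p_area", "n_pct")])
  stepwise_tab <- NULL
  if (sum(ok_sw) > 6L) {
    cand <- expand_predictors(insitu_cwm[ok_sw, c("cn", "p_area", "n_pct")])
    sw <- stepwise_aic(efp_year[ok_sw], cand)
    stepwise_tab <- data.frame(selected = paste(sw$selected, collapse = " + "),
                               aic = sw$aic,
                               r2 = if (is.null(sw$result)) NA_real_ else sw$result$r2,
                               adj_r2 = if (is.null(sw$result)) NA_real_ else sw$result$adj_r2)
  }

  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("efpcap")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   n_sites = config$n_sites,
                   n_site_years_kept = sum(screening$keep),
                   n_daily_fits = nrow(daily_efp),
                   n_daily_retained = sum(daily_efp$retained),
                   warnings = warnings_log)

  out <- list(screening = screening, daily_efp = daily_efp,
              annual_efp = annual_efp, site_iav = site_iav,
              estimator_comparison = comparison, traits_cwm = traits_cwm,
              scenarios = scenarios, ancova = anc, year_resampling = resamp,
              stepwise = stepwise_tab, truth = traits_sim$truth,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(out), "manifest")) {
      if (!is.null(out[[nm]]) && is.data.frame(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
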