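#' Convert global shortwave radiation to PAR
#'
#' Incoming photosynthetically active radiation is derived from global
#' shortwave radiation by the standard conversion factor 2.11
#' (umol photons J-1), so Rg = 1000 W m-2 corresponds to a PAR of
#' 2110 umol m-2 s-1.
#'
#' @param rg Global shortwave radiation, W m-2 (vectorised, `rg >= 0`).
#' @return PAR in umol m-2 s-1.
#' @examples
#' par_from_rg(1000) # 2110
#' @export
par_from_rg <- function(rg) {
  if (any(rg < 0, na.rm = TRUE)) stop("par_from_rg: rg must be >= 0", call. = FALSE)
  2.11 * rg
}

#' Keep daytime, measured flux records
#'
#' Applies the quality screen used before light-response fitting: only
#' half-hours with Rg strictly above 10 W m-2 (daytime) whose NEE was
#' actually measured (not gap-filled) are retained. Record order is
#' preserved; the filter is idempotent.
#'
#' @param records Data frame with at least columns `rg` (W m-2) and
#'   `measured` (logical, `TRUE` = not gap-filled).
#' @param rg_daytime Daytime threshold on Rg, W m-2 (default 10; strict
#'   inequality).
#' @return The subset of `records` passing both screens.
#' @export
filter_daytime_measured <- function(records, rg_daytime = 10) {
  if (!all(c("rg", "measured") %in% names(records))) {
    stop("filter_daytime_measured: records need columns 'rg' and 'measured'",
         call. = FALSE)
  }
  keep <- !is.na(records$rg) & records$rg > rg_daytime &
    !is.na(records$measured) & records$measured
  records[keep, , drop = FALSE]
}

#' Screen a site-year by growing-season gap density
#'
#' Counts, over April 1 to September 30 (183 calendar days), the days with
#' more than 80% gaps among the 48 expected half-hours (a gap is a
#' gap-filled or absent record). Site-years where more than 25% of those
#' days are bad are excluded. Both thresholds are strict, and days with no
#' records at all count their missing slots as gaps.
#'
#' @param records Data frame with columns `timestamp` (POSIXct) and
#'   `measured` (logical).
#' @param year Calendar year to screen.
#' @param day_gap Per-day bad-gap fraction threshold (default 0.80).
#' @param year_bad Site-year bad-day fraction threshold (default 0.25).
#' @return List with `year`, `n_days_screened`, `n_bad_days`,
#'   `bad_fraction`, `keep`, `status` ("ok" or "empty").
#' @export
screen_site_year <- function(records, year, day_gap = 0.80, year_bad = 0.25) {
  if (!all(c("timestamp", "measured") %in% names(records))) {
    stop("screen_site_year: records need columns 'timestamp' and 'measured'",
         call. = FALSE)
  }
  start <- as.Date(sprintf("%d-04-01", year))
  end <- as.Date(sprintf("%d-09-30", year))
  days <- seq(start, end, by = "day")
  n_days <- length(days) # 183
  rec_day <- as.Date(records$timestamp, tz = "UTC")
  in_season <- rec_day >= start & rec_day <= end
  if (!any(in_season)) {
    return(list(year = year, n_days_screened = n_days, n_bad_days = n_days,
                bad_fraction = 1, keep = FALSE, status = "empty"))
  }
  measured_by_day <- tapply(records$measured[in_season], rec_day[in_season],
                            function(m) sum(m, na.rm = TRUE))
  n_measured <- rep(0L, n_days)
  names(n_measured) <- as.character(days)
  n_measured[names(measured_by_day)] <- as.integer(measured_by_day)
  gap_frac <- (48 - pmin(n_measured, 48)) / 48
  n_bad <- sum(gap_frac > day_gap)
  bad_fraction <- n_bad / n_days
  list(year = year, n_days_screened = n_days, n_bad_days = n_bad,
       bad_fraction = bad_fraction, keep = bad_fraction <= year_bad,
       status = "ok")
}

#' Attach absorbed PAR to half-hourly records
#'
#' APAR = FAPAR(day) x PAR for every half-hour. Records on days with no
#' FAPAR value get `NA` APAR (missing, never silently zero).
#'
#' @param records Data frame with `timestamp` and `par` columns.
#' @param daily_fapar Data frame with columns `date` (Date) and `fapar`.
#' @return `records` with an `apar` column added (umol m-2 s-1).
#' @export
compute_apar <- function(records, daily_fapar) {
  if (!all(c("date", "fapar") %in% names(daily_fapar))) {
    stop("compute_apar: daily_fapar needs columns 'date' and 'fapar'", call. = FALSE)
  }
  day <- as.Date(records$timestamp, tz = "UTC")
  idx <- match(day, daily_fapar$date)
  records$apar <- daily_fapar$fapar[idx] * records$par
  records
}
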