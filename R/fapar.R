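# 16-day FAPAR gap-filling from neighbour pixels, daily smoothing, and
# annual maximum LAI. A FAPAR series is a data frame with columns
# `date` (Date, strictly increasing 16-day grid) and `fapar` in [0, 1]
# (NA = gap); neighbours carry a `pixel_id`.

#' Rank neighbour pixels as gap-fill donors
#'
#' Computes, for every candidate neighbour pixel, the dependence of its
#' FAPAR series with the central pixel over pairwise-complete time steps
#' and keeps the pixels with correlation strictly above `threshold`
#' (default .75), sorted by decreasing correlation. Distance correlation
#' is the default measure; Pearson is available as a switch.
#'
#' @param central FAPAR series of the tower pixel.
#' @param neighbors Named list of neighbour FAPAR series.
#' @param threshold Donor screening threshold (default 0.75, strict).
#' @param method `"dcor"` (default) or `"pearson"`.
#' @param min_pairs Minimum pairwise-complete steps per candidate (default 8).
#' @return Data frame `pixel_id`, `correlation`, ordered best first, with
#'   the qualifying series in `attr(, "series")`.
#' @export
neighbor_screen <- function(central, neighbors, threshold = 0.75,
                            method = c("dcor", "pearson"), min_pairs = 8L) {
  method <- match.arg(method)
  if (all(is.na(central$fapar))) stop("neighbor_screen: central pixel all missing", call. = FALSE)
  rows <- lapply(names(neighbors), function(id) {
    nb <- neighbors[[id]]
    v <- nb$fapar[match(central$date, nb$date)]
    ok <- !is.na(central$fapar) & !is.na(v)
    if (sum(ok) < min_pairs) return(NULL)
    r <- tryCatch(
      if (method == "dcor") distance_correlation(central$fapar[ok], v[ok])
      else stats::cor(central$fapar[ok], v[ok]),
      error = function(e) NA_real_)
    if (is.na(r) || r <= threshold) return(NULL)
    data.frame(pixel_id = id, correlation = r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(pixel_id = character(), correlation = numeric())
  out <- out[order(-out$correlation), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "series") <- neighbors[out$pixel_id]
  out
}

#' Fill central-pixel FAPAR gaps from ranked donor pixels
#'
#' Each gap is filled from the highest-ranked donor that has a value at
#' that date. By default the donor value passes through an affine bias
#' correction (central regressed on donor over their shared dates) so
#' that donors at a different level still fill at the central pixel's
#' scale; `bias_correct = FALSE` substitutes raw donor values. Non-missing
#' central values are never altered; unfillable gaps stay `NA`.
#'
#' @param central Central FAPAR series.
#' @param donors Ranked donor table from [neighbor_screen()].
#' @param bias_correct Apply per-donor affine correction (default `TRUE`).
#' @return `central` with filled `fapar` (clamped to `[0, 1]`) and a
#'   `provenance` column: `"observed"`, donor pixel id, or `"unfilled"`.
#' @export
gapfill_central <- function(central, donors, bias_correct = TRUE) {
  series <- attr(donors, "series")
  out <- central
  out$provenance <- ifelse(is.na(out$fapar), "unfilled", "observed")
  if (nrow(donors) == 0L || !any(is.na(out$fapar))) return(out)
  for (id in donors$pixel_id) {
    gaps <- which(is.na(out$fapar))
    if (length(gaps) == 0L) break
    nb <- series[[id]]
    v <- nb$fapar[match(out$date, nb$date)]
    if (bias_correct) {
      shared <- !is.na(central$fapar) & !is.na(v)
      if (sum(shared) >= 3L && stats::var(v[shared]) > 0) {
        fit <- stats::lm.fit(cbind(1, v[shared]), central$fapar[shared])
        v <- fit$coefficients[1] + fit$coefficients[2] * v
      }
    }
    fillable <- gaps[!is.na(v[gaps])]
    out$fapar[fillable] <- clamp01(v[fillable])
    out$provenance[fillable] <- id
  }
  out
}

#' Fill residual FAPAR gaps by climatology, then interpolation
#'
#' Stands in for a full spatiotemporal gap-filler: each remaining gap is
#' replaced by the mean of same-period values (same 16-day slot of the
#' year) from the other years when any exist, and otherwise by linear
#' interpolation in time (nearest value at the ends). Output is gapless
#' and clamped to `[0, 1]`. This is a deliberately simple fallback; its
#' provenance marks make the filled steps auditable.
#'
#' @param series FAPAR series (columns `date`, `fapar`, optional
#'   `provenance`).
#' @return Fully filled series with updated `provenance`
#'   (`"climatology"` / `"interpolated"`).
#' @export
fallback_fill <- function(series) {
  if (all(is.na(series$fapar))) stop("fallback_fill: no non-missing values", call. = FALSE)
  out <- series
  if (is.null(out$provenance)) {
    out$provenance <- ifelse(is.na(out$fapar), "unfilled", "observed")
  }
  gaps <- which(is.na(out$fapar))
  if (length(gaps) > 0L) {
    doy <- as.integer(format(out$date, "%j"))
    slot <- (doy - 1L) %/% 16L
    yr <- as.integer(format(out$date, "%Y"))
    for (i in gaps) {
      same <- slot == slot[i] & yr != yr[i] & !is.na(series$fapar)
      if (any(same)) {
        out$fapar[i] <- mean(series$fapar[same])
        out$provenance[i] <- "climatology"
      }
    }
  }
  gaps <- which(is.na(out$fapar))
  if (length(gaps) > 0L) {
    known <- !is.na(out$fapar)
    t <- as.numeric(out$date)
    out$fapar[gaps] <- stats::approx(t[known], out$fapar[known], xout = t[gaps],
                                     rule = 2)$y
    out$provenance[gaps] <- "interpolated"
  }
  out$fapar <- clamp01(out$fapar)
  out
}

#' Smooth a gapless 16-day FAPAR series to daily resolution
#'
#' A cubic smoothing spline (smoothing parameter chosen by generalized
#' cross-validation) is fitted to the 16-day values and evaluated on every
#' calendar day between the first and last knot; results are clamped to
#' `[0, 1]`.
#'
#' @param series Gapless FAPAR series (`date`, `fapar`).
#' @return Data frame `date`, `fapar` at daily step.
#' @export
smooth_to_daily <- function(series) {
  if (anyNA(series$fapar)) stop("smooth_to_daily: series has gaps; fill first", call. = FALSE)
  if (nrow(series) < 4L) stop("smooth_to_daily: need at least 4 knots", call. = FALSE)
  t <- as.numeric(series$date)
  # smooth.spline needs response variance; a constant series is returned as is
  if (stats::var(series$fapar) == 0) {
    days <- seq(min(series$date), max(series$date), by = "day")
    return(data.frame(date = days, fapar = rep(series$fapar[1], length(days))))
  }
  fit <- stats::smooth.spline(t, series$fapar, cv = FALSE)
  days <- seq(min(series$date), max(series$date), by = "day")
  data.frame(date = days,
             fapar = clamp01(stats::predict(fit, as.numeric(days))$y))
}

#' Annual maximum LAI as the 90th percentile of retrievals
#'
#' The annual "maximum" leaf area index is taken as the 90th percentile of
#' that year's 16-day satellite retrievals (shared percentile convention),
#' which is robust to single-retrieval outliers.
#'
#' @param lai Data frame with `date` (Date) and `lai` (m2 m-2, `>= 0`).
#' @param year Calendar year.
#' @param p Percentile (default 0.9).
#' @return Scalar LAI.
#' @export
annual_max_lai <- function(lai, year, p = 0.9) {
  v <- lai$lai[as.integer(format(lai$date, "%Y")) == year]
  v <- v[!is.na(v)]
  if (any(v < 0)) stop("annual_max_lai: negative LAI", call. = FALSE)
  if (length(v) < 5L) stop("annual_max_lai: need >= 5 retrievals in the year", call. = FALSE)
  efp_percentile(v, p)
}
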