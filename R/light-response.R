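# Nonrectangular hyperbolic light response of ecosystem GPP and the
# capacity quantities derived from it. Radiation Q is PAR or APAR in
# umol photons m-2 s-1; GPP in umol CO2 m-2 s-1.

#' Nonrectangular hyperbolic light response
#'
#' The Gilmanov-type nonrectangular hyperbola
#' \deqn{GPP(Q) = \frac{\alpha Q + A_{max} -
#'   \sqrt{(\alpha Q + A_{max})^2 - 4\theta\alpha Q A_{max}}}{2\theta}}
#' i.e. the smaller root of
#' \eqn{\theta\,GPP^2 - (\alpha Q + A_{max})\,GPP + \alpha Q A_{max} = 0},
#' where `alpha` is the initial (quantum-yield) slope, `amax` the plateau
#' and `theta` in `[0, 1]` the curvature. `theta = 0` is evaluated through
#' its analytic Michaelis-Menten limit (the rectangular hyperbola) to
#' avoid 0/0; `theta = 1` reduces to the Blackman limit
#' `min(alpha * Q, amax)`.
#'
#' @param q Radiation, umol m-2 s-1 (vectorised, `q >= 0`).
#' @param alpha Initial slope, umol CO2 per umol photons (> 0).
#' @param amax Plateau, umol CO2 m-2 s-1 (> 0).
#' @param theta Curvature in `[0, 1]`.
#' @return GPP, bounded by `0 <= GPP <= min(alpha * q, amax)`.
#' @examples
#' nrh_gpp(2110, alpha = 0.03, amax = 25, theta = 0.7)
#' @export
nrh_gpp <- function(q, alpha, amax, theta) {
  if (theta < 0 || theta > 1) stop("nrh_gpp: theta must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || amax <= 0) stop("nrh_gpp: alpha and amax must be > 0", call. = FALSE)
  if (any(q < 0, na.rm = TRUE)) stop("nrh_gpp: q must be >= 0", call. = FALSE)
  if (theta == 0) return(mm_gpp(q, alpha, amax))
  s <- alpha * q + amax
  disc <- pmax(s * s - 4 * theta * alpha * q * amax, 0)
  (s - sqrt(disc)) / (2 * theta)
}

#' Michaelis-Menten (rectangular hyperbola) light response
#'
#' `GPP(Q) = alpha * Q * amax / (alpha * Q + amax)`; the `theta -> 0`
#' limit of [nrh_gpp()], used by the original analysis as a cross-check
#' model.
#'
#' @inheritParams nrh_gpp
#' @return GPP, umol CO2 m-2 s-1.
#' @export
mm_gpp <- function(q, alpha, amax) {
  if (alpha <= 0 || amax <= 0) stop("mm_gpp: alpha and amax must be > 0", call. = FALSE)
  if (any(q < 0, na.rm = TRUE)) stop("mm_gpp: q must be >= 0", call. = FALSE)
  aq <- alpha * q
  ifelse(q == 0, 0, aq * amax / (aq + amax))
}

#' Coefficient of determination of a fit
#'
#' `R2 = 1 - SSE/SST` with `SST` about the observed mean; can be negative
#' when the model is worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length, `n >= 2`.
#' @return Scalar R2 (`<= 1`).
#' @export
r2_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("r2_of_fit: need equal-length vectors with n >= 2", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("r2_of_fit: observed values have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

#' Fit the light-response curve in one 5-day window
#'
#' Minimises the residual sum of squares of the nonrectangular hyperbola
#' over the QC-filtered half-hours in `center_date` +/- `half_width` days,
#' using box-constrained quasi-Newton optimisation (`optim`, L-BFGS-B)
#' with multiple starts: `theta` start values spread over (0, 1), `alpha`
#' from a low-light slope heuristic, `amax` from the window's 95th GPP
#' percentile. Box constraints default to `alpha` in `[1e-6, 0.5]`,
#' `amax` in `[0.1, 100]`, `theta` in `[0, 1]`.
#'
#' @param records QC-filtered data frame with `timestamp`, `gpp`, and the
#'   radiation column selected by `radiation_kind` (`par` or `apar`).
#' @param center_date `Date` at the window centre.
#' @param radiation_kind `"PAR"` or `"APAR"`.
#' @param half_width Window half-width in days (default 2: 5-day window).
#' @param min_obs Minimum half-hours required to attempt a fit (default 20).
#' @param n_starts Number of curvature start values (default 5).
#' @param bounds List with `alpha`, `amax`, `theta` two-vectors.
#' @return List of class `"lr_fit"`: `alpha`, `amax`, `theta`, `r2`,
#'   `n_obs`, `center_date`, `radiation_kind`, `converged`, `rss`,
#'   `q_max` (highest radiation seen; low values mean a poorly
#'   constrained plateau).
#' @export
fit_window <- function(records, center_date, radiation_kind = c("PAR", "APAR"),
                       half_width = 2L, min_obs = 20L, n_starts = 5L,
                       bounds = list(alpha = c(1e-6, 0.5),
                                     amax = c(0.1, 100),
                                     theta = c(0, 1))) {
  radiation_kind <- match.arg(radiation_kind)
  qcol <- if (radiation_kind == "PAR") "par" else "apar"
  day <- as.Date(records$timestamp, tz = "UTC")
  sel <- day >= center_date - half_width & day <= center_date + half_width
  q <- records[[qcol]][sel]
  g <- records$gpp[sel]
  ok <- !is.na(q) & !is.na(g)
  q <- q[ok]; g <- g[ok]
  failed <- list(alpha = NA_real_, amax = NA_real_, theta = NA_real_,
                 r2 = NA_real_, n_obs = length(g), center_date = center_date,
                 radiation_kind = radiation_kind, converged = FALSE,
                 rss = NA_real_, q_max = if (length(q)) max(q) else NA_real_)
  class(failed) <- "lr_fit"
  if (length(g) < min_obs) return(failed)

  obj <- function(p) sum((g - nrh_gpp(q, p[1], p[2], p[3]))^2)
  # analytic gradient of the residual sum of squares
  grad <- function(p) {
    al <- p[1]; am <- p[2]; th <- max(p[3], 1e-9)
    s <- al * q + am
    D <- sqrt(pmax(s * s - 4 * th * al * q * am, 1e-12))
    G <- (s - D) / (2 * th)
    r <- g - G
    dG_da <- (q - (s * q - 2 * th * q * am) / D) / (2 * th)
    dG_dm <- (1 - (s - 2 * th * al * q) / D) / (2 * th)
    dG_dt <- al * q * am / (th * D) - (s - D) / (2 * th * th)
    -2 * c(sum(r * dG_da), sum(r * dG_dm), sum(r * dG_dt))
  }

  # start heuristics
  low <- q < stats::quantile(q, 0.25)
  a0 <- if (sum(low) >= 3 && stats::var(q[low]) > 0) {
    stats::cov(q[low], g[low]) / stats::var(q[low])
  } else 0.03
  a0 <- min(max(a0, bounds$alpha[1] * 10), bounds$alpha[2] * 0.9)
  m0 <- min(max(stats::quantile(g, 0.95), bounds$amax[1] * 2), bounds$amax[2] * 0.9)
  thetas <- seq(0.1, 0.9, length.out = n_starts)

  best <- NULL
  for (th in thetas) {
    fit <- tryCatch(
      stats::optim(c(a0, m0, th), obj, gr = grad, method = "L-BFGS-B",
                   lower = c(bounds$alpha[1], bounds$amax[1], bounds$theta[1]),
                   upper = c(bounds$alpha[2], bounds$amax[2], bounds$theta[2]),
                   control = list(maxit = 500, factr = 1e4, pgtol = 1e-12,
                                  parscale = c(0.05, m0, 0.5))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(failed)
  p <- best$par
  pred <- nrh_gpp(q, p[1], p[2], p[3])
  r2 <- if (stats::var(g) > 0) r2_of_fit(g, pred) else NA_real_
  out <- list(alpha = p[1], amax = p[2], theta = p[3], r2 = r2,
              n_obs = length(g), center_date = center_date,
              radiation_kind = radiation_kind, converged = TRUE,
              rss = best$value, q_max = max(q))
  class(out) <- "lr_fit"
  out
}

#' Daily capacity quantities from one window fit
#'
#' From a converged fit, computes GPP at saturating light
#' (`gpp_sat = GPP(Qsat)`, with `Qsat` 2110 umol m-2 s-1 for PAR and
#' 2000 for APAR, the defaults) and the cumulative light response
#' (`gpp_cum = integral of GPP(Q) dQ from 0 to Qsat`, adaptive
#' quadrature), copies `amax`, and flags the day as retained when the
#' fit's R2 exceeds `r2_threshold`.
#'
#' @param params An `"lr_fit"` from [fit_window()] with `converged = TRUE`.
#' @param qsat_par,qsat_apar Saturating-light thresholds (umol m-2 s-1).
#' @param r2_threshold Retention threshold on fit R2 (default 0.6, strict).
#' @return List: `center_date`, `radiation_kind`, `alpha`, `amax`,
#'   `theta`, `r2`, `n_obs`, `gpp_sat`, `gpp_cum`, `retained`.
#' @export
derive_daily <- function(params, qsat_par = 2110, qsat_apar = 2000,
                         r2_threshold = 0.6) {
  if (!isTRUE(params$converged)) stop("derive_daily: fit did not converge", call. = FALSE)
  qsat <- if (params$radiation_kind == "PAR") qsat_par else qsat_apar
  gpp_sat <- nrh_gpp(qsat, params$alpha, params$amax, params$theta)
  f <- function(qq) nrh_gpp(qq, params$alpha, params$amax, params$theta)
  quad <- tryCatch(stats::integrate(f, 0, qsat, rel.tol = 1e-6,
                                    subdivisions = 200L), error = function(e) NULL)
  gpp_cum <- if (!is.null(quad) && quad$message == "OK") quad$value else {
    # composite Simpson fallback for near-Blackman curvature, where the
    # adaptive rule reports roundoff; 4001 nodes give ~1e-8 relative here
    x <- seq(0, qsat, length.out = 4001L)
    h <- x[2] - x[1]
    y <- f(x)
    h / 3 * (y[1] + y[4001] + 4 * sum(y[seq(2, 4000, 2)]) +
               2 * sum(y[seq(3, 3999, 2)]))
  }
  list(center_date = params$center_date, radiation_kind = params$radiation_kind,
       alpha = params$alpha, amax = params$amax, theta = params$theta,
       r2 = params$r2, n_obs = params$n_obs,
       gpp_sat = gpp_sat, gpp_cum = gpp_cum,
       retained = !is.na(params$r2) && params$r2 > r2_threshold)
}

#' Daily capacity series for a span of window centres
#'
#' Slides the 5-day window one day at a time over `center_dates`, fits
#' each window and derives the daily quantities; non-converged windows
#' yield `NA` rows with `retained = FALSE`.
#'
#' @inheritParams fit_window
#' @inheritParams derive_daily
#' @param center_dates Vector of `Date` window centres (consecutive days).
#' @param ... Passed to [fit_window()].
#' @return Data frame, one row per centre date: the [derive_daily()]
#'   fields.
#' @export
fit_lrc_series <- function(records, center_dates,
                           radiation_kind = c("PAR", "APAR"),
                           qsat_par = 2110, qsat_apar = 2000,
                           r2_threshold = 0.6, ...) {
  radiation_kind <- match.arg(radiation_kind)
  rows <- lapply(center_dates, function(d) {
    fit <- fit_window(records, d, radiation_kind, ...)
    if (!fit$converged) {
      return(data.frame(center_date = d, radiation_kind = radiation_kind,
                        alpha = NA_real_, amax = NA_real_, theta = NA_real_,
                        r2 = NA_real_, n_obs = fit$n_obs, gpp_sat = NA_real_,
                        gpp_cum = NA_real_, retained = FALSE))
    }
    as.data.frame(derive_daily(fit, qsat_par, qsat_apar, r2_threshold))
  })
  do.call(rbind, rows)
}
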