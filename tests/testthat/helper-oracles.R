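# Independent oracles and fixture builders used across the suite.

# Percentile oracle: sort + linear interpolation at rank h = (n - 1) p + 1.
pctl_oracle <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# O(n^2) double-centering distance-correlation oracle, explicit loops.
dcor_brute <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    a[j, k] <- abs(x[j] - x[k])
    b[j, k] <- abs(y[j] - y[k])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    A[j, k] <- a[j, k] - mean(a[j, ]) - mean(a[, k]) + mean(a)
    B[j, k] <- b[j, k] - mean(b[j, ]) - mean(b[, k]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  sqrt(max(dcov2, 0)) / sqrt(sqrt(dvx) * sqrt(dvy))
}

# Normal-equations OLS oracle.
ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Trapezoid-rule integral oracle on n nodes.
trapz_oracle <- function(f, lower, upper, n = 10000L) {
  x <- seq(lower, upper, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# Smaller root of theta G^2 - (alpha q + amax) G + alpha q amax = 0 via
# polyroot: a light-response oracle independent of the closed form.
nrh_oracle <- function(q, alpha, amax, theta) {
  vapply(q, function(qq) {
    if (qq == 0) return(0)
    if (theta == 0) return(alpha * qq * amax / (alpha * qq + amax))
    r <- Re(polyroot(c(alpha * qq * amax, -(alpha * qq + amax), theta)))
    min(r)
  }, numeric(1))
}

# Half-hourly records for one 5-day window with known light response.
make_window_records <- function(alpha, amax, theta, n = 240,
                                q_max = 2000, noise_sd = 0, seed = 1,
                                center = as.Date("2001-07-15")) {
  set.seed(seed)
  q <- seq(10, q_max, length.out = n)
  gpp <- efpcap::nrh_gpp(q, alpha, amax, theta)
  if (noise_sd > 0) gpp <- gpp + rnorm(n, 0, noise_sd * pmax(gpp, 1e-9))
  days <- rep(center + (-2:2), length.out = n)
  ts <- as.POSIXct(paste(days, "10:00:00"), tz = "UTC") +
    1800 * (seq_len(n) %/% 5)
  data.frame(timestamp = ts, gpp = gpp, rg = q / 2.11, par = q,
             measured = TRUE)
}

# 16-day FAPAR series helper.
fapar_series <- function(values, start = as.Date("2001-01-01")) {
  data.frame(date = start + 16 * (seq_along(values) - 1), fapar = values)
}

# Annual-EFP + trait fixture for the year-resampling permutation test:
# aligned = TRUE puts the trait signal only in the sampling year.
make_resampling_data <- function(n_sites = 15, n_years = 4, aligned = TRUE,
                                 constant = FALSE, seed = 99) {
  set.seed(seed)
  trait <- runif(n_sites, 1, 3)
  sampling_year <- 2010
  rows <- list()
  for (i in 1:n_sites) {
    for (y in 2008:(2008 + n_years - 1)) {
      v <- if (constant) 15 + 7 * trait[i]
      else if (aligned && y == sampling_year) 15 + 7 * trait[i] + rnorm(1, 0, 0.5)
      else rnorm(1, 30, 6) # scrambled in other years
      rows[[length(rows) + 1]] <- data.frame(site = i, year = y, value = v)
    }
  }
  list(annual = do.call(rbind, rows),
       traits = data.frame(site = 1:n_sites, trait = trait,
                           sampling_year = sampling_year))
}
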