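#' Distance correlation
#'
#' Dependence measure of Szekely, Rizzo and Bakirov based on double-centred
#' Euclidean distance matrices. Unlike Pearson's r it is zero (in the
#' population) only under independence and is sensitive to nonlinear
#' association, which is why it backs both the FAPAR neighbour-pixel screen
#' and the trait-capacity relationship diagnostics.
#'
#' The V-statistic form is used: with `a_jk = |x_j - x_k|` and `A` the
#' double-centred version of `a` (row means, column means and grand mean
#' removed), `dCov^2 = mean(A * B)` and
#' `dCor = dCov / sqrt(dVar_x * dVar_y)`.
#'
#' @param x,y Numeric vectors of equal length (`n >= 4`), no `NA`s.
#' @return Scalar in `[0, 1]` (up to floating point).
#' @examples
#' x <- seq(-3, 3, length.out = 50)
#' distance_correlation(x, x^2) # high despite Pearson ~ 0
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("distance_correlation: missing values", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("distance_correlation: need n >= 4", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("distance_correlation: constant input", call. = FALSE)
  }
  A <- dc_center(abs(outer(x, x, "-")))
  B <- dc_center(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  sqrt(max(dcov2, 0)) / sqrt(sqrt(dvarx) * sqrt(dvary))
}

dc_center <- function(d) {
  rm_ <- rowMeans(d)
  cm_ <- colMeans(d)
  d - outer(rm_, rep(1, ncol(d))) - outer(rep(1, nrow(d)), cm_) + mean(d)
}
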