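# Internal helpers shared across the package.

#' Percentile with the shared linear-interpolation convention
#'
#' Every percentile extraction in the package (annual capacity values,
#' annual maximum LAI, estimator summaries) uses one convention: linear
#' interpolation between order statistics at rank `h = (n - 1) * p + 1`.
#' `"max"` is accepted as a label for the sample maximum.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @param p Probability in `[0, 1]`, or the string `"max"`.
#' @return Numeric scalar.
#' @examples
#' efp_percentile(seq(10, 100, by = 10), 0.9) # 91
#' @export
efp_percentile <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("efp_percentile: no non-missing values", call. = FALSE)
  if (identical(p, "max")) return(max(x))
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop("efp_percentile: 'p' must be a probability in [0, 1] or \"max\"", call. = FALSE)
  }
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# Run code with a temporary RNG state seeded at `seed`; the caller's RNG
# state is untouched. Used so each generator stage has its own stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for a named stream, kept inside 32-bit range.
stream_seed <- function(seed, stream) {
  offsets <- c(radiation = 11L, noise = 23L, gaps = 37L, fapar = 53L,
               traits = 71L, years = 83L, pipeline = 97L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream, call. = FALSE)
  (as.integer(seed) %% 1000003L) * 1009L + offsets[[stream]]
}

clamp01 <- function(x) pmin(1, pmax(0, x))

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
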