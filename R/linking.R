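# Trait-capacity linking: OLS with diagnostics, leave-one-out
# cross-validation (modeling efficiency / RRMSE), ANCOVA across
# synchronisation scenarios, a year-resampling permutation test, and
# stepwise AIC selection over transformed trait predictors.

#' Ordinary least squares with the linking diagnostics
#'
#' Fits `y ~ terms` by least squares and bundles the statistics reported
#' alongside each trait-capacity relationship: coefficients with standard
#' errors, R2, adjusted R2, overall F p-value, distance correlation
#' between observations and fitted values, leave-one-out modeling
#' efficiency (EF) and relative RMSE.
#'
#' @param y Response vector.
#' @param terms Data frame of predictor columns (may include transformed
#'   or interaction columns).
#' @param loocv Also compute leave-one-out EF/RRMSE (default `TRUE`).
#' @return List of class `"efp_ols"`: `coefficients` (data frame `term`,
#'   `estimate`, `se`), `r2`, `adj_r2`, `p`, `df`, `dcor`, `ef`, `rrmse`,
#'   `n`, `fit` (the underlying `lm`).
#' @export
ols <- function(y, terms, loocv = TRUE) {
  terms <- as.data.frame(terms)
  n <- length(y)
  if (n <= ncol(terms) + 1L) stop("ols: need n > number of terms + 1", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(terms))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("ols: rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = y, terms, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- suppressWarnings(summary(fit)) # perfect fits are legitimate here
  if (stats::var(y) == 0) { # constant response: define R2 = 0, not 0/0
    sm$r.squared <- 0
    sm$adj.r.squared <- 0
  }
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  co <- sm$coefficients
  res <- list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], row.names = NULL),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared, p = pval,
    df = c(predictors = ncol(terms), residual = fit$df.residual),
    dcor = tryCatch(distance_correlation(y, stats::fitted(fit)),
                    error = function(e) NA_real_),
    ef = NA_real_, rrmse = NA_real_, n = n, fit = fit)
  if (loocv) {
    cvm <- loocv_metrics(y, terms)
    res$ef <- cvm$ef
    res$rrmse <- cvm$rrmse
  }
  class(res) <- "efp_ols"
  res
}

#' @export
print.efp_ols <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): R2 = %.3f, adj R2 = %.3f, p = %.3g\n",
              x$n, x$r2, x$adj_r2, x$p))
  cat(sprintf("dcor = %.3f, LOOCV EF = %.3f, RRMSE = %.1f%%\n",
              x$dcor, x$ef, x$rrmse))
  print(x$coefficients, ...)
  invisible(x)
}

#' Leave-one-out cross-validated modeling efficiency and RRMSE
#'
#' Refits the linear model excluding each observation in turn, predicts
#' the left-out point, and computes modeling efficiency
#' `EF = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` (Nash-Sutcliffe
#' form; negative when predictions are worse than the observed mean) and
#' `RRMSE = 100 * RMSE / mean(y)` in percent.
#'
#' @inheritParams ols
#' @return List: `ef`, `rrmse`, `predictions`.
#' @export
loocv_metrics <- function(y, terms) {
  terms <- as.data.frame(terms)
  n <- length(y)
  if (n < 3L) stop("loocv_metrics: need n >= 3", call. = FALSE)
  if (mean(y) == 0) stop("loocv_metrics: mean(y) is zero, RRMSE undefined", call. = FALSE)
  X <- cbind(1, as.matrix(terms))
  pred <- vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
    sum(X[i, ] * fit$coefficients)
  }, numeric(1))
  ef <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  rrmse <- 100 * sqrt(mean((y - pred)^2)) / mean(y)
  list(ef = ef, rrmse = rrmse, predictions = pred)
}

#' ANCOVA: slope and intercept differences across groups
#'
#' Fits `y ~ x + group + x:group` and reports the sequential F-tests of
#' the interaction (slope homogeneity across the synchronisation
#' scenarios) and of the group factor (intercept differences, adjusted
#' for `x`).
#'
#' @param y Response vector.
#' @param x Covariate.
#' @param group Factor (or coercible) of scenario labels, each level with
#'   at least 3 observations.
#' @return List: `interaction_F`, `interaction_p` (slope differences),
#'   `group_F`, `group_p` (intercept differences), `fit`.
#' @export
ancova <- function(y, x, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("ancova: need at least 2 groups", call. = FALSE)
  if (any(table(group) < 3L)) stop("ancova: every group needs n >= 3", call. = FALSE)
  fit <- stats::lm(y ~ x + group + x:group)
  an <- suppressWarnings(stats::anova(fit))
  list(interaction_F = an["x:group", "F value"],
       interaction_p = an["x:group", "Pr(>F)"],
       group_F = an["group", "F value"],
       group_p = an["group", "Pr(>F)"],
       fit = fit)
}

#' Permutation test of the gain from year-synchronised capacity values
#'
#' Tests whether using the capacity value of the trait-sampling year
#' gives a better trait relationship than an arbitrary year would: the
#' observed R2 (sampling-year values regressed on the trait) is compared
#' with a null distribution obtained by assigning each site a uniformly
#' random available year, `B` times. The empirical p-value uses the +1
#' correction, `p = (1 + #(null >= observed)) / (B + 1)`.
#'
#' @param annual Data frame with columns `site`, `year`, `value` (annual
#'   capacity per site-year).
#' @param traits Data frame with columns `site`, `trait` (one row per
#'   site) and `sampling_year`.
#' @param B Number of permutations (default 999, minimum 99).
#' @param seed Integer seed for the resampling stream.
#' @return List: `observed_r2`, `null_r2` (length `B`), `p`.
#' @export
year_resampling_test <- function(annual, traits, B = 999L, seed = 1L) {
  if (B < 1L) stop("year_resampling_test: B must be >= 1", call. = FALSE)
  sites <- traits$site
  by_site <- split(annual$value[!is.na(annual$value)],
                   annual$site[!is.na(annual$value)])
  obs_val <- vapply(seq_along(sites), function(i) {
    v <- annual$value[annual$site == sites[i] &
                        annual$year == traits$sampling_year[i]]
    if (length(v) == 0L) NA_real_ else v[1]
  }, numeric(1))
  ok <- !is.na(obs_val) & !is.na(traits$trait)
  if (sum(ok) < 4L) stop("year_resampling_test: too few sites with sampling-year values",
                         call. = FALSE)
  r2_of <- function(v) {
    f <- stats::lm.fit(cbind(1, traits$trait[ok]), v[ok])
    1 - sum(f$residuals^2) / sum((v[ok] - mean(v[ok]))^2)
  }
  observed <- r2_of(obs_val)
  null_r2 <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      drawn <- vapply(sites, function(s) {
        v <- by_site[[as.character(s)]]
        if (is.null(v) || length(v) == 0L) NA_real_ else v[sample.int(length(v), 1L)]
      }, numeric(1))
      r2_of(drawn)
    }, numeric(1))
  })
  list(observed_r2 = observed, null_r2 = null_r2,
       p = (1 + sum(null_r2 >= observed)) / (B + 1))
}

#' Expand base predictors into the candidate term set
#'
#' For every base variable `v` the candidates `v`, `v^2`, `sqrt(v)` and
#' `log(v)` are generated (square root and logarithm are dropped with a
#' warning for variables with non-positive values), plus every ordered
#' ratio `vi/vj` of two distinct base variables. Candidates are
#' deduplicated by name, so a measured ratio trait (e.g. C/N) and its
#' reconstructed counterpart enter once.
#'
#' @param traits Data frame of base predictor columns (numeric).
#' @return Data frame of candidate columns, named `v`, `v^2`, `sqrt(v)`,
#'   `log(v)`, `vi/vj`.
#' @export
expand_predictors <- function(traits) {
  traits <- as.data.frame(traits)
  vars <- names(traits)
  out <- list()
  for (v in vars) {
    x <- traits[[v]]
    out[[v]] <- x
    out[[paste0(v, "^2")]] <- x^2
    if (all(x > 0, na.rm = TRUE)) {
      out[[paste0("sqrt(", v, ")")]] <- sqrt(x)
      out[[paste0("log(", v, ")")]] <- log(x)
    } else {
      warning(sprintf("expand_predictors: dropping sqrt/log of '%s' (non-positive values)", v),
              call. = FALSE)
    }
  }
  for (vi in vars) for (vj in vars) {
    if (vi == vj) next
    nm <- paste0(vi, "/", vj)
    if (nm %in% names(out)) next
    out[[nm]] <- traits[[vi]] / traits[[vj]]
  }
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}

# AIC convention used by the stepwise search: constant terms dropped,
# k = number of regression coefficients including the intercept.
aic_rss <- function(rss, n, k) n * log(rss / n) + 2 * k

#' Bidirectional stepwise selection by AIC
#'
#' Starting from the intercept-only model, repeatedly applies the single
#' term addition or removal that most lowers
#' `AIC = n * log(RSS / n) + 2k` (`k` = coefficients incl. intercept),
#' stopping when no move lowers it, when the model reaches `max_terms`
#' (default `n / 5`), or when direction restrictions forbid further
#' moves. Ties are broken in favour of the earlier candidate; candidates
#' that would make the design rank-deficient are skipped.
#'
#' @param y Response vector.
#' @param candidates Data frame of candidate predictor columns, e.g. from
#'   [expand_predictors()].
#' @param direction `"both"` (default), `"forward"`, or `"backward"`
#'   (backward starts from the full — rank-permitting — model).
#' @param max_terms Cap on selected terms (default `floor(n / 5)`, at
#'   least 1).
#' @return List: `selected` (term names in selection order), `aic`,
#'   `result` (an [ols()] bundle for the final model, `NULL` if
#'   intercept-only), `trace` (data frame of moves).
#' @export
stepwise_aic <- function(y, candidates, direction = c("both", "forward", "backward"),
                         max_terms = NULL) {
  direction <- match.arg(direction)
  candidates <- as.data.frame(candidates, check.names = FALSE)
  n <- length(y)
  if (n <= 5L) stop("stepwise_aic: need n > 5", call. = FALSE)
  max_terms <- max(1L, max_terms %||% floor(n / 5))
  cand_names <- names(candidates)

  rank_ok <- function(sel) {
    X <- cbind(1, as.matrix(candidates[, sel, drop = FALSE]))
    qr(X)$rank == ncol(X)
  }
  model_aic <- function(sel) {
    X <- cbind(1, as.matrix(candidates[, sel, drop = FALSE]))
    fit <- stats::lm.fit(X, y)
    aic_rss(sum(fit$residuals^2), n, ncol(X))
  }

  current <- character(0)
  if (direction == "backward") {
    for (nm in cand_names) {
      if (length(current) >= max_terms) break
      if (rank_ok(c(current, nm))) current <- c(current, nm)
    }
  }
  current_aic <- model_aic(current)
  trace <- data.frame(step = 0L, move = "start",
                      term = NA_character_, aic = current_aic)
  step <- 0L
  repeat {
    step <- step + 1L
    best_move <- NULL
    best_aic <- current_aic
    if (direction %in% c("both", "forward") && length(current) < max_terms) {
      for (nm in setdiff(cand_names, current)) {
        if (anyNA(candidates[[nm]])) next
        if (!rank_ok(c(current, nm))) next
        a <- model_aic(c(current, nm))
        if (a < best_aic - 1e-10) { # strict improvement; earlier candidate wins ties
          best_aic <- a
          best_move <- list(kind = "add", term = nm)
        }
      }
    }
    if (direction %in% c("both", "backward")) {
      for (nm in current) {
        a <- model_aic(setdiff(current, nm))
        if (a < best_aic - 1e-10) {
          best_aic <- a
          best_move <- list(kind = "drop", term = nm)
        }
      }
    }
    if (is.null(best_move)) break
    current <- if (best_move$kind == "add") c(current, best_move$term)
               else setdiff(current, best_move$term)
    current_aic <- best_aic
    trace <- rbind(trace, data.frame(step = step, move = best_move$kind,
                                     term = best_move$term, aic = current_aic))
  }
  result <- if (length(current) > 0L) {
    ols(y, candidates[, current, drop = FALSE])
  } else NULL
  list(selected = current, aic = current_aic, result = result, trace = trace)
}
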