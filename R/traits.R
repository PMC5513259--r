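# Species trait tables -> site-level community-weighted means (CWM) and
# derived stoichiometric / per-area traits. Units: n_mass, p_mass, c_mass
# in mg g-1 (N% = g per 100 g is numerically n_mass/10), sla in mm2 mg-1,
# delta13c in permil, n_area/p_area in g m-2.

#' Community-weighted mean of one trait
#'
#' `CWM = sum(abundance_i * value_i)` over the species of a site. Species
#' with missing trait values are dropped and the remaining abundances
#' renormalised to sum to one; if every value is missing the CWM is `NA`.
#'
#' @param values Species trait values.
#' @param abundances Relative abundances, same length, summing to 1.
#' @return Scalar CWM (or `NA`).
#' @examples
#' cwm(c(2, 4), c(0.7, 0.3)) # 2.6
#' @export
cwm <- function(values, abundances) {
  if (length(values) != length(abundances)) {
    stop("cwm: values and abundances must have equal length", call. = FALSE)
  }
  if (abs(sum(abundances) - 1) > 1e-6) {
    stop("cwm: abundances must sum to 1", call. = FALSE)
  }
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  w <- abundances[ok] / sum(abundances[ok])
  sum(w * values[ok])
}

#' Derive stoichiometric and per-area traits
#'
#' Adds `cn = c_mass / n_mass` (g/g), `n_area = n_mass / sla` and
#' `p_area = p_mass / sla` (mg g-1 divided by mm2 mg-1 is g m-2 after
#' unit cancellation). Already-provided per-area values take precedence;
#' a warning is raised when a provided value disagrees with the derived
#' one by more than 5%.
#'
#' @param record Data frame of species trait records (columns `n_mass`,
#'   `p_mass`, `c_mass`, `sla`; optional `n_area`, `p_area`).
#' @return `record` with `cn`, `n_area`, `p_area` columns filled.
#' @export
derive_stoichiometry <- function(record) {
  record$cn <- ifelse(!is.na(record$n_mass) & record$n_mass > 0,
                      record$c_mass / record$n_mass, NA_real_)
  for (el in c("n", "p")) {
    mass <- record[[paste0(el, "_mass")]]
    area_col <- paste0(el, "_area")
    derived <- ifelse(!is.na(record$sla) & record$sla > 0, mass / record$sla, NA_real_)
    provided <- record[[area_col]] %||% rep(NA_real_, nrow(record))
    conflict <- !is.na(provided) & !is.na(derived) &
      abs(provided - derived) > 0.05 * abs(derived)
    if (any(conflict)) {
      warning(sprintf("%s: %d provided value(s) differ from SLA-derived by >5%%; keeping provided",
                      area_col, sum(conflict)), call. = FALSE)
    }
    record[[area_col]] <- ifelse(is.na(provided), derived, provided)
  }
  record
}

#' Site-level trait aggregation, weighted or unweighted
#'
#' Aggregates the species records of one site to a community trait
#' vector, either abundance-weighted (CWM, the default) or as a simple
#' species mean (used to gauge the sensitivity of trait-capacity
#' relationships to abundance information).
#'
#' @param records Species trait records of one site (needs `abundance`
#'   plus trait columns).
#' @param weighting `"abundance"` or `"unweighted"`.
#' @param traits Trait columns to aggregate.
#' @return Named list of community trait values.
#' @export
site_species_mean <- function(records, weighting = c("abundance", "unweighted"),
                              traits = c("n_mass", "p_mass", "c_mass", "sla",
                                         "delta13c", "cn", "n_area", "p_area")) {
  weighting <- match.arg(weighting)
  if (nrow(records) < 1L) stop("site_species_mean: no species", call. = FALSE)
  traits <- intersect(traits, names(records))
  out <- lapply(traits, function(tr) {
    v <- records[[tr]]
    if (weighting == "abundance") cwm(v, records$abundance)
    else if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(out) <- traits
  out
}
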