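#' Nb/Ne ratio from two life-history traits
#'
#' Predicts the ratio of the effective number of breeders per reproductive
#' cycle to the per-generation effective size from adult lifespan and age at
#' maturity: 0.485 + 0.758 * log10(AL / alpha). The base-10 logarithm is the
#' published regression scale.
#'
#' @param AL adult lifespan in years (>= alpha).
#' @param alpha age at maturity in years (> 0).
#' @return the Nb/Ne ratio.
#' @export
nb_ne_ratio <- function(AL, alpha) {
  if (any(alpha <= 0) || any(AL <= 0)) stop("AL and alpha must be positive")
  if (any(AL < alpha)) stop("AL must be at least alpha")
  0.485 + 0.758 * log10(AL / alpha)
}

#' Life-history record for a monitored species
#'
#' @param adult_lifespan_years adult lifespan AL (default 23, a long-lived
#'   iteroparous percichthyid).
#' @param age_at_maturity_years age at maturity alpha (default 3).
#' @param generation_time_years metadata only (default 7).
#' @return list of class `life_history` with the derived `nb_ne_ratio`.
#' @export
life_history <- function(adult_lifespan_years = 23, age_at_maturity_years = 3,
                         generation_time_years = 7) {
  structure(list(adult_lifespan_years = adult_lifespan_years,
                 age_at_maturity_years = age_at_maturity_years,
                 generation_time_years = generation_time_years,
                 nb_ne_ratio = nb_ne_ratio(adult_lifespan_years,
                                           age_at_maturity_years)),
            class = "life_history")
}

#' Adjust a raw single-cohort LD estimate for iteroparity
#'
#' A raw LD-based estimate from a single cohort mixes the effective number of
#' breeders in one cycle with the per-generation effective size. The adjusted
#' number of breeders is nb_raw / (1.26 - 0.323 * ratio), and the adjusted
#' per-generation effective size divides that again by the ratio.
#'
#' @param nb_raw raw LD-based estimate (may be `Inf`, which propagates).
#' @param ratio Nb/Ne ratio (see [nb_ne_ratio()]).
#' @return list of class `adjusted_estimate`: `nb_raw`, `divisor`, `nb_adj`,
#'   `ne_adj`.
#' @export
adjust_nb <- function(nb_raw, ratio) {
  if (any(nb_raw <= 0)) stop("nb_raw must be positive")
  divisor <- 1.26 - 0.323 * ratio
  if (any(divisor <= 0))
    stop("ratio outside the adjustment's validity (divisor <= 0)")
  structure(list(nb_raw = nb_raw, divisor = divisor,
                 nb_adj = nb_raw / divisor, ne_adj = nb_raw / divisor / ratio),
            class = "adjusted_estimate")
}

#' Round half up to the nearest integer (presentation only)
#' @param x numeric.
#' @return integer-valued numeric; infinite values pass through.
#' @export
round_half_up <- function(x) ifelse(is.finite(x), floor(x + 0.5), x)

#' Fraction of breeders that must be outbred migrants
#'
#' To lower a site's effective inbreeding from `Fe_site` to `Fe_target`, the
#' required proportion of breeders derived from outbred migrants is
#' 1 - sqrt(Fe_target / Fe_site), floored at 0 when the site is already at or
#' below target.
#'
#' @param Fe_site current effective inbreeding of the site (> 0).
#' @param Fe_target target effective inbreeding (default 0.1, half the level
#'   above which severe inbreeding depression is usually observed).
#' @return migrant fraction in [0, 1).
#' @export
migrant_fraction <- function(Fe_site, Fe_target = 0.1) {
  if (any(Fe_site <= 0)) stop("Fe_site must be positive")
  if (any(Fe_target < 0)) stop("Fe_target must be non-negative")
  pmax(0, 1 - sqrt(Fe_target / Fe_site))
}

#' Number of effective migrants needed
#'
#' Given the required migrant fraction among breeders and the site's number
#' of breeders, the number of effective migrants is
#' f * Nb / (1 - f).
#'
#' @param f_migrant migrant fraction in [0, 1).
#' @param Nb_site number of breeders at the site (>= 0).
#' @return number of effective migrants.
#' @export
migrants_needed <- function(f_migrant, Nb_site) {
  if (any(f_migrant < 0 | f_migrant >= 1))
    stop("f_migrant must lie in [0, 1)")
  if (any(Nb_site < 0)) stop("Nb_site must be non-negative")
  f_migrant * Nb_site / (1 - f_migrant)
}

#' Build a per-site genetic-rescue plan
#'
#' @param sites character vector of site labels.
#' @param Fe_site per-site effective inbreeding (see
#'   [effective_inbreeding()]).
#' @param Nb_site per-site (adjusted) number of breeders.
#' @param Fe_target target effective inbreeding.
#' @return data.frame: site, Fe_site, Fe_target, f_migrant, Nb_site, Nm.
#' @export
rescue_plan <- function(sites, Fe_site, Nb_site, Fe_target = 0.1) {
  f <- migrant_fraction(Fe_site, Fe_target)
  data.frame(site = sites, Fe_site = Fe_site, Fe_target = Fe_target,
             f_migrant = f, Nb_site = Nb_site,
             Nm = migrants_needed(f, Nb_site))
}
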