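#' Water-column nitrogen deficit N*
#'
#' Fixed-nitrogen deficit relative to Redfield stoichiometry:
#' `N* = [NH4+] + [NO2-] + [NO3-] - 16 [PO4^3-] + 2.9` (all umol l^-1;
#' the +2.9 offset, in umol N l^-1, centres the global mean). Strongly
#' negative values mark waters where fixed N has been removed in excess of
#' phosphorus, the signature of denitrification/anammox in an oxygen
#' minimum zone.
#'
#' @param nh4,no2,no3,po4 Nutrient concentrations in umol l^-1; vectors
#'   are recycled to a common length. All four are required; a missing or
#'   non-finite value raises an error naming the field.
#' @return N* in umol N l^-1.
#' @export
nstar <- function(nh4, no2, no3, po4) {
  args <- list(nh4 = nh4, no2 = no2, no3 = no3, po4 = po4)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (is.null(v) || length(v) == 0L || any(!is.finite(v)))
      stop("missing or non-finite required field: ", nm)
    if (any(v < 0)) stop("negative concentration in field: ", nm)
  }
  nh4 + no2 + no3 - 16 * po4 + 2.9
}

#' N* profile from a nutrient table
#'
#' Applies [nstar()] row-wise to a profile data frame with columns
#' `depth_m, nh4, no2, no3, po4`; rows with any missing nutrient get `NA`
#' and are counted in a message.
#'
#' @param profile Data frame of nutrient samples.
#' @return The input with an added `nstar` column.
#' @export
nstar_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("depth_m", "nh4", "no2", "no3", "po4") %in%
                  names(profile)))
  ok <- stats::complete.cases(profile[, c("nh4", "no2", "no3", "po4")])
  out <- profile
  out$nstar <- NA_real_
  if (any(ok))
    out$nstar[ok] <- nstar(profile$nh4[ok], profile$no2[ok],
                           profile$no3[ok], profile$po4[ok])
  if (any(!ok))
    message(sum(!ok), " row(s) with incomplete nutrients set to NA")
  out
}

#' Basin-scale annual nitrogen loss
#'
#' Scales an areal N-loss rate to an annual basin-wide mass flux:
#' `Tg N yr^-1 = rate * 1e-3 (mol) * molar_mass * days * area * 1e-12`.
#'
#' @param areal_rate Areal rate in mmol N m^-2 d^-1 (> 0 domain, 0 allowed).
#' @param area_m2 Seafloor or basin area in m^2. Two relevant areas for the
#'   emulated study region: 1.15e12 m^2 of basin seafloor under
#'   oxygen-deficient (< 22 umol O2 l^-1) water, and 4.93e12 m^2 for the
#'   basin north of 6 N.
#' @param days_per_year Days per year (default 365; no leap handling).
#' @param molar_mass Molar mass of N in g mol^-1 (default 14.007).
#' @return Annual loss in Tg N yr^-1.
#' @export
annual_basin_nloss <- function(areal_rate, area_m2, days_per_year = 365,
                               molar_mass = 14.007) {
  stopifnot(is.finite(areal_rate), areal_rate >= 0,
            is.finite(area_m2), area_m2 > 0,
            is.finite(days_per_year), days_per_year > 0,
            is.finite(molar_mass), molar_mass > 0)
  areal_rate * 1e-3 * molar_mass * days_per_year * area_m2 * 1e-12
}
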