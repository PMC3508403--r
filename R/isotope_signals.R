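#' Excess 29N2 and 30N2 relative to air
#'
#' Converts raw isotope ratios to excess concentrations above the
#' air-equilibrium baseline: `excess29_i = (r29_i - air_r29) * n28_i`, and
#' analogously for the 30N2 channel. Excess is what the tracer experiments
#' produce on top of the dissolved atmospheric N2 background; it may be
#' slightly negative under measurement noise.
#'
#' @param series An [incubation_series()].
#' @param air_r29,air_r30 Air-equilibrium mole ratios; default from
#'   [air_n2_ratios()]. Must lie in (0, 0.1).
#' @return A data frame of class `excess_series` with columns `time_h`,
#'   `excess29`, `excess30` (umol N2 l^-1).
#' @export
excess_relative_to_air <- function(series,
                                   air_r29 = air_n2_ratios()$r29,
                                   air_r30 = air_n2_ratios()$r30) {
  stopifnot(inherits(series, "incubation_series"))
  for (a in c(air_r29, air_r30))
    if (!is.finite(a) || a <= 0 || a >= 0.1)
      stop("air ratios must be finite and in (0, 0.1)")
  n28 <- rep_len(series$n28_umol_l, length(series$time_h))
  bad <- which(!is.finite(series$r29) | !is.finite(series$r30) |
                 !is.finite(n28))
  if (length(bad))
    stop("non-finite ratio or concentration at index ",
         paste(bad, collapse = ", "))
  out <- data.frame(time_h = series$time_h,
                    excess29 = (series$r29 - air_r29) * n28,
                    excess30 = (series$r30 - air_r30) * n28)
  class(out) <- c("excess_series", class(out))
  out
}

#' Production slope with significance and delay filters
#'
#' Ordinary least-squares slope of concentration against time with a
#' two-sided t-test on the slope (df = n - 2). Only production with a
#' significant linear increase over time and without an initial delay is
#' accepted for rate calculations. The delay screen refits the series
#' without its first point and flags a delay when the first point's
#' externally studentized residual exceeds `delay_rstudent` or the two
#' slopes differ by more than `delay_slope_se` pooled standard errors.
#'
#' Replicate subsamples at one time point enter as independent
#' observations; the regression is unweighted.
#'
#' @param time_h Sampling times (h), at least 4 values with nonzero spread.
#' @param conc Concentrations (umol l^-1), same length.
#' @param alpha Significance level for the slope t-test (default 0.05).
#' @param delay_rstudent Threshold on the first point's externally
#'   studentized residual (default 2.0).
#' @param delay_slope_se Threshold, in pooled standard errors, on the
#'   full-vs-reduced slope difference (default 2.0).
#' @return A list of class `slope_estimate`: `slope`, `stderr`, `p_value`,
#'   `intercept`, `n_points`, `delay_detected`, `accepted`. `accepted` is
#'   true iff `p_value < alpha` and no delay was detected.
#' @export
production_slope <- function(time_h, conc, alpha = 0.05,
                             delay_rstudent = 2.0, delay_slope_se = 2.0) {
  n <- length(time_h)
  if (n < 4L)
    stop("insufficient data: at least 4 points required, got ", n)
  stopifnot(length(conc) == n, is.finite(alpha), alpha > 0, alpha < 1)
  if (!all(is.finite(time_h)) || !all(is.finite(conc)))
    stop("non-finite time or concentration value")
  if (stats::var(time_h) == 0)
    stop("degenerate design: zero variance in time")
  ord <- order(time_h)
  t_h <- time_h[ord]; y <- conc[ord]

  # a constant series carries no production signal; lm residuals there are
  # pure floating-point noise and the t-test is meaningless
  if (diff(range(y)) <= 1e-12 * max(abs(y), 1e-300))
    return(structure(
      list(slope = 0, stderr = 0, p_value = 1, intercept = y[1L],
           n_points = n, delay_detected = FALSE, accepted = FALSE),
      class = "slope_estimate"))

  fit <- stats::lm(y ~ t_h)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["t_h", "Estimate"]
  se <- sm["t_h", "Std. Error"]
  p <- sm["t_h", "Pr(>|t|)"]
  # a flat, noise-free channel gives 0/0 in the t statistic: no production
  if (!is.finite(p)) p <- 1

  # delay screen: compare against the fit without the earliest point.
  # An (essentially) perfect linear fit carries no delay information —
  # studentized residuals there are pure floating-point noise.
  delay <- FALSE
  sigma <- suppressWarnings(summary(fit))$sigma
  perfect <- !is.finite(sigma) || sigma <= 1e-8 * max(diff(range(y)), 1e-300)
  if (!perfect) {
    rs1 <- suppressWarnings(stats::rstudent(fit)[1L])
    if (isTRUE(is.finite(rs1)) && abs(rs1) > delay_rstudent) delay <- TRUE
    if (!delay && stats::var(t_h[-1L]) > 0) {
      fit2 <- stats::lm(y[-1L] ~ t_h[-1L])
      sm2 <- suppressWarnings(summary(fit2))$coefficients
      pooled <- sqrt(se^2 + sm2[2L, "Std. Error"]^2)
      dslope <- abs(slope - sm2[2L, "Estimate"])
      if (is.finite(pooled) && pooled > 0 &&
          dslope > delay_slope_se * pooled &&
          dslope > 1e-8 * max(abs(slope), abs(sm2[2L, "Estimate"])))
        delay <- TRUE
    }
  }

  structure(
    list(slope = unname(slope), stderr = unname(se), p_value = unname(p),
         intercept = unname(sm["(Intercept)", "Estimate"]),
         n_points = n, delay_detected = delay,
         accepted = (p < alpha) && !delay),
    class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf(
    "<slope_estimate> %.4g +/- %.3g umol l^-1 h^-1 (p = %.3g, n = %d)%s\n",
    x$slope, x$stderr, x$p_value, x$n_points,
    if (x$accepted) ", accepted"
    else if (x$delay_detected) ", rejected (delay)"
    else ", rejected (not significant)"))
  invisible(x)
}

#' Slurry unit bridge: aqueous slope to volumetric sediment rate
#'
#' Converts an aqueous N2 isotopologue production slope (umol N2 l^-1 h^-1
#' in the slurry liquid phase) to a sediment-volumetric rate in
#' nmol N cm^-3 d^-1:
#' `rate = slope * 24 * 2 * (V_water_l / V_sediment_cm3) * 1e3`.
#' The factor 24 converts hours to days, the factor 2 converts N2
#' molecules to N atoms (the unit the rate figures report), and the volume
#' ratio maps the dissolved pool back onto the sediment that produced it.
#' The aqueous volume is added water plus pore water ([aqueous_volume_l()]).
#'
#' @param slope Aqueous production slope, umol N2 l^-1 h^-1.
#' @param series The slurry `incubation_series` carrying the volumes.
#' @param porosity Porosity for the pore-water volume estimate.
#' @return Rate in nmol N cm^-3 d^-1.
#' @export
volumetric_rate <- function(slope, series, porosity = 0.8) {
  stopifnot(inherits(series, "incubation_series"), is.finite(slope))
  if (series$experiment == "core")
    stop("volumetric_rate applies to slurry incubations")
  if (!is.finite(series$volume_sediment_cm3) ||
      !is.finite(series$volume_water_ml))
    stop("configuration error: slurry volumes are missing")
  v_w <- aqueous_volume_l(series, porosity)
  slope * 24 * 2 * (v_w / series$volume_sediment_cm3) * 1e3
}

#' Core unit bridge: overlying-water slope to areal rate
#'
#' Converts an N2 isotopologue concentration slope measured in a sealed
#' intact-core incubation (umol N2 l^-1 h^-1 in the water phase) to an
#' areal production rate in umol N2 m^-2 d^-1, using the height of the
#' overlying water column:
#' `rate = slope * 1000 * water_height_m * 24`
#' (umol l^-1 = mmol m^-3; x height gives mmol m^-2 h^-1; x1000 to umol
#' and x24 to per day). No N2-to-N doubling here: the pairing algebra of
#' [ript_nloss()] runs in N2 units and doubles on output.
#'
#' @param slope Concentration slope, umol N2 l^-1 h^-1.
#' @param water_height_m Height of the overlying water column in metres
#'   (default 0.125, i.e. 12.5 cm).
#' @return Areal rate in umol N2 m^-2 d^-1.
#' @export
areal_rate_core <- function(slope, water_height_m = 0.125) {
  stopifnot(is.finite(slope), is.finite(water_height_m),
            water_height_m > 0)
  slope * 1000 * water_height_m * 24
}
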