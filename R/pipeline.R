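#' Run configuration
#'
#' Validated bundle of the tunable parameters of the inference chain. All
#' defaults mirror the emulated cruise design: slope-significance alpha
#' 0.05, 2 cm integration depth (the nitrate penetration depth), porosity
#' 0.8, 12.5 cm overlying water in core incubations, atmospheric 15N atom
#' fraction 0.0036765 for the air baseline, and the two extrapolation
#' areas (1.15e12 m^2 of oxygen-deficient seafloor; 4.93e12 m^2 of basin
#' north of 6 N).
#'
#' @param alpha Significance level for slope acceptance.
#' @param porosity Sediment porosity (pore-water volume estimate).
#' @param bulk_density Dry bulk density, g cm^-3 (cell-specific rates
#'   scale with it).
#' @param integration_depth_cm Depth for areal integration of slurry rates.
#' @param air_atom15 Atmospheric 15N atom fraction.
#' @param water_height_m Overlying water height in core incubations.
#' @param area_omz_benthic_m2,area_basin_north6N_m2 Extrapolation areas.
#' @param days_per_year,molar_mass_n Budget constants.
#' @param seed Integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, porosity = 0.8, bulk_density = 1.0,
                       integration_depth_cm = 2,
                       air_atom15 = 0.0036765, water_height_m = 0.125,
                       area_omz_benthic_m2 = 1.15e12,
                       area_basin_north6N_m2 = 4.93e12,
                       days_per_year = 365, molar_mass_n = 14.007,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, porosity > 0, porosity < 1,
            bulk_density > 0, integration_depth_cm > 0,
            air_atom15 > 0, air_atom15 < 0.5, water_height_m > 0,
            area_omz_benthic_m2 > 0, area_basin_north6N_m2 > 0,
            days_per_year > 0, molar_mass_n > 0)
  cfg <- as.list(environment())
  cfg$air <- air_n2_ratios(air_atom15)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(x), "air"))
    cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# slope estimates for both labelled channels of one series
channel_slopes <- function(series, config) {
  ex <- excess_relative_to_air(series, config$air$r29, config$air$r30)
  list(s29 = production_slope(ex$time_h, ex$excess29, config$alpha),
       s30 = production_slope(ex$time_h, ex$excess30, config$alpha))
}

slope_row <- function(series, channel, est) {
  data.frame(sample_id = series$sample_id, experiment = series$experiment,
             station_id = series$station_id,
             layer_top_cm = series$layer_top_cm,
             layer_bottom_cm = series$layer_bottom_cm,
             channel = channel,
             slope_umol_l_h = est$slope, stderr = est$stderr,
             p_value = est$p_value, n_points = est$n_points,
             delay_detected = est$delay_detected, accepted = est$accepted)
}

#' Slurry rates for one sediment layer
#'
#' Runs the full slurry inference for one station/layer: accepted channel
#' slopes are bridged to volumetric rates (nmol N cm^-3 d^-1), anammox is
#' taken from Experiment 1, the nitrate labelling fraction F* is inverted
#' under the constraint A(Ex1) = A(Ex2), denitrification follows from the
#' 30N2 channel at F*, and excess (intracellularly stored) 14NO3- from the
#' gap between F* and the nominal fraction. Channels rejected by the slope
#' filter propagate as `NA`, never as zero rates.
#'
#' @param ex1,ex2 `incubation_series` for Experiments 1 and 2 of the layer.
#' @param f_nh4 Nominal ammonium labelling fraction (Experiment 1).
#' @param f_no3_nominal Nominal nitrate labelling fraction from dissolved
#'   pools (Experiment 2).
#' @param conc15_no3 15NO3- concentration in the Experiment-2 slurry
#'   liquid, umol l^-1.
#' @param config A [run_config()].
#' @return One-row data frame: volumetric p29/p30, `A_ex1`, `D_ex2`,
#'   `A_ex2` (nmol N cm^-3 d^-1), `f_star`, `excess_no3_nmol_cm3`, and
#'   acceptance provenance.
#' @export
slurry_layer_rates <- function(ex1, ex2, f_nh4, f_no3_nominal,
                               conc15_no3, config = run_config()) {
  stopifnot(inherits(ex1, "incubation_series"),
            inherits(ex2, "incubation_series"),
            ex1$experiment == "slurry_ex1", ex2$experiment == "slurry_ex2")
  sl1 <- channel_slopes(ex1, config)
  sl2 <- channel_slopes(ex2, config)
  vol <- function(est, series)
    if (est$accepted) volumetric_rate(max(est$slope, 0), series,
                                      config$porosity) else NA_real_
  p29_ex1 <- vol(sl1$s29, ex1)
  p29_ex2 <- vol(sl2$s29, ex2)
  p30_ex2 <- vol(sl2$s30, ex2)

  a_ex1 <- if (!is.na(p29_ex1)) anammox_ex1(p29_ex1, f_nh4) else NA_real_
  f_star <- NA_real_; d_ex2 <- NA_real_; a_ex2 <- NA_real_
  excess <- NA_real_
  note <- character(0)
  if (!is.na(a_ex1) && !is.na(p29_ex2) && !is.na(p30_ex2)) {
    fs <- tryCatch(infer_fstar(p29_ex2, p30_ex2, a_ex1, f_no3_nominal),
                   error = function(e) e)
    if (inherits(fs, "error")) {
      note <- c(note, conditionMessage(fs))
    } else {
      f_star <- fs$value
      d_ex2 <- denit_ex2(p30_ex2, fs)
      a_ex2 <- suppressWarnings(anammox_ex2(p29_ex2, p30_ex2, fs))
      excess <- suppressWarnings(excess_nitrate(
        conc15_no3, fs, f_no3_nominal,
        slurry_to_sediment_factor(ex2, config$porosity)))
    }
  } else {
    note <- c(note, "rejected channel(s); inversion skipped")
  }
  data.frame(station_id = ex1$station_id,
             layer_top_cm = ex1$layer_top_cm,
             layer_bottom_cm = ex1$layer_bottom_cm,
             p29_ex1_nmolN_cm3_d = p29_ex1,
             p29_ex2_nmolN_cm3_d = p29_ex2,
             p30_ex2_nmolN_cm3_d = p30_ex2,
             A_ex1_nmolN_cm3_d = a_ex1,
             D_ex2_nmolN_cm3_d = d_ex2,
             A_ex2_nmolN_cm3_d = as.numeric(a_ex2),
             f_no3_nominal = f_no3_nominal,
             f_star = f_star,
             excess_no3_nmol_cm3 = excess,
             note = paste(note, collapse = "; "))
}

#' Simulate the full transect study
#'
#' Generates the complete stated world the analysis emulates: four
#' stations (360, 680, 970, 1430 m) with four slurry layers each
#' (0-2 ... 6-8 cm, Experiments 1 and 2) and one intact core per station.
#' True surface rates follow the printed transect pattern (surface
#' denitrification falling from 136 to 73 nmol N cm^-3 d^-1 with water
#' depth while anammox rises from 10 to 45; core totals 0.39-0.18 mmol N
#' m^-2 d^-1; surface intracellular nitrate stores 96-222 nmol cm^-3) and
#' decay with sediment depth so that deep layers often fail the
#' significance filter, as in the emulated cruise.
#'
#' @param seed Integer seed; scenario seeds are derived from it.
#' @param noise_sd_ratio Relative ratio noise (default 0.02).
#' @return A list with `slurry_ex1`, `slurry_ex2`, `cores` (lists of
#'   series), `tracers` (per-layer nominal fractions), and `truth`
#'   (per-station true parameter table).
#' @export
simulate_study <- function(seed = 1L, noise_sd_ratio = 0.02) {
  stations <- data.frame(
    station_id = c("10", "04", "16", "08"),
    depth_m = c(360, 680, 970, 1430),
    bottom_no3 = c(22, 28, 33, 39),
    porewater_no3 = c(10, 15, 20, 25),
    D_surf_n2 = c(68, 55, 45, 36.5),   # 136..73 nmol N cm^-3 d^-1
    A_surf_n2 = c(5, 10, 15, 22.5),    # 10..45 nmol N cm^-3 d^-1
    core_total_n2 = c(195, 260, 110, 90))  # umol N2 m^-2 d^-1
  layers <- data.frame(top = c(0, 2, 4, 6), bottom = c(2, 4, 6, 8),
                       d_mult = c(1, 0.35, 0.12, 0.03),
                       a_mult = c(1, 0.5, 0.25, 0.1))
  store <- matrix(c(96, 22, 12, 0,
                    111, 24, 3, 0,
                    222, 0, 0, 0,
                    112, 0, 0, 0), nrow = 4, byrow = TRUE)
  ex1 <- list(); ex2 <- list(); cores <- list(); tracers <- NULL
  k <- 0L
  for (i in seq_len(nrow(stations))) {
    st <- stations[i, ]
    for (j in seq_len(nrow(layers))) {
      k <- k + 1L
      scn <- slurry_scenario(
        true_D = st$D_surf_n2 * layers$d_mult[j],
        true_A = st$A_surf_n2 * layers$a_mult[j],
        bottomwater_14no3 = st$bottom_no3,
        porewater_14no3 = st$porewater_no3,
        intracellular_14no3 = store[i, j],
        noise_sd_ratio = noise_sd_ratio,
        seed = seed * 1000L + k * 10L,
        station_id = st$station_id,
        layer_top_cm = layers$top[j], layer_bottom_cm = layers$bottom[j])
      s1 <- simulate_slurry_ex1(scn)
      s2 <- simulate_slurry_ex2(scn)
      ex1[[s1$sample_id]] <- s1
      ex2[[s2$sample_id]] <- s2
      tr <- attr(s2, "truth")
      tracers <- rbind(tracers, data.frame(
        station_id = st$station_id, layer_top_cm = layers$top[j],
        layer_bottom_cm = layers$bottom[j],
        f_nh4 = attr(s1, "truth")$f_nh4,
        f_no3_nominal = tr$f_nominal,
        conc15_no3 = tr$conc15_no3))
    }
    ra <- st$A_surf_n2 / (st$A_surf_n2 + st$D_surf_n2)
    f <- 50 / (50 + st$bottom_no3)
    D_core <- (1 - ra) * st$core_total_n2
    cscn <- core_scenario(
      true_D14 = (1 - f) * D_core, true_D15 = f * D_core,
      true_A = ra * st$core_total_n2,
      noise_sd_ratio = noise_sd_ratio,
      seed = seed * 1000L + 900L + i,
      station_id = st$station_id)
    cores[[st$station_id]] <- simulate_core(cscn)
  }
  list(slurry_ex1 = ex1, slurry_ex2 = ex2, cores = cores,
       tracers = tracers, truth = stations)
}

#' Run the end-to-end inference pipeline
#'
#' Orchestrates the full chain on a set of incubation series: excess
#' computation, slope estimation with significance/delay filtering,
#' slurry pairing inversion, depth integration to areal fluxes with the
#' station-wise anammox fraction, and revised-IPT core N-loss using that
#' fraction. Emits per-stage tables with provenance (acceptance flags and
#' notes) and, optionally, writes them as CSV next to the resolved
#' configuration.
#'
#' @param study A list as returned by [simulate_study()]: elements
#'   `slurry_ex1`, `slurry_ex2`, `cores` (lists of series, matched by
#'   station and layer) and `tracers` (per-layer nominal fractions).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, `slopes.csv`,
#'   `slurry_rates.csv`, `integrated.csv`, `core_nloss.csv` and
#'   `config.txt` are written there.
#' @return A list of class `nloss_report`: `slopes`, `slurry_rates`,
#'   `integrated` (areal A/D, ra per station), `core_nloss`, `config`.
#' @export
run_pipeline <- function(study, config = run_config(), out_dir = NULL) {
  stopifnot(is.list(study),
            all(c("slurry_ex1", "slurry_ex2", "tracers") %in% names(study)))
  tracers <- study$tracers

  slopes <- NULL
  rates <- NULL
  for (s1 in study$slurry_ex1) {
    key <- tracers$station_id == s1$station_id &
      tracers$layer_top_cm == s1$layer_top_cm
    if (!any(key))
      stop("no tracer metadata for ", s1$sample_id)
    tr <- tracers[which(key)[1L], ]
    s2 <- Filter(function(s) s$station_id == s1$station_id &&
                   isTRUE(s$layer_top_cm == s1$layer_top_cm),
                 study$slurry_ex2)
    if (!length(s2))
      stop("no Experiment-2 series matching ", s1$sample_id)
    s2 <- s2[[1L]]
    cs1 <- channel_slopes(s1, config); cs2 <- channel_slopes(s2, config)
    slopes <- rbind(slopes,
                    slope_row(s1, "29N2", cs1$s29),
                    slope_row(s1, "30N2", cs1$s30),
                    slope_row(s2, "29N2", cs2$s29),
                    slope_row(s2, "30N2", cs2$s30))
    rates <- rbind(rates,
                   slurry_layer_rates(s1, s2, tr$f_nh4, tr$f_no3_nominal,
                                      tr$conc15_no3, config))
  }

  # station-wise depth integration and anammox fraction
  integrated <- NULL
  for (st in unique(rates$station_id)) {
    r <- rates[rates$station_id == st, ]
    lay <- data.frame(top_cm = r$layer_top_cm, bottom_cm = r$layer_bottom_cm)
    a_int <- depth_integrate(cbind(lay, rate = r$A_ex1_nmolN_cm3_d),
                             config$integration_depth_cm)
    d_int <- depth_integrate(cbind(lay, rate = r$D_ex2_nmolN_cm3_d),
                             config$integration_depth_cm)
    ra <- if (a_int + d_int > 0) anammox_fraction(a_int, d_int) else NA_real_
    integrated <- rbind(integrated, data.frame(
      station_id = st,
      anammox_mmolN_m2_d = a_int, denit_mmolN_m2_d = d_int,
      total_mmolN_m2_d = a_int + d_int, ra = ra))
  }

  # intact cores: rIPT with the slurry-derived station ra
  core_tab <- NULL
  for (s in study$cores) {
    cs <- channel_slopes(s, config)
    slopes <- rbind(slopes,
                    slope_row(s, "29N2", cs$s29),
                    slope_row(s, "30N2", cs$s30))
    ra <- integrated$ra[integrated$station_id == s$station_id]
    row <- data.frame(station_id = s$station_id,
                      p29_umolN2_m2_d = NA_real_,
                      p30_umolN2_m2_d = NA_real_, ra = NA_real_,
                      nloss_mmolN_m2_d = NA_real_,
                      denit_mmolN_m2_d = NA_real_,
                      anammox_mmolN_m2_d = NA_real_,
                      note = "")
    if (!length(ra) || is.na(ra)) {
      row$note <- "no slurry-derived ra for station"
    } else if (ra >= 1) {
      row$note <- "slurry ra = 1 (no accepted denitrification); rIPT undefined"
    } else if (!cs$s29$accepted || !cs$s30$accepted) {
      row$note <- "rejected channel(s); rIPT skipped"
    } else {
      p29 <- areal_rate_core(max(cs$s29$slope, 0), config$water_height_m)
      p30 <- areal_rate_core(max(cs$s30$slope, 0), config$water_height_m)
      nl <- ript_nloss(p29, p30, ra)
      row[, c("p29_umolN2_m2_d", "p30_umolN2_m2_d", "ra")] <-
        c(p29, p30, ra)
      row[, c("nloss_mmolN_m2_d", "denit_mmolN_m2_d",
              "anammox_mmolN_m2_d")] <-
        c(nl$nloss_total, nl$denit, nl$anammox) / 1000
    }
    core_tab <- rbind(core_tab, row)
  }

  n_acc <- sum(slopes$accepted); n_tot <- nrow(slopes)
  message("slope filter: ", n_acc, "/", n_tot, " channel series accepted (",
          n_tot - n_acc, " rejected)")

  report <- structure(list(slopes = slopes, slurry_rates = rates,
                           integrated = integrated, core_nloss = core_tab,
                           config = config),
                      class = "nloss_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to CSV
#'
#' @param report An `nloss_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "nloss_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("slopes", "slurry_rates", "integrated", "core_nloss"))
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  cfg <- report$config
  lines <- vapply(setdiff(names(cfg), "air"),
                  function(nm) sprintf("%s: %s", nm, format(cfg[[nm]])),
                  character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
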