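#' Slurry incubation scenario
#'
#' The stated world for a simulated sediment-slurry incubation: true
#' pathway rates plus the tracer additions and volumes of the emulated
#' cruise design (Experiment 1: 15NH4+ 200 and 14NO2- 100 umol l^-1 with
#' ATU; Experiment 2: 15NO3- 200 umol l^-1; ~160 cm^3 sediment slurried
#' with 200 ml degassed bottom water; 5-7 subsamples over 26-28 h).
#'
#' @param true_D,true_A True denitrification and anammox N2 production in
#'   nmol N2 cm^-3 d^-1 (defaults 68 and 5, i.e. 136 and 10 nmol N
#'   cm^-3 d^-1 — the shallow-station surface layer of the emulated
#'   transect).
#' @param added_15nh4,added_14no2,added_15no3 Tracer/amendment
#'   concentrations in the slurry liquid, umol l^-1.
#' @param ambient_14nh4 Unlabelled ammonium in the slurry liquid,
#'   umol l^-1 (default 10, a typical pore-water scale; the bottom water
#'   of the emulated region holds < 0.1).
#' @param porewater_14no3,bottomwater_14no3 Dissolved unlabelled nitrate
#'   in pore water and added bottom water, umol l^-1.
#' @param intracellular_14no3 Intracellularly stored nitrate released into
#'   the slurry at t = 0, nmol (cm^3 sediment)^-1 (default 95,
#'   the scale inferred for surface layers of the emulated margin).
#' @param n_timepoints Number of subsamples (>= 5).
#' @param duration_h Incubation length in hours.
#' @param noise_sd_ratio Relative (multiplicative Gaussian) noise on the
#'   isotope ratios, reflecting IRMS error structure (default 0.02).
#' @param seed Integer RNG seed; must be given explicitly.
#' @param volume_sediment_cm3,volume_water_ml Slurry volumes.
#' @param porosity Porosity for the pore-water volume.
#' @param n28_umol_l 28N2 reference concentration, umol l^-1 (default 500,
#'   near air saturation at the incubation temperatures).
#' @param station_id,layer_top_cm,layer_bottom_cm Labels.
#' @return A list of class `slurry_scenario`.
#' @export
slurry_scenario <- function(true_D = 68, true_A = 5,
                            added_15nh4 = 200, added_14no2 = 100,
                            added_15no3 = 200, ambient_14nh4 = 10,
                            porewater_14no3 = 10, bottomwater_14no3 = 22,
                            intracellular_14no3 = 95,
                            n_timepoints = 6, duration_h = 26,
                            noise_sd_ratio = 0.02, seed,
                            volume_sediment_cm3 = 160,
                            volume_water_ml = 200, porosity = 0.8,
                            n28_umol_l = 500,
                            station_id = "S1", layer_top_cm = 0,
                            layer_bottom_cm = 2) {
  if (missing(seed)) stop("seed must be set explicitly")
  stopifnot(true_D >= 0, true_A >= 0, added_15nh4 >= 0, added_14no2 >= 0,
            added_15no3 >= 0, ambient_14nh4 >= 0, porewater_14no3 >= 0,
            bottomwater_14no3 >= 0, intracellular_14no3 >= 0,
            n_timepoints >= 5, duration_h > 0, noise_sd_ratio >= 0,
            volume_sediment_cm3 > 0, volume_water_ml > 0,
            porosity > 0, porosity < 1, n28_umol_l > 0)
  structure(as.list(environment()), class = "slurry_scenario")
}

#' Intact-core incubation scenario
#'
#' The stated world for a simulated sealed intact-core incubation: 15NO3-
#' added to 50 umol l^-1 in the constantly stirred overlying water, five
#' time points over 15 h. The simulator is well-mixed with a single
#' effective labelling fraction in the NOx reduction zone — it exists to
#' test the pairing algebra, not sediment diffusion physics. Truth is
#' parameterised as D14/D15 (denitrification fuelled by unlabelled and
#' labelled nitrate, N2-equivalent units) plus anammox A; the reduction
#' zone labelling is `f = D15 / (D14 + D15)`.
#'
#' @param true_D14,true_D15,true_A True rates in umol N2 m^-2 d^-1
#'   (defaults 56/125/14: total ~0.39 mmol N m^-2 d^-1 at anammox
#'   fraction ~0.07, the shallow end of the emulated transect, with
#'   f ~ 50/(50 + 22)).
#' @param overlying_15no3 15NO3- in the overlying water, umol l^-1.
#' @param n_timepoints Number of time points (default 5).
#' @param duration_h Incubation length (default 15 h; with the default 5
#'   time points sampling is at 0, 2, 6, 10, 15 h).
#' @param noise_sd_ratio Relative Gaussian noise on isotope ratios.
#' @param n_replicates Replicate cores sacrificed per time point (default
#'   3, the emulated cruise design); their ratios are pooled (averaged)
#'   before slope fitting, the default replicate treatment.
#' @param seed Integer RNG seed; required.
#' @param water_height_m Overlying water height (default 0.125 m).
#' @param n28_umol_l 28N2 reference concentration.
#' @param station_id Label.
#' @return A list of class `core_scenario`.
#' @export
core_scenario <- function(true_D14 = 56, true_D15 = 125, true_A = 14,
                          overlying_15no3 = 50, n_timepoints = 5,
                          duration_h = 15, noise_sd_ratio = 0.02,
                          n_replicates = 3, seed,
                          water_height_m = 0.125, n28_umol_l = 500,
                          station_id = "S1") {
  if (missing(seed)) stop("seed must be set explicitly")
  stopifnot(true_D14 >= 0, true_D15 >= 0, true_A >= 0,
            overlying_15no3 > 0, n_timepoints >= 4, duration_h > 0,
            noise_sd_ratio >= 0, n_replicates >= 1,
            water_height_m > 0, n28_umol_l > 0)
  structure(as.list(environment()), class = "core_scenario")
}

# shared tail: build ratio series from cumulative excess and apply noise
ratio_series <- function(times, slope29, slope30, n28, noise, air) {
  r29 <- air$r29 + slope29 * times / n28
  r30 <- air$r30 + slope30 * times / n28
  if (noise > 0) {
    r29 <- r29 * (1 + stats::rnorm(length(times), 0, noise))
    r30 <- r30 * (1 + stats::rnorm(length(times), 0, noise))
  }
  list(r29 = pmax(r29, .Machine$double.xmin),
       r30 = pmax(r30, .Machine$double.xmin))
}

#' Simulate slurry Experiment 1 (15NH4+ + 14NO2- + ATU)
#'
#' Anammox pairs one ammonium-derived and one nitrite-derived N atom, so
#' with ammonium labelling `F_NH4 = 15NH4 / (15NH4 + 14NH4)` it produces
#' 29N2 at `true_A * F_NH4` and no 30N2; denitrification of the unlabelled
#' NOx pool adds nothing to either labelled channel. Production is
#' zero-order (linear accumulation; the large tracer amendments are not
#' depleted over the incubation). Cumulative excess is mapped to isotope
#' ratios on the air baseline and multiplicative Gaussian noise is applied
#' per the scenario seed.
#'
#' @param scn A [slurry_scenario()].
#' @return An [incubation_series()] with attribute `truth` (list with
#'   `f_nh4`, `true_A_n2`, `true_A_natoms`, per-channel slopes).
#' @export
simulate_slurry_ex1 <- function(scn) {
  stopifnot(inherits(scn, "slurry_scenario"))
  set.seed(scn$seed)
  f_nh4 <- scn$added_15nh4 / (scn$added_15nh4 + scn$ambient_14nh4)
  v_w <- scn$volume_water_ml / 1000 +
    scn$porosity * scn$volume_sediment_cm3 / 1000
  # inverse of the slurry unit bridge, in N2 units
  to_slope <- scn$volume_sediment_cm3 / (24 * 1e3 * v_w)
  slope29 <- scn$true_A * f_nh4 * to_slope
  times <- seq(0, scn$duration_h, length.out = scn$n_timepoints)
  air <- air_n2_ratios()
  rr <- ratio_series(times, slope29, 0, scn$n28_umol_l,
                     scn$noise_sd_ratio, air)
  s <- incubation_series(
    sample_id = sprintf("%s_ex1_%g-%g", scn$station_id,
                        scn$layer_top_cm, scn$layer_bottom_cm),
    experiment = "slurry_ex1", station_id = scn$station_id,
    time_h = times, r29 = rr$r29, r30 = rr$r30,
    n28_umol_l = scn$n28_umol_l,
    layer_top_cm = scn$layer_top_cm, layer_bottom_cm = scn$layer_bottom_cm,
    volume_sediment_cm3 = scn$volume_sediment_cm3,
    volume_water_ml = scn$volume_water_ml)
  attr(s, "truth") <- list(f_nh4 = f_nh4,
                           true_A_n2 = scn$true_A,
                           true_A_natoms = 2 * scn$true_A,
                           slope29 = slope29, slope30 = 0,
                           aqueous_volume_l = v_w)
  s
}

#' Simulate slurry Experiment 2 (15NO3- with intracellular 14NO3- release)
#'
#' The true nitrate labelling fraction reflects tracer, dissolved
#' unlabelled nitrate (bottom water + pore water, volume-weighted) and the
#' intracellular store released instantaneously when the slurry is mixed
#' at t = 0:
#' `F_true = 15NO3 / (15NO3 + 14NO3_dissolved + 14NO3_released)`.
#' Denitrification produces 30N2 at `D F^2` and 29N2 at `2 F (1-F) D`;
#' anammox adds `A F` to the 29N2 channel. The nominal fraction computed
#' from dissolved pools alone (what an analyst would assume without
#' knowing about the store) is recorded in the truth attribute.
#'
#' @param scn A [slurry_scenario()].
#' @return An [incubation_series()] with attribute `truth` (`f_nominal`,
#'   `f_true`, `conc15_no3`, `excess_14no3_percm3`, true rates, slopes).
#' @export
simulate_slurry_ex2 <- function(scn) {
  stopifnot(inherits(scn, "slurry_scenario"))
  set.seed(scn$seed + 1L)
  v_bw <- scn$volume_water_ml / 1000
  v_pw <- scn$porosity * scn$volume_sediment_cm3 / 1000
  v_w <- v_bw + v_pw
  dissolved14 <- (scn$bottomwater_14no3 * v_bw +
                    scn$porewater_14no3 * v_pw) / v_w
  released_aq <- scn$intracellular_14no3 * scn$volume_sediment_cm3 /
    v_w / 1000                      # nmol cm^-3 sed -> umol l^-1 aqueous
  conc15 <- scn$added_15no3
  f_nom <- conc15 / (conc15 + dissolved14)
  f_true <- conc15 / (conc15 + dissolved14 + released_aq)
  p30 <- scn$true_D * f_true^2
  p29 <- 2 * f_true * (1 - f_true) * scn$true_D + scn$true_A * f_true
  to_slope <- scn$volume_sediment_cm3 / (24 * 1e3 * v_w)
  times <- seq(0, scn$duration_h, length.out = scn$n_timepoints)
  air <- air_n2_ratios()
  rr <- ratio_series(times, p29 * to_slope, p30 * to_slope,
                     scn$n28_umol_l, scn$noise_sd_ratio, air)
  s <- incubation_series(
    sample_id = sprintf("%s_ex2_%g-%g", scn$station_id,
                        scn$layer_top_cm, scn$layer_bottom_cm),
    experiment = "slurry_ex2", station_id = scn$station_id,
    time_h = times, r29 = rr$r29, r30 = rr$r30,
    n28_umol_l = scn$n28_umol_l,
    layer_top_cm = scn$layer_top_cm, layer_bottom_cm = scn$layer_bottom_cm,
    volume_sediment_cm3 = scn$volume_sediment_cm3,
    volume_water_ml = scn$volume_water_ml)
  attr(s, "truth") <- list(
    f_nominal = f_nom, f_true = f_true, conc15_no3 = conc15,
    dissolved_14no3 = dissolved14, released_14no3_aq = released_aq,
    excess_14no3_percm3 = scn$intracellular_14no3,
    true_D_n2 = scn$true_D, true_A_n2 = scn$true_A,
    true_D_natoms = 2 * scn$true_D, true_A_natoms = 2 * scn$true_A,
    slope29 = p29 * to_slope, slope30 = p30 * to_slope,
    aqueous_volume_l = v_w)
  s
}

#' Simulate an intact-core incubation (15NO3- in overlying water)
#'
#' Well-mixed forward model with a single effective labelling fraction
#' `f = D15 / (D14 + D15)` in the NOx reduction zone: 30N2 is produced at
#' `(D14 + D15) f^2`, 29N2 at `2 f (1-f) (D14 + D15) + A f` (anammox pairs
#' one labelled NOx atom with unlabelled ammonium). Areal rates are mapped
#' to overlying-water concentration slopes through the water-column
#' height, then to isotope ratios with multiplicative noise.
#'
#' @param scn A [core_scenario()].
#' @return An [incubation_series()] with attribute `truth` (`f_label`,
#'   `ra`, `p29_areal`, `p30_areal`, `total_n2`, `nloss_natoms`).
#' @export
simulate_core <- function(scn) {
  stopifnot(inherits(scn, "core_scenario"))
  set.seed(scn$seed + 2L)
  D <- scn$true_D14 + scn$true_D15
  if (D == 0 && scn$true_A > 0)
    stop("core scenario with anammox needs true_D15 > 0 to define the ",
         "reduction-zone labelling")
  f <- if (D > 0) scn$true_D15 / D else NA_real_
  if (D > 0 && f <= 0)
    stop("core scenario needs true_D15 > 0 (some labelled denitrification)")
  p30 <- if (D > 0) D * f^2 else 0
  p29 <- if (D > 0) 2 * f * (1 - f) * D + scn$true_A * f else 0
  to_slope <- 1 / (1000 * scn$water_height_m * 24)
  times <- if (scn$n_timepoints == 5L) c(0, 2, 6, 10, 15) / 15 *
    scn$duration_h else seq(0, scn$duration_h,
                            length.out = scn$n_timepoints)
  air <- air_n2_ratios()
  # n_replicates cores are sacrificed per time point; pool their ratios
  reps <- lapply(seq_len(scn$n_replicates), function(i)
    ratio_series(times, p29 * to_slope, p30 * to_slope,
                 scn$n28_umol_l, scn$noise_sd_ratio, air))
  rr <- list(r29 = rowMeans(sapply(reps, `[[`, "r29")),
             r30 = rowMeans(sapply(reps, `[[`, "r30")))
  s <- incubation_series(
    sample_id = sprintf("%s_core", scn$station_id),
    experiment = "core", station_id = scn$station_id,
    time_h = times, r29 = rr$r29, r30 = rr$r30,
    n28_umol_l = scn$n28_umol_l)
  attr(s, "truth") <- list(
    f_label = f,
    ra = if (scn$true_A + D > 0) scn$true_A / (scn$true_A + D) else NA_real_,
    p29_areal = p29, p30_areal = p30,
    total_n2 = D + scn$true_A,
    nloss_natoms = 2 * (D + scn$true_A),
    slope29 = p29 * to_slope, slope30 = p30 * to_slope,
    water_height_m = scn$water_height_m)
  s
}
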