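#' Construct an incubation time series
#'
#' Container for one incubation's N2 isotope-ratio time series together with
#' the tracer and volume metadata needed downstream. A series holds the raw
#' 29N2/28N2 and 30N2/28N2 mole ratios of each exetainer subsample; excess
#' concentrations and production slopes are derived from it, never stored.
#'
#' @param sample_id Character identifier for the incubation.
#' @param experiment One of `"slurry_ex1"` (15NH4+ + 14NO2- + ATU),
#'   `"slurry_ex2"` (15NO3-) or `"core"` (intact core, 15NO3- in the
#'   overlying water).
#' @param station_id Station label.
#' @param time_h Sampling times in hours, non-negative, strictly increasing,
#'   at least 4 points (5-7 subsamples for slurries, 5 for cores in the
#'   emulated cruise design).
#' @param r29,r30 29N2/28N2 and 30N2/28N2 mole ratios per time point,
#'   all > 0.
#' @param n28_umol_l 28N2 reference concentration in umol l^-1; either a
#'   single value (air saturation at incubation temperature; exetainer 28N2
#'   is effectively constant relative to the tracer excess) or one per time
#'   point.
#' @param layer_top_cm,layer_bottom_cm Sediment layer interval in cm for
#'   slurry incubations; `NA` for cores.
#' @param volume_sediment_cm3 Sediment volume in the slurry bag (cm^3);
#'   required for slurry experiments.
#' @param volume_water_ml Added degassed bottom water (ml); required for
#'   slurry experiments.
#' @return An object of class `incubation_series`.
#' @export
incubation_series <- function(sample_id, experiment, station_id,
                              time_h, r29, r30, n28_umol_l,
                              layer_top_cm = NA_real_,
                              layer_bottom_cm = NA_real_,
                              volume_sediment_cm3 = NA_real_,
                              volume_water_ml = NA_real_) {
  experiment <- match.arg(experiment, c("slurry_ex1", "slurry_ex2", "core"))
  n <- length(time_h)
  if (n < 4L)
    stop("insufficient data: at least 4 time points are required, got ", n)
  if (length(r29) != n || length(r30) != n)
    stop("r29 and r30 must have the same length as time_h")
  if (!all(is.finite(time_h)) || any(time_h < 0))
    stop("time_h must be finite and non-negative")
  if (any(diff(time_h) <= 0))
    stop("time_h must be strictly increasing")
  bad <- which(!is.finite(r29) | r29 <= 0 | !is.finite(r30) | r30 <= 0)
  if (length(bad))
    stop("non-finite or non-positive isotope ratio at index ",
         paste(bad, collapse = ", "))
  if (!length(n28_umol_l) %in% c(1L, n))
    stop("n28_umol_l must be length 1 or match time_h")
  if (!all(is.finite(n28_umol_l)) || any(n28_umol_l <= 0))
    stop("n28_umol_l must be finite and positive")
  if (experiment != "core") {
    if (!is.finite(volume_sediment_cm3) || volume_sediment_cm3 <= 0 ||
        !is.finite(volume_water_ml) || volume_water_ml <= 0)
      stop("slurry experiments require positive volume_sediment_cm3 ",
           "and volume_water_ml")
  }
  structure(
    list(sample_id = as.character(sample_id), experiment = experiment,
         station_id = as.character(station_id),
         layer_top_cm = layer_top_cm, layer_bottom_cm = layer_bottom_cm,
         time_h = as.numeric(time_h), r29 = as.numeric(r29),
         r30 = as.numeric(r30), n28_umol_l = as.numeric(n28_umol_l),
         volume_sediment_cm3 = volume_sediment_cm3,
         volume_water_ml = volume_water_ml),
    class = "incubation_series")
}

#' @export
print.incubation_series <- function(x, ...) {
  cat("<incubation_series>", x$sample_id, sprintf("(%s)", x$experiment),
      "station", x$station_id, "\n")
  if (is.finite(x$layer_top_cm))
    cat("  layer:", x$layer_top_cm, "-", x$layer_bottom_cm, "cm\n")
  cat("  ", length(x$time_h), "time points over",
      max(x$time_h), "h\n")
  invisible(x)
}

#' Aqueous volume of a slurry incubation
#'
#' Total liquid volume of the slurry: added degassed bottom water plus pore
#' water, the latter estimated as porosity times sediment volume. The total
#' liquid volume of the incubations is not measured directly, so the
#' pore-water term is a configurable estimate.
#'
#' @param series An `incubation_series` (slurry experiment).
#' @param porosity Sediment porosity used to estimate pore-water volume
#'   (default 0.8, typical of fine-grained margin surface sediment).
#' @return Aqueous volume in litres.
#' @export
aqueous_volume_l <- function(series, porosity = 0.8) {
  stopifnot(inherits(series, "incubation_series"))
  if (series$experiment == "core")
    stop("aqueous_volume_l applies to slurry incubations only")
  stopifnot(is.finite(porosity), porosity > 0, porosity < 1)
  series$volume_water_ml / 1000 +
    porosity * series$volume_sediment_cm3 / 1000
}

#' Read incubation series from CSV
#'
#' Reads a long-format table, one row per exetainer subsample, with columns
#' `sample_id, experiment, station_id, layer_top_cm, layer_bottom_cm,
#' time_h, r29, r30, n28_umol_l` and optional `volume_sediment_cm3,
#' volume_water_ml` (constant within a sample). Missing values use the
#' token `NA`. Rows are grouped by `sample_id` into `incubation_series`
#' objects, ordered by time.
#'
#' @param path Path to the CSV file.
#' @return A named list of `incubation_series` objects.
#' @export
read_incubation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       station_id = "character"))
  need <- c("sample_id", "experiment", "station_id", "time_h",
            "r29", "r30", "n28_umol_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (opt in c("layer_top_cm", "layer_bottom_cm",
                "volume_sediment_cm3", "volume_water_ml"))
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  out <- lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$time_h), ]
    incubation_series(
      sample_id = d$sample_id[1], experiment = d$experiment[1],
      station_id = d$station_id[1],
      time_h = d$time_h, r29 = d$r29, r30 = d$r30,
      n28_umol_l = if (length(unique(d$n28_umol_l)) == 1L)
        d$n28_umol_l[1] else d$n28_umol_l,
      layer_top_cm = d$layer_top_cm[1],
      layer_bottom_cm = d$layer_bottom_cm[1],
      volume_sediment_cm3 = d$volume_sediment_cm3[1],
      volume_water_ml = d$volume_water_ml[1])
  })
  out[unique(df$sample_id)]
}

#' Write incubation series to CSV
#'
#' Inverse of [read_incubation_csv()]: writes a list of series as one
#' long-format table, one row per subsample.
#'
#' @param series_list A list of `incubation_series` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_incubation_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    n <- length(s$time_h)
    data.frame(sample_id = s$sample_id, experiment = s$experiment,
               station_id = s$station_id,
               layer_top_cm = s$layer_top_cm,
               layer_bottom_cm = s$layer_bottom_cm,
               time_h = s$time_h, r29 = s$r29, r30 = s$r30,
               n28_umol_l = rep_len(s$n28_umol_l, n),
               volume_sediment_cm3 = s$volume_sediment_cm3,
               volume_water_ml = s$volume_water_ml)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
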