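#' Read a qPCR copy-number table
#'
#' Reads a CSV with columns `station_id, layer_top_cm, layer_bottom_cm,
#' target, copies_per_mg, sd` where `target` is `denitrifier_nirS` or
#' `anammox_nirS`. The token `n.d.` (or `NA`) in `copies_per_mg` marks a
#' below-detection measurement: copies are recorded as missing, never as
#' zero, and a logical `below_detection` column is added.
#'
#' @param path Path to the CSV file.
#' @return A data frame with numeric `copies_per_mg`, `sd` and logical
#'   `below_detection`.
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""),
                        colClasses = c(station_id = "character"))
  need <- c("station_id", "layer_top_cm", "layer_bottom_cm", "target",
            "copies_per_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  nd <- !is.na(df$copies_per_mg) &
    tolower(trimws(as.character(df$copies_per_mg))) %in%
      c("n.d.", "nd", "n.d")
  df$below_detection <- nd | is.na(df$copies_per_mg)
  df$copies_per_mg <- suppressWarnings(as.numeric(df$copies_per_mg))
  df$copies_per_mg[df$below_detection] <- NA_real_
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  df$sd <- suppressWarnings(as.numeric(df$sd))
  bad <- which(!df$below_detection & df$copies_per_mg < 0)
  if (length(bad)) stop("negative copy number at row ",
                        paste(bad, collapse = ", "))
  df$target <- match.arg(df$target,
                         c("denitrifier_nirS", "anammox_nirS"),
                         several.ok = TRUE)
  df
}

#' Anammox share of total nirS gene copies
#'
#' `fraction = anammox / (anammox + denitrifier)` for one station/layer.
#' Below-detection measurements (`NA` copies) are excluded, not treated as
#' zero: if either target is below detection the fraction is undefined for
#' that layer (`NA` with a warning); if both are, an error is raised.
#' When standard deviations are supplied, a first-order delta-method
#' uncertainty is attached: with `f = a/(a+d)`,
#' `var(f) = (d^2 sa^2 + a^2 sd^2) / (a+d)^4`.
#'
#' @param anammox,denitrifier Copy numbers per mg dry sediment (`NA` for
#'   below detection).
#' @param sd_anammox,sd_denitrifier Optional standard deviations.
#' @return The fraction in \[0, 1\], with attribute `sd` when
#'   uncertainties were given.
#' @export
anammox_nirs_fraction <- function(anammox, denitrifier,
                                  sd_anammox = NULL,
                                  sd_denitrifier = NULL) {
  if (is.na(anammox) && is.na(denitrifier))
    stop("undefined fraction: both targets below detection")
  if (is.na(anammox) || is.na(denitrifier)) {
    warning("one target below detection; fraction undefined (NA)")
    return(NA_real_)
  }
  stopifnot(anammox >= 0, denitrifier >= 0)
  if (anammox + denitrifier == 0)
    stop("undefined fraction: both copy numbers are zero")
  f <- anammox / (anammox + denitrifier)
  if (!is.null(sd_anammox) && !is.null(sd_denitrifier) &&
      is.finite(sd_anammox) && is.finite(sd_denitrifier)) {
    s <- sqrt(denitrifier^2 * sd_anammox^2 +
                anammox^2 * sd_denitrifier^2) / (anammox + denitrifier)^2
    attr(f, "sd") <- s
  }
  f
}

#' Cell-specific rate from a volumetric rate and gene copy numbers
#'
#' Converts a sediment-volumetric N transformation rate into a per-cell
#' rate assuming the marker gene is present in `copies_per_cell` copies
#' per cell (nirS is single-copy in the sequenced anammox genomes):
#' `cells cm^-3 = copies_per_mg * 1e3 * bulk_density / copies_per_cell`,
#' `rate = volumetric_rate * 1e6 / cells_cm3` (nmol to fmol).
#' Note the result scales inversely with the assumed dry bulk density,
#' which is a required configuration input, not a measured value.
#'
#' @param volumetric_rate Rate in nmol N cm^-3 d^-1.
#' @param copies_per_mg Gene copies per mg dry sediment (> 0).
#' @param bulk_density Dry bulk density in g cm^-3 (default 1.0; results
#'   scale with it).
#' @param copies_per_cell Marker copies per cell (default 1).
#' @return Cell-specific rate in fmol N cell^-1 d^-1.
#' @export
cell_specific_rate <- function(volumetric_rate, copies_per_mg,
                               bulk_density = 1.0, copies_per_cell = 1) {
  stopifnot(is.finite(volumetric_rate), volumetric_rate >= 0,
            is.finite(bulk_density), bulk_density > 0,
            is.finite(copies_per_cell), copies_per_cell >= 1)
  if (!is.finite(copies_per_mg) || copies_per_mg <= 0)
    stop("copies_per_mg must be positive")
  cells_cm3 <- copies_per_mg * 1e3 * bulk_density / copies_per_cell
  volumetric_rate * 1e6 / cells_cm3
}
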