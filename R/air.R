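#' Air-equilibrium N2 isotopologue ratios
#'
#' Computes the 29N2/28N2 and 30N2/28N2 mole ratios of atmospheric N2 from
#' the atmospheric 15N atom fraction under binomial pairing of N atoms:
#' p28 = (1-x)^2, p29 = 2x(1-x), p30 = x^2, so r29 = 2x/(1-x) and
#' r30 = x^2/(1-x)^2. These serve as the baseline from which tracer-derived
#' excess 29N2 and 30N2 are measured. Calibration against a local air
#' standard can override either ratio wherever they are accepted.
#'
#' @param atom15 Atmospheric 15N atom fraction (default 0.0036765).
#' @return A list with elements `r29`, `r30` and `atom15`.
#' @examples
#' air_n2_ratios()$r29  # ~0.00738
#' @export
air_n2_ratios <- function(atom15 = 0.0036765) {
  stopifnot(is.numeric(atom15), length(atom15) == 1L,
            is.finite(atom15), atom15 > 0, atom15 < 0.5)
  list(
    r29 = 2 * atom15 / (1 - atom15),
    r30 = atom15^2 / (1 - atom15)^2,
    atom15 = atom15
  )
}
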