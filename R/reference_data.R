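#' Reported drying constants for vacuum-dried sage leaves
#'
#' The 3 temperature x 3 pressure grid of exponential drying constants (and
#' the R2 of their log-linear fits) reported for thin-layer vacuum drying of
#' sage leaves at 40/50/60 C and gauge pressures of 0 (atmospheric), -5 and
#' -10 kPa. These constants are the anchor inputs for the diffusivity,
#' activation-energy and thermodynamic stages, and the default truth values of
#' the synthetic-curve generator.
#'
#' @return Data frame with columns `temp_C`, `pressure_kPa`, `k` (1/min),
#'   `r2`.
#' @export
sage_drying_constants <- function() {
  data.frame(
    temp_C = rep(c(40, 50, 60), times = 3),
    pressure_kPa = rep(c(0, -5, -10), each = 3),
    k = c(0.0069, 0.0116, 0.0164,
          0.0124, 0.0143, 0.0195,
          0.0171, 0.0240, 0.0398),
    r2 = c(0.9947, 0.9987, 0.9981,
           0.9959, 0.9734, 0.9915,
           0.9950, 0.9964, 0.9927))
}

#' Default economic assumption set of the sage-dryer case study
#'
#' The scenario reported for the 300-USD automatic vacuum dryer: 3% interest,
#' 2.5% inflation, 20-year life, maintenance 3% and salvage 8% of the annual
#' capital cost, 2 kg batches, 350 drying days/year with 600 effective drying
#' minutes/day, fresh leaves at 2 USD/kg, dried leaves selling at 5 USD/kg
#' with a flat dried-product cost of 4.25 USD/kg.
#'
#' @return An [economic_scenario()] with the case-study defaults.
#' @export
sage_economic_assumptions <- function() economic_scenario()
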