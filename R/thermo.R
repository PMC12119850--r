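#' Eyring transition-state regression
#'
#' Fits `ln(k/T) = ln(kB/h) + dS/R - (dH/R)(1/T)` by ordinary least squares of
#' `ln(k/T)` on `1/T`: the slope gives the activation enthalpy
#' `dH = -slope * R` and the intercept the activation entropy
#' `dS = R * (intercept - ln(kB/h))`. Because the intercept (and hence dS)
#' depends on the unit of the rate constant, the unit is a mandatory tag:
#' rate constants supplied in 1/min are converted to 1/s when
#' `unit = "per_min"`, and the reported dS shifts by exactly `R ln(60)`
#' between the two conventions.
#'
#' @param temperature_K absolute temperatures, K (>= 2 distinct).
#' @param k rate constants (> 0), in the unit named by `unit`.
#' @param unit `"per_s"` (default) or `"per_min"`; the regression always runs
#'   on 1/s.
#' @return An object of class `eyring_fit`: `dH` and `dS` (J/mol and
#'   J/(mol K)), the regression `r2`, and `rate_unit = "per_s"` recording the
#'   unit actually regressed on.
#' @export
eyring_fit <- function(temperature_K, k, unit = c("per_s", "per_min")) {
  unit <- match.arg(unit)
  if (length(temperature_K) != length(k))
    stop("temperature_K and k must have equal length")
  if (length(unique(temperature_K)) < 2)
    stop("need at least 2 distinct temperatures")
  if (any(k <= 0)) stop("rate constants must be positive")
  if (unit == "per_min") k <- k / 60
  x <- 1 / temperature_K
  y <- log(k / temperature_K)
  fit <- lm(y ~ x)
  dH <- -unname(coef(fit)[2]) * .GAS_CONSTANT
  dS <- .GAS_CONSTANT * (unname(coef(fit)[1]) - log(.BOLTZMANN / .PLANCK))
  structure(
    list(dH = dH, dS = dS,
         r2 = if (length(k) > 2) .lm_r2(fit) else 1,
         rate_unit = "per_s", temperature_K = temperature_K),
    class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("Eyring fit (k in 1/s): dH = %.3f kJ/mol, dS = %.4f kJ/(mol K), R2 = %.4f\n",
              x$dH / 1000, x$dS / 1000, x$r2))
  invisible(x)
}

#' Per-temperature activation enthalpy from activation energy
#'
#' The transition-state convention `dH(T) = E_a - R T`, which makes the
#' activation enthalpy decrease by R per kelvin of drying temperature
#' (about 0.08 kJ/mol per 10 K).
#'
#' @param e_a activation energy, J/mol.
#' @param temperature_K absolute temperature(s), K (> 0). Vectorized.
#' @return Activation enthalpy dH in J/mol.
#' @examples
#' enthalpy_ea_convention(37700, 313.15) / 1000 # 35.10 kJ/mol
#' @export
enthalpy_ea_convention <- function(e_a, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature_K must be positive")
  e_a - .GAS_CONSTANT * temperature_K
}

#' Gibbs free energy of activation
#'
#' `dG = dH - T dS`; positive (non-spontaneous process) whenever `dH > 0` and
#' `dS < 0`, the signature of endothermic drying with chemisorption-like
#' ordering.
#'
#' @param dH activation enthalpy, J/mol.
#' @param dS activation entropy, J/(mol K).
#' @param temperature_K absolute temperature(s), K (> 0).
#' @return dG in J/mol. Vectorized over the arguments.
#' @export
gibbs_free_energy <- function(dH, dS, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature_K must be positive")
  dH - temperature_K * dS
}

#' Transition-state summary for a set of drying rate constants
#'
#' Combines the thermodynamic pieces for one pressure level's temperature
#' series: an Arrhenius activation energy (from diffusivities implied by the
#' rate constants), the Eyring regression (for the activation entropy), the
#' per-temperature enthalpy convention `dH = E_a - R T`, and the Gibbs free
#' energy at each temperature.
#'
#' @param temperature_K absolute temperatures, K.
#' @param k drying constants in 1/min.
#' @param half_thickness_m slab half thickness used for the diffusivity step.
#' @return An object of class `thermo_result`: per-temperature data frame with
#'   `dH_kJ`, `dS_kJ`, `dG_kJ`, plus the underlying `arrhenius` and `eyring`
#'   fits and the enthalpy `method` tag.
#' @export
thermo_summary <- function(temperature_K, k, half_thickness_m = 0.005) {
  d_eff <- deff_from_k(k, half_thickness_m)
  arr <- arrhenius_fit(temperature_K, d_eff)
  eyr <- eyring_fit(temperature_K, k, unit = "per_min")
  dH <- enthalpy_ea_convention(arr$e_a, temperature_K)
  dG <- gibbs_free_energy(dH, eyr$dS, temperature_K)
  structure(
    list(table = data.frame(temperature_K = temperature_K,
                            dH_kJ = dH / 1000,
                            dS_kJ = eyr$dS / 1000,
                            dG_kJ = dG / 1000),
         arrhenius = arr, eyring = eyr,
         method = "ea_minus_rt", rate_unit = eyr$rate_unit),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Transition-state summary (dH = E_a - RT; dS from Eyring, k in 1/s):\n"))
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("E_a = %.3f kJ/mol\n", x$arrhenius$e_a_kJ))
  invisible(x)
}
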