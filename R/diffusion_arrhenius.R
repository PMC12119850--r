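#' Fickian slab-solution moisture ratio
#'
#' Truncated series solution of Fick's second law for an infinite slab dried
#' from both faces, in terms of the half thickness `L`:
#' `MR = (8/pi^2) * sum_{odd n} (1/n^2) exp(-n^2 pi^2 D t / (4 L^2))`.
#' With one term this is the log-linear form whose intercept is `ln(8/pi^2)`;
#' as `n_terms -> Inf`, `MR(0) -> 1`.
#'
#' @param d_eff effective moisture diffusivity, m^2/s (> 0).
#' @param half_thickness_m slab half thickness `L` in metres (> 0).
#' @param t_s time(s) in seconds (vectorized).
#' @param n_terms number of odd series terms (>= 1).
#' @return Moisture ratio at `t_s`.
#' @examples
#' fick_mr_series(6.716e-9, 0.005, 5400, n_terms = 1) # 0.0226
#' @export
fick_mr_series <- function(d_eff, half_thickness_m, t_s, n_terms = 200) {
  if (d_eff <= 0) stop("d_eff must be positive")
  if (half_thickness_m <= 0) stop("half_thickness_m must be positive")
  if (n_terms < 1) stop("n_terms must be >= 1")
  n <- 2 * seq_len(n_terms) - 1         # odd indices 1, 3, 5, ...
  fo <- pi^2 * d_eff * outer(t_s, rep(1, n_terms)) / (4 * half_thickness_m^2)
  terms <- sweep(exp(-sweep(fo, 2, n^2, `*`)), 2, n^2, `/`)
  as.numeric(8 / pi^2 * rowSums(terms))
}

#' Effective moisture diffusivity from a drying curve
#'
#' Ordinary least squares of `ln(MR)` on drying time; the slope (converted to
#' 1/s) gives `D_eff = -slope * 4 L^2 / pi^2` under the one-term slab
#' solution. The intercept is retained (expected near `ln(8/pi^2)`) and points
#' with `MR <= 0` are excluded.
#'
#' @param curve a [drying_curve()] (moisture ratio derived from weights if
#'   absent).
#' @param half_thickness_m slab half thickness `L` in metres; defaults to half
#'   the layer thickness stored in the curve's conditions.
#' @return An object of class `diffusivity_result`: `d_eff` (m^2/s),
#'   `slope_per_min`, `intercept`, `r2`, `half_thickness_m`, and a
#'   `physical` flag (FALSE when the slope is non-negative).
#' @export
deff_from_curve <- function(curve, half_thickness_m = NULL) {
  stopifnot(inherits(curve, "drying_curve"))
  if (is.null(half_thickness_m))
    half_thickness_m <- curve$conditions$thickness_m / 2
  curve <- moisture_ratio_series(curve)
  keep <- is.finite(curve$moisture_ratio) & curve$moisture_ratio > 0
  if (sum(keep) < 3) stop("need at least 3 points with MR > 0")
  t <- curve$times[keep]
  y <- log(curve$moisture_ratio[keep])
  fit <- lm(y ~ t)
  slope_min <- unname(coef(fit)[2])      # 1/min
  d_eff <- -(slope_min / 60) * 4 * half_thickness_m^2 / pi^2
  physical <- d_eff > 0
  if (!physical)
    warning("non-negative ln(MR) slope: returned D_eff is non-physical")
  structure(
    list(d_eff = d_eff, slope_per_min = slope_min,
         intercept = unname(coef(fit)[1]), r2 = .lm_r2(fit),
         half_thickness_m = half_thickness_m, physical = physical,
         label = curve$label),
    class = "diffusivity_result")
}

#' @export
print.diffusivity_result <- function(x, ...) {
  cat(sprintf("D_eff = %.4g m^2/s (slope %.4g 1/min, R2 = %.4f, L = %g m)%s\n",
              x$d_eff, x$slope_per_min, x$r2, x$half_thickness_m,
              if (x$physical) "" else " [non-physical]"))
  invisible(x)
}

#' Effective moisture diffusivity from a drying constant
#'
#' Identifies the log-linear slope of the one-term slab solution with the
#' exponential drying constant: `D_eff = (k/60) * 4 L^2 / pi^2`, `k` in 1/min.
#'
#' @param k drying constant, 1/min (> 0). Vectorized.
#' @param half_thickness_m slab half thickness `L` in metres (> 0).
#' @return `D_eff` in m^2/s.
#' @examples
#' deff_from_k(0.0398, 0.005) # 6.72e-9 m^2/s
#' @export
deff_from_k <- function(k, half_thickness_m = 0.005) {
  if (any(k <= 0)) stop("k must be positive")
  if (half_thickness_m <= 0) stop("half_thickness_m must be positive")
  (k / 60) * 4 * half_thickness_m^2 / pi^2
}

#' Arrhenius fit of diffusivity against temperature
#'
#' Ordinary least squares of `ln(D_eff)` on `1/T` for the Arrhenius law
#' `D_eff = D_0 exp(-E_a / (R T))`: `E_a = -slope * R`, `D_0 = exp(intercept)`.
#'
#' @param temperature_K absolute temperatures, K (at least 2 distinct).
#' @param d_eff effective diffusivities, m^2/s (> 0, same length).
#' @return An object of class `arrhenius_result`: `e_a` (J/mol), `e_a_kJ`,
#'   `d_0` (m^2/s), `r2`, and the temperatures used.
#' @export
arrhenius_fit <- function(temperature_K, d_eff) {
  if (length(temperature_K) != length(d_eff))
    stop("temperature_K and d_eff must have equal length")
  if (length(unique(temperature_K)) < 2)
    stop("need at least 2 distinct temperatures")
  if (any(d_eff <= 0)) stop("d_eff must be positive")
  x <- 1 / temperature_K
  y <- log(d_eff)
  fit <- lm(y ~ x)
  e_a <- -unname(coef(fit)[2]) * .GAS_CONSTANT
  structure(
    list(e_a = e_a, e_a_kJ = e_a / 1000, d_0 = exp(unname(coef(fit)[1])),
         r2 = if (length(d_eff) > 2) .lm_r2(fit) else 1,
         temperature_K = temperature_K),
    class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures: E_a = %.3f kJ/mol, D_0 = %.4g m^2/s, R2 = %.4f\n",
              length(x$temperature_K), x$e_a_kJ, x$d_0, x$r2))
  invisible(x)
}
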