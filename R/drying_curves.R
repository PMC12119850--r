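#' Drying condition metadata
#'
#' Bundles the process conditions attached to a single drying run: drying air
#' temperature, chamber gauge pressure (0 = atmospheric), product layer
#' thickness, and the initial (and optionally equilibrium) wet-basis moisture
#' fraction of the product.
#'
#' @param temperature_C drying temperature in degrees Celsius.
#' @param pressure_kPa gauge pressure in kPa; 0 means atmospheric, vacuum
#'   conditions are negative (e.g. -10).
#' @param thickness_m product layer thickness in metres (full layer, not half).
#' @param initial_moisture_wb initial moisture content, wet-basis fraction in
#'   `[0, 1)`.
#' @param equilibrium_moisture_wb optional equilibrium moisture content,
#'   wet-basis fraction; must be below `initial_moisture_wb`.
#' @return An object of class `drying_conditions`.
#' @examples
#' drying_conditions(60, -10, 0.01, 0.855, 0.134)
#' @export
drying_conditions <- function(temperature_C, pressure_kPa = 0,
                              thickness_m = 0.01,
                              initial_moisture_wb = 0.855,
                              equilibrium_moisture_wb = NULL) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L)
  if (temperature_C <= -273.15)
    stop("temperature_C must be above absolute zero (-273.15 C)")
  if (thickness_m <= 0) stop("thickness_m must be positive")
  if (initial_moisture_wb < 0 || initial_moisture_wb >= 1)
    stop("initial_moisture_wb must be a wet-basis fraction in [0, 1)")
  if (!is.null(equilibrium_moisture_wb)) {
    if (equilibrium_moisture_wb < 0 || equilibrium_moisture_wb >= 1)
      stop("equilibrium_moisture_wb must be a wet-basis fraction in [0, 1)")
    if (equilibrium_moisture_wb >= initial_moisture_wb)
      stop("equilibrium_moisture_wb must be below initial_moisture_wb")
  }
  structure(
    list(temperature_C = temperature_C,
         temperature_K = temperature_C + 273.15,
         pressure_kPa = pressure_kPa,
         thickness_m = thickness_m,
         initial_moisture_wb = initial_moisture_wb,
         equilibrium_moisture_wb = equilibrium_moisture_wb),
    class = "drying_conditions")
}

#' @export
print.drying_conditions <- function(x, ...) {
  cat(sprintf("Drying conditions: %g C, %g kPa gauge, layer %g m, M0 = %.1f%% wb",
              x$temperature_C, x$pressure_kPa, x$thickness_m,
              100 * x$initial_moisture_wb))
  if (!is.null(x$equilibrium_moisture_wb))
    cat(sprintf(", Me = %.1f%% wb", 100 * x$equilibrium_moisture_wb))
  cat("\n")
  invisible(x)
}

#' A single-condition drying curve
#'
#' The pipeline's universal input: one run's time series of sample weights
#' and/or moisture ratios, with its condition metadata. Times are minutes and
#' must start at 0 and be strictly increasing. At least one of `weights`
#' (grams) or `moisture_ratio` (dimensionless) must be given.
#'
#' @param times sampling times in minutes, strictly increasing, `times[1] == 0`.
#' @param weights optional sample weights in grams (all positive).
#' @param moisture_ratio optional dimensionless moisture-ratio trace.
#' @param conditions a [drying_conditions()] object.
#' @param label free-text label for the run.
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(times, weights = NULL, moisture_ratio = NULL,
                         conditions, label = "") {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("a drying curve needs at least two time points")
  if (times[1] != 0) stop("times must start at 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(weights) && is.null(moisture_ratio))
    stop("at least one of weights / moisture_ratio must be supplied")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(times))
      stop("weights and times must have equal length")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be finite and positive")
  }
  if (!is.null(moisture_ratio)) {
    moisture_ratio <- as.numeric(moisture_ratio)
    if (length(moisture_ratio) != length(times))
      stop("moisture_ratio and times must have equal length")
  }
  if (!inherits(conditions, "drying_conditions"))
    stop("conditions must be a drying_conditions object")
  structure(
    list(times = times, weights = weights, moisture_ratio = moisture_ratio,
         conditions = conditions, label = as.character(label)),
    class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("Drying curve '%s': %d points over %g min (%g C, %g kPa)\n",
              x$label, length(x$times), max(x$times),
              x$conditions$temperature_C, x$conditions$pressure_kPa))
  if (!is.null(x$weights))
    cat(sprintf("  weights: %.2f -> %.2f g\n",
                x$weights[1], x$weights[length(x$weights)]))
  if (!is.null(x$moisture_ratio))
    cat(sprintf("  moisture ratio: %.3f -> %.4f\n",
                x$moisture_ratio[1],
                x$moisture_ratio[length(x$moisture_ratio)]))
  invisible(x)
}

#' @export
as.data.frame.drying_curve <- function(x, ...) {
  d <- data.frame(time_min = x$times)
  if (!is.null(x$weights)) d$weight_g <- x$weights
  if (!is.null(x$moisture_ratio)) d$mr <- x$moisture_ratio
  d$label <- x$label
  d$temp_C <- x$conditions$temperature_C
  d$pressure_kPa <- x$conditions$pressure_kPa
  d$thickness_m <- x$conditions$thickness_m
  d$initial_mc_wb <- x$conditions$initial_moisture_wb
  d$equilib_mc_wb <- if (is.null(x$conditions$equilibrium_moisture_wb)) NA_real_
                     else x$conditions$equilibrium_moisture_wb
  d
}

#' Dry-basis moisture content from oven-drying weights
#'
#' Gravimetric (oven-drying) moisture content on the dry basis:
#' `100 * (wet - dry) / dry` percent, i.e. grams of water per 100 g of dry
#' matter.
#'
#' @param wet_weight wet sample weight, g.
#' @param dry_weight bone-dry sample weight, g (> 0).
#' @return Moisture content in percent, dry basis. Vectorized.
#' @examples
#' moisture_content_dry_basis(100, 14.5) # 85.5% wb sample -> 589.66% db
#' @export
moisture_content_dry_basis <- function(wet_weight, dry_weight) {
  if (any(dry_weight <= 0)) stop("dry_weight must be positive")
  if (any(wet_weight < dry_weight)) stop("wet_weight must be >= dry_weight")
  100 * (wet_weight - dry_weight) / dry_weight
}

#' Convert moisture content between wet and dry basis
#'
#' Wet basis (water / total mass) to dry basis (water / dry matter) and back:
#' `db = wb / (1 - wb)`, `wb = db / (1 + db)`. Fractions in, fractions out.
#'
#' @param value moisture fraction(s): wet-basis in `[0, 1)` or dry-basis >= 0.
#' @param direction `"wb_to_db"` or `"db_to_wb"`.
#' @return Converted moisture fraction(s).
#' @examples
#' convert_moisture_basis(0.855, "wb_to_db") # 5.8966 g/g dry matter
#' @export
convert_moisture_basis <- function(value,
                                   direction = c("wb_to_db", "db_to_wb")) {
  direction <- match.arg(direction)
  if (direction == "wb_to_db") {
    if (any(value < 0) || any(value >= 1))
      stop("wet-basis moisture must lie in [0, 1)")
    value / (1 - value)
  } else {
    if (any(value < 0)) stop("dry-basis moisture must be non-negative")
    value / (1 + value)
  }
}

#' Per-interval weight losses
#'
#' Successive-difference weight loss, one value per sampling interval; the
#' cumulative sum equals first minus last weight exactly.
#'
#' @param curve a [drying_curve()] with weights present.
#' @return Numeric vector of per-interval losses in grams (length
#'   `length(times) - 1`); negative values (noise) are retained.
#' @export
weight_loss_series <- function(curve) {
  stopifnot(inherits(curve, "drying_curve"))
  if (is.null(curve$weights))
    stop("weight_loss_series needs a curve with weights")
  -diff(curve$weights)
}

#' Drying-rate series
#'
#' Interval drying rate: weight loss per interval divided by the interval
#' length in hours (g/h); when the dry-matter mass is supplied the rate is
#' additionally normalized to g water per g dry matter per hour.
#'
#' @param curve a [drying_curve()] with weights present.
#' @param dry_matter optional dry-matter mass in grams for normalization.
#' @return A data frame of class `rate_series` with columns `midpoint_min`
#'   (interval midpoints) and `rate` (g/h, or g/g dm/h when normalized), plus
#'   attribute `unit`.
#' @export
drying_rate_series <- function(curve, dry_matter = NULL) {
  stopifnot(inherits(curve, "drying_curve"))
  if (is.null(curve$weights))
    stop("drying_rate_series needs a curve with weights")
  dt_min <- diff(curve$times)
  if (any(dt_min <= 0)) stop("duplicate or non-increasing time stamps")
  loss <- weight_loss_series(curve)
  rate <- loss / (dt_min / 60)           # g per hour
  unit <- "g/h"
  if (!is.null(dry_matter)) {
    if (dry_matter <= 0) stop("dry_matter must be positive")
    rate <- rate / dry_matter
    unit <- "g_water/g_dm/h"
  }
  out <- data.frame(
    midpoint_min = (curve$times[-length(curve$times)] + curve$times[-1]) / 2,
    rate = rate)
  attr(out, "unit") <- unit
  class(out) <- c("rate_series", "data.frame")
  out
}

## dry matter implied by the curve's initial weight and wet-basis moisture
.dry_matter <- function(curve) {
  if (is.null(curve$weights)) return(NULL)
  curve$weights[1] * (1 - curve$conditions$initial_moisture_wb)
}

#' Fill the moisture-ratio trace of a curve
#'
#' Derives dry-basis moisture contents from the weight trace (dry matter taken
#' from the initial weight and the wet-basis initial moisture in the
#' conditions) and normalizes them to a moisture ratio. By default the
#' equilibrium moisture is neglected (`MR = M_t / M_0`), the usual thin-layer
#' simplification; with `use_equilibrium = TRUE` and an equilibrium moisture in
#' the conditions, `MR = (M_t - M_e) / (M_0 - M_e)` is used instead.
#'
#' @param curve a [drying_curve()]; weights required unless a moisture-ratio
#'   trace is already present (then returned unchanged).
#' @param use_equilibrium use the equilibrium-corrected definition.
#' @return The curve with `moisture_ratio` filled (`MR[1] == 1`).
#' @export
moisture_ratio_series <- function(curve, use_equilibrium = FALSE) {
  stopifnot(inherits(curve, "drying_curve"))
  if (!is.null(curve$moisture_ratio)) return(curve)
  if (is.null(curve$weights))
    stop("cannot derive moisture ratio: no weights and no mr trace")
  wd <- .dry_matter(curve)
  m <- (curve$weights - wd) / wd          # dry-basis moisture, g/g
  m0 <- m[1]
  me <- 0
  if (use_equilibrium) {
    ewb <- curve$conditions$equilibrium_moisture_wb
    if (is.null(ewb))
      stop("use_equilibrium = TRUE needs equilibrium_moisture_wb in conditions")
    me <- convert_moisture_basis(ewb, "wb_to_db")
  }
  if (abs(m0 - me) < .Machine$double.eps)
    stop("degenerate normalization: initial and equilibrium moisture coincide")
  curve$moisture_ratio <- (m - me) / (m0 - me)
  curve
}
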