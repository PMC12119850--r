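#' Specification for the synthetic drying-curve generator
#'
#' Describes the simulated experiment: a kinetic model (default Page) with
#' true parameters per condition, the sampling interval (15 min load-cell
#' weighings), the stop rule (moisture ratio threshold or fixed horizon), the
#' sample's initial mass and moisture, and the weight-domain noise level.
#' Defaults emulate the vacuum-drying study the package was built around:
#' 100 g samples at 85.5% wet-basis initial moisture drying towards 13.4% wb
#' equilibrium, weighed every 15 min with a +-0.1 g balance, per-condition
#' true rate constants from [sage_drying_constants()].
#'
#' @param conditions data frame with columns `temp_C`, `pressure_kPa` and the
#'   true model parameters (`k`, and `n` unless constant); defaults to the
#'   reported drying-constant grid with `n = 1`.
#' @param model kinetic model for the truth curves (one of
#'   [thinlayer_models()]; default `"page"`).
#' @param interval_min sampling interval, minutes.
#' @param mr_stop stop when the true moisture ratio falls to this value.
#' @param max_time_min hard horizon, minutes.
#' @param initial_mass_g initial sample mass, g.
#' @param initial_moisture_wb initial wet-basis moisture fraction.
#' @param equilibrium_moisture_wb equilibrium wet-basis moisture fraction.
#' @param thickness_m product layer thickness, m.
#' @param noise_sd_g i.i.d. Gaussian weight noise, g (0 for noiseless).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(conditions = NULL, model = "page",
                           interval_min = 15, mr_stop = 0.01,
                           max_time_min = 510, initial_mass_g = 100,
                           initial_moisture_wb = 0.855,
                           equilibrium_moisture_wb = 0.134,
                           thickness_m = 0.01, noise_sd_g = 0.1) {
  if (is.null(conditions)) {
    conditions <- sage_drying_constants()[, c("temp_C", "pressure_kPa", "k")]
    conditions$n <- 1
  }
  stopifnot(all(c("temp_C", "pressure_kPa") %in% names(conditions)))
  if (noise_sd_g < 0) stop("noise_sd_g must be non-negative")
  if (equilibrium_moisture_wb >= initial_moisture_wb)
    stop("equilibrium moisture must be below initial moisture")
  structure(
    list(conditions = conditions, model = model,
         interval_min = interval_min, mr_stop = mr_stop,
         max_time_min = max_time_min, initial_mass_g = initial_mass_g,
         initial_moisture_wb = initial_moisture_wb,
         equilibrium_moisture_wb = equilibrium_moisture_wb,
         thickness_m = thickness_m, noise_sd_g = noise_sd_g),
    class = "generator_spec")
}

## true model parameters for one condition row
.condition_params <- function(spec, row) {
  pn <- .get_model(spec$model)$params
  miss <- setdiff(pn, names(row))
  if (length(miss))
    stop("condition row lacks true parameter(s): ", paste(miss, collapse = ", "))
  setNames(as.numeric(row[pn]), pn)
}

#' Generate one synthetic drying curve
#'
#' Evaluates the true kinetic model on the sampling grid, maps the moisture
#' ratio to sample weights through the dry-matter mass balance
#' (`M_t = M_e + (M_0 - M_e) * MR`, weights `= dry_matter * (1 + M_t)`), and
#' adds i.i.d. Gaussian load-cell noise in the weight domain. The stored
#' moisture-ratio trace is the noiseless truth; re-deriving MR from the noisy
#' weights is the job of [moisture_ratio_series()].
#'
#' @param spec a [generator_spec()].
#' @param condition one-row data frame (or row index into
#'   `spec$conditions`) giving the condition and its true parameters.
#' @param seed integer seed; fully determines the output.
#' @return A [drying_curve()]; the true parameters are attached as attribute
#'   `truth`.
#' @export
generate_curve <- function(spec, condition = 1, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.numeric(condition) && length(condition) == 1)
    condition <- spec$conditions[condition, , drop = FALSE]
  params <- .condition_params(spec, condition)

  times <- seq(0, spec$max_time_min, by = spec$interval_min)
  mr <- predict_mr(spec$model, params, times)
  stop_idx <- which(mr <= spec$mr_stop)
  if (length(stop_idx))
    times <- times[seq_len(min(stop_idx))]
  mr <- predict_mr(spec$model, params, times)

  m0 <- convert_moisture_basis(spec$initial_moisture_wb, "wb_to_db")
  me <- convert_moisture_basis(spec$equilibrium_moisture_wb, "wb_to_db")
  dry_matter <- spec$initial_mass_g * (1 - spec$initial_moisture_wb)
  m_t <- me + (m0 - me) * mr
  weights <- dry_matter * (1 + m_t)
  if (spec$noise_sd_g > 0) {
    noise <- .with_seed(seed,
                        rnorm(length(weights), sd = spec$noise_sd_g))
    noise[1] <- 0                       # anchor the initial weighing
    weights <- weights + noise
  }
  ## observed MR re-derived from the (noisy) weights via the equilibrium-
  ## corrected definition, so measurement noise propagates downstream; at
  ## noise_sd_g = 0 this equals the closed-form model trace exactly
  m_obs <- (weights - dry_matter) / dry_matter
  mr <- (m_obs - me) / (m0 - me)

  cond <- drying_conditions(
    temperature_C = condition$temp_C,
    pressure_kPa = condition$pressure_kPa,
    thickness_m = spec$thickness_m,
    initial_moisture_wb = spec$initial_moisture_wb,
    equilibrium_moisture_wb = spec$equilibrium_moisture_wb)
  curve <- drying_curve(
    times = times, weights = weights, moisture_ratio = mr,
    conditions = cond,
    label = sprintf("T%g_P%g", condition$temp_C, condition$pressure_kPa))
  attr(curve, "truth") <- c(as.list(params), model = spec$model)
  curve
}

#' Generate the full condition grid
#'
#' One synthetic curve per condition row (default: the 3 x 3
#' temperature-pressure grid), each with its own derived seed, plus a truth
#' manifest recording the generating parameters for recovery scoring.
#'
#' @param spec a [generator_spec()].
#' @param seed integer master seed.
#' @return List with `curves` (list of [drying_curve()]) and `truth` (data
#'   frame of conditions and true parameters).
#' @export
generate_grid <- function(spec = generator_spec(), seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- nrow(spec$conditions)
  curves <- lapply(seq_len(n), function(i)
    generate_curve(spec, i, seed = seed + i - 1L))
  names(curves) <- vapply(curves, `[[`, character(1), "label")
  truth <- spec$conditions
  truth$model <- spec$model
  truth$seed <- seed + seq_len(n) - 1L
  list(curves = curves, truth = truth)
}
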