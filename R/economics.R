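#' Techno-economic scenario for a batch dryer
#'
#' Cost assumptions for the payback analysis of a small batch dryer. Defaults
#' are the assumption set of the case study this package was built around
#' (300 USD dryer amortized over 20 years at 3% interest, 2.5% inflation,
#' maintenance 3% and salvage 8% of the annual capital cost, 2 kg batches,
#' 350 drying days/year with 600 effective drying minutes/day, fresh leaves
#' at 2 USD/kg, dried product selling at 5 USD/kg).
#'
#' @param capital_cost dryer capital cost, USD.
#' @param interest annual interest rate, fraction.
#' @param inflation annual inflation rate, fraction.
#' @param lifespan dryer operating life, years (>= 1).
#' @param maintenance_frac annual maintenance as a fraction of the annual
#'   capital cost.
#' @param salvage_frac annual salvage value as a fraction of the annual
#'   capital cost.
#' @param batch_mass dried product per batch, kg.
#' @param fresh_mass optional fresh mass loaded per batch, kg; when given, the
#'   dried-product cost is built from the fresh-leaf price chain instead of
#'   `dried_cost`.
#' @param fresh_price fresh-leaf price, USD/kg.
#' @param selling_price dried-leaf selling price, USD/kg.
#' @param dried_cost direct cost of one kg of dried leaves, USD/kg, used when
#'   `fresh_mass` is not supplied (condition-independent convention).
#' @param days_per_year operating days per year.
#' @param minutes_per_day effective drying minutes per day.
#' @return An object of class `economic_scenario`.
#' @export
economic_scenario <- function(capital_cost = 300, interest = 0.03,
                              inflation = 0.025, lifespan = 20,
                              maintenance_frac = 0.03, salvage_frac = 0.08,
                              batch_mass = 2, fresh_mass = NULL,
                              fresh_price = 2, selling_price = 5,
                              dried_cost = 4.25,
                              days_per_year = 350, minutes_per_day = 600) {
  if (interest < 0 || interest >= 1) stop("interest must be a fraction in [0, 1)")
  if (inflation < 0 || inflation >= 1) stop("inflation must be a fraction in [0, 1)")
  if (lifespan < 1) stop("lifespan must be >= 1 year")
  if (capital_cost <= 0 || batch_mass <= 0 || selling_price <= 0 ||
      days_per_year <= 0 || minutes_per_day <= 0)
    stop("capital cost, masses, prices and times must be positive")
  structure(
    list(capital_cost = capital_cost, interest = interest,
         inflation = inflation, lifespan = lifespan,
         maintenance_frac = maintenance_frac, salvage_frac = salvage_frac,
         batch_mass = batch_mass, fresh_mass = fresh_mass,
         fresh_price = fresh_price, selling_price = selling_price,
         dried_cost = dried_cost, days_per_year = days_per_year,
         minutes_per_day = minutes_per_day),
    class = "economic_scenario")
}

#' Capital recovery factor
#'
#' Annuity factor `F_c = d (1+d)^tau / ((1+d)^tau - 1)` converting a capital
#' cost into an equal annual payment at interest rate `d` over `tau` years.
#' At `d = 0` the limit `1/tau` is returned.
#'
#' @param d annual interest rate, fraction (>= 0).
#' @param tau lifespan in years (>= 1).
#' @return The recovery factor.
#' @examples
#' capital_recovery_factor(0.03, 20) # 0.067216
#' @export
capital_recovery_factor <- function(d, tau) {
  if (d < 0) stop("interest rate must be non-negative")
  if (tau < 1) stop("lifespan must be >= 1 year")
  if (d == 0) return(1 / tau)
  d * (1 + d)^tau / ((1 + d)^tau - 1)
}

#' Annualized dryer costs
#'
#' Annual capital cost `C_ac = C_cc * F_c`, maintenance and salvage as
#' scenario fractions of `C_ac`, and the annualized investment cost
#' `C_a = C_ac + C_m - V_a`.
#'
#' @param scenario an [economic_scenario()].
#' @return List with `F_c`, `C_ac`, `C_m`, `V_a`, `C_a` (USD/year).
#' @export
annual_costs <- function(scenario) {
  stopifnot(inherits(scenario, "economic_scenario"))
  F_c <- capital_recovery_factor(scenario$interest, scenario$lifespan)
  C_ac <- scenario$capital_cost * F_c
  C_m <- scenario$maintenance_frac * C_ac
  V_a <- scenario$salvage_frac * C_ac
  list(F_c = F_c, C_ac = C_ac, C_m = C_m, V_a = V_a, C_a = C_ac + C_m - V_a)
}

#' Annual dried-product throughput
#'
#' Batches per day times batch mass times operating days:
#' `M_y = (minutes_per_day / batch_time) * batch_mass * days_per_year`.
#' Fractional batches per day are allowed.
#'
#' @param batch_mass dried product per batch, kg.
#' @param batch_time drying time of one batch, minutes (> 0).
#' @param minutes_per_day effective drying minutes per day.
#' @param days_per_year operating days per year.
#' @return Annual throughput, kg/year.
#' @examples
#' annual_throughput(2, 90, 600, 350) # 4666.7 kg/yr
#' @export
annual_throughput <- function(batch_mass, batch_time, minutes_per_day = 600,
                              days_per_year = 350) {
  if (batch_time <= 0) stop("batch_time must be positive")
  (minutes_per_day / batch_time) * batch_mass * days_per_year
}

#' Unit cost chain and per-kg savings
#'
#' Drying cost per kg `C_s = C_a / M_y`; dried-product cost
#' `C_ds = C_dp + C_s` with `C_dp = fresh_price * fresh_mass / batch_mass`
#' when the fresh load is known, otherwise the scenario's direct `dried_cost`;
#' savings per kg `S_kg = selling_price - C_ds`.
#'
#' @param scenario an [economic_scenario()].
#' @param C_a annualized investment cost, USD/year.
#' @param M_y annual throughput, kg/year (> 0).
#' @return List with `C_s`, `C_dp` (NA under the direct convention), `C_ds`,
#'   `S_kg` and a `loss_making` flag (TRUE when `S_kg < 0`).
#' @export
unit_costs <- function(scenario, C_a, M_y) {
  stopifnot(inherits(scenario, "economic_scenario"))
  if (M_y <= 0) stop("M_y must be positive")
  C_s <- C_a / M_y
  if (!is.null(scenario$fresh_mass)) {
    C_dp <- scenario$fresh_price * scenario$fresh_mass / scenario$batch_mass
    C_ds <- C_dp + C_s
  } else {
    C_dp <- NA_real_
    C_ds <- scenario$dried_cost
  }
  S_kg <- scenario$selling_price - C_ds
  if (S_kg < 0) warning("negative per-kg savings: scenario is loss-making")
  list(C_s = C_s, C_dp = C_dp, C_ds = C_ds, S_kg = S_kg,
       loss_making = S_kg < 0)
}

#' Savings cascade: per batch, per day, after j years
#'
#' `S_b = S_kg * batch_mass`; `S_d = S_b * batches_per_day`;
#' `S_j = S_d * days_per_year * (1 + j)^(j - 1)` (growth factor 1 in the first
#' year).
#'
#' @param S_kg savings per kg of dried product, USD/kg.
#' @param batch_mass dried product per batch, kg.
#' @param batch_time drying time of one batch, minutes.
#' @param minutes_per_day effective drying minutes per day.
#' @param days_per_year operating days per year.
#' @param j year index (integer >= 1).
#' @return List with `S_b` (USD/batch), `S_d` (USD/day), `S_j` (USD in year
#'   j), and `S_1` (first-year savings).
#' @export
savings_cascade <- function(S_kg, batch_mass, batch_time,
                            minutes_per_day = 600, days_per_year = 350,
                            j = 1) {
  if (j < 1 || j != round(j)) stop("j must be a positive integer")
  S_b <- S_kg * batch_mass
  S_d <- S_b * minutes_per_day / batch_time
  S_1 <- S_d * days_per_year
  list(S_b = S_b, S_d = S_d, S_1 = S_1,
       S_j = S_1 * (1 + j)^(j - 1))
}

#' Inflation-adjusted payback period
#'
#' `T = ln(1 - (C_cc / S_1)(d - i)) / ln((1 + i) / (1 + d))` years; reduces to
#' the simple ratio `C_cc / S_1` as `d -> i` (used as the fallback when
#' `d == i`). Errors when the log argument is non-positive (savings never
#' recover the capital).
#'
#' @param capital_cost dryer capital cost, USD.
#' @param S_1 first-year savings, USD (> 0).
#' @param d interest rate, fraction.
#' @param i inflation rate, fraction.
#' @return List with `years` and `months` (= 12 * years).
#' @examples
#' payback_period(300, 3500, 0.03, 0.025) # 0.088 yr, about 1.06 months
#' @export
payback_period <- function(capital_cost, S_1, d, i) {
  if (S_1 <= 0) stop("S_1 must be positive")
  if (d == i) {
    yrs <- capital_cost / S_1
    return(list(years = yrs, months = 12 * yrs, method = "simple_ratio"))
  }
  arg <- 1 - (capital_cost / S_1) * (d - i)
  if (arg <= 0) stop("savings never recover the capital cost (log argument <= 0)")
  yrs <- log(arg) / log((1 + i) / (1 + d))
  list(years = yrs, months = 12 * yrs, method = "discounted")
}

#' Full techno-economic evaluation of one drying condition
#'
#' Runs the whole chain — annualized costs, throughput, unit costs, savings
#' cascade, payback — for one batch drying time under a scenario.
#'
#' @param scenario an [economic_scenario()].
#' @param batch_time drying time of one batch, minutes.
#' @return An object of class `economic_result` collecting every intermediate
#'   (annual costs, `M_y`, unit costs, savings, payback).
#' @export
evaluate_economics <- function(scenario, batch_time) {
  ac <- annual_costs(scenario)
  M_y <- annual_throughput(scenario$batch_mass, batch_time,
                           scenario$minutes_per_day, scenario$days_per_year)
  uc <- unit_costs(scenario, ac$C_a, M_y)
  sv <- savings_cascade(uc$S_kg, scenario$batch_mass, batch_time,
                        scenario$minutes_per_day, scenario$days_per_year)
  pb <- payback_period(scenario$capital_cost, sv$S_1,
                       scenario$interest, scenario$inflation)
  structure(
    c(ac, list(M_y = M_y), uc, sv,
      list(payback_years = pb$years, payback_months = pb$months,
           batch_time = batch_time, scenario = scenario)),
    class = "economic_result")
}

#' @export
print.economic_result <- function(x, ...) {
  cat("Batch-dryer economics\n")
  cat(sprintf("  annual capital cost C_ac  : %8.2f USD/yr\n", x$C_ac))
  cat(sprintf("  maintenance C_m           : %8.2f USD/yr\n", x$C_m))
  cat(sprintf("  salvage V_a               : %8.2f USD/yr\n", x$V_a))
  cat(sprintf("  annualized investment C_a : %8.2f USD/yr\n", x$C_a))
  cat(sprintf("  throughput M_y            : %8.1f kg/yr (batch %g min)\n",
              x$M_y, x$batch_time))
  cat(sprintf("  drying cost C_s           : %8.5f USD/kg\n", x$C_s))
  cat(sprintf("  savings S_kg              : %8.2f USD/kg\n", x$S_kg))
  cat(sprintf("  first-year savings S_1    : %8.2f USD\n", x$S_1))
  cat(sprintf("  payback                   : %8.3f yr (%.2f months)\n",
              x$payback_years, x$payback_months))
  invisible(x)
}
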