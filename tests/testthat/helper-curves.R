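# Shared fixtures: small curves built in code.

# A noiseless single-exponential curve expressed directly as a moisture-ratio
# trace (no weights), for log-domain and diffusivity identities.
make_exp_mr_curve <- function(k, A = 1, t_max = 510, by = 15,
                              temp_C = 60, pressure_kPa = -10) {
  t <- seq(0, t_max, by = by)
  drying_curve(
    times = t, moisture_ratio = A * exp(-k * t),
    conditions = drying_conditions(temp_C, pressure_kPa, 0.01, 0.855, 0.134),
    label = sprintf("exp_k%g", k))
}

# A noiseless Page curve as a moisture-ratio trace.
make_page_mr_curve <- function(k, n, t_max = 510, by = 15) {
  t <- seq(0, t_max, by = by)
  drying_curve(
    times = t, moisture_ratio = exp(-k * t^n),
    conditions = drying_conditions(50, -5, 0.01, 0.855, 0.134),
    label = sprintf("page_k%g_n%g", k, n))
}

# Generator spec for a single Page condition with configurable noise.
single_page_spec <- function(k, n = 1, noise_sd_g = 0) {
  generator_spec(
    conditions = data.frame(temp_C = 50, pressure_kPa = -5, k = k, n = n),
    model = "page", noise_sd_g = noise_sd_g)
}

# Weight-domain noise sd equivalent to a given moisture-ratio sd, for the
# default 100 g / 85.5% wb / 13.4% wb sample.
mr_noise_to_weight_sd <- function(mr_sd) {
  dry <- 100 * (1 - 0.855)
  m0 <- 0.855 / (1 - 0.855)
  me <- 0.134 / (1 - 0.134)
  mr_sd * dry * (m0 - me)
}

# Brute-force grid-search SSE minimizer for the Page model: box scan refined
# twice around the incumbent. The recentred window keeps +-4 grid steps so the
# incumbent can travel along the correlated (k, n) valley while refining.
# Independent of the package optimizer.
page_grid_search_sse <- function(t, y, k_range = c(1e-4, 0.2),
                                 n_range = c(0.3, 2), steps = 81,
                                 refinements = 2) {
  best <- c(k = NA, n = NA, sse = Inf)
  for (r in 0:refinements) {
    ks <- seq(k_range[1], k_range[2], length.out = steps)
    ns <- seq(n_range[1], n_range[2], length.out = steps)
    for (k in ks) for (n in ns) {
      sse <- sum((y - exp(-k * t^n))^2)
      if (sse < best["sse"]) best <- c(k = k, n = n, sse = sse)
    }
    dk <- 4 * diff(k_range) / (steps - 1)
    dn <- 4 * diff(n_range) / (steps - 1)
    k_range <- c(max(best[["k"]] - dk, 1e-6), best[["k"]] + dk)
    n_range <- c(max(best[["n"]] - dn, 0.05), best[["n"]] + dn)
  }
  best
}
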