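## The thin-layer model bank. Each entry: closed form MR(t; theta), parameter
## names, default initializer (given a log-linear k seed) and box bounds.
## Bounds keep MR physically decaying without excluding published estimates
## (k2 of Aghbashlo may legitimately be negative).

.MODEL_BANK <- list(
  aghbashlo = list(
    params = c("k1", "k2"),
    fn = function(t, p) exp(-p[["k1"]] * t / (1 + p[["k2"]] * t)),
    init = function(k0) c(k1 = k0, k2 = 0.001),
    lower = c(k1 = 1e-8, k2 = -Inf),
    upper = c(k1 = Inf, k2 = Inf)),
  logarithmic = list(
    params = c("a", "k", "c"),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t) + p[["c"]],
    init = function(k0) c(a = 1, k = k0, c = 0),
    lower = c(a = 1e-8, k = 1e-8, c = -Inf),
    upper = c(a = 2, k = Inf, c = Inf)),
  midilli = list(
    params = c("a", "k", "n", "b"),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t^p[["n"]]) + p[["b"]] * t,
    init = function(k0) c(a = 1, k = k0, n = 1, b = 0),
    lower = c(a = 1e-8, k = 1e-8, n = 0.05, b = -Inf),
    upper = c(a = 2, k = Inf, n = 5, b = Inf)),
  modified_midilli_1 = list(
    params = c("k", "n", "b"),
    fn = function(t, p) exp(-p[["k"]] * t^p[["n"]]) + p[["b"]] * t,
    init = function(k0) c(k = k0, n = 1, b = 0),
    lower = c(k = 1e-8, n = 0.05, b = -Inf),
    upper = c(k = Inf, n = 5, b = Inf)),
  modified_midilli_2 = list(
    params = c("a", "k", "n", "b"),
    fn = function(t, p) p[["a"]] * exp(-p[["k"]] * t^p[["n"]]) + p[["b"]],
    init = function(k0) c(a = 1, k = k0, n = 1, b = 0),
    lower = c(a = 1e-8, k = 1e-8, n = 0.05, b = -Inf),
    upper = c(a = 2, k = Inf, n = 5, b = Inf)),
  page = list(
    params = c("k", "n"),
    fn = function(t, p) exp(-p[["k"]] * t^p[["n"]]),
    init = function(k0) c(k = k0, n = 1),
    lower = c(k = 1e-8, n = 0.05),
    upper = c(k = Inf, n = 5)),
  wang_singh = list(
    params = c("b", "a"),
    fn = function(t, p) 1 + p[["b"]] * t + p[["a"]] * t^2,
    init = function(k0) c(b = -k0, a = k0^2 / 4),
    lower = c(b = -Inf, a = -Inf),
    upper = c(b = Inf, a = Inf)),
  weibullian = list(
    params = c("alpha", "beta"),
    fn = function(t, p) exp(-(t / p[["alpha"]])^p[["beta"]]),
    init = function(k0) c(alpha = 1 / k0, beta = 1),
    lower = c(alpha = 1e-8, beta = 0.05),
    upper = c(alpha = Inf, beta = 5)),
  weibullian_1 = list(
    params = c("delta", "n"),
    fn = function(t, p) 10^(-(t / p[["delta"]])^p[["n"]]),
    init = function(k0) c(delta = log(10) / k0, n = 1),
    lower = c(delta = 1e-8, n = 0.05),
    upper = c(delta = Inf, n = 5))
)

#' Names of the thin-layer models in the bank
#' @return Character vector of the nine model identifiers.
#' @export
thinlayer_models <- function() names(.MODEL_BANK)

.get_model <- function(model) {
  if (!model %in% names(.MODEL_BANK))
    stop("unknown thin-layer model: ", model,
         " (see thinlayer_models())")
  .MODEL_BANK[[model]]
}

#' Evaluate a thin-layer model
#'
#' Closed-form moisture ratio MR(t) for one of the nine bank models, e.g.
#' `exp(-k t^n)` for Page or `exp(-(t/alpha)^beta)` for the Weibullian form.
#'
#' @param model model identifier, one of [thinlayer_models()].
#' @param params named numeric vector of the model's parameters.
#' @param t times in minutes (vectorized), `t >= 0`.
#' @return Predicted moisture ratio at `t`.
#' @examples
#' predict_mr("page", c(k = 0.02139, n = 0.80779), c(0, 60, 300))
#' @export
predict_mr <- function(model, params, t) {
  spec <- .get_model(model)
  if (any(t < 0)) stop("t must be non-negative")
  missing <- setdiff(spec$params, names(params))
  if (length(missing))
    stop("missing parameter(s) for ", model, ": ",
         paste(missing, collapse = ", "))
  p <- as.list(params)
  if (model == "weibullian" && p$alpha <= 0) stop("alpha must be positive")
  if (model == "weibullian_1" && p$delta <= 0) stop("delta must be positive")
  spec$fn(t, p)
}

#' Goodness-of-fit statistics with the n - p convention
#'
#' `R2 = 1 - SSE/SST`, `adjR2 = 1 - (1 - R2)(n-1)/(n-p)` and
#' `RMSE = sqrt(SSE/(n-p))` — the residual degrees of freedom are `n - p`
#' (data points minus fitted parameters), not `n`.
#'
#' @param observed observed moisture ratios.
#' @param fitted fitted moisture ratios (same length).
#' @param p number of fitted parameters (`n > p`).
#' @return List with `r2`, `adj_r2`, `rmse`, `sse`, `sst`, `n`, `p`.
#' @export
goodness_of_fit <- function(observed, fitted, p) {
  n <- length(observed)
  if (length(fitted) != n) stop("observed and fitted must have equal length")
  if (n <= p) stop("need more data points than parameters")
  sse <- sum((observed - fitted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("constant observed sequence: R2 undefined (SST = 0)")
  r2 <- 1 - sse / sst
  list(r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
       rmse = sqrt(sse / (n - p)),
       sse = sse, sst = sst, n = n, p = p)
}

#' Log-linear drying-constant fit
#'
#' Fits the single-exponential decay `MR = A exp(-k t)` by ordinary least
#' squares of `ln(MR)` on time; points with `MR <= 0` (equilibrium tail noise)
#' are excluded from the log-domain regression.
#'
#' @param curve a [drying_curve()]; a moisture-ratio trace is derived from the
#'   weights if absent.
#' @return An object of class `exponential_fit`: `k` (1/min), `A`, `r2` of the
#'   log-domain regression, and `n_used` points.
#' @export
fit_drying_constant <- function(curve) {
  curve <- moisture_ratio_series(curve)
  keep <- is.finite(curve$moisture_ratio) & curve$moisture_ratio > 0
  if (sum(keep) < 3) stop("need at least 3 points with MR > 0")
  t <- curve$times[keep]
  y <- log(curve$moisture_ratio[keep])
  fit <- lm(y ~ t)
  structure(
    list(k = -unname(coef(fit)[2]), A = exp(unname(coef(fit)[1])),
         r2 = .lm_r2(fit), n_used = sum(keep)),
    class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential drying-constant fit: k = %.4g 1/min, A = %.4g, R2 = %.4f (%d points)\n",
              x$k, x$A, x$r2, x$n_used))
  invisible(x)
}

#' Fit a thin-layer model to a drying curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of one bank model to the
#' curve's moisture-ratio trace. The rate constant is seeded from
#' [fit_drying_constant()]; shape parameters start at their pure-exponential
#' values, and up to `n_start - 1` jittered restarts guard against local
#' minima. Standard errors come from the Jacobian-based covariance at the
#' optimum; p-values are two-sided t tests on `n - p` degrees of freedom, and
#' fit metrics follow the `n - p` convention of [goodness_of_fit()].
#'
#' @param curve a [drying_curve()].
#' @param model model identifier, one of [thinlayer_models()].
#' @param n_start number of optimizer starts (first is deterministic).
#' @param seed seed for the jittered restarts.
#' @return An object of class `model_fit`: parameter `estimates`, `se`,
#'   `p_value`, `significant` (at p <= 0.05), the metrics of
#'   [goodness_of_fit()], the `fitted` trace and the data sizes.
#' @export
fit_model <- function(curve, model = "page", n_start = 5, seed = 1) {
  spec <- .get_model(model)
  curve <- moisture_ratio_series(curve)
  t <- curve$times
  y <- curve$moisture_ratio
  keep <- is.finite(y)
  t <- t[keep]; y <- y[keep]
  p_n <- length(spec$params)
  if (length(y) < p_n + 2)
    stop("need at least p + 2 data points to fit ", model)

  k0 <- tryCatch(fit_drying_constant(curve)$k, error = function(e) 0.01)
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.01
  start0 <- spec$init(k0)

  starts <- list(start0)
  if (n_start > 1) {
    rng <- .with_seed(seed, lapply(seq_len(n_start - 1), function(i)
      start0 * exp(rnorm(length(start0), sd = 0.3))))
    ## multiplicative jitter, clamped into the box
    rng <- lapply(rng, function(s) {
      s <- pmax(s, spec$lower + ifelse(is.finite(spec$lower), 1e-9, 0))
      s <- pmin(s, spec$upper - ifelse(is.finite(spec$upper), 1e-9, 0))
      setNames(s, names(start0))
    })
    starts <- c(starts, rng)
  }

  resid_fn <- function(par)
    y - spec$fn(t, as.list(setNames(par, spec$params)))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = unname(s), lower = unname(spec$lower),
        upper = unname(spec$upper), fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("nonlinear fit failed to converge for model '", model,
         "' after ", n_start, " starts")

  est <- setNames(coef(best), spec$params)
  fitted_mr <- spec$fn(t, as.list(est))
  gof <- goodness_of_fit(y, fitted_mr, p_n)

  ## Jacobian-based covariance at the optimum: sigma^2 (J'J)^-1 with
  ## sigma^2 = SSE / (n - p); singular Jacobians leave the SEs undefined
  se <- pv <- setNames(rep(NA_real_, p_n), spec$params)
  vc <- tryCatch({
    jtj <- best$hessian
    solve(jtj) * gof$sse / (gof$n - p_n)
  }, error = function(e) NULL)
  if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
    se[] <- sqrt(diag(vc))
    tt <- est / se
    pv[] <- 2 * pt(abs(tt), df = gof$n - p_n, lower.tail = FALSE)
  }

  structure(
    list(model = model, estimates = est, se = se, p_value = pv,
         significant = !is.na(pv) & pv <= 0.05,
         r2 = gof$r2, adj_r2 = gof$adj_r2, rmse = gof$rmse,
         sse = gof$sse, n = gof$n, p = p_n,
         fitted = fitted_mr, times = t, observed = y,
         label = curve$label),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Thin-layer fit: %s (%d points)\n", x$model, x$n))
  tab <- data.frame(estimate = x$estimates, se = x$se, p_value = x$p_value,
                    signif = ifelse(x$significant, "Sign.", "Insign."))
  print(tab, digits = 5)
  cat(sprintf("RMSE = %.6f, R2 = %.6f, adj R2 = %.6f\n",
              x$rmse, x$r2, x$adj_r2))
  invisible(x)
}

#' Rank fitted thin-layer models
#'
#' Orders fits by ascending RMSE (least error first); ties broken by
#' descending adjusted R2, then by fewer parameters.
#'
#' @param fits list of `model_fit` objects.
#' @return The list reordered, best model first.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("no fits to rank")
  rmse <- vapply(fits, `[[`, numeric(1), "rmse")
  adj <- vapply(fits, `[[`, numeric(1), "adj_r2")
  np <- vapply(fits, `[[`, numeric(1), "p")
  fits[order(rmse, -adj, np)]
}

#' Closed-form Page / Weibull parameter equivalences
#'
#' The Page model `exp(-k t^n)`, the Weibullian `exp(-(t/alpha)^beta)` and the
#' base-10 Weibullian `10^(-(t/delta)^n)` are reparameterizations of the same
#' curve: `beta = n`, `alpha = k^(-1/n)`, `delta = alpha * ln(10)^(1/n)`.
#'
#' @param k Page rate constant (1/min^n), > 0.
#' @param n Page exponent, > 0.
#' @return List with `alpha` (min), `beta`, `delta` (min).
#' @examples
#' page_weibull_equivalents(0.02139, 0.80779) # alpha = 116.70, delta = 327.68
#' @export
page_weibull_equivalents <- function(k, n) {
  if (k <= 0 || n <= 0) stop("k and n must be positive")
  alpha <- k^(-1 / n)
  list(alpha = alpha, beta = n, delta = alpha * log(10)^(1 / n))
}

## evaluate expr with a local RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
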