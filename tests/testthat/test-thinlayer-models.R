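test_that("model bank closed forms evaluate correctly", {
  expect_equal(predict_mr("page", c(k = 0.09174, n = 0.81831), 0), 1)
  expect_equal(predict_mr("weibullian", c(alpha = 116.70, beta = 0.80779),
                          116.70),
               exp(-1), tolerance = 1e-12)
  # Page and Weibullian are the same curve under alpha = k^(-1/n)
  tt <- c(30, 120, 300)
  expect_equal(predict_mr("page", c(k = 0.02139, n = 0.80779), tt),
               predict_mr("weibullian", c(alpha = 116.70, beta = 0.80779), tt),
               tolerance = 1e-3)
  expect_error(predict_mr("nope", c(k = 1), 0), "unknown")
  expect_error(predict_mr("weibullian", c(alpha = -1, beta = 1), 1), "alpha")
  expect_error(predict_mr("page", c(k = 0.01), 1), "missing parameter")
})

test_that("Page/Weibull reparameterizations are exact algebra", {
  eq <- page_weibull_equivalents(0.02139, 0.80779)
  expect_equal(signif(eq$alpha, 4), 116.7)
  expect_equal(signif(eq$delta, 4), 327.7)
  eq2 <- page_weibull_equivalents(0.09174, 0.81831)
  expect_equal(signif(eq2$alpha, 5), 18.526)
  expect_equal(signif(eq2$delta, 4), 51.34)
  eq3 <- page_weibull_equivalents(0.01, 1)
  expect_equal(eq3$alpha, 100)
  expect_equal(eq3$delta, 100 * log(10), tolerance = 1e-12)

  # the three parameterizations trace point-identical curves
  t <- seq(0, 500, by = 10)
  k <- 0.031; n <- 0.84
  eqx <- page_weibull_equivalents(k, n)
  page <- predict_mr("page", c(k = k, n = n), t)
  expect_equal(predict_mr("weibullian",
                          c(alpha = eqx$alpha, beta = eqx$beta), t),
               page, tolerance = 1e-12)
  expect_equal(predict_mr("weibullian_1",
                          c(delta = eqx$delta, n = n), t),
               page, tolerance = 1e-12)
  expect_error(page_weibull_equivalents(-1, 1), "positive")
})

test_that("goodness of fit uses the n - p convention", {
  expect_equal(goodness_of_fit(c(1, .5, 0), c(1, .5, 0), 1)$r2, 1)
  expect_equal(goodness_of_fit(c(1, .5, 0), c(1, .5, 0), 1)$rmse, 0)

  g <- goodness_of_fit(c(1, .5, 0), c(1, .4, 0), 1)
  expect_equal(g$sse, 0.01, tolerance = 1e-12)
  expect_equal(g$rmse, sqrt(0.01 / 2), tolerance = 1e-12)
  expect_equal(g$r2, 1 - 0.01 / 0.5, tolerance = 1e-12)

  # adj R2 arithmetic: n = 10, p = 2, R2 = 0.99 -> 0.98875
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  sst <- sum((y - mean(y))^2)
  f <- y + sqrt(0.01 * sst / 10) * rep(c(1, -1), 5)  # SSE = 0.01 * SST
  g2 <- goodness_of_fit(y, f, 2)
  expect_equal(g2$r2, 0.99, tolerance = 1e-12)
  expect_equal(g2$adj_r2, 1 - 0.01 * 9 / 8, tolerance = 1e-12)
  expect_equal(g2$adj_r2, 0.98875)

  # adding a parameter never increases adj R2 at fixed SSE
  for (p in 1:5) {
    a1 <- goodness_of_fit(y, f, p)$adj_r2
    a2 <- goodness_of_fit(y, f, p + 1)$adj_r2
    expect_lte(a2, a1)
    expect_lte(a2, goodness_of_fit(y, f, p + 1)$r2)
  }
  expect_error(goodness_of_fit(rep(1, 5), rep(1, 5), 1), "SST = 0")
})

test_that("log-linear drying-constant fit recovers exponential parameters", {
  f <- fit_drying_constant(make_exp_mr_curve(0.0164))
  expect_equal(f$k, 0.0164, tolerance = 1e-10)
  expect_equal(f$A, 1, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)

  f2 <- fit_drying_constant(make_exp_mr_curve(0.02, A = 0.95))
  expect_equal(f2$k, 0.02, tolerance = 1e-10)
  expect_equal(f2$A, 0.95, tolerance = 1e-10)

  # MR <= 0 tail points are dropped, finite k returned
  cond <- drying_conditions(40, 0, 0.01, 0.855, 0.134)
  t <- seq(0, 90, 15)
  mr <- c(exp(-0.02 * t[1:5]), 0, -0.001)
  cv <- drying_curve(t, moisture_ratio = mr, conditions = cond)
  f3 <- fit_drying_constant(cv)
  expect_equal(f3$n_used, 5)
  expect_equal(f3$k, 0.02, tolerance = 1e-10)
})

test_that("nonlinear fits recover noiseless truth and its reparameterization", {
  cv <- make_page_mr_curve(0.02, 0.9)
  fp <- fit_model(cv, "page")
  expect_equal(unname(fp$estimates["k"]), 0.02, tolerance = 1e-6)
  expect_equal(unname(fp$estimates["n"]), 0.9, tolerance = 1e-6)
  expect_equal(fp$rmse, 0, tolerance = 1e-7)

  fw <- fit_model(cv, "weibullian")
  expect_equal(unname(fw$estimates["alpha"]), 0.02^(-1 / 0.9),
               tolerance = 1e-4)
  expect_equal(unname(fw$estimates["beta"]), 0.9, tolerance = 1e-5)

  # standard errors and p-values carry the n - p degrees of freedom
  spec <- single_page_spec(0.02, n = 0.9,
                           noise_sd_g = mr_noise_to_weight_sd(0.01))
  fn <- fit_model(generate_curve(spec, 1, seed = 11), "page")
  expect_true(all(is.finite(fn$se)))
  expect_true(all(fn$p_value >= 0 & fn$p_value <= 1))
  expect_true(all(fn$significant))
})

test_that("fitted traces of MR(0) = 1 models start at one", {
  spec <- single_page_spec(0.025, n = 0.85,
                           noise_sd_g = mr_noise_to_weight_sd(0.005))
  cv <- generate_curve(spec, 1, seed = 3)
  for (m in c("page", "weibullian", "weibullian_1", "aghbashlo",
              "wang_singh")) {
    f <- fit_model(cv, m)
    expect_equal(f$fitted[1], 1, tolerance = 1e-9,
                 info = paste("model", m))
  }
})

test_that("optimizer SSE matches a refined grid-search oracle", {
  spec <- single_page_spec(0.03, n = 0.8,
                           noise_sd_g = mr_noise_to_weight_sd(0.01))
  spec$max_time_min <- 420              # <= 30 points
  cv <- generate_curve(spec, 1, seed = 5)
  f <- fit_model(cv, "page")
  oracle <- page_grid_search_sse(f$times, f$observed)
  expect_lt(abs(f$sse - oracle[["sse"]]) / oracle[["sse"]], 0.001)
})

test_that("noisy replicates recover the Page rate constant within its errors", {
  k_true <- 0.02; n_true <- 0.9
  spec <- single_page_spec(k_true, n = n_true,
                           noise_sd_g = mr_noise_to_weight_sd(0.01))
  hits <- 0
  for (i in 1:50) {
    f <- fit_model(generate_curve(spec, 1, seed = 100 + i), "page",
                   n_start = 1)
    if (abs(f$estimates["k"] - k_true) <= 3 * f$se["k"]) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("model ranking prefers low RMSE, then adj R2, then parsimony", {
  mk <- function(model, rmse, adj, p)
    structure(list(model = model, rmse = rmse, adj_r2 = adj, p = p),
              class = "model_fit")
  fits <- list(mk("wang_singh", 0.08, 0.88, 2), mk("page", 0.009, 0.998, 2),
               mk("midilli", 0.009, 0.998, 4))
  r <- rank_models(fits)
  expect_equal(vapply(r, `[[`, character(1), "model"),
               c("page", "midilli", "wang_singh"))
  tie <- rank_models(list(mk("midilli", 0.01, 0.99, 4), mk("page", 0.01, 0.99, 2)))
  expect_equal(tie[[1]]$model, "page")
  expect_equal(rank_models(fits[2])[[1]]$model, "page")
  expect_error(rank_models(list()), "no fits")
})
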