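test_that("dry-basis moisture content follows the gravimetric definition", {
  expect_equal(moisture_content_dry_basis(100, 50), 100)
  expect_equal(moisture_content_dry_basis(50, 50), 0)
  # 100 g sample at 85.5% wet basis: 14.5 g dry matter -> 589.66% db
  expect_equal(moisture_content_dry_basis(100, 14.5), 100 * 85.5 / 14.5,
               tolerance = 1e-12)
  expect_equal(round(moisture_content_dry_basis(100, 14.5), 2), 589.66)
  expect_error(moisture_content_dry_basis(100, 0), "dry_weight")
  expect_error(moisture_content_dry_basis(40, 50), "wet_weight")
})

test_that("moisture basis conversion is exact and round-trips", {
  expect_equal(convert_moisture_basis(0.855, "wb_to_db"), 0.855 / 0.145,
               tolerance = 1e-12)
  expect_equal(round(convert_moisture_basis(0.855, "wb_to_db"), 4), 5.8966)
  expect_equal(convert_moisture_basis(0, "wb_to_db"), 0)
  expect_equal(convert_moisture_basis(1, "db_to_wb"), 0.5)
  wb <- seq(0, 0.99, by = 0.01)
  expect_equal(convert_moisture_basis(convert_moisture_basis(wb, "wb_to_db"),
                                      "db_to_wb"),
               wb, tolerance = 1e-12)
  expect_error(convert_moisture_basis(1, "wb_to_db"), "\\[0, 1\\)")
})

test_that("weight losses are interval differences that conserve total loss", {
  cond <- drying_conditions(40, 0, 0.01, 0.855, 0.134)
  cv <- drying_curve(c(0, 15, 30), weights = c(100, 90, 85), conditions = cond)
  expect_equal(weight_loss_series(cv), c(10, 5))
  expect_equal(sum(weight_loss_series(cv)), 100 - 85)

  flat <- drying_curve(c(0, 15, 30), weights = c(50, 50, 50), conditions = cond)
  expect_equal(weight_loss_series(flat), c(0, 0))

  # closed-form mass balance: 100 g at 85.5% wb dried fully to 13.4% wb
  w_final <- 14.5 / (1 - 0.134)
  cv2 <- drying_curve(c(0, 15, 30), weights = c(100, 40, w_final),
                      conditions = cond)
  expect_equal(sum(weight_loss_series(cv2)), 100 - w_final)
  expect_equal(round(sum(weight_loss_series(cv2)), 2), 83.26)

  mr_only <- drying_curve(c(0, 15), moisture_ratio = c(1, 0.5),
                          conditions = cond)
  expect_error(weight_loss_series(mr_only), "weights")
})

test_that("drying rate converts interval losses to hourly rates", {
  cond <- drying_conditions(60, -10, 0.01, 0.855, 0.134)
  cv <- drying_curve(c(0, 15, 30), weights = c(100, 95, 95), conditions = cond)
  rs <- drying_rate_series(cv)
  expect_equal(rs$rate, c(20, 0))        # 5 g / 0.25 h, then plateau
  expect_equal(rs$midpoint_min, c(7.5, 22.5))
  expect_equal(attr(rs, "unit"), "g/h")

  # exponential decay in the dry basis: first-interval closed form
  k <- 0.0398; dry <- 14.5; m0 <- 0.855 / 0.145
  t <- seq(0, 90, by = 15)
  w <- dry * (1 + m0 * exp(-k * t))
  cve <- drying_curve(t, weights = w, conditions = cond)
  rse <- drying_rate_series(cve, dry_matter = dry)
  expect_equal(rse$rate[1], (1 - exp(-k * 15)) * m0 / 0.25,
               tolerance = 1e-12)
  expect_equal(attr(rse, "unit"), "g_water/g_dm/h")
})

test_that("rate series integrated over intervals reproduces total loss", {
  spec <- single_page_spec(0.02, n = 0.9, noise_sd_g = 0.3)
  cv <- generate_curve(spec, 1, seed = 7)
  rs <- drying_rate_series(cv)
  dt_h <- diff(cv$times) / 60
  expect_equal(sum(rs$rate * dt_h), cv$weights[1] - cv$weights[length(cv$weights)],
               tolerance = 1e-9)
})

test_that("moisture ratio normalization matches both definitions", {
  # dry-basis contents M0 = 5.897, Me = 0.1547, Mt = 3.0 encoded as weights
  m0 <- 5.897; me <- 0.1547
  cond <- drying_conditions(40, 0, 0.01,
                            initial_moisture_wb = m0 / (1 + m0),
                            equilibrium_moisture_wb = me / (1 + me))
  w <- 1 + c(m0, 3.0, me)               # dry matter = 1 g
  cv <- drying_curve(c(0, 15, 30), weights = w, conditions = cond)

  eq5 <- moisture_ratio_series(cv)
  expect_equal(eq5$moisture_ratio[1], 1, tolerance = 1e-12)
  expect_equal(eq5$moisture_ratio[2], 3.0 / m0, tolerance = 1e-9)
  expect_equal(round(eq5$moisture_ratio[2], 4), 0.5087)

  eq4 <- moisture_ratio_series(cv, use_equilibrium = TRUE)
  expect_equal(eq4$moisture_ratio[2], (3.0 - me) / (m0 - me), tolerance = 1e-9)
  expect_equal(round(eq4$moisture_ratio[2], 4), 0.4955)
  expect_equal(eq4$moisture_ratio[3], 0, tolerance = 1e-9)

  # MR is non-increasing for monotone weight loss
  expect_true(all(diff(eq5$moisture_ratio) <= 0))
})

test_that("curve constructor enforces its invariants", {
  cond <- drying_conditions(40, 0)
  expect_error(drying_curve(c(5, 15), weights = c(2, 1), conditions = cond),
               "start at 0")
  expect_error(drying_curve(c(0, 15, 15), weights = c(3, 2, 1),
                            conditions = cond),
               "strictly increasing")
  expect_error(drying_curve(c(0, 15), conditions = cond), "at least one")
  expect_error(drying_conditions(40, 0, initial_moisture_wb = 1.2), "wet-basis")
  expect_error(drying_conditions(40, 0, initial_moisture_wb = 0.5,
                                 equilibrium_moisture_wb = 0.6),
               "below initial")
})
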