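test_that("time ratios follow their definitions and bounds", {
  expect_equal(waiting_time_ratio(2, 2), 0)
  expect_equal(waiting_time_ratio(2, 1), 0.5)
  expect_equal(waiting_time_ratio(0.5, 2), -3)
  expect_equal(service_time_ratio(2, c(2, 3, 1)), c(0, 0.5, -0.5))

  expect_error(waiting_time_ratio(0, 1), class = "eslqueue_domain_error")
  expect_error(waiting_time_ratio(-2, 1), class = "eslqueue_domain_error")
  expect_error(waiting_time_ratio(2, -1), class = "eslqueue_domain_error")
  expect_error(service_time_ratio(0, 1), class = "eslqueue_domain_error")

  # universal bounds: delta_p <= 1, delta_s >= -1, with equality iff the
  # actual time is zero
  set.seed(11)
  expected <- runif(500, 0.01, 10)
  actual <- runif(500, 0, 20)
  expect_true(all(waiting_time_ratio(expected, actual) <= 1))
  expect_true(all(service_time_ratio(expected, actual) >= -1))
  expect_equal(waiting_time_ratio(expected, 0), rep(1, 500))
  expect_equal(service_time_ratio(expected, 0), rep(-1, 500))
})

test_that("staff satisfaction curve matches its published coefficients", {
  expect_identical(staff_satisfaction(0, published), 0.95)
  expect_equal(staff_satisfaction(-0.5, published), 0.404884, tolerance = 1e-6)
  expect_equal(staff_satisfaction(3, published), -1.080016, tolerance = 1e-6)
})

test_that("staff curve second term is an even nonpositive penalty with slopes +/- a2", {
  set.seed(21)
  for (i in 1:20) {
    p <- staff_params(a1 = runif(1, -1, 1), b1 = runif(1, 0.2, 5),
                      a2 = runif(1, 0.1, 2), b2 = -runif(1, 0.2, 8),
                      c = runif(1))
    x <- seq(-3, 3, length.out = 61)
    second <- p$a2 * x * tanh(p$b2 * x)
    expect_true(all(second <= 0))
    expect_equal(second, rev(second))  # even
    # asymptotic slope of the full curve by finite differences at |x| = 50
    slope_hi <- (staff_satisfaction(50.5, p) - staff_satisfaction(49.5, p))
    slope_lo <- (staff_satisfaction(-49.5, p) - staff_satisfaction(-50.5, p))
    expect_equal(slope_hi, -p$a2, tolerance = 1e-6)
    expect_equal(slope_lo, p$a2, tolerance = 1e-6)
  }
})

test_that("patient satisfaction curve is strictly increasing and bounded", {
  expect_equal(patient_satisfaction(0), 0.9002495, tolerance = 1e-6)
  expect_equal(patient_satisfaction(1), 0.999254, tolerance = 1e-6)
  expect_equal(patient_satisfaction(-1), 0.05732418, tolerance = 1e-6)
  expect_gt(patient_satisfaction(1), patient_satisfaction(0))

  set.seed(31)
  for (i in 1:20) {
    a <- runif(1, 0.1, 0.6)
    p <- patient_params(a = a, b = runif(1, 0.5, 6), x0 = runif(1, -1, 1),
                        c = runif(1, 0, 1 - a))
    # strict increase checked where tanh has not saturated to +/-1 in
    # double precision; globally the curve is non-decreasing and bounded
    x <- sort(runif(100, p$x0 - 2 / p$b, p$x0 + 2 / p$b))
    expect_true(all(diff(patient_satisfaction(x, p)) > 0))
    wide <- patient_satisfaction(sort(runif(100, -10, 10)), p)
    expect_true(all(diff(wide) >= 0))
    expect_true(all(wide >= p$c - p$a & wide <= p$c + p$a))
  }
})

test_that("staff peak sits slightly past the ideal and beats the grid oracle", {
  peak <- staff_peak(published)
  # brute-force oracle at step 1e-4
  g <- seq(-2, 2, by = 1e-4)
  u <- staff_satisfaction(g, published)
  expect_equal(peak$delta_s, g[which.max(u)], tolerance = 1e-3)
  expect_equal(peak$level, max(u), tolerance = 1e-8)
  expect_gte(peak$level, staff_satisfaction(0, published))
  expect_lt(max(u), 1)
  expect_gte(max(u), 0.95)

  # even pure-penalty curve peaks exactly at the ideal
  sym <- staff_params(a1 = 0, b1 = 1, a2 = 1, b2 = -1, c = 0)
  expect_equal(staff_peak(sym)$delta_s, 0, tolerance = 1e-6)

  # monotone (non-bell) parameter set has no interior maximum
  expect_error(staff_peak(staff_params(a1 = 1, b1 = 1, a2 = 0, b2 = -1, c = 0)),
               class = "eslqueue_shape_error")
})

test_that("sign canonicalization maps mirrored parameter sets to one representative", {
  flipped <- staff_params(a1 = -0.25, b1 = -1.72, a2 = -0.76, b2 = 4.43,
                          c = 0.95)
  expect_equal(unclass(flipped), unclass(published))
  x <- seq(-2, 2, length.out = 41)
  expect_equal(staff_satisfaction(x, flipped), staff_satisfaction(x, published))
  expect_error(staff_params(a1 = 0.25, b1 = 1.72, a2 = 0.76, b2 = 4.43),
               class = "eslqueue_domain_error")
})
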