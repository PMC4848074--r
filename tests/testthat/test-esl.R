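test_that("total satisfaction is the weighted sum, linear and symmetric", {
  expect_equal(total_satisfaction(1.0, 0.9), 0.95)
  expect_equal(total_satisfaction(0.95, 0.95), 0.95)
  expect_equal(total_satisfaction(0.3, 0.8, satisfaction_weights(1, 0)), 0.3)
  # linearity in each weight and role symmetry
  set.seed(51)
  for (i in 1:10) {
    p <- runif(1); s <- runif(1); w <- runif(1)
    expect_equal(total_satisfaction(p, s, satisfaction_weights(w, 1 - w)),
                 w * p + (1 - w) * s)
    expect_equal(total_satisfaction(p, s, satisfaction_weights(w, 1 - w)),
                 total_satisfaction(s, p, satisfaction_weights(1 - w, w)))
  }
  expect_error(satisfaction_weights(0.6, 0.6), class = "eslqueue_domain_error")
})

test_that("operating points compose the queueing link with both curves", {
  scn <- scenario()  # lambda 0.25/h exponential, ideal 2 h, expected 2 h
  op2 <- build_operating_point(scn, 2)
  expect_equal(op2$delta_s, 0)
  expect_equal(op2$actual_wait_h, 2)
  expect_equal(op2$delta_p, 0)
  expect_equal(op2$staff_level, 0.95)
  expect_equal(op2$patient_level, 0.9002495, tolerance = 1e-6)
  expect_equal(op2$tsl, (0.95 + 0.9002495) / 2, tolerance = 1e-6)

  op1 <- build_operating_point(scn, 1)
  expect_equal(op1$actual_wait_h, 1 / 3)
  expect_equal(op1$delta_p, (2 - 1 / 3) / 2)
  expect_equal(op1$delta_s, -0.5)
  expect_equal(op1$staff_level, 0.404884, tolerance = 1e-6)

  expect_error(build_operating_point(scn, 4), class = "eslqueue_instability")
  expect_error(build_operating_point(scn, 4), regexp = "1/arrival_rate")

  # recomputation is bit-identical (pure function of scenario and service)
  expect_identical(build_operating_point(scn, 1.37),
                   build_operating_point(scn, 1.37))
})

test_that("sweep orders by delta_p with the documented reversed sense", {
  tsc <- sweep_tsc(scenario())
  pts <- tsc$points
  expect_equal(nrow(pts), 400)
  expect_true(!is.unsorted(pts$delta_p))
  # larger delta_p <=> shorter service and shorter wait
  expect_true(all(diff(pts$actual_service_h) < 0))
  expect_true(all(diff(pts$actual_wait_h) < 0))
  expect_true(all(diff(pts$delta_s) < 0))
})

test_that("ESL refinement matches the dense-grid brute-force oracle", {
  scn <- scenario()
  tsc <- sweep_tsc(scn)
  oracle <- dense_grid_esl(scn, step = 1e-4)
  expect_gte(tsc$esl, max(tsc$points$tsl))
  expect_equal(tsc$esl, oracle$esl, tolerance = 1e-6)
  expect_lt(abs(tsc$eop$actual_service_h - oracle$service), 0.01)
  # the EOP sits where both parties are near their best
  expect_lt(abs(tsc$eop$actual_service_h - 2),
            diff(range(tsc$points$actual_service_h)) / (nrow(tsc$points) - 1) + 0.1)
  expect_equal(find_esl(tsc)$esl, tsc$esl, tolerance = 1e-9)
})

test_that("degenerate weights reduce the ESL to one party's optimum", {
  scn <- scenario(weights = satisfaction_weights(1, 0))
  tsc <- sweep_tsc(scn)
  expect_equal(tsc$points$tsl, tsc$points$patient_level)
  expect_gte(tsc$esl, max(tsc$points$patient_level))
  expect_equal(tsc$eop$patient_level, tsc$esl, tolerance = 1e-9)
})

test_that("expectation levels reproduce the qualitative satisfiability story", {
  base <- scenario()
  cmp <- scenario_compare(base, expected_waits = c(0.5, 2, 3))
  expect_equal(nrow(cmp$summary), 3)

  esl_05 <- cmp$summary$esl[cmp$summary$expected_wait_h == 0.5]
  esl_2 <- cmp$summary$esl[cmp$summary$expected_wait_h == 2]
  expect_gt(esl_2, esl_05)

  crv <- split(cmp$curves, cmp$curves$expected_wait_h)
  both_ok <- function(df) any(df$patient_level >= 0.85 & df$staff_level >= 0.85)
  expect_false(both_ok(crv[["0.5"]]))  # 30-min expectation: no joint solution
  expect_true(both_ok(crv[["2"]]))     # 2-h expectation: both near maximum

  # shorter-than-expected waits are rewarded: on the 3 h curve some point
  # beats the patient level at delta_p = 0
  c3 <- crv[["3"]]
  at0 <- c3$patient_level[which.min(abs(c3$delta_p))]
  expect_gt(max(c3$patient_level), at0)
})

test_that("distance from the ESL is zero at the EOP and positive elsewhere", {
  scn <- scenario()
  tsc <- sweep_tsc(scn)
  at_eop <- distance_from_esl(scn, tsc$eop$actual_service_h)
  expect_equal(at_eop$delta_tsl, 0, tolerance = 1e-8)
  expect_equal(at_eop$delta_service, 0, tolerance = 1e-6)

  away <- distance_from_esl(scn, 1)
  expect_gt(away$delta_tsl, 0)
  expect_gt(away$delta_service, 0)  # staff should slow down

  set.seed(61)
  for (s in runif(5, scn$sweep$min, scn$sweep$max)) {
    expect_gte(distance_from_esl(scn, s)$delta_tsl, 0)
  }
})

test_that("analytic and simulated waits give consistent ESL", {
  scn <- scenario()
  tsc <- sweep_tsc(scn)
  # rebuild the TSL at the EOP using simulated waits instead of the formula
  sys <- mg1_system(scn$arrival_rate,
                    service_dist("exponential", tsc$eop$actual_service_h))
  sim <- simulate_mg1(sys, n_customers = 200000, replications = 5, seed = 3)
  dp <- waiting_time_ratio(scn$expected_wait, sim$mean_wait)
  tsl_sim <- total_satisfaction(patient_satisfaction(dp, scn$patient_params),
                                tsc$eop$staff_level, scn$weights)
  # propagate the CI through the patient curve's local slope
  slope <- scn$patient_params$a * scn$patient_params$b / scn$expected_wait
  tol <- 0.5 * slope * sim$ci99_halfwidth + 1e-6
  expect_lt(abs(tsl_sim - tsc$esl), max(tol, 0.005))
})

test_that("tidy and glance summarize sweeps and comparisons", {
  tsc <- sweep_tsc(scenario())
  expect_identical(tidy(tsc), tsc$points)
  gl <- glance(tsc)
  expect_false(gl$degenerate)
  expect_equal(gl$esl, tsc$esl)

  cmp <- scenario_compare(scenario(), expected_waits = c(1, 2))
  expect_identical(glance(cmp), cmp$summary)
  expect_setequal(unique(tidy(cmp)$expected_wait_h), c(1, 2))
})
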