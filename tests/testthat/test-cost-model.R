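# Deterministic cost algebra: hand-computed oracles, the calibration fixed
# point and the structural invariants of the model.

test_that("conventional treatment cost is rate x duration x uplift", {
  p <- smp_params
  expect_equal(conventional_treatment_cost(p), 19.50 * 0.75 * 1.25)  # 18.28125
  p0 <- p; p0$overhead_rate <- 0
  expect_equal(conventional_treatment_cost(p0), 14.625)
  pz <- p; pz$treatment_duration <- 0
  expect_equal(conventional_treatment_cost(pz), 0)
})

test_that("supervision mean is the share-weighted average of group sizes", {
  expect_equal(supervision_mean(4, 3, 0.0932), 3.0932)
  expect_equal(supervision_mean(4, 3, 1), 4)
  expect_equal(supervision_mean(4, 3, 0), 3)
})

test_that("depreciation spreads capital over lifetime x annual volume", {
  # 152,256 + 7 x 15,767 + 1,096.88 = 263,721.88 over 8 x 5,311 treatments
  expect_equal(depreciation_per_treatment(smp_params, 5311),
               263721.875 / 42488, tolerance = 1e-9)
  expect_equal(round(depreciation_per_treatment(smp_params, 5311), 3), 6.207)
  # inverse proportionality in volume
  expect_equal(depreciation_per_treatment(smp_params, 2 * 5311),
               depreciation_per_treatment(smp_params, 5311) / 2)
  expect_error(depreciation_per_treatment(smp_params, 0), "> 0")
})

test_that("energy component matches the printed inputs", {
  rob <- robotic_treatment_cost(smp_params, smp_profile, 5311)
  expect_equal(rob$energy, 0.36 * 0.28 * 0.75)  # 0.0756
  expect_equal(rob$supervision_mean, 3.0932, tolerance = 1e-4)
  expect_equal(rob$assistant_weight, 0.7351, tolerance = 1e-4)
})

test_that("training cost values lost therapist slots, overhead applied downstream", {
  expect_equal(training_cost_direct(75, 0.75, 19.50), 1096.875)
  expect_equal(round(training_cost_direct(75, 0.75, 19.50) * 1.25, 2), 1371.09)
  expect_equal(training_cost_direct(0, 0.75, 19.50), 0)
})

test_that("calibration back-solves the assistant cost against the anchor", {
  expect_equal(smp_params$assistant_cost_per_assisted_treatment, 1.90,
               tolerance = 0.005)
  # fixed point: the calibrated model's marginal saving equals the anchor
  pd <- partial_derivatives(smp_params, smp_profile)
  expect_equal(unname(pd$partials["R"]), -10.53, tolerance = 1e-6)
  # inconsistent anchor (larger saving than C_T permits) fails loudly
  expect_error(calibrate_assistant_cost(smp_params, smp_profile, -30),
               "calibration failed")
  expect_error(calibrate_assistant_cost(smp_params, smp_profile, 1),
               "negative")
})

test_that("calibrated model reproduces the reference savings", {
  cc <- cycle_costs(smp_params, smp_profile, annual_robotic_treatments = 5311)
  gap <- cc$robotic_treatment_cost - cc$conventional_treatment_cost
  expect_equal(round(gap, 2), -2.77)                       # per treatment
  expect_equal(gap / cc$conventional_treatment_cost, -0.1517,
               tolerance = 0.01)                            # 15.17% saving
  expect_equal(cc$cost_difference, -49.60, tolerance = 0.01 * 49.60)
  expect_equal(cc$cost_difference * 891, -44191.06,
               tolerance = 0.01 * 44191.06)                 # 3-year total
})

test_that("DCost identity and degenerate cases", {
  cc <- cycle_costs(smp_params, smp_profile, 5311)
  expect_equal(cc$cycle_conventional,
               smp_profile$S * cc$conventional_treatment_cost,
               tolerance = 1e-9)
  expect_equal(cc$cycle_mixed,
               smp_profile$T * cc$conventional_treatment_cost +
                 smp_profile$R * cc$robotic_treatment_cost,
               tolerance = 1e-9)
  expect_equal(cc$cost_difference,
               smp_profile$R * (cc$robotic_treatment_cost -
                                  cc$conventional_treatment_cost),
               tolerance = 1e-6)
  # no robotic treatments: mixed equals conventional
  prof0 <- volume_profile(P = 27.67, H = 102, D = 167.33, S = 67.94, R = 0,
                          T = 67.94, p_treat_pct = 0.0932,
                          h_treat_pct = 0.3434)
  cc0 <- cycle_costs(smp_params, prof0, 5311)
  expect_equal(cc0$cost_difference, 0)
})

test_that("DCost identity holds across random valid parameter draws", {
  set.seed(99)
  for (i in 1:25) {
    p <- cost_parameters(
      physio_hourly = runif(1, 10, 40),
      treatment_duration = runif(1, 0.25, 1.5),
      energy_price = runif(1, 0.1, 0.6),
      power_absorption = runif(1, 0.05, 1),
      robot_price = runif(1, 5e4, 3e5),
      maintenance_annual = runif(1, 0, 3e4),
      maintenance_years = sample(0:8, 1),
      training_cost_direct = runif(1, 0, 5000),
      robot_lifetime = runif(1, 3, 12),
      overhead_rate = runif(1, 0, 0.5),
      consumables_per_treatment = runif(1, 0, 2),
      assistant_cost_per_assisted_treatment = runif(1, 0, 10),
      supervised_outpatient = runif(1, 1, 6),
      supervised_inpatient_daycase = runif(1, 1, 5)
    )
    R <- runif(1, 1, 30); T_ <- runif(1, 10, 80)
    P <- runif(1, 5, 60); H <- runif(1, 20, 200); D <- runif(1, 20, 300)
    prof <- volume_profile(P = P, H = H, D = D, S = R + T_, R = R, T = T_)
    vol <- runif(1, 500, 10000)
    cc <- cycle_costs(p, prof, vol)
    expect_equal(cc$cost_difference,
                 R * (cc$robotic_treatment_cost -
                        cc$conventional_treatment_cost),
                 tolerance = 1e-6)
    # overhead linearity: scaling the uplift scales every inclusive cost
    p2 <- p; p2$overhead_rate <- 2 * (1 + p$overhead_rate) - 1
    cc2 <- cycle_costs(p2, prof, vol)
    expect_equal(cc2$conventional_treatment_cost,
                 2 * cc$conventional_treatment_cost, tolerance = 1e-9)
    expect_equal(cc2$robotic_treatment_cost,
                 2 * cc$robotic_treatment_cost, tolerance = 1e-9)
  }
})

test_that("robotic cost decreases in annual volume and in group size", {
  vols <- c(2000, 4000, 8000, 16000)
  costs <- vapply(vols, function(v) {
    robotic_treatment_cost(smp_params, smp_profile, v)$robotic_treatment_cost
  }, numeric(1))
  expect_true(all(diff(costs) < 0))

  p_small <- smp_params
  p_small$supervised_outpatient <- 2
  p_small$supervised_inpatient_daycase <- 1.5
  expect_gt(
    robotic_treatment_cost(p_small, smp_profile, 5311)$robotic_treatment_cost,
    robotic_treatment_cost(smp_params, smp_profile, 5311)$robotic_treatment_cost
  )
})

test_that("C_r - C_T decomposes linearly in reciprocal volume", {
  c_t <- conventional_treatment_cost(smp_params)
  gap_at <- function(v) {
    robotic_treatment_cost(smp_params, smp_profile,
                           v)$robotic_treatment_cost - c_t
  }
  v1 <- 3000; v2 <- 9000
  # fit gap = A + B / v through two volumes, check a third lies on the line
  B <- (gap_at(v1) - gap_at(v2)) / (1 / v1 - 1 / v2)
  A <- gap_at(v1) - B / v1
  expect_equal(gap_at(6000), A + B / 6000, tolerance = 1e-9)
  # the slope is the overhead-inclusive capital spread over the lifetime
  expect_equal(B, 1.25 * 263721.875 / 8, tolerance = 1e-6)
  # and the intercept is the calibration anchor
  expect_equal(A, -10.53, tolerance = 1e-9)
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(cost_parameters(
    physio_hourly = -1, treatment_duration = 0.75, energy_price = 0.36,
    power_absorption = 0.28, robot_price = 1e5, maintenance_annual = 1e4,
    training_cost_direct = 1000, robot_lifetime = 8,
    supervised_outpatient = 4, supervised_inpatient_daycase = 3
  ), "physio_hourly")
  expect_error(cost_parameters(
    physio_hourly = 19.5, treatment_duration = 0.75, energy_price = 0.36,
    power_absorption = 0.28, robot_price = 1e5, maintenance_annual = 1e4,
    training_cost_direct = 1000, robot_lifetime = 0,
    supervised_outpatient = 4, supervised_inpatient_daycase = 3
  ), "robot_lifetime")
  expect_error(cost_parameters(
    physio_hourly = 19.5, treatment_duration = 0.75, energy_price = 0.36,
    power_absorption = 0.28, robot_price = 1e5, maintenance_annual = 1e4,
    training_cost_direct = 1000, robot_lifetime = 8,
    supervised_outpatient = 0.5, supervised_inpatient_daycase = 3
  ), "supervision")
})
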