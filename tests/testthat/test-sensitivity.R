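# Partial derivatives, DIM and the constrained optimization of savings.

test_that("analytic and central-difference derivatives agree at the reference", {
  pd <- partial_derivatives(smp_params, smp_profile)
  rel <- abs(pd$partials - pd$partials_numeric) / abs(pd$partials)
  expect_true(all(rel < 1e-6))
  # marginal saving per robotic treatment is the calibration anchor
  expect_equal(unname(pd$partials["R"]), -10.53, tolerance = 1e-9)
  # all four caseload parameters reduce costs at the reference
  expect_true(all(pd$partials < 0))
})

test_that("derivative agreement holds across random valid models", {
  set.seed(123)
  for (i in 1:20) {
    p <- cost_parameters(
      physio_hourly = runif(1, 10, 40),
      treatment_duration = runif(1, 0.3, 1.2),
      energy_price = 0.36, power_absorption = 0.28,
      robot_price = runif(1, 5e4, 3e5),
      maintenance_annual = runif(1, 0, 2e4),
      training_cost_direct = runif(1, 0, 3000),
      robot_lifetime = runif(1, 4, 12),
      overhead_rate = runif(1, 0, 0.4),
      consumables_per_treatment = runif(1, 0, 1),
      assistant_cost_per_assisted_treatment = runif(1, 0, 8),
      supervised_outpatient = runif(1, 1.5, 6),
      supervised_inpatient_daycase = runif(1, 1, 4)
    )
    r_i <- runif(1, 2, 25)
    prof <- volume_profile(P = runif(1, 5, 60), H = runif(1, 20, 200),
                           D = runif(1, 20, 300), S = 68,
                           R = r_i, T = 68 - r_i)
    pd <- partial_derivatives(p, prof)
    rel <- abs(pd$partials - pd$partials_numeric) / pmax(abs(pd$partials),
                                                         1e-12)
    expect_true(all(rel < 1e-6))
  }
})

test_that("boundary profiles are rejected", {
  prof0 <- volume_profile(P = 0, H = 102, D = 167.33, S = 67.94, R = 17.88)
  expect_error(partial_derivatives(smp_params, prof0), "interior")
})

test_that("DIM normalizes printed derivatives into the published importance ranking", {
  dm <- differential_importance(
    partials = c(R = -10.53, P = -0.65, D = -0.43, H = -0.48),
    reference_point = c(R = 17.88, P = 27.67, D = 167.33, H = 102.00),
    reference_dcost = -49.60
  )
  expect_equal(sum(dm$dims), 1, tolerance = 1e-9)
  # published values are rounded to 3 decimals; compare absolutely at that
  # precision (the exact ratio gives 0.5755 / 0.0550 / 0.2199 / 0.1496)
  expect_true(all(abs(unname(dm$dims) -
                        c(0.576, 0.055, 0.219, 0.150)) < 0.0011))
  # elasticity definition
  expect_equal(unname(dm$elasticities["R"]),
               -10.53 * 17.88 / -49.60, tolerance = 1e-12)
  # the dose parameter dominates
  expect_equal(names(which.max(dm$dims)), "R")
})

test_that("DIM is symmetric, scale-invariant and always sums to one", {
  eq <- differential_importance(rep(2, 4), rep(5, 4), reference_dcost = -3)
  expect_equal(unname(eq$dims), rep(0.25, 4))

  set.seed(7)
  for (i in 1:20) {
    partials <- rnorm(4)
    x0 <- runif(4, 1, 200)
    g <- runif(1, -100, -1)
    dm <- differential_importance(partials, x0, g)
    expect_equal(sum(dm$dims), 1, tolerance = 1e-9)
    dm_scaled <- differential_importance(3.7 * partials, x0, g)
    expect_equal(dm_scaled$dims, dm$dims, tolerance = 1e-12)
  }
  expect_error(differential_importance(1:4, 1:4, 0), "nonzero")
})

test_that("the DCost surface is affine in R and flags infeasible cells", {
  cons <- constraint_set()
  surf <- dcost_surface(smp_params, smp_profile,
                        r_grid = seq(2, 30, by = 2),
                        n_grid = c(150, 297, 450), constraints = cons)
  # affine in R along fixed n, slope = volume-independent gap (the anchor)
  col <- surf[surf$n == 297, ]
  slopes <- diff(col$dcost) / diff(col$R)
  expect_equal(slopes, rep(-10.53, length(slopes)), tolerance = 1e-9)
  # SMP point lies in the savings region
  smp_val <- dcost_surface(smp_params, smp_profile, r_grid = c(17.88, 18),
                           n_grid = c(296, 297), constraints = cons)
  expect_lt(smp_val$dcost[smp_val$R == 17.88 & smp_val$n == 297], 0)
  # feasibility flags
  expect_true(all(!surf$feasible[surf$R * surf$n > 8250]))
  expect_true(all(!surf$feasible[surf$R / smp_profile$S > 0.35]))
  # break-even boundary has DCost ~ 0
  be <- attr(surf, "break_even")
  expect_true(!is.null(be) && nrow(be) >= 1)
  frac <- c(P = smp_profile$P, D = smp_profile$D, H = smp_profile$H) /
    smp_profile$n
  for (i in seq_len(nrow(be))) {
    v <- dcost_surface(smp_params, smp_profile,
                       r_grid = c(be$R_break_even[i],
                                  be$R_break_even[i] + 1e-6),
                       n_grid = be$n[i], constraints = cons)$dcost[1]
    expect_lt(abs(v), 0.05)
  }
})

test_that("surface decreases in n at fixed R in the savings regime", {
  surf <- dcost_surface(smp_params, smp_profile, r_grid = c(10, 17.88, 23),
                        n_grid = seq(150, 500, by = 50))
  for (r in unique(surf$R)) {
    expect_true(all(diff(surf$dcost[surf$R == r]) < 0))
  }
})

test_that("constrained optimization reproduces the published optima", {
  o1 <- optimize_savings(smp_params, smp_profile,
                         scenario = "increase_R_only")
  expect_equal(o1$r_star, 0.35 * 67.94, tolerance = 1e-12)  # 23.78
  expect_equal(o1$n_star, 297)
  expect_equal(o1$dcost_at_optimum, -111.70, tolerance = 0.01 * 111.70)
  expect_identical(o1$binding_constraints, "clinical")

  o2 <- optimize_savings(smp_params, smp_profile,
                         scenario = "increase_R_and_n")
  expect_equal(o2$r_star, 23.78, tolerance = 0.001)
  expect_equal(o2$n_star, 346.93, tolerance = 0.02)
  expect_equal(o2$r_star * o2$n_star, 8250, tolerance = 1e-9)
  expect_equal(o2$dcost_at_optimum, -131.68, tolerance = 0.01 * 131.68)

  # optima are feasible and improve on the reference saving
  ref <- cycle_costs(smp_params, smp_profile, 5311)$cost_difference
  for (o in list(o1, o2)) {
    expect_lte(o$r_star * o$n_star, 8250 + 1e-6)
    expect_lte(o$r_star / smp_profile$S, 0.35 + 1e-9)
    expect_lt(o$dcost_at_optimum, ref)
  }
  expect_lt(o2$dcost_at_optimum, o1$dcost_at_optimum)
})

test_that("already-binding constraints return the current point", {
  cons <- constraint_set(max_annual_robotic = 17.88 * 297,
                         max_robotic_fraction = 17.88 / 67.94)
  o <- optimize_savings(smp_params, smp_profile, cons,
                        scenario = "increase_R_and_n")
  expect_equal(o$r_star, 17.88, tolerance = 1e-9)
  expect_equal(o$n_star, 297, tolerance = 1e-9)
  expect_equal(o$dcost_at_optimum,
               cycle_costs(smp_params, smp_profile,
                           17.88 * 297)$cost_difference,
               tolerance = 1e-9)
})
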