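test_that("period estimation recovers a known analytic period", {
  t <- seq(0, 600, by = 0.1)
  tr <- data.frame(time = t, CL_m = 2 + sin(2 * pi * t / 24))
  est <- estimate_period(tr, "CL_m")
  expect_true(est$rhythmic)
  expect_equal(est$period, 24, tolerance = 0.05 / 24)
  expect_equal(classify_rhythmicity(est), "rhythmic")
})

test_that("constant and damped signals classify as arrhythmic", {
  t <- seq(0, 600, by = 0.1)
  flat <- data.frame(time = t, CL_m = rep(1.3, length(t)))
  expect_equal(classify_rhythmicity(estimate_period(flat, "CL_m")),
               "arrhythmic")
  damped <- data.frame(time = t,
                       CL_m = 2 + exp(-t / 40) * sin(2 * pi * t / 24))
  expect_equal(classify_rhythmicity(estimate_period(damped, "CL_m")),
               "arrhythmic")
  expect_error(estimate_period(flat, "nope"), "not in trace")
})

test_that("peak prominence filtering ignores numerical ripple", {
  t <- seq(0, 600, by = 0.1)
  x <- 2 + sin(2 * pi * t / 25) + 1e-4 * sin(2 * pi * t / 0.9)
  est <- estimate_period(data.frame(time = t, CL_m = x), "CL_m")
  expect_true(est$rhythmic)
  expect_equal(est$period, 25, tolerance = 0.05 / 25)
})

test_that("simulation echoes the default initial condition", {
  p <- test_params()
  tr <- pcs_simulate(p, light_constant(0, 0), t_end = 0.5)
  y0 <- as.numeric(tr[1, phytoclock:::.pcs_state_names])
  want <- pcs_initial_state(p)
  expect_equal(y0, unname(want))
  expect_equal(want[["COP1"]], p[["Ctot"]])
  expect_equal(unname(want[c("COP1_PhyA", "COP1_PhyB", "COP1_Cry1", "HYP")]),
               rep(0, 4))
})

test_that("traces are deterministic and structurally sound", {
  p <- test_params()
  prog <- light_photoperiod("6L18D", 26.62, 0)
  tr1 <- pcs_simulate(p, prog, t_end = 72)
  tr2 <- pcs_simulate(p, prog, t_end = 72)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_true(all(diff(tr1$time) > 0))
  expect_false(anyNA(tr1))
  # exact switch times are present in the grid
  expect_true(all(c(6, 24, 30, 48) %in% tr1$time))
  # light columns match the program at every stored time inside the horizon
  inside <- tr1$time < 72
  want <- light_sample(prog, tr1$time[inside])
  expect_equal(tr1$I_red[inside], unname(want[, "I_red"]))
})

test_that("derived totals stay consistent with the stored states", {
  p <- test_params()
  tr <- pcs_simulate(p, light_photoperiod("2L22D", 15, 15), t_end = 96)
  expect_equal(tr$TPhyA, tr$PhyA + tr$COP1_PhyA, tolerance = 1e-12)
  expect_equal(tr$TPhyB, tr$PhyB + tr$COP1_PhyB, tolerance = 1e-12)
  expect_equal(tr$TCry1, tr$Cry1 + tr$COP1_Cry1, tolerance = 1e-12)
})

test_that("trajectories stay non-negative and hypocotyl never shrinks", {
  p <- pcs_params()
  progs <- list(
    light_constant(0, 0),
    light_constant(40, 40),
    light_photoperiod("6L18D", 26.62, 26.62),
    compose_protocol(build_protocol("III", onset = 300), 650),
    compose_protocol(build_protocol("VI", onset = 300), 650))
  for (prog in progs) {
    tr <- pcs_simulate(p, prog, t_end = 620)
    states <- as.matrix(tr[, phytoclock:::.pcs_state_names])
    expect_gt(min(states), -1e-6)
    expect_true(all(diff(tr$HYP) > -1e-9))
  }
})

test_that("period estimates are stable under output-grid refinement", {
  p <- pcs_params()
  tr1 <- pcs_simulate(p, light_constant(0, 0), t_end = 600, dt = 0.1)
  tr2 <- pcs_simulate(p, light_constant(0, 0), t_end = 600, dt = 0.05)
  p1 <- estimate_period(tr1, "CL_m")$period
  p2 <- estimate_period(tr2, "CL_m")$period
  expect_lt(abs(p1 - p2), 0.05)
})

test_that("the clock entrains to a 12L12D photoperiod at 24 h", {
  p <- pcs_params()
  tr <- pcs_simulate(p, light_photoperiod("12L12D", 40, 40), t_end = 600)
  est <- estimate_period(tr, "CL_m", transient_cutoff = 240)
  expect_true(est$rhythmic)
  expect_equal(est$period, 24, tolerance = 0.1 / 24)
})

test_that("the hypocotyl growth rate is bounded by its Hill maximum", {
  p <- test_params()
  tr <- pcs_simulate(p, light_constant(10, 10), t_end = 120)
  rate <- diff(tr$HYP) / diff(tr$time)
  expect_true(all(rate <= p[["g1"]] + p[["g2"]] + 1e-6))
  expect_true(all(rate >= p[["g1"]] - 1e-6))
})
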