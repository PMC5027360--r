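make_const_heat <- function(times, total) {
  out <- data.frame(time_min = times, total = rep(total, length(times)),
                    mw_cal_per_kg_min = 0)
  class(out) <- c("heat_production_series", "data.frame")
  out
}

test_that("equilibrium with no forcing stays at ambient", {
  pr <- thermal_params(Pc = 0, eta_a = 0.02, Ta = 24, T0 = 24)
  heat <- partition_heat(make_const_heat(0:30, 0), 0)
  tr <- simulate_temperatures(pr, heat)
  expect_equal(tr$tc_c, rep(24, 31))
  expect_equal(tr$tm_c, rep(24, 31))
})

test_that("long-time muscle-core gradient equals Pm/eta", {
  pr <- thermal_params(Pc = 0, eta_a = 0.02, eta = 0.125, Ta = 24, T0 = 24)
  heat <- partition_heat(make_const_heat(seq(0, 2000), 0.125), 0,
                         warn_negative = FALSE)
  tr <- simulate_temperatures(pr, heat, times = 2000)
  expect_equal(tr$tm_c - tr$tc_c, 0.125 / 0.125, tolerance = 1e-8)
})

test_that("segment-exact solver matches matrix-exponential and RK4 oracles", {
  set.seed(42)
  max_err_expm <- 0
  max_err_rk4 <- 0
  for (rep in 1:100) {
    p <- random_params()
    total <- runif(31, 0.1, 1.2) # fresh piecewise-constant forcing each draw
    sim <- thermorun:::simulate_tc_grid(p$Pc, p$eta_a, p$eta, p$Ta, p$T0, total)
    orc <- expm_trajectory(p$Pc, p$eta_a, p$eta, p$Ta, p$T0, total)
    max_err_expm <- max(max_err_expm,
                        abs(sim$Tc - orc[, 1]), abs(sim$Tm - orc[, 2]))
    if (rep <= 25) { # RK4 at dt = 0.01 is the slow oracle; subset suffices
      rk <- rk4_trajectory(p$Pc, p$eta_a, p$eta, p$Ta, p$T0, total, h = 0.01)
      max_err_rk4 <- max(max_err_rk4,
                         abs(sim$Tc - rk[, 1]), abs(sim$Tm - rk[, 2]))
    }
  }
  expect_lt(max_err_expm, 1e-8)
  expect_lt(max_err_rk4, 1e-6)
})

test_that("solver handles eta_a = 0 (no dissipation) exactly", {
  total <- rep(0.5, 31)
  sim <- thermorun:::simulate_tc_grid(0.2, 0, 0.125, 24, 37.5, total)
  orc <- expm_trajectory(0.2, 0, 0.125, 24, 37.5, total)
  expect_equal(sim$Tc, orc[, 1], tolerance = 1e-9)
  expect_equal(sim$Tm, orc[, 2], tolerance = 1e-9)
  # without dissipation the summed heat content grows linearly
  expect_equal(sim$Tc[31] + sim$Tm[31], 2 * 37.5 + 30 * 0.5, tolerance = 1e-8)
})

test_that("energy bookkeeping: d(Tc+Tm)/dt = Pc + Pm - eta_a (Tc - Ta)", {
  set.seed(7)
  h <- 1e-4
  for (rep in 1:20) {
    p <- random_params()
    pm <- runif(1, 0, 1)
    x0 <- c(p$T0 + runif(1, -1, 1), p$T0 + runif(1, -1, 1))
    st <- thermorun:::ode_stepper(p$eta, p$eta_a, h)
    b <- c(p$Pc + p$eta_a * p$Ta, pm)
    x1 <- thermorun:::ode_step(st, x0, b)
    lhs <- (sum(x1) - sum(x0)) / h
    rhs <- p$Pc + pm - p$eta_a * (x0[1] - p$Ta)
    expect_equal(lhs, rhs, tolerance = 1e-3)
  }
})

test_that("increasing dissipation never raises core temperature", {
  set.seed(11)
  total <- runif(31, 0.2, 1)
  for (rep in 1:10) {
    p <- random_params()
    T0 <- p$Ta + runif(1, 1, 15) # start above ambient
    lo <- thermorun:::simulate_tc_grid(p$Pc, p$eta_a, p$eta, p$Ta, T0, total)
    hi <- thermorun:::simulate_tc_grid(p$Pc, p$eta_a * 1.5 + 0.005, p$eta,
                                       p$Ta, T0, total)
    expect_true(all(hi$Tc <= lo$Tc + 1e-12))
  }
})

test_that("analytic equilibrium matches long-horizon integration", {
  pr <- thermal_params(Pc = 0.05, eta_a = 0.0156, Ta = 24, T0 = 37.5)
  eq <- equilibrium_temperatures(pr, pm_const = 0.1)
  expect_equal(unname(eq["tc"]), 24 + 0.15 / 0.0156, tolerance = 1e-12)
  expect_equal(unname(eq["tc"]), 33.615, tolerance = 1e-3)
  expect_equal(unname(eq["tm"] - eq["tc"]), 0.1 / 0.125, tolerance = 1e-12)
  expect_equal(equilibrium_temperatures(thermal_params(0, 0.02), 0),
               c(tc = 24, tm = 24))

  heat <- partition_heat(make_const_heat(seq(0, 10000, by = 10), 0.15), 0.05,
                         warn_negative = FALSE)
  tr <- simulate_temperatures(pr, heat, times = 10000)
  expect_equal(tr$tc_c, unname(eq["tc"]), tolerance = 1e-4)
  expect_equal(tr$tm_c, unname(eq["tm"]), tolerance = 1e-4)

  expect_error(equilibrium_temperatures(thermal_params(0.1, 0), 0.1),
               "no equilibrium")
})

test_that("trajectories start at T0 and honor off-grid output times", {
  fx <- make_fixture()
  tr <- fx$truth
  expect_equal(tr$tc_c[1], 37.5)
  expect_equal(tr$tm_c[1], 37.5)
  # half-minute output times agree with a direct half-step of the solver
  mid <- simulate_temperatures(fx$params, partition_heat(fx$heat, 0.25,
                                                         warn_negative = FALSE),
                               times = c(-12, -11.5, -11))
  st <- thermorun:::ode_stepper(0.125, 0.0156, 0.5)
  b <- c(0.25 + 0.0156 * 24, fx$heat$total[1] - 0.25)
  half <- thermorun:::ode_step(st, c(37.5, 37.5), b)
  expect_equal(mid$tc_c[2], half[1], tolerance = 1e-12)
  expect_error(simulate_temperatures(fx$params,
                                     partition_heat(fx$heat, 0.25,
                                                    warn_negative = FALSE),
                                     times = 100), "coverage")
})

test_that("simulate_temperatures guards against a mismatched Pc", {
  fx <- make_fixture()
  heat <- partition_heat(fx$heat, 0.3, warn_negative = FALSE)
  expect_error(simulate_temperatures(fx$params, heat), "different Pc")
  expect_error(simulate_temperatures(fx$params, fx$heat), "partition_heat")
})
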