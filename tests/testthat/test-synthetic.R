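test_that("make_protocol builds the incremental ramp", {
  p1 <- make_protocol(speeds = 10, inclines = 5)
  expect_equal(nrow(p1$stages), 1)
  expect_equal(workload_at(p1, c(0, 5, 10))$speed_m_per_min, rep(10, 3))

  p <- make_protocol()
  expect_equal(nrow(p$stages), ceiling(18 / 3))
  expect_equal(p$stages$start_min[1], 0)
  expect_equal(p$pre_run_start, -12)
  expect_true(all(diff(p$stages$speed_m_per_min) > 0))
  expect_true(all(diff(p$stages$incline_deg) > 0))
  expect_lte(max(p$stages$speed_m_per_min), 26)
  expect_lte(max(p$stages$incline_deg), 20)
  expect_error(make_protocol(speeds = c(1, 2), inclines = 1), "same length")
})

test_that("simulated VO2 is constant pre-run and relaxes first-order", {
  cfg <- cohort_config()
  flat <- treadmill_protocol(0, 0, 0)
  g0 <- simulate_vo2(flat, cfg, times = -12:10)
  expect_equal(g0$vo2_l_per_kg_min, rep(cfg$vo2_baseline, 23))

  prot <- make_protocol(speeds = 20, inclines = 10, run_length = 30)
  g <- simulate_vo2(prot, cfg, times = -12:30)
  pre <- g$time_min < 0
  expect_equal(g$vo2_l_per_kg_min[pre], rep(cfg$vo2_baseline, sum(pre)))
  # step response: 95% of the increment within 3 time constants
  target <- cfg$vo2_baseline +
    cfg$vo2_gain * (20 * tan(10 * pi / 180) + 20)
  t3 <- which(g$time_min >= 3 * cfg$vo2_tau + 1)[1]
  frac <- (g$vo2_l_per_kg_min[t3] - cfg$vo2_baseline) /
    (target - cfg$vo2_baseline)
  expect_gt(frac, 0.95)
  # RER drifts from 0.85 at belt start to 1.0 at the end of the run
  rer <- g$vco2_l_per_kg_min / g$vo2_l_per_kg_min
  expect_equal(rer[g$time_min == 0], 0.85)
  expect_equal(rer[length(rer)], 1.0)
})

test_that("a degenerate cohort collapses to identical rats", {
  cfg <- cohort_config(T0_sd = 0, measurement_sd = 0, rat_sd_Pc = 0,
                       rat_sd_eta_a = 0, exhaustion_threshold_sd = 0, seed = 1)
  coh <- simulate_cohort(thermal_params(0.25, 0.0156), make_protocol(), cfg)
  exh <- vapply(coh$per_rat, `[[`, numeric(1), "exhaustion_time")
  expect_true(all(exh == exh[1]))
  expect_equal(coh$per_rat[[1]]$trajectory$tc_c,
               coh$per_rat[[6]]$trajectory$tc_c)
})

test_that("an infinite threshold lets every rat finish the protocol", {
  cfg <- cohort_config(exhaustion_threshold_mean = Inf, seed = 2)
  prot <- make_protocol()
  coh <- simulate_cohort(thermal_params(0.25, 0.0156), prot, cfg)
  exh <- vapply(coh$per_rat, `[[`, numeric(1), "exhaustion_time")
  expect_true(all(exh == 18))
  expect_equal(nrow(coh$per_rat[[1]]$trajectory), length(seq(-12, 18)))
})

test_that("a threshold below baseline is an immediate-exhaustion error", {
  cfg <- cohort_config(exhaustion_threshold_mean = 37, T0_sd = 0,
                       exhaustion_threshold_sd = 0, seed = 3)
  expect_error(simulate_cohort(thermal_params(0.25, 0.0156), make_protocol(), cfg),
               "exhausted at placement")
})

test_that("higher dissipation delays exhaustion across seeds", {
  prot <- make_protocol(run_length = 30) # long enough that nobody is capped
  later <- 0
  for (s in 1:10) {
    lo <- simulate_cohort(thermal_params(0.25, 0.0156), prot,
                          cohort_config(seed = s))
    hi <- simulate_cohort(thermal_params(0.25, 0.0194), prot,
                          cohort_config(seed = s))
    m_lo <- mean(vapply(lo$per_rat, `[[`, numeric(1), "exhaustion_time"))
    m_hi <- mean(vapply(hi$per_rat, `[[`, numeric(1), "exhaustion_time"))
    later <- later + (m_hi > m_lo)
  }
  expect_equal(later, 10)
})

test_that("cohort generation is deterministic and leaves the RNG alone", {
  cfg <- cohort_config(seed = 17)
  prot <- make_protocol()
  set.seed(1)
  before <- .Random.seed
  a <- simulate_cohort(thermal_params(0.25, 0.0156), prot, cfg)
  expect_identical(.Random.seed, before)
  b <- simulate_cohort(thermal_params(0.25, 0.0156), prot, cfg)
  expect_identical(a$per_rat, b$per_rat)
  expect_identical(a$generating_params, b$generating_params)
})

test_that("aggregation applies the first-dropout truncation rule", {
  cfg <- cohort_config(seed = 5)
  coh <- simulate_cohort(thermal_params(0.25, 0.0156), make_protocol(), cfg)
  # force one rat to drop at t = 13 while the others run longer
  exh <- vapply(coh$per_rat, `[[`, numeric(1), "exhaustion_time")
  stopifnot(min(exh) > 13)
  r1 <- coh$per_rat[[1]]
  keep <- r1$trajectory$time_min <= 13
  coh$per_rat[[1]]$trajectory <- r1$trajectory[keep, ]
  coh$per_rat[[1]]$gas <- r1$gas[r1$gas$time_min <= 13, ]
  coh$per_rat[[1]]$exhaustion_time <- 13
  agg <- suppressMessages(aggregate_group(coh, "saline"))
  expect_equal(max(agg$temperature$time_min), 13)
  expect_equal(agg$temperature$time_min[1], -12)
  expect_identical(attr(agg$temperature, "group_label"), "saline")
  # pre-run group VO2 is flattened to its value at belt start
  pre <- agg$gas$time_min < 0
  expect_true(all(agg$gas$vo2_l_per_kg_min[pre] ==
                    agg$gas$vo2_l_per_kg_min[agg$gas$time_min == 0]))
})

test_that("noiseless aggregation reproduces the model trajectory exactly", {
  cfg <- cohort_config(T0_sd = 0, measurement_sd = 0, rat_sd_Pc = 0,
                       rat_sd_eta_a = 0, exhaustion_threshold_mean = Inf,
                       seed = 8)
  params <- thermal_params(0.25, 0.0156)
  prot <- make_protocol()
  coh <- simulate_cohort(params, prot, cfg)
  agg <- suppressMessages(aggregate_group(coh, "exact"))
  gas <- simulate_vo2(prot, cfg)
  heat <- partition_heat(total_heat_production(gas, prot), 0.25,
                         warn_negative = FALSE)
  ref <- simulate_temperatures(params, heat, agg$temperature$time_min)
  expect_equal(agg$temperature$mean_tc_c, ref$tc_c, tolerance = 1e-12)
  expect_error(aggregate_group(local({
    coh$per_rat <- coh$per_rat[1]
    coh
  })), ">= 2 rats")
})

test_that("baseline temperature draws match their configured distribution", {
  cfg <- cohort_config(n_rats = 100, exhaustion_threshold_mean = Inf, seed = 21)
  coh <- simulate_cohort(thermal_params(0.25, 0.0156), make_protocol(), cfg)
  t0 <- coh$generating_params$T0
  expect_lt(abs(mean(t0) - 37.5), 3 * 0.3 / sqrt(100))
  se_sd <- 0.3 / sqrt(2 * (100 - 1)) # approximate SE of a normal sample SD
  expect_lt(abs(sd(t0) - 0.3), 3 * se_sd)
})
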