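# Independent oracles for the two-compartment system
#   dTc/dt = Pc - eta*(Tc - Tm) - eta_a*(Tc - Ta)
#   dTm/dt = Pm - eta*(Tm - Tc)
# None of these share code with the package's segment-exact solver.

thermo_rhs <- function(x, Pc, pm, eta, eta_a, Ta) {
  c(Pc - eta * (x[1] - x[2]) - eta_a * (x[1] - Ta),
    pm - eta * (x[2] - x[1]))
}

# Classical fixed-step RK4 across one forcing segment.
rk4_segment <- function(x, dt_total, h, Pc, pm, eta, eta_a, Ta) {
  n_steps <- round(dt_total / h)
  stopifnot(abs(n_steps * h - dt_total) < 1e-9)
  for (s in seq_len(n_steps)) {
    k1 <- thermo_rhs(x, Pc, pm, eta, eta_a, Ta)
    k2 <- thermo_rhs(x + h / 2 * k1, Pc, pm, eta, eta_a, Ta)
    k3 <- thermo_rhs(x + h / 2 * k2, Pc, pm, eta, eta_a, Ta)
    k4 <- thermo_rhs(x + h * k3, Pc, pm, eta, eta_a, Ta)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# RK4 trajectory on the 1-min grid under sample-and-hold forcing.
rk4_trajectory <- function(Pc, eta_a, eta, Ta, T0, total, h = 0.01) {
  n <- length(total)
  out <- matrix(NA_real_, n, 2)
  x <- c(T0, T0)
  out[1, ] <- x
  for (k in seq_len(n - 1)) {
    x <- rk4_segment(x, 1, h, Pc, total[k] - Pc, eta, eta_a, Ta)
    out[k + 1, ] <- x
  }
  out
}

# Matrix-exponential oracle: augment the affine system to a 3x3 linear one,
#   d/dt (Tc, Tm, 1) = [[A, b], [0, 0]] (Tc, Tm, 1),
# and propagate with Matrix::expm. Handles eta_a = 0 (singular A) too.
expm_trajectory <- function(Pc, eta_a, eta, Ta, T0, total, dt = 1) {
  A <- matrix(c(-(eta + eta_a), eta, eta, -eta), 2, 2, byrow = TRUE)
  n <- length(total)
  out <- matrix(NA_real_, n, 2)
  x <- c(T0, T0)
  out[1, ] <- x
  for (k in seq_len(n - 1)) {
    b <- c(Pc + eta_a * Ta, total[k] - Pc)
    M <- rbind(cbind(A, b), c(0, 0, 0))
    E <- as.matrix(Matrix::expm(M * dt))
    x <- (E %*% c(x, 1))[1:2]
    out[k + 1, ] <- x
  }
  out
}

# Naive, loop-based Gaussian log-likelihood (no shared code with
# make_log_likelihood beyond calling the public trajectory simulator).
naive_log_likelihood <- function(Pc, eta_a, data, gas, protocol, constants) {
  T0 <- if (is.null(constants$T0)) baseline_t0(data) else constants$T0
  pr <- thermal_params(Pc, eta_a, constants$eta, constants$Ta, T0,
                       constants$specific_heat)
  heat <- total_heat_production(gas, protocol, constants$specific_heat)
  heat <- partition_heat(heat, Pc, warn_negative = FALSE)
  tr <- simulate_temperatures(pr, heat, data$time_min)
  acc <- 0
  for (i in seq_len(nrow(data))) {
    acc <- acc - 0.5 * (data$mean_tc_c[i] - tr$tc_c[i])^2 / data$sd_tc_c[i]^2
  }
  acc
}

# Shared fixture: a protocol, a gas series on its grid, and a noiseless
# model-generated group series at given parameters.
make_fixture <- function(Pc = 0.25, eta_a = 0.0156, eta = 0.125, Ta = 24,
                         T0 = 37.5, n_points = 28, noise_sd = 0,
                         sigma = 0.25, seed = NULL, label = "group") {
  prot <- make_protocol()
  gas_full <- simulate_vo2(prot, cohort_config())
  times <- seq(-12, -12 + n_points - 1)
  gi <- match(times, gas_full$time_min)
  gas <- gas_exchange_series(times, gas_full$vo2_l_per_kg_min[gi],
                             gas_full$vco2_l_per_kg_min[gi])
  heat <- total_heat_production(gas, prot)
  pr <- thermal_params(Pc, eta_a, eta, Ta, T0)
  traj <- simulate_temperatures(pr, partition_heat(heat, Pc, warn_negative = FALSE),
                                times)
  tc <- traj$tc_c
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    }
    tc <- tc + stats::rnorm(length(tc), 0, noise_sd)
  }
  data <- suppressMessages(group_temperature_series(
    times, tc, rep(sigma, length(times)), group_label = label, n_rats = 6))
  list(protocol = prot, gas = gas, data = data, truth = traj,
       params = pr, heat = heat)
}

# Random admissible parameter draw for property tests.
random_params <- function() {
  list(Pc = stats::runif(1, 0, 0.6),
       eta_a = stats::runif(1, 0.001, 0.08),
       eta = stats::runif(1, 0.05, 0.3),
       Ta = stats::runif(1, 10, 30),
       T0 = stats::runif(1, 36, 39))
}
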