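#' Thermal model parameters
#'
#' Parameters of the two-compartment heat balance. The core compartment
#' produces heat at rate `Pc`, exchanges heat with the muscles at rate
#' `eta * (Tc - Tm)` and loses heat to the environment at rate
#' `eta_a * (Tc - Ta)`; the muscle compartment produces the exercise heat
#' `Pm(t)` and exchanges with the core. All production rates are per unit
#' heat capacity, i.e. degC/min.
#'
#' @param Pc core heat production (degC/min).
#' @param eta_a core-to-environment heat dissipation coefficient (1/min),
#'   >= 0; this is the parameter of interest in treatment comparisons.
#' @param eta muscle-core heat transfer coefficient (1/min), > 0; fixed at
#'   0.125 by default.
#' @param Ta ambient temperature (degC).
#' @param T0 shared initial core and muscle temperature (degC).
#' @param specific_heat body specific heat (kcal/(kg*degC)).
#' @return an object of class `thermal_params`.
#' @export
thermal_params <- function(Pc, eta_a, eta = 0.125, Ta = 24, T0 = 37.5,
                           specific_heat = 0.8) {
  if (!is.finite(eta) || eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  if (!is.finite(eta_a) || eta_a < 0) stop("`eta_a` must be >= 0", call. = FALSE)
  if (!is.finite(specific_heat) || specific_heat <= 0) {
    stop("`specific_heat` must be > 0", call. = FALSE)
  }
  stopifnot(is.finite(Pc), is.finite(Ta), is.finite(T0))
  structure(
    list(Pc = Pc, eta = eta, eta_a = eta_a, Ta = Ta, T0 = T0,
         specific_heat = specific_heat),
    class = "thermal_params"
  )
}

#' @export
print.thermal_params <- function(x, ...) {
  cat("Two-compartment thermal parameters:\n")
  cat(sprintf("  Pc    = %g degC/min (core heat production)\n", x$Pc))
  cat(sprintf("  eta   = %g 1/min (muscle-core transfer)\n", x$eta))
  cat(sprintf("  eta_a = %g 1/min (core-environment dissipation)\n", x$eta_a))
  cat(sprintf("  Ta    = %g degC, T0 = %g degC, specific heat = %g kcal/(kg*degC)\n",
              x$Ta, x$T0, x$specific_heat))
  invisible(x)
}

# Precompute the eigen-decomposition of the system matrix
#   A = [ -(eta + eta_a)  eta ;  eta  -eta ]
# (symmetric, so the eigenbasis is orthonormal) together with the
# propagator factors for a step of length dt: exp(lambda*dt) for the
# homogeneous part and phi = (exp(lambda*dt) - 1)/lambda for the constant
# forcing (phi -> dt as lambda -> 0, which happens when eta_a = 0).
ode_stepper <- function(eta, eta_a, dt) {
  a <- -(eta + eta_a)
  d <- -eta
  s <- sqrt((a - d)^2 + 4 * eta^2) # > 0 since eta > 0: eigenvalues distinct
  l1 <- ((a + d) + s) / 2
  l2 <- ((a + d) - s) / 2
  v1 <- c(eta, l1 - a)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(eta, l2 - a)
  v2 <- v2 / sqrt(sum(v2^2))
  phi <- function(l) if (abs(l * dt) < 1e-12) dt else expm1(l * dt) / l
  list(v1 = v1, v2 = v2,
       e1 = exp(l1 * dt), e2 = exp(l2 * dt),
       p1 = phi(l1), p2 = phi(l2))
}

# One closed-form step of length dt from state x = c(Tc, Tm) under constant
# forcing b = c(Pc + eta_a*Ta, Pm).
ode_step <- function(st, x, b) {
  y1 <- st$v1[1] * x[1] + st$v1[2] * x[2]
  y2 <- st$v2[1] * x[1] + st$v2[2] * x[2]
  z1 <- st$v1[1] * b[1] + st$v1[2] * b[2]
  z2 <- st$v2[1] * b[1] + st$v2[2] * b[2]
  w1 <- st$e1 * y1 + st$p1 * z1
  w2 <- st$e2 * y2 + st$p2 * z2
  c(st$v1[1] * w1 + st$v2[1] * w2,
    st$v1[2] * w1 + st$v2[2] * w2)
}

# Fast path used by the likelihood: core/muscle temperatures on the 1-min
# grid the forcing is sampled on. `total` is the total heat production at
# each grid point, held constant over the following interval.
simulate_tc_grid <- function(Pc, eta_a, eta, Ta, T0, total, dt = 1) {
  n <- length(total)
  Tc <- numeric(n)
  Tm <- numeric(n)
  Tc[1] <- T0
  Tm[1] <- T0
  if (n == 1) return(list(Tc = Tc, Tm = Tm))
  st <- ode_stepper(eta, eta_a, dt)
  b1 <- Pc + eta_a * Ta
  v11 <- st$v1[1]; v12 <- st$v1[2]
  v21 <- st$v2[1]; v22 <- st$v2[2]
  e1 <- st$e1; e2 <- st$e2; p1 <- st$p1; p2 <- st$p2
  xc <- T0
  xm <- T0
  for (k in seq_len(n - 1)) {
    pm <- total[k] - Pc
    y1 <- v11 * xc + v12 * xm
    y2 <- v21 * xc + v22 * xm
    z1 <- v11 * b1 + v12 * pm
    z2 <- v21 * b1 + v22 * pm
    w1 <- e1 * y1 + p1 * z1
    w2 <- e2 * y2 + p2 * z2
    xc <- v11 * w1 + v21 * w2
    xm <- v12 * w1 + v22 * w2
    Tc[k + 1] <- xc
    Tm[k + 1] <- xm
  }
  list(Tc = Tc, Tm = Tm)
}

#' Simulate core and muscle temperatures
#'
#' Integrates the two-compartment heat balance
#' \deqn{dT_c/dt = P_c - \eta (T_c - T_m) - \eta_a (T_c - T_a), \quad
#'       dT_m/dt = P_m(t) - \eta (T_m - T_c)}
#' from the shared initial condition `Tc = Tm = T0` at the first forcing
#' time. The muscle heat production `Pm(t)` is held piecewise-constant on
#' each sampling interval of `heat` (sample-and-hold, matching the
#' per-minute calorimetry cadence), so the system is linear with constant
#' coefficients on every segment and is solved exactly there via the
#' eigen-decomposition of the (symmetric) system matrix — no numerical
#' integration error beyond floating point.
#'
#' @param params a [thermal_params()]; its `Pc` must match the one used in
#'   [partition_heat()] (checked when the attribute is present).
#' @param heat a `heat_production_series` with the `pm` column filled.
#' @param times output times (minutes) within the forcing coverage;
#'   defaults to the forcing grid.
#' @return data.frame of class `temperature_trajectory` with columns
#'   `time_min`, `tc_c`, `tm_c`.
#' @export
simulate_temperatures <- function(params, heat, times = heat$time_min) {
  stopifnot(inherits(params, "thermal_params"),
            inherits(heat, "heat_production_series"))
  if (is.null(heat$pm)) {
    stop("`heat` has no `pm` column; call partition_heat() first", call. = FALSE)
  }
  pc_attr <- attr(heat, "Pc")
  if (!is.null(pc_attr) && abs(pc_attr - params$Pc) > 1e-12) {
    stop("`heat` was partitioned with a different Pc than `params$Pc`",
         call. = FALSE)
  }
  grid <- heat$time_min
  t_start <- grid[1]
  t_end <- grid[length(grid)]
  times <- sort(as.numeric(times))
  if (times[1] < t_start - 1e-8 || times[length(times)] > t_end + 1e-8) {
    stop(sprintf("requested times outside forcing coverage [%g, %g]",
                 t_start, t_end), call. = FALSE)
  }

  b1 <- params$Pc + params$eta_a * params$Ta
  x <- c(params$T0, params$T0)
  out_tc <- numeric(length(times))
  out_tm <- numeric(length(times))
  j <- 1
  # emit any outputs at the initial time
  while (j <= length(times) && times[j] <= t_start + 1e-9) {
    out_tc[j] <- x[1]; out_tm[j] <- x[2]; j <- j + 1
  }
  full_dt <- diff(grid)
  steppers <- list() # cache per distinct segment length
  for (k in seq_along(full_dt)) {
    seg_a <- grid[k]
    seg_b <- grid[k + 1]
    b <- c(b1, heat$pm[k])
    # outputs strictly inside this segment: partial step from segment start
    while (j <= length(times) && times[j] < seg_b - 1e-9) {
      stp <- ode_stepper(params$eta, params$eta_a, times[j] - seg_a)
      xi <- ode_step(stp, x, b)
      out_tc[j] <- xi[1]; out_tm[j] <- xi[2]
      j <- j + 1
    }
    key <- sprintf("%.12g", full_dt[k])
    if (is.null(steppers[[key]])) {
      steppers[[key]] <- ode_stepper(params$eta, params$eta_a, full_dt[k])
    }
    x <- ode_step(steppers[[key]], x, b)
    while (j <= length(times) && times[j] <= seg_b + 1e-9) {
      out_tc[j] <- x[1]; out_tm[j] <- x[2]; j <- j + 1
    }
  }
  out <- data.frame(time_min = times, tc_c = out_tc, tm_c = out_tm)
  class(out) <- c("temperature_trajectory", "data.frame")
  out
}

#' Equilibrium temperatures under constant forcing
#'
#' Analytic fixed point of the two-compartment system for constant muscle
#' heat production: the core settles where dissipation balances total
#' production, `Tc* = Ta + (Pc + Pm)/eta_a`, and the muscles run hotter by
#' the gradient needed to export their heat, `Tm* = Tc* + Pm/eta`. Requires
#' `eta_a > 0`; without dissipation the system has no equilibrium (it heats
#' without bound for positive production).
#'
#' @param params a [thermal_params()].
#' @param pm_const constant muscle heat production (degC/min).
#' @return named numeric vector `c(tc = ..., tm = ...)` (degC).
#' @export
equilibrium_temperatures <- function(params, pm_const) {
  stopifnot(inherits(params, "thermal_params"))
  if (params$eta_a <= 0) {
    stop("no equilibrium when `eta_a` = 0 (nothing balances heat production)",
         call. = FALSE)
  }
  tc <- params$Ta + (params$Pc + pm_const) / params$eta_a
  c(tc = tc, tm = tc + pm_const / params$eta)
}
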