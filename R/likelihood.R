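#' Group-mean core temperature series
#'
#' Per-minute group-average telemetry with the across-animal sample SD at
#' each time. This is the data object the Gaussian likelihood is evaluated
#' on. SDs below `sd_floor` (telemetry-resolution scale) are floored so a
#' coincidentally tight time point cannot dominate the fit; flooring is
#' reported via a message.
#'
#' @param time_min sample times (minutes), 1-min spacing, starting at the
#'   placement time (conventionally -12).
#' @param mean_tc group-mean core temperature (degC).
#' @param sd_tc across-animal sample SD per time (degC), >= 0 before
#'   flooring.
#' @param group_label text label (e.g. "saline", "amph").
#' @param n_rats cohort size behind the mean.
#' @param sd_floor minimum admissible SD (degC, default 0.05).
#' @return data.frame of class `group_temperature_series` with columns
#'   `time_min`, `mean_tc_c`, `sd_tc_c`; label and cohort size as
#'   attributes.
#' @export
group_temperature_series <- function(time_min, mean_tc, sd_tc,
                                     group_label = "group", n_rats = NA_integer_,
                                     sd_floor = 0.05) {
  n <- length(time_min)
  if (length(mean_tc) != n || length(sd_tc) != n) {
    stop("`time_min`, `mean_tc`, `sd_tc` must have equal length", call. = FALSE)
  }
  if (n < 2 || any(abs(diff(time_min) - 1) > 1e-8)) {
    stop("temperature samples must be on a 1-minute grid", call. = FALSE)
  }
  if (any(!is.finite(mean_tc))) stop("`mean_tc` must be finite", call. = FALSE)
  if (any(!is.finite(sd_tc)) || any(sd_tc < 0)) {
    stop("`sd_tc` must be finite and >= 0", call. = FALSE)
  }
  floored <- sd_tc < sd_floor
  if (any(floored)) {
    message(sprintf("flooring %d of %d sd_tc values to %g degC",
                    sum(floored), n, sd_floor))
    sd_tc[floored] <- sd_floor
  }
  out <- data.frame(
    time_min = as.numeric(time_min),
    mean_tc_c = as.numeric(mean_tc),
    sd_tc_c = as.numeric(sd_tc)
  )
  class(out) <- c("group_temperature_series", "data.frame")
  attr(out, "group_label") <- group_label
  attr(out, "n_rats") <- n_rats
  out
}

#' Baseline temperature for model initialization
#'
#' The shared initial core/muscle temperature is the average of the samples
#' taken just before placement on the treadmill (times at or before -12 min)
#' when such samples exist; otherwise the first available sample.
#'
#' @param data a [group_temperature_series()].
#' @param placement_time the placement time (min, default -12).
#' @return T0 (degC).
#' @export
baseline_t0 <- function(data, placement_time = -12) {
  stopifnot(inherits(data, "group_temperature_series"))
  pre <- data$time_min <= placement_time + 1e-9
  if (any(pre)) mean(data$mean_tc_c[pre]) else data$mean_tc_c[1]
}

#' Model constants for fitting
#'
#' Bundles the quantities held fixed during parameter estimation: the
#' muscle-core transfer coefficient, ambient temperature, body specific
#' heat, and optionally a baseline temperature (computed from the data with
#' [baseline_t0()] when `T0` is `NULL`).
#'
#' @param eta muscle-core heat transfer coefficient (1/min).
#' @param Ta ambient temperature (degC).
#' @param specific_heat body specific heat (kcal/(kg*degC)).
#' @param T0 baseline temperature (degC) or `NULL` to derive from data.
#' @return a list of class `model_constants`.
#' @export
model_constants <- function(eta = 0.125, Ta = 24, specific_heat = 0.8,
                            T0 = NULL) {
  stopifnot(is.finite(eta), eta > 0, is.finite(Ta),
            is.finite(specific_heat), specific_heat > 0,
            is.null(T0) || is.finite(T0))
  structure(list(eta = eta, Ta = Ta, specific_heat = specific_heat, T0 = T0),
            class = "model_constants")
}

#' Build the log-likelihood function for a group series
#'
#' Returns a closure `f(Pc, eta_a)` evaluating the Gaussian log-likelihood
#' of the group-mean temperatures under the two-compartment model:
#' \deqn{\log L = -\tfrac12 \sum_t \frac{(T_k(t) - T_c(\eta_a, P_c, t))^2}
#'   {\sigma_k^2(t)}}
#' (up to an additive constant). The model trajectory is the segment-exact
#' solution with the muscle forcing `Pm(t) = total(t) - Pc` recomputed for
#' each proposed `Pc`. The total heat production is precomputed from the
#' gas series once, which is what makes MCMC over this closure cheap.
#'
#' @param data a [group_temperature_series()].
#' @param gas a [gas_exchange_series()] covering the data times.
#' @param protocol a [treadmill_protocol()].
#' @param constants a [model_constants()]; `T0 = NULL` uses [baseline_t0()].
#' @param window `"full"` sums over every data point (the pre-run points
#'   are what pin down the baseline balance of `Pc` against `eta_a`);
#'   `"run_only"` restricts to times >= the protocol's `run_start`.
#' @return a function `(Pc, eta_a) -> log-likelihood`, with the precomputed
#'   pieces attached as attributes (`total`, `T0`, `weights`).
#' @export
make_log_likelihood <- function(data, gas, protocol, constants = model_constants(),
                                window = c("full", "run_only")) {
  stopifnot(inherits(data, "group_temperature_series"),
            inherits(gas, "gas_exchange_series"),
            inherits(protocol, "treadmill_protocol"),
            inherits(constants, "model_constants"))
  window <- match.arg(window)

  idx <- match(round(data$time_min, 6), round(gas$time_min, 6))
  if (any(is.na(idx))) {
    stop("gas series does not cover every temperature time point", call. = FALSE)
  }
  heat <- total_heat_production(gas, protocol, constants$specific_heat)
  total <- heat$total[idx]

  T0 <- if (is.null(constants$T0)) baseline_t0(data, protocol$pre_run_start)
        else constants$T0
  use <- if (window == "full") rep(TRUE, nrow(data))
         else data$time_min >= protocol$run_start - 1e-9
  obs <- data$mean_tc_c
  inv_var <- 1 / data$sd_tc_c^2
  eta <- constants$eta
  Ta <- constants$Ta

  f <- function(Pc, eta_a) {
    tr <- simulate_tc_grid(Pc, eta_a, eta, Ta, T0, total)
    r <- obs - tr$Tc
    -0.5 * sum((r * r * inv_var)[use])
  }
  attr(f, "total") <- total
  attr(f, "T0") <- T0
  attr(f, "weights") <- inv_var
  attr(f, "window") <- window
  f
}

#' Gaussian log-likelihood of a group series at given parameters
#'
#' Convenience wrapper around [make_log_likelihood()] for a single
#' evaluation. For repeated evaluation (MCMC, profiling) build the closure
#' once instead.
#'
#' @inheritParams make_log_likelihood
#' @param Pc core heat production (degC/min).
#' @param eta_a heat dissipation coefficient (1/min).
#' @return the log-likelihood (up to an additive constant).
#' @export
log_likelihood <- function(Pc, eta_a, data, gas, protocol,
                           constants = model_constants(),
                           window = c("full", "run_only")) {
  f <- make_log_likelihood(data, gas, protocol, constants, window)
  f(Pc, eta_a)
}
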