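#' Respiratory exchange ratio
#'
#' RER is the ratio of carbon-dioxide production to oxygen consumption
#' measured by open-circuit indirect calorimetry. It indexes the fuel mix
#' being oxidized (0.7 for pure fat, 1.0 for pure carbohydrate); transient
#' values above 1 occur near exhaustion when CO2 stores are flushed.
#'
#' @param vco2 CO2 production (L/kg/min), non-negative.
#' @param vo2 O2 consumption (L/kg/min), strictly positive.
#' @return RER (dimensionless), vectorized over the inputs.
#' @examples
#' respiratory_exchange_ratio(0.072, 0.08) # 0.9
#' @export
respiratory_exchange_ratio <- function(vco2, vo2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0)) {
    stop("`vo2` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(vco2)) || any(vco2 < 0)) {
    stop("`vco2` must be finite and >= 0", call. = FALSE)
  }
  vco2 / vo2
}

#' Calorific value of consumed oxygen
#'
#' Energy released per liter of O2 consumed, as a linear function of the
#' respiratory exchange ratio: CV = 3.815 + 1.232 * RER (kcal/L).
#' Values of RER outside the physiological steady-state band \[0.7, 1\]
#' are accepted (exercise transients exceed 1) but raise a warning.
#'
#' @param rer respiratory exchange ratio, non-negative.
#' @return calorific value (kcal/L).
#' @examples
#' calorific_value(1.0) # 5.047
#' @export
calorific_value <- function(rer) {
  if (any(!is.finite(rer)) || any(rer < 0)) {
    stop("`rer` must be finite and >= 0", call. = FALSE)
  }
  if (any(rer < 0.7) || any(rer > 1)) {
    warning("RER outside [0.7, 1]; keeping value (exercise transients can exceed 1)",
            call. = FALSE)
  }
  3.815 + 1.232 * rer
}

#' Oxygen-to-temperature conversion coefficient
#'
#' The coefficient turning oxygen consumption (L/kg/min) into a whole-body
#' heating rate (degC/min): calorific value divided by the specific heat of
#' the body (approximately 0.8 kcal/(kg*degC) for a rat).
#'
#' @param cv calorific value (kcal/L).
#' @param specific_heat body specific heat (kcal/(kg*degC)), default 0.8.
#' @return alpha (degC * kg / L).
#' @export
alpha_coefficient <- function(cv, specific_heat = 0.8) {
  if (!is.finite(specific_heat) || specific_heat <= 0) {
    stop("`specific_heat` must be finite and > 0", call. = FALSE)
  }
  cv / specific_heat
}

#' Mechanical work rate of inclined treadmill running
#'
#' Power spent climbing the belt, per unit body mass:
#' MW = g * speed * tan(incline) / 4.184 in cal/kg/min, with g = 9.8 m/s^2,
#' speed in m/min and incline in degrees. Zero speed or a flat belt gives
#' zero mechanical work.
#'
#' @param speed belt speed (m/min), non-negative.
#' @param incline belt incline (degrees), in \[0, 90).
#' @param g gravitational acceleration (m/s^2).
#' @param joules_per_cal joules per calorie (4.184).
#' @return mechanical work rate (cal/kg/min), vectorized.
#' @examples
#' mechanical_work(26, 20) # ~22.17
#' @export
mechanical_work <- function(speed, incline, g = 9.8, joules_per_cal = 4.184) {
  if (any(!is.finite(speed)) || any(speed < 0)) {
    stop("`speed` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(incline)) || any(incline < 0) || any(incline >= 90)) {
    stop("`incline` must be in [0, 90) degrees", call. = FALSE)
  }
  g * speed * tan(incline * pi / 180) / joules_per_cal
}

#' Treadmill protocol
#'
#' An incremental treadmill protocol: the animal is placed on the stationary
#' belt at `pre_run_start` (injection time, clock zeroed at belt activation),
#' the belt starts at `run_start`, and workload stages (speed, incline) begin
#' at the listed start times. Stage intervals are left-closed, right-open:
#' at a stage boundary the newly started stage applies. Workload is zero
#' before `run_start`.
#'
#' @param start_min stage start times (minutes), strictly increasing,
#'   first one at `run_start`.
#' @param speed_m_per_min belt speed per stage (m/min).
#' @param incline_deg belt incline per stage (degrees).
#' @param pre_run_start time of placement on the belt (min, default -12).
#' @param run_start time of belt activation (min, default 0).
#' @return an object of class `treadmill_protocol`.
#' @seealso [make_protocol()] for the incremental-ramp constructor.
#' @export
treadmill_protocol <- function(start_min, speed_m_per_min, incline_deg,
                               pre_run_start = -12, run_start = 0) {
  n <- length(start_min)
  if (length(speed_m_per_min) != n || length(incline_deg) != n) {
    stop("stage vectors must have equal length", call. = FALSE)
  }
  if (n == 0) stop("protocol needs at least one stage", call. = FALSE)
  if (any(diff(start_min) <= 0)) {
    stop("stage start times must be strictly increasing", call. = FALSE)
  }
  if (pre_run_start >= run_start) {
    stop("`pre_run_start` must precede `run_start`", call. = FALSE)
  }
  if (start_min[1] < run_start) {
    stop("stages cannot start before `run_start`", call. = FALSE)
  }
  if (any(speed_m_per_min < 0)) stop("speeds must be >= 0", call. = FALSE)
  if (any(incline_deg < 0) || any(incline_deg >= 90)) {
    stop("inclines must be in [0, 90) degrees", call. = FALSE)
  }
  structure(
    list(
      stages = data.frame(
        start_min = as.numeric(start_min),
        speed_m_per_min = as.numeric(speed_m_per_min),
        incline_deg = as.numeric(incline_deg)
      ),
      pre_run_start = pre_run_start,
      run_start = run_start
    ),
    class = "treadmill_protocol"
  )
}

#' @export
print.treadmill_protocol <- function(x, ...) {
  cat(sprintf(
    "Treadmill protocol: placement at %g min, belt start at %g min, %d stage(s)\n",
    x$pre_run_start, x$run_start, nrow(x$stages)
  ))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Workload active at given times
#'
#' Looks up the protocol stage covering each time (left-closed, right-open
#' stage intervals) and returns the mechanical work rate; zero before belt
#' activation.
#'
#' @param protocol a [treadmill_protocol()].
#' @param times minutes on the experiment clock.
#' @return data.frame with `time_min`, `speed_m_per_min`, `incline_deg`,
#'   `mw_cal_per_kg_min`.
#' @export
workload_at <- function(protocol, times) {
  stopifnot(inherits(protocol, "treadmill_protocol"))
  idx <- findInterval(times, protocol$stages$start_min)
  speed <- ifelse(idx >= 1, protocol$stages$speed_m_per_min[pmax(idx, 1)], 0)
  incline <- ifelse(idx >= 1, protocol$stages$incline_deg[pmax(idx, 1)], 0)
  running <- times >= protocol$run_start & idx >= 1
  speed[!running] <- 0
  incline[!running] <- 0
  data.frame(
    time_min = times,
    speed_m_per_min = speed,
    incline_deg = incline,
    mw_cal_per_kg_min = mechanical_work(speed, incline)
  )
}

#' Gas-exchange series
#'
#' Per-minute VO2 / VCO2 series on the experiment clock. Samples must be at
#' a strict 1-minute spacing. Pre-run oxygen consumption is assumed constant
#' (the calorimeter's level is steady before the run starts); construction
#' optionally enforces this by overwriting pre-run VO2/VCO2 with their
#' values at `run_start`.
#'
#' @param time_min sample times (minutes), 1-min spacing.
#' @param vo2 O2 consumption (L/kg/min), > 0.
#' @param vco2 CO2 production (L/kg/min), >= 0.
#' @param run_start belt activation time used when flattening the pre-run
#'   period (default 0).
#' @param flatten_pre_run replace pre-run samples with the value at
#'   `run_start` (default FALSE; the aggregation step applies it for
#'   group-level series).
#' @return data.frame of class `gas_exchange_series` with columns
#'   `time_min`, `vo2_l_per_kg_min`, `vco2_l_per_kg_min`.
#' @export
gas_exchange_series <- function(time_min, vo2, vco2, run_start = 0,
                                flatten_pre_run = FALSE) {
  n <- length(time_min)
  if (length(vo2) != n || length(vco2) != n) {
    stop("`time_min`, `vo2`, `vco2` must have equal length", call. = FALSE)
  }
  if (n < 2 || any(abs(diff(time_min) - 1) > 1e-8)) {
    stop("gas-exchange samples must be on a 1-minute grid", call. = FALSE)
  }
  if (any(!is.finite(vo2)) || any(vo2 <= 0)) {
    stop("`vo2` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(vco2)) || any(vco2 < 0)) {
    stop("`vco2` must be finite and >= 0", call. = FALSE)
  }
  vo2 <- as.numeric(vo2)
  vco2 <- as.numeric(vco2)
  if (flatten_pre_run && any(time_min < run_start)) {
    i0 <- which(time_min >= run_start)[1]
    if (!is.na(i0)) {
      pre <- time_min < run_start
      vo2[pre] <- vo2[i0]
      vco2[pre] <- vco2[i0]
    }
  }
  out <- data.frame(
    time_min = as.numeric(time_min),
    vo2_l_per_kg_min = vo2,
    vco2_l_per_kg_min = vco2
  )
  class(out) <- c("gas_exchange_series", "data.frame")
  out
}

#' Total heat production from gas exchange and workload
#'
#' Converts oxygen consumption into whole-body heat production per unit heat
#' capacity. With the skeletal muscle and core compartments carrying equal
#' heat capacities, the summed core + muscle heating rate is
#' `total = 2 * (CV(RER) * VO2 - MW/1000) / specific_heat` in degC/min,
#' where MW (cal/kg/min) is the mechanical work of climbing the belt and
#' the division by 1000 puts it on the kcal scale of the calorific value.
#'
#' @param gas a [gas_exchange_series()].
#' @param protocol a [treadmill_protocol()] on the same clock.
#' @param specific_heat body specific heat (kcal/(kg*degC)).
#' @return data.frame of class `heat_production_series` with columns
#'   `time_min`, `total` (degC/min), `mw_cal_per_kg_min`; muscle heat `pm`
#'   is added by [partition_heat()] once a core heat production is chosen.
#' @export
total_heat_production <- function(gas, protocol, specific_heat = 0.8) {
  stopifnot(inherits(gas, "gas_exchange_series"),
            inherits(protocol, "treadmill_protocol"))
  if (gas$time_min[1] < protocol$pre_run_start - 1e-8) {
    stop("gas series starts before the protocol's placement time", call. = FALSE)
  }
  rer <- respiratory_exchange_ratio(gas$vco2_l_per_kg_min, gas$vo2_l_per_kg_min)
  cv <- suppressWarnings(calorific_value(rer))
  wl <- workload_at(protocol, gas$time_min)
  total <- 2 * (cv * gas$vo2_l_per_kg_min - wl$mw_cal_per_kg_min / 1000) /
    specific_heat
  out <- data.frame(
    time_min = gas$time_min,
    total = total,
    mw_cal_per_kg_min = wl$mw_cal_per_kg_min
  )
  class(out) <- c("heat_production_series", "data.frame")
  out
}

#' Split total heat production into core and muscle shares
#'
#' Once a core heat production rate Pc is fixed, the muscle share is what
#' remains of the measured total: `pm(t) = total(t) - Pc`. A negative
#' muscle share (possible pre-run, when total metabolism dips below the
#' chosen Pc) is permitted but flagged, since muscle heat is interpreted as
#' extra heat from physical activity.
#'
#' @param heat a `heat_production_series` from [total_heat_production()].
#' @param Pc core heat production (degC/min).
#' @param warn_negative warn if any `pm` is negative (default TRUE).
#' @return the series with a `pm` column added and `Pc` stored as an
#'   attribute.
#' @export
partition_heat <- function(heat, Pc, warn_negative = TRUE) {
  stopifnot(inherits(heat, "heat_production_series"))
  heat$pm <- heat$total - Pc
  if (warn_negative && any(heat$pm < 0)) {
    warning("negative muscle heat production at some time points (total < Pc)",
            call. = FALSE)
  }
  attr(heat, "Pc") <- Pc
  heat
}
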