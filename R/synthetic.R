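#' Incremental treadmill protocol constructor
#'
#' Builds the stepwise protocol used in incremental exercise tests: the
#' animal sits on the stationary belt from `pre_run` to 0, then workload
#' stages of `stage_minutes` each begin at t = 0, with monotone speed and
#' incline ramps. Defaults ramp over 18 min to the familiarization maxima
#' of 26 m/min and 20 degrees.
#'
#' @param stage_minutes stage duration (min, default 3).
#' @param speeds belt speed per stage (m/min); default a linear ramp
#'   10..26 over `ceiling(run_length/stage_minutes)` stages.
#' @param inclines incline per stage (degrees); default a linear ramp 5..20.
#' @param pre_run placement time (min, default -12).
#' @param run_length nominal run duration used to size the default ramps
#'   (min, default 18).
#' @return a [treadmill_protocol()] with an `end_min` element marking the
#'   end of the last stage.
#' @export
make_protocol <- function(stage_minutes = 3, speeds = NULL, inclines = NULL,
                          pre_run = -12, run_length = 18) {
  stopifnot(stage_minutes > 0, run_length > 0)
  n_stages <- ceiling(run_length / stage_minutes)
  if (is.null(speeds)) speeds <- seq(10, 26, length.out = n_stages)
  if (is.null(inclines)) inclines <- seq(5, 20, length.out = n_stages)
  if (length(speeds) != length(inclines)) {
    stop("`speeds` and `inclines` must have the same length", call. = FALSE)
  }
  n_stages <- length(speeds)
  p <- treadmill_protocol(
    start_min = (seq_len(n_stages) - 1) * stage_minutes,
    speed_m_per_min = speeds,
    incline_deg = inclines,
    pre_run_start = pre_run,
    run_start = 0
  )
  p$end_min <- n_stages * stage_minutes
  p
}

# End of the protocol: explicit end_min when present, else last stage start
# plus the typical stage duration.
protocol_end <- function(protocol) {
  if (!is.null(protocol$end_min)) return(protocol$end_min)
  starts <- protocol$stages$start_min
  dur <- if (length(starts) > 1) stats::median(diff(starts)) else 3
  starts[length(starts)] + dur
}

#' Synthetic cohort configuration
#'
#' Distributions and response constants for the cohort generator. Baseline
#' temperature defaults reproduce the 37.5 +/- 0.3 degC band typical of
#' rats at room temperature; exhaustion thresholds sit near 40 degC, the
#' core temperature at which treadmill running stops regardless of
#' treatment. Oxygen uptake follows a first-order response to workload
#' (`vo2_baseline + vo2_gain * (speed * tan(incline) + speed)` target, time
#' constant `vo2_tau`), spanning roughly 0.02 L/kg/min at rest to 0.08 at
#' the top of the ramp.
#'
#' @param n_rats animals per group (default 6).
#' @param T0_mean,T0_sd baseline temperature distribution (degC).
#' @param measurement_sd per-minute telemetry noise on core temperature
#'   (degC).
#' @param rat_sd_Pc,rat_sd_eta_a between-animal SDs of the thermal
#'   parameters (degC/min, 1/min).
#' @param vo2_baseline resting oxygen consumption (L/kg/min).
#' @param vo2_gain VO2 per unit workload index (L/kg/min per
#'   (m/min)-equivalent).
#' @param vo2_tau first-order VO2 response time constant (min).
#' @param exhaustion_threshold_mean,exhaustion_threshold_sd core
#'   temperature at which running stops (degC).
#' @param exhaustion_on `"noiseless"` evaluates the threshold on the true
#'   trajectory (interpretable exhaustion-time distributions);
#'   `"noisy"` on the telemetry samples.
#' @param seed integer seed; generation is deterministic given it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_rats = 6, T0_mean = 37.5, T0_sd = 0.3,
                          measurement_sd = 0.15,
                          rat_sd_Pc = 0.02, rat_sd_eta_a = 0.001,
                          vo2_baseline = 0.02, vo2_gain = 0.0017, vo2_tau = 1,
                          exhaustion_threshold_mean = 40,
                          exhaustion_threshold_sd = 0.2,
                          exhaustion_on = c("noiseless", "noisy"),
                          seed = 1L) {
  stopifnot(n_rats >= 1, T0_sd >= 0, measurement_sd >= 0,
            rat_sd_Pc >= 0, rat_sd_eta_a >= 0,
            vo2_baseline > 0, vo2_gain >= 0, vo2_tau > 0,
            exhaustion_threshold_sd >= 0)
  structure(
    list(n_rats = as.integer(n_rats), T0_mean = T0_mean, T0_sd = T0_sd,
         measurement_sd = measurement_sd, rat_sd_Pc = rat_sd_Pc,
         rat_sd_eta_a = rat_sd_eta_a, vo2_baseline = vo2_baseline,
         vo2_gain = vo2_gain, vo2_tau = vo2_tau,
         exhaustion_threshold_mean = exhaustion_threshold_mean,
         exhaustion_threshold_sd = exhaustion_threshold_sd,
         exhaustion_on = match.arg(exhaustion_on),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate protocol-driven gas exchange
#'
#' Emulates the structure of open-circuit calorimetry during an incremental
#' run: oxygen consumption is exactly constant at `vo2_baseline` before the
#' belt starts, then relaxes first-order (time constant `vo2_tau`) toward a
#' workload-proportional target `vo2_baseline + vo2_gain *
#' (speed * tan(incline) + speed)`. The respiratory exchange ratio drifts
#' linearly from 0.85 at belt start to 1.0 at the end of the run
#' (progressive shift to carbohydrate oxidation), fixing VCO2 = RER * VO2.
#'
#' @param protocol a [treadmill_protocol()].
#' @param config a [cohort_config()].
#' @param times 1-min grid covering the experiment; default placement to
#'   protocol end.
#' @return a [gas_exchange_series()].
#' @export
simulate_vo2 <- function(protocol, config = cohort_config(),
                         times = seq(protocol$pre_run_start, protocol_end(protocol))) {
  stopifnot(inherits(protocol, "treadmill_protocol"),
            inherits(config, "cohort_config"))
  wl <- workload_at(protocol, times)
  drive <- wl$speed_m_per_min * tan(wl$incline_deg * pi / 180) +
    wl$speed_m_per_min
  target <- config$vo2_baseline + config$vo2_gain * drive
  vo2 <- numeric(length(times))
  decay <- exp(-diff(times) / config$vo2_tau)
  vo2[1] <- config$vo2_baseline
  for (k in seq_along(decay)) {
    if (times[k + 1] < protocol$run_start - 1e-9) {
      vo2[k + 1] <- config$vo2_baseline
    } else {
      vo2[k + 1] <- target[k] + (vo2[k] - target[k]) * decay[k]
    }
  }
  run_end <- times[length(times)]
  rer <- ifelse(
    times < protocol$run_start, 0.85,
    0.85 + 0.15 * (times - protocol$run_start) /
      max(run_end - protocol$run_start, 1)
  )
  gas_exchange_series(times, vo2, rer * vo2)
}

#' Simulate a cohort of running rats
#'
#' Draws per-animal baseline temperatures, thermal parameters and
#' exhaustion thresholds from the configured normal distributions, runs
#' each animal through the protocol (shared deterministic VO2 response,
#' two-compartment temperature dynamics), adds i.i.d. Gaussian telemetry
#' noise to the per-minute core samples, and stops each animal at the first
#' sample where its (by default noiseless) core temperature reaches its
#' threshold, capped at the protocol end. Deterministic given
#' `config$seed`; the caller's RNG state is preserved.
#'
#' @param params group-level [thermal_params()] (per-animal `Pc`, `eta_a`
#'   are drawn around `params$Pc`, `params$eta_a`).
#' @param protocol a [treadmill_protocol()].
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: `per_rat` (each with
#'   `trajectory` — `time_min`, `tc_c` noisy, `tc_true_c`, `tm_c` —, `gas`,
#'   `exhaustion_time`), `generating_params` data.frame, `protocol`,
#'   `config`.
#' @export
simulate_cohort <- function(params, protocol, config = cohort_config()) {
  stopifnot(inherits(params, "thermal_params"),
            inherits(protocol, "treadmill_protocol"),
            inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  times <- seq(protocol$pre_run_start, protocol_end(protocol))
  gas <- simulate_vo2(protocol, config, times)
  heat_total <- total_heat_production(gas, protocol, params$specific_heat)

  n <- config$n_rats
  gp <- data.frame(
    rat_id = seq_len(n),
    T0 = stats::rnorm(n, config$T0_mean, config$T0_sd),
    Pc = pmax(stats::rnorm(n, params$Pc, config$rat_sd_Pc), 0),
    eta_a = pmax(stats::rnorm(n, params$eta_a, config$rat_sd_eta_a), 0),
    threshold = if (is.finite(config$exhaustion_threshold_mean)) {
      stats::rnorm(n, config$exhaustion_threshold_mean,
                   config$exhaustion_threshold_sd)
    } else rep(Inf, n) # no exhaustion: every animal finishes the protocol
  )
  per_rat <- vector("list", n)
  for (i in seq_len(n)) {
    if (gp$threshold[i] <= gp$T0[i]) {
      stop(sprintf(
        "rat %d would be exhausted at placement (threshold %.2f <= T0 %.2f)",
        i, gp$threshold[i], gp$T0[i]), call. = FALSE)
    }
    pr <- thermal_params(gp$Pc[i], gp$eta_a[i], params$eta, params$Ta,
                         gp$T0[i], params$specific_heat)
    heat_i <- partition_heat(heat_total, gp$Pc[i], warn_negative = FALSE)
    traj <- simulate_temperatures(pr, heat_i, times)
    noise <- stats::rnorm(nrow(traj), 0, config$measurement_sd)
    tc_noisy <- traj$tc_c + noise
    basis <- if (config$exhaustion_on == "noiseless") traj$tc_c else tc_noisy
    crossed <- which(basis >= gp$threshold[i] & traj$time_min > protocol$run_start)
    t_exh <- if (length(crossed)) traj$time_min[crossed[1]]
             else times[length(times)]
    if (t_exh <= protocol$run_start) {
      stop(sprintf("rat %d exhausted before the belt started", i), call. = FALSE)
    }
    keep <- traj$time_min <= t_exh + 1e-9
    per_rat[[i]] <- list(
      trajectory = data.frame(
        time_min = traj$time_min[keep],
        tc_c = tc_noisy[keep],
        tc_true_c = traj$tc_c[keep],
        tm_c = traj$tm_c[keep]
      ),
      gas = gas[gas$time_min <= t_exh + 1e-9, , drop = FALSE],
      exhaustion_time = t_exh
    )
  }
  structure(
    list(per_rat = per_rat, generating_params = gp, protocol = protocol,
         config = config, group_params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  exh <- vapply(x$per_rat, `[[`, numeric(1), "exhaustion_time")
  cat(sprintf("Synthetic cohort: %d rats, exhaustion times %s min (seed %d)\n",
              length(x$per_rat),
              paste(format(exh, digits = 3), collapse = ", "),
              x$config$seed))
  invisible(x)
}

#' Aggregate a cohort into group-level series
#'
#' Applies the group truncation rule: the common time grid ends at the
#' earliest exhaustion time in the cohort, so every retained time point
#' averages over all animals. Core temperature is summarized by across-rat
#' mean and sample SD per time; gas exchange by the across-rat mean, with
#' the pre-run VO2/VCO2 replaced by the group's value at belt start (the
#' calorimeter's level is steady before the run).
#'
#' @param cohort a [simulate_cohort()] result with at least 2 animals.
#' @param label group label for the output series.
#' @param sd_floor minimum SD passed to [group_temperature_series()].
#' @return list with `temperature` (a [group_temperature_series()]), `gas`
#'   (a [gas_exchange_series()]), and `exhaustion_times`.
#' @export
aggregate_group <- function(cohort, label = "group", sd_floor = 0.05) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- length(cohort$per_rat)
  if (n < 2) {
    stop("need >= 2 rats to form an across-animal SD", call. = FALSE)
  }
  exh <- vapply(cohort$per_rat, `[[`, numeric(1), "exhaustion_time")
  t_cut <- min(exh)
  times <- cohort$per_rat[[1]]$trajectory$time_min
  times <- times[times <= t_cut + 1e-9]
  tc <- sapply(cohort$per_rat, function(r) {
    r$trajectory$tc_c[match(round(times, 6), round(r$trajectory$time_min, 6))]
  })
  vo2 <- sapply(cohort$per_rat, function(r) {
    r$gas$vo2_l_per_kg_min[match(round(times, 6), round(r$gas$time_min, 6))]
  })
  vco2 <- sapply(cohort$per_rat, function(r) {
    r$gas$vco2_l_per_kg_min[match(round(times, 6), round(r$gas$time_min, 6))]
  })
  temp <- group_temperature_series(
    times, rowMeans(tc), apply(tc, 1, stats::sd),
    group_label = label, n_rats = n, sd_floor = sd_floor
  )
  gas <- gas_exchange_series(times, rowMeans(vo2), rowMeans(vco2),
                             run_start = cohort$protocol$run_start,
                             flatten_pre_run = TRUE)
  list(temperature = temp, gas = gas, exhaustion_times = exh)
}
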