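#' Fit the thermal model to a group series
#'
#' Estimates core heat production `Pc` and the heat dissipation coefficient
#' `eta_a` for one group by Metropolis-Hastings sampling of the Gaussian
#' likelihood over the group-mean core-temperature series. The baseline
#' temperature is taken from `constants$T0` or derived from the data
#' ([baseline_t0()]). The best-fit trajectory is the one at the
#' maximum-likelihood draw (the most probable parameter values in the
#' ensemble); posterior means/SDs come from [summarize_posterior()].
#'
#' @param data a [group_temperature_series()].
#' @param gas a [gas_exchange_series()] covering the data times.
#' @param protocol a [treadmill_protocol()].
#' @param constants a [model_constants()].
#' @param mcmc an [mcmc_config()].
#' @param window likelihood window, see [make_log_likelihood()].
#' @param reconstruct also reconstruct muscle temperature with posterior
#'   uncertainty (default TRUE).
#' @param n_draws posterior draws used for muscle reconstruction
#'   (subsampled evenly from the retained ensemble; default 2000).
#' @return an object of class `group_fit`: `group_label`, `posterior`,
#'   `estimates` (`Pc`, `eta_a`), `best_fit` (a `temperature_trajectory`),
#'   `posterior_mean_fit`, `muscle` (`time_min`, `mean`, `se`), `vo2max`,
#'   `T0`, `data`.
#' @export
fit_group <- function(data, gas, protocol, constants = model_constants(),
                      mcmc = mcmc_config(), window = c("full", "run_only"),
                      reconstruct = TRUE, n_draws = 2000) {
  window <- match.arg(window)
  loglik <- make_log_likelihood(data, gas, protocol, constants, window)
  T0 <- attr(loglik, "T0")
  ens <- metropolis_hastings(loglik, mcmc)
  est <- summarize_posterior(ens)

  heat <- total_heat_production(gas, protocol, constants$specific_heat)
  traj_at <- function(Pc, eta_a) {
    pr <- thermal_params(Pc, eta_a, constants$eta, constants$Ta, T0,
                         constants$specific_heat)
    simulate_temperatures(pr, partition_heat(heat, Pc, warn_negative = FALSE),
                          data$time_min)
  }
  i_best <- which.max(ens$log_like)
  best <- traj_at(ens$draws$Pc[i_best], ens$draws$eta_a[i_best])
  mean_fit <- traj_at(est$Pc$mean, est$eta_a$mean)

  fit <- structure(
    list(
      group_label = attr(data, "group_label"),
      posterior = ens,
      estimates = est,
      best_fit = best,
      posterior_mean_fit = mean_fit,
      muscle = NULL,
      vo2max = max(gas$vo2_l_per_kg_min),
      T0 = T0,
      data = data
    ),
    class = "group_fit"
  )
  if (reconstruct) {
    fit$muscle <- reconstruct_muscle_temperature(fit, data, gas, protocol,
                                                 constants, n_draws)
  }
  fit
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("Group fit: %s (T0 = %.2f degC, VO2max = %.3g L/kg/min)\n",
              x$group_label, x$T0, x$vo2max))
  cat(sprintf("  Pc    = %.3f +/- %.3f degC/min\n",
              x$estimates$Pc$mean, x$estimates$Pc$se))
  cat(sprintf("  eta_a = %.4f +/- %.4f 1/min\n",
              x$estimates$eta_a$mean, x$estimates$eta_a$se))
  cat(sprintf("  acceptance rate %.2f over %d retained draws\n",
              x$posterior$acceptance_rate, nrow(x$posterior$draws)))
  if (!is.null(x$muscle)) {
    m <- x$muscle[nrow(x$muscle), ]
    cat(sprintf("  muscle T at end of fit window: %.2f +/- %.2f degC\n",
                m$mean, m$se))
  }
  invisible(x)
}

#' Reconstruct muscle temperature with posterior uncertainty
#'
#' The muscle compartment is unobserved; its temperature is recovered by
#' propagating posterior parameter draws through the model. For each
#' retained draw `(Pc, eta_a)` the muscle forcing `Pm(t) = total(t) - Pc`
#' is formed and the two-compartment system integrated from the group
#' baseline; the per-time mean and SD across draws give the reconstruction
#' and its standard error. The ensemble is subsampled evenly (deterministic)
#' to at most `n_draws` trajectories.
#'
#' @param fit a `group_fit` (only its posterior and `T0` are used).
#' @param data the fitted [group_temperature_series()] (defines the grid).
#' @param gas,protocol,constants as in [fit_group()].
#' @param n_draws maximum number of posterior draws to propagate.
#' @return data.frame `time_min`, `mean`, `se` (degC) of class
#'   `muscle_reconstruction`, plus a `tc_mean` column with the
#'   corresponding core-temperature posterior mean.
#' @export
reconstruct_muscle_temperature <- function(fit, data, gas, protocol,
                                           constants = model_constants(),
                                           n_draws = 2000) {
  stopifnot(inherits(fit, "group_fit") || inherits(fit, "posterior_ensemble"))
  ens <- if (inherits(fit, "group_fit")) fit$posterior else fit
  T0 <- if (inherits(fit, "group_fit")) fit$T0 else {
    if (is.null(constants$T0)) baseline_t0(data) else constants$T0
  }
  n_ret <- nrow(ens$draws)
  idx <- unique(round(seq(1, n_ret, length.out = min(n_draws, n_ret))))

  heat <- total_heat_production(gas, protocol, constants$specific_heat)
  gidx <- match(round(data$time_min, 6), round(heat$time_min, 6))
  if (any(is.na(gidx))) {
    stop("gas series does not cover every temperature time point", call. = FALSE)
  }
  total <- heat$total[gidx]

  nt <- length(total)
  tm <- matrix(NA_real_, nt, length(idx))
  tc <- matrix(NA_real_, nt, length(idx))
  for (j in seq_along(idx)) {
    d <- idx[j]
    sim <- simulate_tc_grid(ens$draws$Pc[d], ens$draws$eta_a[d],
                            constants$eta, constants$Ta, T0, total)
    tm[, j] <- sim$Tm
    tc[, j] <- sim$Tc
  }
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  out <- data.frame(
    time_min = data$time_min,
    mean = rowMeans(tm),
    se = apply(tm, 1, sd0),
    tc_mean = rowMeans(tc)
  )
  class(out) <- c("muscle_reconstruction", "data.frame")
  out
}

#' Compare two fitted groups
#'
#' z-tests on the posterior summaries of `Pc` and `eta_a` and on the
#' reconstructed muscle temperature at each group's own last fitted time
#' point (groups run for different durations, so "end of run" differs per
#' group).
#'
#' @param a,b `group_fit` objects (with muscle reconstructions).
#' @param exhaustion_times optional named list of per-animal exhaustion
#'   times (minutes) per group, summarized into the report when given.
#' @return an object of class `comparison_report`.
#' @export
compare_groups <- function(a, b, exhaustion_times = NULL) {
  stopifnot(inherits(a, "group_fit"), inherits(b, "group_fit"))
  tm_end <- function(f) {
    if (is.null(f$muscle)) {
      stop("group fit lacks a muscle reconstruction", call. = FALSE)
    }
    m <- f$muscle[nrow(f$muscle), ]
    parameter_estimate("Tm_end", m$mean, m$se)
  }
  ta <- tm_end(a)
  tb <- tm_end(b)
  rep <- list(
    groups = stats::setNames(
      list(
        list(Pc = a$estimates$Pc, eta_a = a$estimates$eta_a,
             vo2max = a$vo2max, Tm_end = ta),
        list(Pc = b$estimates$Pc, eta_a = b$estimates$eta_a,
             vo2max = b$vo2max, Tm_end = tb)
      ),
      c(a$group_label, b$group_label)
    ),
    comparisons = list(
      Pc = z_test(a$estimates$Pc, b$estimates$Pc),
      eta_a = z_test(a$estimates$eta_a, b$estimates$eta_a),
      Tm_end = z_test(ta, tb)
    )
  )
  if (!is.null(exhaustion_times)) {
    rep$exhaustion <- lapply(exhaustion_times, function(v) {
      list(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
    })
  }
  structure(rep, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  labs <- names(x$groups)
  cat(sprintf("Group comparison: %s vs %s\n", labs[1], labs[2]))
  for (p in c("Pc", "eta_a", "Tm_end")) {
    g1 <- x$groups[[1]][[p]]
    g2 <- x$groups[[2]][[p]]
    cmp <- x$comparisons[[p]]
    cat(sprintf("  %-6s %.4g +/- %.2g  vs  %.4g +/- %.2g   z = %+.2f, p = %.3g\n",
                p, g1$mean, g1$se, g2$mean, g2$se, cmp$z, cmp$p))
  }
  invisible(x)
}

# 32-bit polynomial rolling hash over the ASCII serialization of a config
# list; stable fingerprint without an external hashing dependency. Exact in
# double precision (intermediate values stay far below 2^53).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full two-group analysis
#'
#' End-to-end workflow: generate synthetic cohorts (or read group CSVs),
#' fit each group by MCMC, reconstruct muscle temperatures, compare groups,
#' and write a JSON report plus per-group trajectory and posterior-draw
#' CSVs. Fully reproducible: all randomness derives from the config seed
#' (cohort seeds are `seed + 1000 + i`, chain seeds `seed + i` for group
#' index i).
#'
#' @param config a configuration list or path to a YAML/JSON file; see
#'   [read_run_config()] for the schema.
#' @param out_dir output directory (created if needed); `NULL` writes no
#'   files.
#' @return invisibly, a list with `fits`, `report` (the
#'   [compare_groups()] result for two groups), and `report_json` (the
#'   serializable report).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  seed <- config$seed

  constants <- do.call(model_constants, config$constants)
  protocol <- resolve_protocol(config$protocol)
  mcmc_base <- config$mcmc

  inputs <- list()
  exhaustion <- NULL
  if (!is.null(config$synthetic)) {
    labels <- names(config$synthetic$groups)
    exhaustion <- list()
    for (i in seq_along(labels)) {
      lab <- labels[i]
      g <- config$synthetic$groups[[lab]]
      params <- thermal_params(g$Pc, g$eta_a, constants$eta, constants$Ta,
                               if (is.null(g$T0)) 37.5 else g$T0,
                               constants$specific_heat)
      cc_args <- config$synthetic$cohort
      cc_args$seed <- seed + 1000 + i
      cohort <- simulate_cohort(params, protocol, do.call(cohort_config, cc_args))
      agg <- aggregate_group(cohort, lab)
      inputs[[lab]] <- agg
      exhaustion[[lab]] <- agg$exhaustion_times
    }
  } else {
    for (lab in names(config$groups)) {
      g <- config$groups[[lab]]
      inputs[[lab]] <- list(
        temperature = read_group_csv(g$temperature_csv, group_label = lab),
        gas = read_gas_csv(g$gas_csv)
      )
    }
  }

  fits <- list()
  for (i in seq_along(inputs)) {
    lab <- names(inputs)[i]
    mc_args <- mcmc_base
    mc_args$seed <- seed + i
    fits[[lab]] <- fit_group(inputs[[lab]]$temperature, inputs[[lab]]$gas,
                             protocol, constants, do.call(mcmc_config, mc_args),
                             window = config$likelihood_window)
  }

  report <- NULL
  if (length(fits) >= 2) {
    report <- compare_groups(fits[[1]], fits[[2]], exhaustion_times = exhaustion)
  }

  est_json <- function(e) list(mean = e$mean, se = e$se)
  report_json <- list(
    groups = lapply(names(fits), function(lab) {
      f <- fits[[lab]]
      m <- f$muscle[nrow(f$muscle), ]
      list(label = lab,
           Pc = est_json(f$estimates$Pc),
           eta_a = est_json(f$estimates$eta_a),
           vo2max = f$vo2max,
           Tm_end = list(mean = m$mean, se = m$se),
           acceptance_rate = f$posterior$acceptance_rate)
    }),
    comparisons = if (!is.null(report)) report$comparisons else NULL,
    exhaustion = if (!is.null(report)) report$exhaustion else NULL,
    config_hash = config_hash(config),
    seed = seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    for (lab in names(fits)) {
      f <- fits[[lab]]
      utils::write.csv(
        data.frame(time_min = f$best_fit$time_min,
                   tc_fit_c = f$best_fit$tc_c,
                   tm_fit_c = f$best_fit$tm_c,
                   tm_mean_c = f$muscle$mean,
                   tm_se_c = f$muscle$se,
                   tc_data_c = f$data$mean_tc_c,
                   sd_data_c = f$data$sd_tc_c),
        file.path(out_dir, paste0("trajectory_", lab, ".csv")),
        row.names = FALSE)
      utils::write.csv(f$posterior$draws,
                       file.path(out_dir, paste0("draws_", lab, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(list(fits = fits, report = report, report_json = report_json))
}
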