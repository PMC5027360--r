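# CSV dialect: UTF-8, comma separators, '.' decimal, mandatory header row;
# times in minutes on the experiment clock (injection at -12, belt start 0).

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in required) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (any(is.na(v))) {
      row <- c(bad, which(is.na(df[[col]])))[1]
      stop(sprintf("%s: non-numeric or missing value in column '%s', row %d",
                   path, col, row), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

check_time_column <- function(df, path) {
  t <- df$time_min
  if (anyDuplicated(t)) {
    stop(sprintf("%s: duplicate time_min at row %d", path,
                 anyDuplicated(t)), call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop(sprintf("%s: time_min not strictly increasing at row %d", path,
                 which(diff(t) <= 0)[1] + 1L), call. = FALSE)
  }
  invisible(df)
}

#' Read a gas-exchange CSV
#'
#' Expects columns `time_min`, `vo2_l_per_kg_min`, `vco2_l_per_kg_min`.
#'
#' @param path CSV file path.
#' @return a [gas_exchange_series()].
#' @export
read_gas_csv <- function(path) {
  df <- read_checked_csv(path, c("time_min", "vo2_l_per_kg_min",
                                 "vco2_l_per_kg_min"))
  check_time_column(df, path)
  gas_exchange_series(df$time_min, df$vo2_l_per_kg_min, df$vco2_l_per_kg_min)
}

#' Read a group temperature CSV
#'
#' Expects columns `time_min`, `mean_tc_c`, `sd_tc_c`.
#'
#' @param path CSV file path.
#' @param group_label label attached to the series.
#' @param n_rats cohort size, if known.
#' @param sd_floor SD floor passed to [group_temperature_series()].
#' @return a [group_temperature_series()].
#' @export
read_group_csv <- function(path, group_label = basename(path), n_rats = NA,
                           sd_floor = 0.05) {
  df <- read_checked_csv(path, c("time_min", "mean_tc_c", "sd_tc_c"))
  check_time_column(df, path)
  group_temperature_series(df$time_min, df$mean_tc_c, df$sd_tc_c,
                           group_label = group_label, n_rats = n_rats,
                           sd_floor = sd_floor)
}

#' Read a treadmill protocol CSV
#'
#' Expects columns `start_min`, `speed_m_per_min`, `incline_deg`.
#'
#' @param path CSV file path.
#' @param pre_run_start placement time (min).
#' @param run_start belt activation time (min).
#' @return a [treadmill_protocol()].
#' @export
read_protocol_csv <- function(path, pre_run_start = -12, run_start = 0) {
  df <- read_checked_csv(path, c("start_min", "speed_m_per_min", "incline_deg"))
  treadmill_protocol(df$start_min, df$speed_m_per_min, df$incline_deg,
                     pre_run_start = pre_run_start, run_start = run_start)
}

#' Read a time-series CSV by kind
#'
#' @param path CSV file path.
#' @param kind one of `"gas"`, `"temperature"`, `"protocol"`.
#' @param ... forwarded to the kind-specific reader.
#' @return the corresponding series object.
#' @export
read_timeseries_csv <- function(path, kind = c("gas", "temperature", "protocol"),
                                ...) {
  switch(match.arg(kind),
         gas = read_gas_csv(path, ...),
         temperature = read_group_csv(path, ...),
         protocol = read_protocol_csv(path, ...))
}

#' Write series objects to CSV
#'
#' Writers matching the readers above; round-trip through write-then-read
#' is the identity (up to numeric formatting at 15 significant digits).
#'
#' @param x the series object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_csv <- function(x, path) {
  stopifnot(inherits(x, "gas_exchange_series"))
  utils::write.csv(format(as.data.frame(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gas_csv
#' @export
write_group_csv <- function(x, path) {
  stopifnot(inherits(x, "group_temperature_series"))
  utils::write.csv(format(as.data.frame(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gas_csv
#' @export
write_protocol_csv <- function(x, path) {
  stopifnot(inherits(x, "treadmill_protocol"))
  utils::write.csv(x$stages, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a synthetic cohort
#'
#' Writes the tidy per-rat telemetry/calorimetry table
#' (`rat_id, time_min, tc_c, vo2, vco2`) and a JSON sidecar with the
#' generating parameters — the ground truth for recovery tests.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(seq_along(cohort$per_rat), function(i) {
    r <- cohort$per_rat[[i]]
    gi <- match(round(r$trajectory$time_min, 6), round(r$gas$time_min, 6))
    data.frame(rat_id = i,
               time_min = r$trajectory$time_min,
               tc_c = r$trajectory$tc_c,
               vo2 = r$gas$vo2_l_per_kg_min[gi],
               vco2 = r$gas$vco2_l_per_kg_min[gi])
  }))
  csv <- file.path(dir, "cohort.csv")
  js <- file.path(dir, "cohort_truth.json")
  utils::write.csv(rows, csv, row.names = FALSE)
  truth <- list(
    generating_params = cohort$generating_params,
    group_params = unclass(cohort$group_params),
    exhaustion_times = vapply(cohort$per_rat, `[[`, numeric(1),
                              "exhaustion_time"),
    config = unclass(cohort$config)
  )
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(csv = csv, truth = js))
}

#' Read a run configuration (YAML or JSON)
#'
#' The configuration drives [run_full_analysis()]. Recognized top-level
#' keys: `seed` (integer, required), `constants` (eta, Ta, specific_heat,
#' T0), `mcmc` (passed to [mcmc_config()]), `protocol` (either ramp
#' settings for [make_protocol()] or `{file: path}` for a CSV),
#' `likelihood_window` (`"full"`/`"run_only"`), and exactly one of
#' `synthetic` (`cohort` settings plus `groups: {label: {Pc, eta_a}}`) or
#' `groups` (`{label: {temperature_csv, gas_csv}}`). Unknown keys are
#' rejected with a message naming them.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
                   yaml = ,
                   yml = yaml::read_yaml(path),
                   json = jsonlite::read_json(path, simplifyVector = TRUE),
                   stop(sprintf("unsupported config extension '.%s' (use YAML or JSON)",
                                ext), call. = FALSE))
  validate_run_config(config)
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  known <- c("seed", "constants", "mcmc", "protocol", "likelihood_window",
             "synthetic", "groups", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  if (is.null(config$seed)) stop("config must set `seed`", call. = FALSE)
  config$seed <- as.integer(config$seed)
  if (is.null(config$constants)) config$constants <- list()
  if (is.null(config$mcmc)) config$mcmc <- list()
  if (!is.null(config$mcmc$support)) {
    config$mcmc$support <- rbind(Pc = as.numeric(config$mcmc$support$Pc),
                                 eta_a = as.numeric(config$mcmc$support$eta_a))
  }
  if (is.null(config$likelihood_window)) config$likelihood_window <- "full"
  if (!config$likelihood_window %in% c("full", "run_only")) {
    stop("`likelihood_window` must be 'full' or 'run_only'", call. = FALSE)
  }
  has_syn <- !is.null(config$synthetic)
  has_csv <- !is.null(config$groups)
  if (has_syn == has_csv) {
    stop("config must set exactly one of `synthetic` or `groups`", call. = FALSE)
  }
  if (has_syn) {
    if (is.null(config$synthetic$groups) || !length(config$synthetic$groups)) {
      stop("`synthetic` needs a `groups` map of {label: {Pc, eta_a}}",
           call. = FALSE)
    }
    if (is.null(config$synthetic$cohort)) config$synthetic$cohort <- list()
    for (lab in names(config$synthetic$groups)) {
      g <- config$synthetic$groups[[lab]]
      if (is.null(g$Pc) || is.null(g$eta_a)) {
        stop(sprintf("synthetic group '%s' must set Pc and eta_a", lab),
             call. = FALSE)
      }
    }
  } else {
    for (lab in names(config$groups)) {
      g <- config$groups[[lab]]
      if (is.null(g$temperature_csv) || is.null(g$gas_csv)) {
        stop(sprintf("group '%s' must set temperature_csv and gas_csv", lab),
             call. = FALSE)
      }
    }
  }
  config
}

resolve_protocol <- function(spec) {
  if (is.null(spec)) return(make_protocol())
  if (inherits(spec, "treadmill_protocol")) return(spec)
  if (!is.null(spec$file)) {
    args <- spec
    args$file <- NULL
    return(do.call(read_protocol_csv, c(list(spec$file), args)))
  }
  do.call(make_protocol, spec)
}
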