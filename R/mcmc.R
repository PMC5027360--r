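#' MCMC sampler configuration
#'
#' Settings for the random-walk Metropolis-Hastings sampler over
#' `(Pc, eta_a)`. The support box acts as a flat prior: proposals outside
#' it are rejected outright, so the chain targets the likelihood restricted
#' to the box. Defaults (50,000 draws, 5,000 burn-in, proposal SDs 0.01
#' degC/min and 5e-4 1/min) put the acceptance rate in the conventional
#' 0.2-0.5 band on group series of the scale this model is fit to; all are
#' overridable.
#'
#' @param n_samples total chain length (including burn-in).
#' @param burn_in leading draws discarded; `0 <= burn_in < n_samples`.
#' @param proposal_sd length-2 numeric, proposal SD for `Pc` (degC/min) and
#'   `eta_a` (1/min).
#' @param seed integer seed; the sampler is deterministic given it.
#' @param support 2x2 matrix, rows `Pc` and `eta_a`, columns lower/upper
#'   bounds (finite, lower >= 0).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 50000, burn_in = 5000,
                        proposal_sd = c(Pc = 0.01, eta_a = 5e-4),
                        seed = 1L,
                        support = rbind(Pc = c(0, 1), eta_a = c(0, 0.1))) {
  stopifnot(n_samples > burn_in, burn_in >= 0,
            length(proposal_sd) == 2, all(proposal_sd > 0),
            is.matrix(support), nrow(support) == 2, ncol(support) == 2,
            all(is.finite(support)), all(support[, 1] >= 0),
            all(support[, 2] > support[, 1]))
  rownames(support) <- c("Pc", "eta_a")
  structure(
    list(n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
         proposal_sd = stats::setNames(as.numeric(proposal_sd), c("Pc", "eta_a")),
         seed = as.integer(seed), support = support),
    class = "mcmc_config"
  )
}

#' Random-walk Metropolis-Hastings over (Pc, eta_a)
#'
#' Samples a 2-parameter target with independent Gaussian proposals per
#' coordinate, initialized at the center of the support box. A proposal
#' outside the box has target density zero (flat prior on the box) and is
#' rejected without evaluating `log_target`. Burn-in draws are discarded;
#' the retained draws, their log-target values and the retained-phase
#' acceptance rate are returned. Runs are reproducible: the RNG is seeded
#' from `config$seed` (the caller's RNG state is preserved).
#'
#' @param log_target function of `(Pc, eta_a)` returning a log-density up
#'   to a constant; must be finite somewhere in the support.
#' @param config an [mcmc_config()].
#' @return an object of class `posterior_ensemble`: list with `draws`
#'   (data.frame `Pc`, `eta_a`), `log_like`, `acceptance_rate`, `config`.
#' @export
metropolis_hastings <- function(log_target, config = mcmc_config()) {
  stopifnot(is.function(log_target), inherits(config, "mcmc_config"))
  n <- config$n_samples
  sup <- config$support

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  step1 <- stats::rnorm(n, 0, config$proposal_sd[1])
  step2 <- stats::rnorm(n, 0, config$proposal_sd[2])
  log_u <- log(stats::runif(n))

  cur <- c(mean(sup[1, ]), mean(sup[2, ]))
  cur_ll <- log_target(cur[1], cur[2])
  if (!is.finite(cur_ll)) {
    stop("log_target is not finite at the support center; choose a support ",
         "box containing non-degenerate parameter values", call. = FALSE)
  }
  draws <- matrix(NA_real_, n, 2)
  lls <- numeric(n)
  accepted <- logical(n)
  for (i in seq_len(n)) {
    p1 <- cur[1] + step1[i]
    p2 <- cur[2] + step2[i]
    if (p1 >= sup[1, 1] && p1 <= sup[1, 2] &&
        p2 >= sup[2, 1] && p2 <= sup[2, 2]) {
      ll <- log_target(p1, p2)
      if (is.finite(ll) && (ll >= cur_ll || log_u[i] < ll - cur_ll)) {
        cur <- c(p1, p2)
        cur_ll <- ll
        accepted[i] <- TRUE
      }
    }
    draws[i, 1] <- cur[1]
    draws[i, 2] <- cur[2]
    lls[i] <- cur_ll
  }

  keep <- seq.int(config$burn_in + 1L, n)
  acc <- mean(accepted[keep])
  if (acc == 0) {
    stop(sprintf(
      paste0("no accepted moves after burn-in (chain stuck at Pc=%.4g, ",
             "eta_a=%.4g, log-target %.4g); reduce proposal_sd or widen ",
             "the support"),
      cur[1], cur[2], cur_ll), call. = FALSE)
  }
  structure(
    list(
      draws = data.frame(Pc = draws[keep, 1], eta_a = draws[keep, 2]),
      log_like = lls[keep],
      acceptance_rate = acc,
      config = config
    ),
    class = "posterior_ensemble"
  )
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf("Posterior ensemble: %d retained draws, acceptance rate %.3f\n",
              nrow(x$draws), x$acceptance_rate))
  s <- summarize_posterior(x)
  cat(sprintf("  Pc    = %.4f +/- %.4f degC/min\n", s$Pc$mean, s$Pc$se))
  cat(sprintf("  eta_a = %.5f +/- %.5f 1/min\n", s$eta_a$mean, s$eta_a$se))
  invisible(x)
}

#' Parameter estimate (mean with standard error)
#'
#' @param name parameter name.
#' @param mean point estimate.
#' @param se its standard error (posterior SD for MCMC summaries), >= 0.
#' @return a list of class `parameter_estimate`.
#' @export
parameter_estimate <- function(name, mean, se) {
  stopifnot(is.finite(mean), is.finite(se), se >= 0)
  structure(list(name = name, mean = mean, se = se),
            class = "parameter_estimate")
}

#' @export
print.parameter_estimate <- function(x, ...) {
  cat(sprintf("%s = %g +/- %g\n", x$name, x$mean, x$se))
  invisible(x)
}

#' Posterior summaries of the sampled parameters
#'
#' Reports the posterior mean and posterior SD of each parameter over the
#' retained draws; the posterior SD is reported as the estimate's standard
#' error, which is how ensemble spreads are quoted alongside group
#' comparisons.
#'
#' @param ens a `posterior_ensemble`.
#' @return named list of two [parameter_estimate()]s, `Pc` and `eta_a`.
#' @export
summarize_posterior <- function(ens) {
  stopifnot(inherits(ens, "posterior_ensemble"))
  if (nrow(ens$draws) == 0) stop("empty ensemble", call. = FALSE)
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  list(
    Pc = parameter_estimate("Pc", mean(ens$draws$Pc), sd0(ens$draws$Pc)),
    eta_a = parameter_estimate("eta_a", mean(ens$draws$eta_a), sd0(ens$draws$eta_a))
  )
}

#' Two-sample z-test on parameter estimates
#'
#' Compares two estimates by `z = (a - b) / sqrt(se_a^2 + se_b^2)` with a
#' two-sided standard-normal p-value — the conventional test for comparing
#' group-level posterior means quoted as mean +/- SE.
#'
#' @param a,b [parameter_estimate()]s (or lists with `mean` and `se`).
#' @return list with `z` and two-sided `p`.
#' @export
z_test <- function(a, b) {
  stopifnot(is.finite(a$mean), is.finite(b$mean),
            is.finite(a$se), is.finite(b$se), a$se >= 0, b$se >= 0)
  if (a$se == 0 && b$se == 0) {
    stop("z-test undefined: both standard errors are zero", call. = FALSE)
  }
  z <- (a$mean - b$mean) / sqrt(a$se^2 + b$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
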