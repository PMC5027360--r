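test_that("mcmc_config validates its fields", {
  expect_s3_class(mcmc_config(), "mcmc_config")
  expect_error(mcmc_config(n_samples = 100, burn_in = 100))
  expect_error(mcmc_config(proposal_sd = c(0.01, -1)))
  expect_error(mcmc_config(support = rbind(c(1, 0), c(0, 0.1))))
})

test_that("a flat target inside the box accepts every proposal", {
  # proposals too small to reach the box edge from the center in 2000 steps
  cfg <- mcmc_config(n_samples = 2000, burn_in = 100,
                     proposal_sd = c(1e-4, 1e-6), seed = 1)
  ens <- metropolis_hastings(function(Pc, eta_a) 0, cfg)
  expect_equal(ens$acceptance_rate, 1.0)
})

test_that("a flat target yields uniform draws over the box", {
  cfg <- mcmc_config(n_samples = 20000, burn_in = 2000,
                     proposal_sd = c(0.25, 0.025), seed = 2)
  ens <- metropolis_hastings(function(Pc, eta_a) 0, cfg)
  thin <- seq(1, nrow(ens$draws), by = 60) # decorrelate before the KS test
  expect_gt(stats::ks.test(ens$draws$Pc[thin], "punif", 0, 1)$p.value, 0.01)
  expect_gt(stats::ks.test(ens$draws$eta_a[thin], "punif", 0, 0.1)$p.value, 0.01)
})

test_that("a 2-D Gaussian target is recovered in mean and covariance", {
  mu <- c(0.5, 0.05)
  sd_t <- c(0.05, 0.005)
  target <- function(Pc, eta_a) {
    -0.5 * ((Pc - mu[1])^2 / sd_t[1]^2 + (eta_a - mu[2])^2 / sd_t[2]^2)
  }
  cfg <- mcmc_config(n_samples = 55000, burn_in = 5000,
                     proposal_sd = c(0.05, 0.005), seed = 3)
  ens <- metropolis_hastings(target, cfg)
  # batch-means Monte Carlo SE accounts for chain autocorrelation
  bm_se <- function(v, n_batch = 50) {
    m <- matrix(v[seq_len(n_batch * (length(v) %/% n_batch))],
                ncol = n_batch)
    stats::sd(colMeans(m)) / sqrt(n_batch)
  }
  expect_lt(abs(mean(ens$draws$Pc) - mu[1]), 3 * bm_se(ens$draws$Pc))
  expect_lt(abs(mean(ens$draws$eta_a) - mu[2]), 3 * bm_se(ens$draws$eta_a))
  emp <- stats::cov(ens$draws)
  tru <- diag(sd_t^2)
  expect_lt(norm(emp - tru, "F") / norm(tru, "F"), 0.1)
})

test_that("sampling is deterministic given the seed and preserves RNG state", {
  target <- function(Pc, eta_a) -0.5 * ((Pc - 0.5)^2 + (eta_a - 0.05)^2 / 1e-4)
  cfg <- mcmc_config(n_samples = 2000, burn_in = 200, seed = 42)
  set.seed(123)
  before <- .Random.seed
  e1 <- metropolis_hastings(target, cfg)
  expect_identical(.Random.seed, before)
  e2 <- metropolis_hastings(target, cfg)
  expect_identical(e1$draws, e2$draws)
  expect_identical(e1$log_like, e2$log_like)
})

test_that("draws never leave the support box", {
  cfg <- mcmc_config(n_samples = 5000, burn_in = 500,
                     proposal_sd = c(0.5, 0.05), seed = 6)
  ens <- metropolis_hastings(function(Pc, eta_a) 0, cfg)
  expect_true(all(ens$draws$Pc >= 0 & ens$draws$Pc <= 1))
  expect_true(all(ens$draws$eta_a >= 0 & ens$draws$eta_a <= 0.1))
})

test_that("a stuck chain raises a convergence failure", {
  # spike target: zero density everywhere except the (unreachable) corner
  spike <- function(Pc, eta_a) if (Pc > 0.999) 0 else -Inf
  cfg <- mcmc_config(n_samples = 200, burn_in = 10,
                     proposal_sd = c(1e-6, 1e-8), seed = 1)
  expect_error(metropolis_hastings(spike, cfg), "not finite at the support center")
  flat_spike <- function(Pc, eta_a) {
    if (abs(Pc - 0.5) < 1e-9 && abs(eta_a - 0.05) < 1e-9) 0 else -Inf
  }
  expect_error(metropolis_hastings(flat_spike, cfg), "no accepted moves")
})

test_that("posterior summaries are the ensemble mean and SD", {
  ens <- structure(list(draws = data.frame(Pc = c(0.2, 0.3),
                                           eta_a = c(0.01, 0.02)),
                        log_like = c(0, 0), acceptance_rate = 0.5,
                        config = mcmc_config()),
                   class = "posterior_ensemble")
  s <- summarize_posterior(ens)
  expect_equal(s$Pc$mean, 0.25)
  expect_equal(s$eta_a$mean, 0.015)
  expect_equal(s$Pc$se, stats::sd(c(0.2, 0.3)))
  ens$draws <- data.frame(Pc = rep(0.3, 5), eta_a = rep(0.02, 5))
  s2 <- summarize_posterior(ens)
  expect_equal(s2$Pc$se, 0)
  ens$draws <- ens$draws[0, ]
  expect_error(summarize_posterior(ens), "empty")
})

test_that("z-test reproduces the group-comparison significance pattern", {
  equal <- z_test(parameter_estimate("x", 0.2, 0.01),
                  parameter_estimate("x", 0.2, 0.01))
  expect_equal(equal$z, 0)
  expect_equal(equal$p, 1)
  # heat dissipation: clearly significant at the reported group estimates
  zd <- z_test(parameter_estimate("eta_a", 0.0194, 0.0005),
               parameter_estimate("eta_a", 0.0156, 0.0005))
  expect_lt(zd$p, 0.005)
  # core heat production: no significant difference
  zp <- z_test(parameter_estimate("Pc", 0.25, 0.02),
               parameter_estimate("Pc", 0.24, 0.02))
  expect_gt(zp$p, 0.05)
  expect_error(z_test(parameter_estimate("x", 1, 0),
                      parameter_estimate("x", 2, 0)), "undefined")
})
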