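test_that("identical seeds give identical traces", {
  sim <- sim_bd_tree(seed = 81, n_range = c(20, 120))
  st <- mcmc_settings(generations = 400, thin = 4, pre_burn_in = 100,
                      n_runs = 1, seed = 42)
  a <- run_ebd_mcmc(sim$phy, zeta = 0.01, rho = 1, settings = st)
  b <- run_ebd_mcmc(sim$phy, zeta = 0.01, rho = 1, settings = st)
  expect_identical(a[[1]]$samples, b[[1]]$samples)
})

test_that("prior-only runs reproduce the calibrated shift expectation", {
  # with the likelihood switched off the sampler targets the HSMRF prior;
  # the effective-shift count of sampled trajectories must match the
  # calibration target the zeta was built for
  K <- 24
  zeta <- calibrate_zeta(K, mc_reps = 4e4, seed = 2)
  sim <- sim_bd_tree(seed = 91, n_range = c(10, 200))
  st <- mcmc_settings(generations = 30000, thin = 10, pre_burn_in = 500,
                      n_runs = 1, seed = 7)
  tra <- run_ebd_mcmc(sim$phy, time_grid(K), zeta, 1, settings = st,
                      likelihood = "none")
  lam <- tra[[1]]$samples[, paste0("lambda_", 1:K)]
  count_shifts <- function(x) {
    cum <- log(x) - log(x[1]); ref <- 0; n <- 0
    for (i in seq_along(cum)) {
      if (abs(cum[i] - ref) >= log(2)) { n <- n + 1; ref <- cum[i] }
    }
    n
  }
  ns <- apply(lam, 1, count_shifts)
  ess <- effective_size(ns)
  se <- sd(ns) / sqrt(ess)
  expect_lt(abs(mean(ns) - log(2)), 4 * se)
})

test_that("identical traces pass the KS convergence check", {
  m <- matrix(rnorm(600), 200, 3,
              dimnames = list(NULL, c("lambda_1", "lambda_2", "mu_1")))
  t1 <- list(samples = m)
  rep <- check_convergence(list(t1, t1))
  expect_true(rep$converged)
  expect_true(all(rep$parameters$ks == 0))
})

test_that("the KS check passes same-distribution runs at the stated rate", {
  set.seed(10)
  res <- vapply(1:200, function(i) {
    t1 <- list(samples = matrix(rnorm(1000), ncol = 1,
                                dimnames = list(NULL, "x")))
    t2 <- list(samples = matrix(rnorm(1000), ncol = 1,
                                dimnames = list(NULL, "x")))
    check_convergence(list(t1, t2))$converged
  }, logical(1))
  expect_gte(mean(res), 0.95)
})

test_that("the KS check fails distributions separated by 3 SD", {
  set.seed(11)
  t1 <- list(samples = matrix(rnorm(1000), ncol = 1,
                              dimnames = list(NULL, "x")))
  t2 <- list(samples = matrix(rnorm(1000, mean = 3), ncol = 1,
                              dimnames = list(NULL, "x")))
  expect_false(check_convergence(list(t1, t2))$converged)
})

test_that("short traces are flagged inconclusive rather than failed", {
  set.seed(12)
  x <- cumsum(rnorm(60))  # strongly autocorrelated, tiny ESS
  t1 <- list(samples = matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  t2 <- list(samples = matrix(cumsum(rnorm(60)), ncol = 1,
                              dimnames = list(NULL, "x")))
  rep <- check_convergence(list(t1, t2),
                           convergence_config(min_ess = 100))
  expect_true(all(rep$parameters$status %in% c("inconclusive", "pass")))
})

test_that("rate summaries match brute-force quantiles and truncation", {
  K <- 6
  set.seed(3)
  m <- cbind(matrix(rlnorm(300 * K, log(0.1), 0.3), 300, K),
             matrix(rlnorm(300 * K, log(0.05), 0.3), 300, K), 1, 1, 0)
  colnames(m) <- c(paste0("lambda_", 1:K), paste0("mu_", 1:K),
                   "global_lambda", "global_mu", "loglik")
  tr <- structure(list(samples = m, grid = time_grid(K)),
                  class = "posterior_trace")
  s <- summarize_rates(tr, burn_in_fraction = 0)
  kept <- m[, "lambda_3"]
  expect_equal(s$intervals$lambda_median[3], median(kept))
  expect_equal(s$intervals$lambda_lower[3],
               sort(kept)[ceiling(0.025 * length(kept))],
               tolerance = 0.02)
  # burn-in removal
  s2 <- summarize_rates(tr, burn_in_fraction = 0.5)
  expect_equal(s2$n_samples, 150)
  # constant trace: zero-width intervals
  m2 <- m; m2[, 1:(2 * K)] <- 0.2
  tr2 <- tr; tr2$samples <- m2
  s3 <- summarize_rates(tr2, burn_in_fraction = 0)
  expect_equal(s3$intervals$lambda_lower, s3$intervals$lambda_upper)
  # truncation drops exactly the old intervals
  s4 <- summarize_rates(tr, burn_in_fraction = 0, truncate_to = 4)
  expect_equal(nrow(s4$intervals), 4)
  expect_error(summarize_rates(tr, truncate_to = 10), "exceeds")
})
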