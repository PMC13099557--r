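make_reference <- function(K = 14) {
  rate_trajectory(time_grid(K),
                  seq(0.16, 0.30, length.out = K),
                  seq(0.03, 0.10, length.out = K))
}

test_that("pulled diversification rate is lambda - mu for constant rates", {
  tr <- rate_trajectory(time_grid(8), 0.2, 0.07)
  expect_equal(pulled_diversification_rate(tr), rep(0.13, 8),
               tolerance = 1e-12)
  expect_error(
    pulled_diversification_rate(rate_trajectory(time_grid(3), 0, 0.1)),
    "lambda > 0")
})

test_that("a doubled-lambda step carries the discrete log-derivative spike", {
  lam <- c(0.1, 0.1, 0.2, 0.2)
  tr <- rate_trajectory(time_grid(4), lam, 0.02)
  rp <- pulled_diversification_rate(tr)
  # hand computation: interval 2 sees (0.2 - 0.1) / (1 * 0.1) = 1
  expect_equal(rp, c(0.08, 0.1 - 0.02 + 1, 0.18, 0.18), tolerance = 1e-12)
})

test_that("congruent partners preserve the pulled rate exactly", {
  ref <- make_reference()
  # identity: mu* = reference mu
  ident <- congruent_lambda_given_mu(ref, ref$mu)
  expect_equal(ident$lambda, ref$lambda, tolerance = 1e-12)
  expect_true(attr(ident, "valid"))

  p <- congruent_lambda_given_mu(ref, mean(ref$mu))
  K <- ref$grid$n_intervals
  expect_equal(pulled_diversification_rate(p)[-K],
               pulled_diversification_rate(ref)[-K], tolerance = 1e-8)

  # extreme extinction forces negative lambda* somewhere -> invalid
  huge <- congruent_lambda_given_mu(ref, 5)
  expect_false(attr(huge, "valid"))
})

test_that("congruent partners reproduce the reference likelihood", {
  ref <- make_reference()
  sim <- sim_bd_tree(lambda = 0.3, mu = 0.05, root_age = 13, seed = 101,
                     n_range = c(40, 200))
  phy <- sim$phy
  f <- 5e4
  ll_ref <- ebd_log_likelihood(phy, divpace:::refine_trajectory(ref, f), 1)
  p <- congruent_lambda_given_mu(ref, mean(ref$mu), refine = f)
  expect_true(attr(p, "valid"))
  expect_equal(ebd_log_likelihood(phy, p, 1), ll_ref, tolerance = 2e-6)
})

test_that("the four named scenarios behave at their fixed points", {
  const <- rate_trajectory(time_grid(10), 0.2, 0.08)
  for (s in c("constant-mu", "exp-increasing-mu", "constant-lambda",
              "exp-decreasing-lambda")) {
    out <- scenario_test(const, s)
    expect_true(out$valid)
    expect_equal(out$trajectory$lambda, rep(0.2, 10), tolerance = 1e-9)
    expect_equal(out$trajectory$mu, rep(0.08, 10), tolerance = 1e-9)
  }
  # exp-increasing-mu with exponent 0 is exactly constant-mu
  ref <- make_reference()
  a <- scenario_test(ref, "exp-increasing-mu", exponent = 0)
  b <- congruent_lambda_given_mu(ref, ref$mu[1])
  expect_equal(a$trajectory$lambda, b$lambda, tolerance = 1e-12)
})

test_that("steeply rising speciation makes constant-lambda invalid", {
  K <- 12
  ref <- rate_trajectory(time_grid(K),
                         0.05 * exp(seq(0, 2.5, length.out = K)), 0.01)
  out <- scenario_test(ref, "constant-lambda")
  expect_false(out$valid)
})

test_that("trend labels follow the twice-mean-delta-lambda threshold", {
  # hand-built 5-interval trajectory
  lam <- c(0.10, 0.11, 0.20, 0.20, 0.19)
  mu <- rep(0.02, 5)
  ref <- rate_trajectory(time_grid(5), lam, mu)
  # threshold = 2 * mean(|diff|) = 2 * mean(0.01, 0.09, 0, 0.01) = 0.055
  set <- list(reference = ref,
              members = list(list(trajectory = ref),
                             list(trajectory = rate_trajectory(
                               time_grid(5), 0.15, 0.02))))
  tr <- summarize_trends(set)
  expect_equal(tr$threshold, 0.055, tolerance = 1e-12)
  expect_equal(unname(tr$reference_labels$r),
               c("flat", "increase", "flat", "flat"))
  # member 1 = reference: full agreement; member 2 constant: all flat
  expect_equal(unname(tr$member_labels[1, ]), tr$reference_labels$r)
  expect_equal(unname(tr$member_labels[2, ]), rep("flat", 4))
  expect_equal(unname(tr$agreement), c(1, 0.5, 1, 1))
})

test_that("the joint congruence sampler is deterministic and validated", {
  ref <- make_reference()
  cfg <- congruence_sampler_config(n_sets = 6, seed = 9)
  s1 <- sample_congruent_set(ref, cfg)
  s2 <- sample_congruent_set(ref, cfg)
  expect_equal(length(s1$members), 6)
  expect_identical(
    lapply(s1$members, function(m) m$trajectory$lambda),
    lapply(s2$members, function(m) m$trajectory$lambda))
  expect_true(all(vapply(s1$members, `[[`, TRUE, "valid")))
  for (m in s1$members) {
    expect_true(all(m$trajectory$lambda >= 0))
    expect_true(all(m$trajectory$mu >= 0))
  }
  # n_sets = 0: empty member list
  s0 <- sample_congruent_set(ref, congruence_sampler_config(n_sets = 0))
  expect_length(s0$members, 0)
})
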