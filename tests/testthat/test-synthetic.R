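test_that("pure-birth mean tip count matches the closed form", {
  # E[N] = 2 exp(r * T) for a crown-start pure birth with no sampling
  tr <- rate_trajectory(time_grid(10), 0.1, 0)
  set.seed(99)
  n <- vapply(1:1000, function(i) {
    sim <- simulate_ebd_tree(tr, 10, rho = 1, condition_on_survival = FALSE)
    sim$truth$n_extant_full
  }, numeric(1))
  expected <- 2 * exp(0.1 * 10)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("survival conditioning guarantees at least two sampled tips", {
  tr <- rate_trajectory(time_grid(8), 0.3, 0.3)
  for (s in 1:10) {
    sim <- simulate_ebd_tree(tr, 8, rho = 0.5, seed = s)
    expect_gte(length(sim$phy$tip.label), 2)
  }
})

test_that("rho-sampling is Bernoulli thinning of the full extant set", {
  tr <- rate_trajectory(time_grid(10), 0.25, 0.05)
  set.seed(7)
  kept <- full <- numeric(300)
  for (i in seq_len(300)) {
    sim <- simulate_ebd_tree(tr, 10, rho = 0.5)
    kept[i] <- length(sim$phy$tip.label)
    full[i] <- sim$truth$n_extant_full
  }
  # conditional on the full count, kept ~ Binomial(full, rho): check the
  # aggregate mean and a variance-consistent z-score
  expect_lt(abs(sum(kept) - 0.5 * sum(full)) / sqrt(0.25 * sum(full)), 4)
})

test_that("same seed gives bit-identical simulations", {
  tr <- rate_trajectory(time_grid(10), 0.25, 0.05)
  a <- simulate_ebd_tree(tr, 10, rho = 0.7, seed = 123)
  b <- simulate_ebd_tree(tr, 10, rho = 0.7, seed = 123)
  expect_identical(ape::write.tree(a$phy), ape::write.tree(b$phy))
  m <- hisse2_model(c(0.2, 0.2, 0.25, 0.25), rep(0.05, 4), 0.05, 0.02)
  s1 <- simulate_sse_tree(m, 8, seed = 5)
  s2 <- simulate_sse_tree(m, 8, seed = 5)
  expect_identical(s1$tip_state, s2$tip_state)
  expect_identical(ape::write.tree(s1$phy), ape::write.tree(s2$phy))
})

test_that("state-dependent simulation respects degenerate transition rates", {
  # Q = 0 keeps every lineage in the root state
  m <- sse_model(c("s1", "s2"), c(1L, 2L), c(0.25, 0.25), c(0.05, 0.05),
                 matrix(0, 2, 2))
  sim <- simulate_sse_tree(m, 10, seed = 2, root_state = 1)
  expect_true(all(sim$truth$tip_state_combined == 1))
  expect_true(all(sim$truth$edge_truth$n_state_changes == 0))
})

test_that("state-1 dominance emerges under asymmetric speciation", {
  m <- sse_model(c("s0", "s1"), c(0L, 1L), c(0.1, 0.2), c(0.02, 0.02),
                 matrix(c(-0.05, 0.05, 0.05, -0.05), 2, 2, byrow = TRUE))
  set.seed(31)
  frac1 <- vapply(1:40, function(i) {
    sim <- simulate_sse_tree(m, 25, root_state = 1, max_tips = 20000)
    mean(sim$tip_state == 1)
  }, numeric(1))
  expect_gt(mean(frac1), 0.5)
})

test_that("shift events in the BDS simulator occur at the nominal rate", {
  # eta = 0: no category changes anywhere
  s0 <- simulate_bds_tree(c(0.1, 0.2), 0.02, 0, 15, seed = 8)
  expect_true(all(s0$truth$edge_truth$n_state_changes == 0))

  # one category: degenerate, identical to constant-rate simulation
  s1 <- simulate_bds_tree(0.2, 0.05, 0.3, 12, seed = 9)
  expect_true(all(abs(s1$truth$edge_truth$mean_lambda - 0.2) < 1e-9))

  # Poisson rate oracle on the reconstructed tree: the switch process is
  # independent of diversification, so event count / tree length ~ eta
  eta <- 0.02
  set.seed(12)
  tot_ev <- tot_len <- 0
  for (i in 1:60) {
    sim <- simulate_bds_tree(c(0.15, 0.15), 0.03, eta, 15)
    tot_ev <- tot_ev + sum(sim$truth$edge_truth$n_state_changes)
    tot_len <- tot_len + sum(sim$phy$edge.length)
  }
  se <- sqrt(tot_ev) / tot_len
  expect_lt(abs(tot_ev / tot_len - eta), 4 * se + 1e-12)
})

test_that("posterior fixtures reproduce exact counting", {
  r0 <- rep(0.1, 50)
  fx <- make_posterior_fixture(r0, 2 * r0)
  expect_equal(t_statistic(fx, 1.3, "A"), 1.0)
  expect_equal(t_statistic(fx, 1.9, "B"), 1.0)
  expect_equal(t_statistic(fx, 2.1, "A"), 0.0)

  r1 <- c(rep(0.2, 25), rep(0.05, 25))
  fx2 <- make_posterior_fixture(r0, r1)
  expect_equal(t_statistic(fx2, 1.5, "A"), 0.5)

  set.seed(77)
  ra <- rnorm(200, 0.1, 0.05)
  rb <- rnorm(200, 0.12, 0.05)
  fx3 <- make_posterior_fixture(ra, rb)
  for (a in c(1.0, 1.3, 1.5)) {
    expect_identical(t_statistic(fx3, a, "A"), mean(rb > a * ra))
  }
})

test_that("the lineage cap refuses supercritical runaway simulations", {
  tr <- rate_trajectory(time_grid(100), 0.5, 0)
  expect_error(simulate_ebd_tree(tr, 100, max_tips = 1000), "cap")
})
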