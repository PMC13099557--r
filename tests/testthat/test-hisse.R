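test_that("feeding-mode classification follows the detachment rules", {
  expect_equal(classify_feeding("detachment-required"), "benthic")
  expect_equal(classify_feeding("attached-resource"), "benthic")
  expect_equal(classify_feeding("ram-biter"), "nonbenthic")
  expect_equal(classify_feeding("free-swimming"), "nonbenthic")
  expect_equal(classify_feeding("ectoparasite-feeder"), "benthic")
  # majority rule and ties
  expect_equal(classify_feeding(c("detachment-required", "attached-resource",
                                  "free-swimming")), "benthic")
  expect_equal(classify_feeding(c("ram-biter", "attached-resource")),
               "unclassified")
  expect_equal(classify_feeding(character(0)), "unclassified")
  expect_error(classify_feeding("grazer"), "unknown")

  tab <- classify_feeding_table(data.frame(
    species = c("a", "b"),
    descriptors = c("detachment-required; free-swimming; attached-resource",
                    "ram-biter")))
  expect_equal(tab$classification, c("benthic", "nonbenthic"))
})

test_that("HiSSE-2 collapses to constant birth-death when states are idle", {
  sim <- sim_bd_tree(lambda = 0.22, mu = 0.06, seed = 151,
                     n_range = c(25, 150))
  phy <- sim$phy
  m <- hisse2_model(rep(0.2, 4), rep(0.05, 4), q01 = 0.07, qAB = 0.03,
                    rho = 0.7)
  amb <- setNames(rep(NA, length(phy$tip.label)), phy$tip.label)
  expect_equal(hisse2_log_likelihood(phy, amb, m),
               bd_constant_log_likelihood(phy, 0.2, 0.05, 0.7),
               tolerance = 1e-6)
})

test_that("HiSSE-2 with idle hidden states matches a BiSSE oracle", {
  m0 <- hisse2_model(c(0.15, 0.3, 0.15, 0.3), c(0.05, 0.08, 0.05, 0.08),
                     q01 = 0.04, qAB = 0.02, rho = 0.8)
  sim <- simulate_sse_tree(m0, 16, seed = 33, max_tips = 5000)
  n <- length(sim$phy$tip.label)
  skip_if(n < 10 || n > 300, "fixture outside size window")
  ours <- hisse2_log_likelihood(sim$phy, sim$tip_state, m0)
  oracle <- bisse_oracle_loglik(sim$phy, sim$tip_state,
                                lambda = c(0.15, 0.3), mu = c(0.05, 0.08),
                                q01 = 0.04, rho = 0.8)
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("impossible states give -Inf likelihood", {
  # every tip in state 1, lambda for state-1 zero in both hidden layers,
  # no transitions, no extinction: any branching in state 1 is impossible
  sim <- sim_bd_tree(seed = 161, n_range = c(5, 60))
  phy <- sim$phy
  m <- hisse2_model(c(0.2, 0, 0.2, 0), rep(0, 4), q01 = 0, qAB = 0)
  all1 <- setNames(rep(1, length(phy$tip.label)), phy$tip.label)
  expect_identical(hisse2_log_likelihood(phy, all1, m), -Inf)
})

test_that("the T statistic is an exact posterior counting", {
  set.seed(30)
  r0 <- rnorm(500, 0.08, 0.04)
  r1 <- rnorm(500, 0.12, 0.04)
  fx <- make_posterior_fixture(r0, r1)
  for (a in c(1.0, 1.3, 1.5)) {
    for (h in c("A", "B")) {
      expect_identical(t_statistic(fx, a, h), mean(r1 > a * r0))
    }
  }
  empty <- make_posterior_fixture(numeric(0), numeric(0))
  expect_error(t_statistic(empty, 1.3, "A"), "empty")
})

test_that("states-through-time fractions are exact for hand-built maps", {
  # 3-branch tree: ((A:1,B:1):1,C:2)
  phy <- read_ultrametric_tree(tiny_newick())
  grid <- time_grid(2)
  td <- divpace:::sse_tree_data(phy)
  # hand-built lineage-time: state 1 on all branches except tip C in state 2
  # interval 1 (0-1 My): A, B in state 1 (2 My), C in state 2 (1 My)
  # interval 2 (1-2 My): one internal branch state 1 (1), C state 2 (1)
  lt <- matrix(0, 2, 4)
  lt[1, 1] <- 2; lt[1, 2] <- 1
  lt[2, 1] <- 1; lt[2, 2] <- 1
  trace <- structure(list(
    maps = list(list(node_state = c(1, 1, 2, 1, 1), lineage_time = lt)),
    stt_grid = grid, state_names = c("0A", "1A", "0B", "1B"),
    samples = matrix(0, 1, 1), burn_in_applied = TRUE),
    class = "hisse_trace")
  stt <- states_through_time(trace, burn_in_fraction = 0)
  expect_equal(stt$prop_0A, c(2 / 3, 1 / 2))
  expect_equal(stt$prop_1A, c(1 / 3, 1 / 2))
  expect_equal(rowSums(as.matrix(stt[, 3:6])), c(1, 1))
})

test_that("ancestral state frequencies are exact map counts", {
  ns <- rbind(c(1, 2, 3, 4, 1), c(1, 2, 3, 4, 1), c(2, 2, 3, 4, 3),
              c(1, 2, 3, 4, 1))
  maps <- lapply(seq_len(nrow(ns)), function(i) {
    list(node_state = ns[i, ], lineage_time = NULL)
  })
  trace <- structure(list(maps = maps, state_names = c("0A", "1A", "0B", "1B"),
                          stt_grid = time_grid(2)),
                     class = "hisse_trace")
  p <- ancestral_states(trace, burn_in_fraction = 0)
  expect_equal(unname(p[1, ]), c(0.75, 0.25, 0, 0))
  expect_equal(unname(p[5, ]), c(0.75, 0, 0.25, 0))
  expect_equal(unname(rowSums(p)), rep(1, 5))
  # all maps agree -> probability 1 at every node
  p2 <- ancestral_states(structure(list(
    maps = maps[c(1, 2)], state_names = c("0A", "1A", "0B", "1B"),
    stt_grid = time_grid(2)), class = "hisse_trace"),
    burn_in_fraction = 0)
  expect_true(all(apply(p2, 1, max) == 1))
})

test_that("stochastic maps agree with posterior frequencies on a tiny tree", {
  # single-state sanity: with one effective state all maps are that state
  phy <- read_ultrametric_tree(tiny_newick())
  td <- divpace:::sse_tree_data(phy)
  tips <- matrix(1, 3, 2); tips[, 2] <- 0   # all tips state 1 of 2
  Q <- matrix(c(-0.001, 0.001, 0.001, -0.001), 2, 2, byrow = TRUE)
  mp <- divpace:::sse_map_cpp(td, tips, c(0.2, 0.2), c(0.02, 0.02), Q, 1,
                              c(0.5, 0.5), TRUE, 1e-8, 1e-10, 20L,
                              time_grid(2)$boundaries)
  expect_true(all(mp$node_state[, 1:3] == 1))  # tips forced to state 1
  lt <- apply(mp$lineage_time, c(1, 2), mean)
  expect_gt(sum(lt[, 1]), 0.95 * sum(lt))     # nearly all time in state 1
})

test_that("floor-mode extinction keeps mu at least half of lambda", {
  m0 <- hisse2_model(rep(0.25, 4), rep(0.1, 4), 0.03, 0.02)
  sim <- simulate_sse_tree(m0, 12, seed = 41, max_tips = 2000)
  skip_if(length(sim$phy$tip.label) < 10, "fixture too small")
  tra <- run_hisse_mcmc(sim$phy, sim$tip_state,
                        priors = hisse_priors(extinction_mode = "floor"),
                        settings = mcmc_settings(generations = 300, thin = 5,
                                                 pre_burn_in = 100,
                                                 n_runs = 1, seed = 3),
                        map_every = 0)
  m <- tra[[1]]$samples
  for (s in c("0A", "1A", "0B", "1B")) {
    expect_true(all(m[, paste0("mu_", s)] >=
                      0.5 * m[, paste0("lambda_", s)] - 1e-12))
  }
})

test_that("HiSSE MCMC is deterministic given the seed", {
  m0 <- hisse2_model(rep(0.25, 4), rep(0.05, 4), 0.03, 0.02)
  sim <- simulate_sse_tree(m0, 10, seed = 43, max_tips = 2000)
  skip_if(length(sim$phy$tip.label) < 6, "fixture too small")
  st <- mcmc_settings(generations = 120, thin = 4, pre_burn_in = 40,
                      n_runs = 1, seed = 11)
  a <- run_hisse_mcmc(sim$phy, sim$tip_state, settings = st, map_every = 0)
  b <- run_hisse_mcmc(sim$phy, sim$tip_state, settings = st, map_every = 0)
  expect_identical(a[[1]]$samples, b[[1]]$samples)
})
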