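test_that("lognormal discretization matches numeric quantiles", {
  expect_equal(discretize_lognormal(log(0.2), 0, 6), rep(0.2, 6))
  expect_equal(discretize_lognormal(log(0.2), 1, 1), 0.2)  # median
  cats <- discretize_lognormal(0, 1, 6)
  oracle <- vapply(seq_len(6), function(i) {
    # numeric inversion of the lognormal CDF at (i - 0.5) / 6
    uniroot(function(q) plnorm(q, 0, 1) - (i - 0.5) / 6,
            c(1e-8, 1e8), tol = 1e-12)$root
  }, numeric(1))
  expect_equal(cats, oracle, tolerance = 1e-10)
  expect_false(is.unsorted(cats))
})

test_that("BDS likelihood collapses to the constant-rate closed form", {
  sim <- sim_bd_tree(lambda = 0.22, mu = 0.06, seed = 111,
                     n_range = c(25, 150))
  phy <- sim$phy
  closed <- bd_constant_log_likelihood(phy, 0.2, 0.05, 0.7)
  # k = 1
  expect_equal(bds_log_likelihood(phy, bds_model(0.2, 0.05, 0, rho = 0.7)),
               closed, tolerance = 1e-6)
  # k = 2 with identical categories and switching: degenerate to k = 1
  expect_equal(
    bds_log_likelihood(phy, bds_model(c(0.2, 0.2), 0.05, 0.4, rho = 0.7)),
    closed, tolerance = 1e-6)
})

test_that("BDS likelihood is invariant to category permutation", {
  sim <- sim_bd_tree(seed = 121, n_range = c(20, 120))
  cats <- c(0.1, 0.2, 0.35)
  m1 <- bds_model(cats, 0.05, 0.02)
  ll1 <- bds_log_likelihood(sim$phy, m1)
  # bds_model sorts categories, so feed a permutation through the C++ core
  td <- divpace:::sse_tree_data(sim$phy)
  perm <- c(3, 1, 2)
  Q <- divpace:::bds_Q(3, 0.02)
  ll2 <- divpace:::sse_loglik_cpp(td, matrix(1, td$ntip, 3), cats[perm],
                                  rep(0.05, 3), Q, 1, rep(1 / 3, 3), TRUE,
                                  1e-8, 1e-10)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("BDS likelihood is continuous in eta near zero", {
  sim <- sim_bd_tree(seed = 131, n_range = c(20, 120))
  cats <- discretize_lognormal(log(0.15), 0.5, 4)
  ll <- vapply(c(0, 1e-6, 1e-4), function(eta) {
    bds_log_likelihood(sim$phy, bds_model(cats, 0.05, eta))
  }, numeric(1))
  expect_lt(abs(ll[2] - ll[1]), 1e-3)
  expect_lt(abs(ll[3] - ll[1]), 1e-1)
})

test_that("BDS likelihood agrees with a matrix-exponential discretization", {
  # brute-force oracle on a 4-tip tree: propagate [E, D] with fine fixed
  # Euler steps (independent of the package's adaptive RK core)
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1.5,(C:2,D:2):0.5);", path)
  phy <- read_ultrametric_tree(path)
  cats <- c(0.1, 0.3); mu <- 0.05; eta <- 0.2; rho <- 0.8
  h <- 5e-5
  step <- function(y) {
    E <- y[1:2]; D <- y[3:4]
    dE <- mu - (cats + mu + eta) * E + cats * E^2 + eta * rev(E)
    dD <- -(cats + mu + eta) * D + 2 * cats * E * D + eta * rev(D)
    y + h * c(dE, dD)
  }
  run <- function(y, tlen) {
    for (i in seq_len(round(tlen / h))) y <- step(y)
    y
  }
  tipY <- function() c(1 - rho, 1 - rho, rho, rho)
  yA <- run(tipY(), 1); yB <- run(tipY(), 1)
  yAB <- c(yA[1:2], cats * yA[3:4] * yB[3:4])
  yAB <- run(yAB, 1.5)
  yC <- run(tipY(), 2); yD <- run(tipY(), 2)
  yCD <- c(yC[1:2], cats * yC[3:4] * yD[3:4])
  yCD <- run(yCD, 0.5)
  Droot <- cats * yAB[3:4] * yCD[3:4]
  oracle <- log(sum(0.5 * Droot / (cats * (1 - yAB[1:2])^2)))
  ll <- bds_log_likelihood(phy, bds_model(cats, mu, eta, rho = rho))
  expect_equal(ll, oracle, tolerance = 1e-4)
})

test_that("shift records reproduce exact posterior-probability counting", {
  sim <- sim_bd_tree(seed = 141, n_range = c(10, 60))
  td <- divpace:::sse_tree_data(sim$phy)
  nedge <- length(td$child)
  # synthetic occupancy: branch j shifts in maps with known pattern
  set.seed(4)
  nmaps <- 40
  ev <- matrix(rbinom(nmaps * nedge, 1, 0.3), nmaps, nedge)
  ml <- matrix(runif(nmaps * nedge, 0.1, 0.3), nmaps, nedge)
  maps <- lapply(seq_len(nmaps), function(i) {
    list(events = ev[i, ], mean_lambda = ml[i, ], node_state = NULL)
  })
  trace <- structure(list(maps = maps, tree_data = td, k = 2),
                     class = "bds_trace")
  rec <- detect_shifts(trace, threshold = 0.5, burn_in_fraction = 0)
  ab <- attr(rec, "all_branches")
  expect_equal(ab$pp, colMeans(ev >= 1))
  expect_equal(ab$mean_lambda, colMeans(ml))
  # multiplier = branch mean / parent-branch mean
  pe <- match(td$parent, td$child)
  expect_equal(ab$multiplier, colMeans(ml) / colMeans(ml)[pe])
  # root branches excluded; strict threshold
  expect_true(all(!is.na(rec$multiplier)))
  expect_true(all(rec$pp > 0.5))

  # boundary: PP exactly 0.5 is excluded
  ev2 <- matrix(0L, 40, nedge); ev2[1:20, 3] <- 1L  # PP = 0.5 on branch 3
  maps2 <- lapply(seq_len(40), function(i) {
    list(events = ev2[i, ], mean_lambda = ml[i, ], node_state = NULL)
  })
  trace2 <- structure(list(maps = maps2, tree_data = td, k = 2),
                      class = "bds_trace")
  rec2 <- detect_shifts(trace2, threshold = 0.5, burn_in_fraction = 0)
  expect_equal(nrow(rec2), 0)
  # no category changes at all -> empty
  maps3 <- lapply(1:5, function(i) {
    list(events = rep(0L, nedge), mean_lambda = ml[1, ], node_state = NULL)
  })
  trace3 <- structure(list(maps = maps3, tree_data = td, k = 2),
                      class = "bds_trace")
  expect_equal(nrow(detect_shifts(trace3, burn_in_fraction = 0)), 0)
})

test_that("group comparisons match hand-computed ANOVA", {
  # identical distributions in both groups: between-group mean square 0
  rec <- data.frame(multiplier = exp(c(1, 2, 3, 1, 2, 3)))
  out <- compare_shift_groups(rec, rep(c("a", "b"), each = 3))
  expect_equal(out$anova_F, 0, tolerance = 1e-12)
  expect_equal(out$ratio, 1, tolerance = 1e-12)

  # hand-worked two-group ANOVA on log multipliers
  ya <- c(0.2, 0.5, 0.9, 0.4)
  yb <- c(1.1, 1.4, 1.0)
  rec2 <- data.frame(multiplier = exp(c(ya, yb)))
  out2 <- compare_shift_groups(rec2, c(rep("a", 4), rep("b", 3)))
  gm <- mean(c(ya, yb))
  ssb <- 4 * (mean(ya) - gm)^2 + 3 * (mean(yb) - gm)^2
  ssw <- sum((ya - mean(ya))^2) + sum((yb - mean(yb))^2)
  Fhand <- (ssb / 1) / (ssw / 5)
  expect_equal(out2$anova_F, Fhand, tolerance = 1e-10)
  expect_equal(unname(out2$ratio), exp(mean(yb) - mean(ya)),
               tolerance = 1e-10)
  expect_error(compare_shift_groups(rec2, rep("a", 7)), "2 groups")
})

test_that("a true 1.2x multiplier ratio is covered by the interval estimate", {
  # lognormal groups mirroring the benthic/nonbenthic sample sizes
  set.seed(20)
  cover <- vapply(1:100, function(i) {
    a <- rnorm(57, 0, 0.35)           # log multipliers, nonbenthic
    b <- rnorm(38, log(1.2), 0.35)    # benthic: true 1.2x larger
    ci <- t.test(b, a)$conf.int
    log(1.2) >= ci[1] && log(1.2) <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
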