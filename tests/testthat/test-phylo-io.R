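test_that("newick reading validates topology, branch lengths and tip ages", {
  phy <- read_ultrametric_tree(tiny_newick())
  expect_s3_class(phy, "phylo")
  expect_equal(length(phy$tip.label), 3)
  expect_equal(root_age(phy), 2)
  expect_equal(branching_times(phy), c(2, 1))

  bad <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2.5);", bad)
  expect_error(read_ultrametric_tree(bad), "ultrametric")

  poly <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,C:1);", poly)
  expect_error(read_ultrametric_tree(poly), "binary")

  nolen <- tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", nolen)
  expect_error(read_ultrametric_tree(nolen), "branch length")
})

test_that("write/read round trip preserves topology and branching times", {
  sim <- sim_bd_tree(seed = 21)
  path <- tempfile(fileext = ".nwk")
  write_ultrametric_tree(sim$phy, path)
  back <- read_ultrametric_tree(path)
  expect_setequal(back$tip.label, sim$phy$tip.label)
  expect_equal(branching_times(back), branching_times(sim$phy),
               tolerance = 1e-9)
})

test_that("pruning preserves ages and composes with nested subsets", {
  sim <- sim_bd_tree(seed = 31, n_range = c(40, 200))
  phy <- sim$phy
  n <- length(phy$tip.label)

  # identity
  same <- prune_to_set(phy, phy$tip.label)
  expect_equal(branching_times(same), branching_times(phy), tolerance = 1e-12)

  # two sister tips -> root at their MRCA age
  pair <- phy$tip.label[phy$edge[phy$edge[, 2] <= n, 2][1:2]]
  cherry_mrca <- ape::getMRCA(phy, pair)
  two <- prune_to_set(phy, pair)
  expect_equal(length(two$tip.label), 2)
  expect_equal(root_age(two), node_ages(phy)[cherry_mrca], tolerance = 1e-10)

  # brute-force pairwise-MRCA oracle on a random subset
  set.seed(5)
  keep <- sample(phy$tip.label, 25)
  sub <- prune_to_set(phy, keep)
  ages_full <- node_ages(phy)
  oracle <- sort(unique(vapply(combn(keep, 2, simplify = FALSE), function(p) {
    ages_full[ape::getMRCA(phy, p)]
  }, numeric(1))), decreasing = TRUE)
  expect_equal(branching_times(sub), oracle[seq_len(24)], tolerance = 1e-10)

  # composition: prune(prune(big), small) == prune(big, small)
  keep2 <- keep[1:10]
  expect_equal(branching_times(prune_to_set(sub, keep2)),
               branching_times(prune_to_set(phy, keep2)), tolerance = 1e-12)

  expect_error(prune_to_set(phy, phy$tip.label[1]), "fewer than 2")
})

test_that("branching times of simulated trees count and sort correctly", {
  sim <- sim_bd_tree(lambda = 0.2, mu = 0, seed = 41)
  bt <- branching_times(sim$phy)
  expect_length(bt, length(sim$phy$tip.label) - 1)
  expect_true(all(diff(bt) <= 0))
  # independent recursive traversal oracle
  phy <- sim$phy
  depth <- numeric(max(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + phy$edge.length[e]
  }
  ra <- max(depth[seq_along(phy$tip.label)])
  internal <- (length(phy$tip.label) + 1):max(phy$edge)
  expect_equal(bt, sort(ra - depth[internal], decreasing = TRUE),
               tolerance = 1e-10)
})

test_that("habitat resolution merges categories and applies exclusions", {
  tab <- data.frame(
    species = paste0("sp", 1:8),
    salinity = c("marine", "freshwater", "freshwater+brackish", "marine",
                 "freshwater", "marine", "brackish", "marine"),
    habitat = c("reef-associated", "bathydemersal", "pelagic-neritic",
                "pelagic-oceanic", "benthopelagic", "bathypelagic",
                "demersal", "kelp-forest"))
  out <- resolve_habitats(tab)
  expect_equal(out$resolved_habitat[1], "RA")
  expect_equal(out$resolved_habitat[2], "FD")
  expect_equal(out$status[3], "excluded")          # multiple salinities
  expect_equal(out$resolved_habitat[4], "MP")
  expect_equal(out$resolved_habitat[5], "FB")
  expect_equal(out$resolved_habitat[6], "MP")      # bathypelagic -> pelagic
  expect_equal(out$status[7], "excluded")          # brackish has no code
  expect_equal(out$status[8], "unresolvable")      # unknown vocabulary

  # surviving records partition into exactly one of the 7 codes
  ok <- out$status == "ok"
  expect_true(all(out$resolved_habitat[ok] %in%
                    c("RA", "MD", "MB", "MP", "FD", "FB", "FP")))
  expect_true(all(is.na(out$resolved_habitat[!ok])))
})

test_that("sampling fractions validate and divide correctly", {
  sf <- sampling_fraction(n_in_tree = 19, n_total = 40)
  expect_equal(sf$rho, 0.475)
  expect_error(sampling_fraction(rho = 1.2), "rho")
  expect_error(sampling_fraction(n_in_tree = 41, n_total = 40))
})

test_that("trait tables read with comma or tab delimiters", {
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("species,salinity,habitat", "a,marine,demersal"), p1)
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("species\tsalinity\thabitat", "a\tmarine\tdemersal"), p2)
  expect_equal(read_trait_table(p1), read_trait_table(p2))
})
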