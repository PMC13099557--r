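# Shared fixtures: tiny hand-checkable trees and cached simulations.

# "((A:1,B:1):1,C:2);" - 3 tips, root age 2, one cherry at age 1
tiny_newick <- function() {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  path
}

# deterministic mid-sized simulated tree, cached across tests
fixture_env <- new.env()

fixture_tree <- function(name = "bd60", builder = NULL) {
  if (!is.null(fixture_env[[name]])) return(fixture_env[[name]])
  phy <- builder()
  fixture_env[[name]] <- phy
  phy
}

# constant-rate tree with ~40-90 tips
sim_bd_tree <- function(lambda = 0.25, mu = 0.08, root_age = 18, seed = 11,
                        rho = 1, n_range = c(25, 200)) {
  tr <- rate_trajectory(time_grid(ceiling(root_age)), lambda, mu)
  for (s in seq(seed, seed + 99)) {
    sim <- try(simulate_ebd_tree(tr, root_age, rho = rho, seed = s),
               silent = TRUE)
    if (inherits(sim, "try-error")) next
    n <- length(sim$phy$tip.label)
    if (n >= n_range[1] && n <= n_range[2]) return(sim)
  }
  stop("fixture simulation failed to hit the size window")
}

# simulate until the tip count lies in [lo, hi]; returns the sim object
sim_until_size <- function(fn, lo, hi, seeds) {
  for (s in seeds) {
    sim <- try(fn(s), silent = TRUE)
    if (inherits(sim, "try-error")) next
    n <- length(sim$phy$tip.label)
    if (n >= lo && n <= hi) return(sim)
  }
  stop("no simulation hit the size window")
}

# independently coded BiSSE-style 2-state log-likelihood oracle (deSolve),
# same conventions as the package: no root speciation factor via
# lambda*(1-E)^2 conditioning, tip D = rho * indicator. lambda and mu are
# length-2 vectors (observed states 0, 1).
bisse_oracle_loglik <- function(phy, tip_states, lambda, mu, q01, rho) {
  rhs <- function(t, y, parms) {
    E <- y[1:2]; D <- y[3:4]
    q <- matrix(c(-q01, q01, q01, -q01), 2, 2, byrow = TRUE)
    dE <- mu - (lambda + mu + q01) * E + lambda * E^2 + q01 * rev(E)
    dD <- -(lambda + mu + q01) * D + 2 * lambda * E * D + q01 * rev(D)
    list(c(dE, dD))
  }
  phy2 <- ape::reorder.phylo(phy, "postorder")
  age <- divpace::node_ages(phy2)
  ntip <- length(phy2$tip.label)
  Dn <- vector("list", ntip + phy2$Nnode)
  En <- vector("list", ntip + phy2$Nnode)
  for (i in seq_len(ntip)) {
    s <- tip_states[phy2$tip.label[i]]
    Dn[[i]] <- rho * c(s == 0, s == 1)
    En[[i]] <- c(1 - rho, 1 - rho)
  }
  logscale <- 0
  for (e in seq_len(nrow(phy2$edge))) {
    pa <- phy2$edge[e, 1]; ch <- phy2$edge[e, 2]
    tlen <- age[pa] - age[ch]
    y0 <- c(En[[ch]], Dn[[ch]])
    sol <- deSolve::lsoda(y0, c(0, tlen), rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    y1 <- sol[2, -1]
    if (is.null(Dn[[pa]])) {
      Dn[[pa]] <- y1[3:4]; En[[pa]] <- y1[1:2]
    } else {
      Dn[[pa]] <- lambda * Dn[[pa]] * y1[3:4]
      s2 <- sum(Dn[[pa]])
      Dn[[pa]] <- Dn[[pa]] / s2
      logscale <- logscale + log(s2)
    }
  }
  root <- ntip + 1
  L <- sum(0.5 * Dn[[root]] / (lambda * (1 - En[[root]])^2))
  log(L) + logscale
}
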