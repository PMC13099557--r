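# Forward birth-death simulators.
#
# One Gillespie core serves all three generators: lineages carry a discrete
# state (a single state for the episodic model, rate categories for the
# branch-shift model, combined observed x hidden states for SSE). Extinct
# lineages are pruned, extant tips are Bernoulli(rho)-sampled at the present,
# and the reconstructed tree is rebuilt with per-branch truth (time-weighted
# mean speciation rate and state-change counts) aggregated across the
# complete-tree path each reconstructed branch spans.

#' Derive an operation-specific sub-seed from a single integer seed
#'
#' Counter-based expansion so that each operation in a pipeline consumes an
#' independent, reproducible stream. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Base integer seed.
#' @param id Operation counter (integer) or a short string tag.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, id = 0) {
  if (is.character(id)) id <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
  s <- (as.double(seed) * 48271 + as.double(id) * 16807) %% 2147483647
  as.integer(s) + 1L
}

# state-dependent Gillespie forward simulation with piecewise-constant
# time-dependence: rates multiply state values lambda[k] by a per-interval
# factor looked up from `traj` when supplied (episodic case uses k = 1 and
# the trajectory's own lambda/mu).
sim_bd_forward <- function(k, lambda, mu, Q, root_age, rho,
                           traj = NULL, max_tips = 50000,
                           condition_on_survival = TRUE,
                           root_state = NULL, max_attempts = 1000) {
  qq <- Q
  if (k > 1) diag(qq) <- 0
  qex <- if (k > 1) rowSums(qq) else 0

  for (attempt in seq_len(max_attempts)) {
    # node store (complete tree)
    pa <- integer(0); age <- numeric(0); tipflag <- logical(0)
    edge_mlam <- numeric(0); edge_events <- integer(0); edge_state <- integer(0)
    new_node <- function(parent, a, tip) {
      pa[length(pa) + 1L] <<- parent
      age[length(age) + 1L] <<- a
      tipflag[length(tipflag) + 1L] <<- tip
      length(pa)
    }
    root <- new_node(0L, root_age, FALSE)
    # active lineage fields
    ln_parent <- c(root, root)
    ln_start <- c(root_age, root_age)
    rs <- if (is.null(root_state)) sample.int(k, 1) else root_state
    ln_state <- c(rs, rs)
    ln_lt <- c(0, 0)       # accumulated lambda * time
    ln_ev <- c(0L, 0L)     # state-change events
    t_now <- root_age
    alive <- TRUE

    close_edge <- function(i, a, tip) {
      node <- new_node(ln_parent[i], a, tip)
      dur <- ln_start[i] - a
      edge_mlam[node] <<- if (dur > 0) ln_lt[i] / dur else lambda[ln_state[i]]
      edge_events[node] <<- ln_ev[i]
      edge_state[node] <<- ln_state[i]
      node
    }

    while (alive && t_now > 0) {
      n_act <- length(ln_parent)
      if (n_act == 0) break
      if (n_act > max_tips) {
        stop("simulation exceeded the lineage cap (", max_tips,
             "); lower the rates or the cap")
      }
      if (is.null(traj)) {
        lam_v <- lambda[ln_state]; mu_v <- mu[ln_state]
      } else {
        lam_v <- rep(rate_at(traj, t_now, "lambda"), n_act)
        mu_v <- rep(rate_at(traj, t_now, "mu"), n_act)
      }
      rates <- lam_v + mu_v + qex[ln_state]
      tot <- sum(rates)
      # next interval boundary below t_now (episodic case)
      t_bound <- if (is.null(traj)) 0 else {
        b <- traj$grid$boundaries
        bb <- b[b < t_now - 1e-12]
        if (length(bb)) max(bb) else 0
      }
      wait <- if (tot > 0) rexp(1, tot) else Inf
      if (t_now - wait <= t_bound) {
        ln_lt <- ln_lt + lam_v * (t_now - t_bound)
        t_now <- t_bound
        if (t_bound <= 0) break
        next
      }
      t_evt <- t_now - wait
      i <- sample.int(n_act, 1, prob = rates)
      lm <- c(lam_v[i], mu_v[i])
      ln_lt <- ln_lt + lam_v * (t_now - t_evt)
      t_now <- t_evt
      u <- runif(1) * rates[i]
      if (u <= lm[1]) {
        # speciation: close edge, spawn two lineages
        node <- close_edge(i, t_evt, FALSE)
        st <- ln_state[i]
        ln_parent <- c(ln_parent[-i], node, node)
        ln_start <- c(ln_start[-i], t_evt, t_evt)
        ln_state <- c(ln_state[-i], st, st)
        ln_lt <- c(ln_lt[-i], 0, 0)
        ln_ev <- c(ln_ev[-i], 0L, 0L)
      } else if (u <= lm[1] + lm[2]) {
        # extinction: dead tip (kept in the complete tree, pruned later)
        close_edge(i, t_evt, TRUE)
        ln_parent <- ln_parent[-i]; ln_start <- ln_start[-i]
        ln_state <- ln_state[-i]; ln_lt <- ln_lt[-i]; ln_ev <- ln_ev[-i]
      } else {
        # anagenetic state change
        pr <- qq[ln_state[i], ]
        ln_state[i] <- sample.int(k, 1, prob = pr)
        ln_ev[i] <- ln_ev[i] + 1L
      }
    }

    # close extant lineages at the present
    extant <- integer(0)
    for (i in seq_along(ln_parent)) extant <- c(extant, close_edge(i, 0, TRUE))
    dead <- age[tipflag] > 0
    n_extant <- length(extant)
    sampled <- extant[runif(n_extant) < rho]
    if (length(sampled) >= 2 || !condition_on_survival) {
      if (length(sampled) < 2) {
        return(list(ok = FALSE, n_extant = n_extant))
      }
      rec <- reconstruct_tree(pa, age, tipflag, sampled,
                              edge_mlam, edge_events, edge_state)
      rec$n_extant_full <- n_extant
      rec$n_dead <- sum(dead)
      rec$attempts <- attempt
      return(rec)
    }
  }
  stop("condition_on_survival: no surviving sampled pair in ", max_attempts,
       " attempts")
}

# Rebuild the reconstructed (sampled-survivors-only) tree from the complete
# node table, aggregating per-branch truth along collapsed paths.
reconstruct_tree <- function(pa, age, tipflag, sampled,
                             edge_mlam, edge_events, edge_state) {
  n <- length(pa)
  keep <- logical(n)
  keep[sampled] <- TRUE
  for (i in n:2) if (keep[i]) keep[pa[i]] <- TRUE   # children created after parents

  children <- vector("list", n)
  for (i in seq_len(n)) if (pa[i] > 0 && keep[i]) {
    children[[pa[i]]] <- c(children[[pa[i]]], i)
  }
  # find reconstructed root: first kept node with 2 kept children
  root <- which(keep & !tipflag & vapply(children, length, 0L) == 2)[1]
  # descend from each kept node with 2 children
  tips <- integer(0); tip_state <- integer(0)
  eparent <- integer(0); echild <- integer(0)
  emlam <- numeric(0); eev <- integer(0); estate <- integer(0)
  eage_c <- numeric(0); eage_p <- numeric(0)
  node_ids <- c()  # complete-tree ids of reconstructed nodes, tips first later
  # stack of (complete-node, reconstructed-parent-slot)
  rec_id <- integer(n)  # reconstructed index per complete node (0 = none)
  nodes_out <- integer(0)

  # assign reconstructed ids: walk with a stack
  st <- list(list(node = root, rparent = 0L))
  while (length(st)) {
    fr <- st[[length(st)]]; st[[length(st)]] <- NULL
    v <- fr$node
    # collapse chain: follow single-kept-child nodes, aggregating truth
    agg_lt <- 0; agg_ev <- 0L; agg_t0 <- age[v]
    repeat {
      ch <- children[[v]]
      if (tipflag[v] || length(ch) == 2) break
      v2 <- ch[1]
      dur <- age[v] - age[v2]
      agg_lt <- agg_lt + edge_mlam[v2] * dur
      agg_ev <- agg_ev + edge_events[v2]
      v <- v2
    }
    nodes_out <- c(nodes_out, v)
    rid <- length(nodes_out)
    rec_id[v] <- rid
    if (fr$rparent > 0) {
      eparent <- c(eparent, fr$rparent); echild <- c(echild, rid)
      # include the edge into the first collapsed node
      top <- nodes_out[fr$rparent]
      # aggregate from top's child that leads here: we accumulated along the
      # chain below; the first segment (top -> first chain node) is the edge
      # of the node where the chain started, i.e. fr$node
      v1 <- fr$node
      dur1 <- age[top] - age[v1]
      tot_lt <- edge_mlam[v1] * dur1 + agg_lt
      tot_ev <- edge_events[v1] + agg_ev
      dur_tot <- age[top] - age[v]
      emlam <- c(emlam, if (dur_tot > 0) tot_lt / dur_tot else edge_mlam[v1])
      eev <- c(eev, tot_ev)
      estate <- c(estate, edge_state[v])
      eage_c <- c(eage_c, age[v]); eage_p <- c(eage_p, age[top])
    }
    if (tipflag[v]) {
      tips <- c(tips, rid)
      tip_state <- c(tip_state, edge_state[v])
    } else {
      for (ch2 in children[[v]]) st[[length(st) + 1L]] <- list(node = ch2, rparent = rid)
    }
  }

  # convert to ape numbering: tips 1..ntip, internals ntip+1 .. (root first)
  ntip <- length(tips)
  nnode <- length(nodes_out) - ntip
  new_id <- integer(length(nodes_out))
  new_id[tips] <- seq_len(ntip)
  internal <- setdiff(seq_along(nodes_out), tips)
  # internal ids in discovery order; root discovered first
  new_id[internal] <- ntip + seq_along(internal)
  edge <- cbind(new_id[eparent], new_id[echild])
  edge_len <- eage_p - eage_c
  phy <- structure(list(
    edge = edge,
    edge.length = edge_len,
    tip.label = paste0("t", seq_len(ntip)),
    Nnode = nnode
  ), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy <- validate_ultrametric_tree(phy)

  states <- integer(ntip)
  states[new_id[tips]] <- tip_state
  edge_truth <- data.frame(
    parent = new_id[eparent], child = new_id[echild],
    age_child = eage_c, age_parent = eage_p,
    mean_lambda = emlam, n_state_changes = eev,
    state_at_child = estate)
  list(ok = TRUE, phy = phy, tip_state = states, edge_truth = edge_truth)
}

#' Simulate a tree under the episodic birth-death model
#'
#' Forward simulation from two lineages at the root with piecewise-constant
#' rates, pruning of extinct lineages, and Bernoulli(`rho`) sampling of
#' extant tips (unsampled taxa random, uniform at the present).
#'
#' @param traj A [rate_trajectory()] spanning `root_age`.
#' @param root_age Root age in My; must not exceed the grid span.
#' @param rho Sampling fraction in (0, 1].
#' @param seed Integer seed (optional; the caller may also seed externally).
#' @param condition_on_survival Re-simulate until at least two sampled tips
#'   survive (matching what the reconstructed-tree likelihood conditions on).
#' @param max_tips Refuse simulations whose lineage count exceeds this cap.
#' @return A list of class `simulated_tree`: `phy`, `truth` (the generating
#'   trajectory, per-branch truth table, complete-tree tip counts), `seed`.
#' @export
simulate_ebd_tree <- function(traj, root_age, rho = 1, seed = NULL,
                              condition_on_survival = TRUE,
                              max_tips = 50000) {
  stopifnot(inherits(traj, "rate_trajectory"))
  if (root_age > max(traj$grid$boundaries) + 1e-9) {
    stop("root_age exceeds the grid span")
  }
  # refuse clearly supercritical runs before simulating
  widths <- diff(traj$grid$boundaries)
  use <- traj$grid$boundaries[-1] <= root_age + 1e-9
  growth <- sum((net_diversification(traj) * widths)[use])
  if (2 * exp(growth) > max_tips) {
    stop("expected tip count exceeds the cap (", max_tips, ")")
  }
  if (!is.null(seed)) set.seed(substream_seed(seed, "ebd_sim"))
  rho <- as_rho(rho)
  out <- sim_bd_forward(1, 1, 1, matrix(0, 1, 1), root_age, rho,
                        traj = traj, max_tips = max_tips,
                        condition_on_survival = condition_on_survival)
  structure(list(phy = out$phy,
                 truth = list(trajectory = traj,
                              edge_truth = out$edge_truth,
                              n_extant_full = out$n_extant_full,
                              attempts = out$attempts),
                 seed = seed),
            class = "simulated_tree")
}

#' State-dependent diversification model container
#'
#' Combined observed x hidden state space for SSE models. For HiSSE-2 use
#' [hisse2_model()].
#'
#' @param state_names Names of the combined states.
#' @param obs_state Integer observed-state index per combined state.
#' @param lambda,mu Per-state speciation/extinction rates.
#' @param Q Transition-rate matrix (rows sum to zero, no dual transitions for
#'   HiSSE-style spaces).
#' @param rho Sampling fraction.
#' @param root_prior Probability vector over combined states.
#' @return Object of class `sse_model`.
#' @export
sse_model <- function(state_names, obs_state, lambda, mu, Q, rho = 1,
                      root_prior = NULL) {
  k <- length(state_names)
  stopifnot(length(lambda) == k, length(mu) == k,
            all(dim(Q) == c(k, k)), all(lambda >= 0), all(mu >= 0))
  if (max(abs(rowSums(Q))) > 1e-8 * (max(abs(Q)) + 1e-12)) {
    stop("Q rows must sum to 0")
  }
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) stop("Q off-diagonals must be >= 0")
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  structure(list(state_names = state_names, obs_state = obs_state,
                 lambda = lambda, mu = mu, Q = Q, rho = as_rho(rho),
                 root_prior = root_prior / sum(root_prior)),
            class = "sse_model")
}

#' Two-hidden-state SSE (HiSSE-2) model
#'
#' Combined states 0A, 1A, 0B, 1B (observed 0 = nonbenthic, 1 = benthic;
#' hidden A, B). Transitions flip one factor at a time: a symmetric observed
#' flip rate `q01` and a symmetric hidden flip rate `qAB`; dual transitions
#' are structurally zero.
#'
#' @param lambda,mu Length-4 rates in order 0A, 1A, 0B, 1B.
#' @param q01 Observed-state flip rate (events/My).
#' @param qAB Hidden-state flip rate (events/My).
#' @param rho Sampling fraction.
#' @param root_prior Prior over the four combined states (default equal).
#' @return An `sse_model`.
#' @export
hisse2_model <- function(lambda, mu, q01, qAB, rho = 1, root_prior = NULL) {
  nm <- c("0A", "1A", "0B", "1B")
  Q <- matrix(0, 4, 4, dimnames = list(nm, nm))
  Q["0A", "1A"] <- Q["1A", "0A"] <- q01
  Q["0B", "1B"] <- Q["1B", "0B"] <- q01
  Q["0A", "0B"] <- Q["0B", "0A"] <- qAB
  Q["1A", "1B"] <- Q["1B", "1A"] <- qAB
  diag(Q) <- -rowSums(Q)
  sse_model(nm, obs_state = c(0L, 1L, 0L, 1L), lambda = lambda, mu = mu,
            Q = Q, rho = rho, root_prior = root_prior)
}

#' Simulate a tree under a state-dependent (SSE) model
#'
#' Forward state-dependent simulation with anagenetic transitions; extinct
#' lineages pruned, tips Bernoulli(`rho`)-sampled. Observed tip states
#' marginalize the hidden factor; the full combined states are kept in the
#' truth record.
#'
#' @param model An [sse_model()].
#' @param root_age Root age (My).
#' @param seed Integer seed (optional).
#' @param root_state Combined root state index (default: drawn from the
#'   model's root prior).
#' @param condition_on_survival,max_tips As in [simulate_ebd_tree()].
#' @return A `simulated_tree` with `tip_state` (observed) and
#'   `truth$tip_state_combined`.
#' @export
simulate_sse_tree <- function(model, root_age, seed = NULL, root_state = NULL,
                              condition_on_survival = TRUE, max_tips = 50000) {
  stopifnot(inherits(model, "sse_model"))
  if (!is.null(seed)) set.seed(substream_seed(seed, "sse_sim"))
  if (is.null(root_state)) {
    root_state <- sample.int(length(model$lambda), 1, prob = model$root_prior)
  }
  out <- sim_bd_forward(length(model$lambda), model$lambda, model$mu,
                        model$Q, root_age, model$rho, max_tips = max_tips,
                        condition_on_survival = condition_on_survival,
                        root_state = root_state)
  obs <- model$obs_state[out$tip_state]
  names(obs) <- out$phy$tip.label
  structure(list(phy = out$phy, tip_state = obs,
                 truth = list(model = model,
                              tip_state_combined = out$tip_state,
                              edge_truth = out$edge_truth,
                              root_state = root_state,
                              n_extant_full = out$n_extant_full),
                 seed = seed),
            class = "simulated_tree")
}

#' Simulate a tree under the branch-specific shift (BDS) model
#'
#' Lineages carry one of `k` speciation-rate categories; shift events arrive
#' at rate `eta` per lineage per My (on extant and, before pruning, extinct
#' lineages alike) and reassign the category uniformly among the other
#' `k - 1`. Extinction is shared across categories.
#'
#' @param categories Speciation rate per category (lineages/My).
#' @param mu Shared extinction rate.
#' @param eta Shift rate (events/lineage/My).
#' @param root_age Root age (My).
#' @param rho Sampling fraction.
#' @param seed Integer seed (optional).
#' @param root_category Starting category (default: sampled uniformly).
#' @param condition_on_survival,max_tips As in [simulate_ebd_tree()].
#' @return A `simulated_tree`; `truth$edge_truth` holds the per-branch mean
#'   speciation rate and shift-event counts of the reconstructed branches.
#' @export
simulate_bds_tree <- function(categories, mu, eta, root_age, rho = 1,
                              seed = NULL, root_category = NULL,
                              condition_on_survival = TRUE,
                              max_tips = 50000) {
  k <- length(categories)
  stopifnot(k >= 1, all(categories > 0), mu >= 0, eta >= 0)
  if (!is.null(seed)) set.seed(substream_seed(seed, "bds_sim"))
  Q <- matrix(eta / max(k - 1, 1), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (is.null(root_category)) root_category <- sample.int(k, 1)
  out <- sim_bd_forward(k, categories, rep(mu, k), Q, root_age, as_rho(rho),
                        max_tips = max_tips,
                        condition_on_survival = condition_on_survival,
                        root_state = root_category)
  structure(list(phy = out$phy, tip_state = out$tip_state,
                 truth = list(categories = categories, mu = mu, eta = eta,
                              edge_truth = out$edge_truth,
                              root_category = root_category,
                              n_extant_full = out$n_extant_full),
                 seed = seed),
            class = "simulated_tree")
}

#' Synthetic posterior trace fixture
#'
#' Builds a minimal posterior trace consumable by [t_statistic()], with net
#' diversification columns for observed states 0/1 within hidden states A/B.
#'
#' @param r0,r1 Net diversification samples for observed states 0 and 1
#'   (equal length).
#' @param hidden `"A"`, `"B"`, or `"both"`: which hidden state receives the
#'   `(r0, r1)` pair (the other receives `(r0, r0)`).
#' @param seed Unused except to record provenance.
#' @return An object of class `hisse_trace` with matrix element `samples`.
#' @export
make_posterior_fixture <- function(r0, r1, hidden = "both", seed = NULL) {
  stopifnot(length(r0) == length(r1))
  m <- cbind(r_0A = r0, r_1A = if (hidden %in% c("A", "both")) r1 else r0,
             r_0B = r0, r_1B = if (hidden %in% c("B", "both")) r1 else r0)
  structure(list(samples = m, n_generations = length(r0), seed = seed,
                 burn_in_applied = TRUE),
            class = "hisse_trace")
}
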