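# Hidden-state state-dependent speciation and extinction (HiSSE-2).
#
# Observed states: 0 = nonbenthic-feeding, 1 = benthic-feeding.
# Hidden states: A, B. Combined order: 0A, 1A, 0B, 1B.

#' Classify feeding mode from diet descriptors
#'
#' Benthic feeding covers resources that are attached to (or firmly
#' associated with) the substrate and require detachment - including
#' ectoparasites picked off hosts; free-swimming prey capture and
#' ram-biting are nonbenthic. Conflicting descriptors resolve by majority;
#' ties and empty descriptor sets are unclassified.
#'
#' @param descriptors Character vector of descriptors from the controlled
#'   vocabulary: `attached-resource`, `detachment-required`,
#'   `free-swimming`, `ram-biter`, `ectoparasite-feeder`.
#' @return `"benthic"`, `"nonbenthic"` or `"unclassified"`.
#' @export
classify_feeding <- function(descriptors) {
  vocab <- c("attached-resource" = "benthic",
             "detachment-required" = "benthic",
             "ectoparasite-feeder" = "benthic",
             "free-swimming" = "nonbenthic",
             "ram-biter" = "nonbenthic")
  descriptors <- descriptors[nzchar(descriptors)]
  if (!length(descriptors)) return("unclassified")
  unknown <- setdiff(descriptors, names(vocab))
  if (length(unknown)) {
    stop("unknown diet descriptor(s): ", paste(unknown, collapse = ", "))
  }
  votes <- table(vocab[descriptors])
  nb <- if ("benthic" %in% names(votes)) votes[["benthic"]] else 0
  nn <- if ("nonbenthic" %in% names(votes)) votes[["nonbenthic"]] else 0
  if (nb > nn) "benthic" else if (nn > nb) "nonbenthic" else "unclassified"
}

#' Classify a feeding table
#'
#' @param table Data.frame with columns `species` and `descriptors`
#'   (`;`-separated descriptor strings).
#' @return The table with a `classification` column.
#' @export
classify_feeding_table <- function(table) {
  stopifnot(all(c("species", "descriptors") %in% names(table)))
  table$classification <- vapply(
    strsplit(table$descriptors, ";"),
    function(d) classify_feeding(trimws(d)), character(1))
  table
}

# tip state matrix over combined states from observed 0/1 (NA = ambiguous)
hisse_tip_matrix <- function(phy, tip_states) {
  if (!is.null(names(tip_states))) {
    tip_states <- tip_states[phy$tip.label]
  }
  n <- length(phy$tip.label)
  stopifnot(length(tip_states) == n)
  m <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    s <- tip_states[i]
    if (is.na(s)) m[i, ] <- 1
    else if (s == 0) m[i, c(1, 3)] <- 1
    else if (s == 1) m[i, c(2, 4)] <- 1
    else stop("tip states must be 0, 1 or NA")
  }
  m
}

#' HiSSE-2 log-likelihood
#'
#' Standard SSE pruning over the four combined states with coupled D/E
#' ODEs; tip partials are initialized with `rho` times the observed-state
#' indicator marginalized over hidden states; the root uses the model's
#' prior over combined states with per-state survival conditioning.
#'
#' @param phy Validated ultrametric tree.
#' @param tip_states Named vector of 0/1 observed states (NA = ambiguous),
#'   names matching tip labels.
#' @param model An [sse_model()] / [hisse2_model()].
#' @param condition_on_survival Condition on survival of both root
#'   lineages.
#' @param rtol,atol ODE tolerances.
#' @return Log-likelihood (nats).
#' @export
hisse2_log_likelihood <- function(phy, tip_states, model,
                                  condition_on_survival = TRUE,
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "sse_model"))
  td <- sse_tree_data(phy)
  tips <- hisse_tip_matrix_ordered(phy, td, tip_states)
  sse_loglik_cpp(td, tips, model$lambda, model$mu, model$Q, model$rho,
                 model$root_prior, condition_on_survival, rtol, atol)
}

hisse_tip_matrix_ordered <- function(phy, td, tip_states) {
  if (is.null(names(tip_states))) names(tip_states) <- phy$tip.label
  m <- hisse_tip_matrix(phy, tip_states)
  # postorder reorder keeps tip numbering, so rows already align
  m
}

#' HiSSE-2 prior configuration
#'
#' @param log_rate_mean Mean of the normal prior on log rates; default
#'   `log(ln(n_taxa / 2) / root_age)` supplied by [run_hisse_mcmc()].
#' @param log_rate_sd SD of the normal prior on log rates.
#' @param expected_transitions Prior expected number of state transitions
#'   across the tree (split evenly between observed and hidden flips and
#'   converted to rates via total tree length).
#' @param extinction_mode `"free"` (independent log-normal prior on mu) or
#'   `"floor"` (mu = A * lambda + delta with delta >= 0).
#' @param extinction_floor_A Multiplier A in floor mode (default 0.5).
#' @return A list of class `hisse_priors`.
#' @export
hisse_priors <- function(log_rate_mean = NULL, log_rate_sd = 1,
                         expected_transitions = 50,
                         extinction_mode = c("free", "floor"),
                         extinction_floor_A = 0.5) {
  extinction_mode <- match.arg(extinction_mode)
  structure(list(log_rate_mean = log_rate_mean, log_rate_sd = log_rate_sd,
                 expected_transitions = expected_transitions,
                 extinction_mode = extinction_mode,
                 extinction_floor_A = extinction_floor_A),
            class = "hisse_priors")
}

#' Run the HiSSE-2 MCMC
#'
#' Samples per-state speciation and extinction rates (normal prior on log
#' rates centred on `ln(n_taxa/2)/root_age` by default), a symmetric
#' observed-flip rate and a symmetric hidden-flip rate (exponential priors
#' with the expected total transition count split between them), and draws
#' stochastic character maps at recorded generations. In `"floor"`
#' extinction mode, `mu_s = A * lambda_s + delta_s` with `delta_s >= 0`
#' sampled on its own (exponential prior), so every posterior sample
#' satisfies the extinction floor.
#'
#' @param phy Validated ultrametric tree.
#' @param tip_states Named 0/1 vector (NA allowed).
#' @param priors A [hisse_priors()].
#' @param rho Sampling fraction.
#' @param settings An [mcmc_settings()].
#' @param map_every Draw a stochastic map every `map_every`-th recorded
#'   sample; 0 disables mapping.
#' @param stt_grid A [time_grid()] for lineage-time accumulation (default:
#'   1-My grid over the tree).
#' @param likelihood `"hisse"` or `"none"` for prior-only runs.
#' @param rtol,atol ODE tolerances.
#' @return A list of `hisse_trace` objects, one per run. `samples` holds
#'   `lambda_*`, `mu_*`, `q01`, `qAB`, the per-state net diversification
#'   `r_*`, and `loglik`; `maps` holds node states and per-interval
#'   lineage-time arrays.
#' @export
run_hisse_mcmc <- function(phy, tip_states, priors = hisse_priors(),
                           rho = 1, settings = mcmc_settings(),
                           map_every = 10, stt_grid = NULL,
                           likelihood = c("hisse", "none"),
                           rtol = 1e-7, atol = 1e-9) {
  likelihood <- match.arg(likelihood)
  td <- sse_tree_data(phy)
  tips <- hisse_tip_matrix_ordered(phy, td, tip_states)
  if (is.null(stt_grid)) stt_grid <- time_grid_for_tree(phy)
  if (is.null(priors$log_rate_mean)) {
    priors$log_rate_mean <- log(log(td$ntip / 2) / max(node_ages(phy)))
  }
  rho <- as_rho(rho)
  lapply(seq_len(settings$n_runs), function(run) {
    hisse_mcmc_one_run(td, tips, priors, rho, settings,
                       substream_seed(settings$seed, 200 + run),
                       map_every, stt_grid, likelihood, rtol, atol)
  })
}

hisse_mcmc_one_run <- function(td, tips, priors, rho, settings, seed,
                               map_every, stt_grid, likelihood, rtol, atol) {
  set.seed(seed)
  TL <- td$total_length
  q_mean <- priors$expected_transitions / 2 / TL   # per flip type
  floor_mode <- priors$extinction_mode == "floor"
  A <- priors$extinction_floor_A
  state_names <- c("0A", "1A", "0B", "1B")

  # parameter vector: log lambda (4), log mu or log delta (4), log q01, log qAB
  st <- c(rep(priors$log_rate_mean, 4),
          rep(priors$log_rate_mean - log(2), 4),
          log(q_mean), log(q_mean))
  names(st) <- c(paste0("ll_", state_names), paste0("lm_", state_names),
                 "lq01", "lqAB")

  mu_of <- function(s) {
    lam <- exp(s[1:4])
    if (floor_mode) A * lam + exp(s[5:8]) else exp(s[5:8])
  }
  loglik_fn <- function(s) {
    if (likelihood == "none") return(0)
    lam <- exp(s[1:4])
    Q <- hisse2_Q(exp(s[9]), exp(s[10]))
    sse_loglik_cpp(td, tips, lam, mu_of(s), Q, rho, rep(0.25, 4), TRUE,
                   rtol, atol)
  }
  logprior_fn <- function(s) {
    lp <- sum(dnorm(s[1:4], priors$log_rate_mean, priors$log_rate_sd,
                    log = TRUE))
    if (floor_mode) {
      # exponential prior on delta, sampled on log scale (with Jacobian)
      delta <- exp(s[5:8])
      lp <- lp + sum(dexp(delta, 1 / exp(priors$log_rate_mean), log = TRUE) +
                       s[5:8])
    } else {
      lp <- lp + sum(dnorm(s[5:8], priors$log_rate_mean, priors$log_rate_sd,
                           log = TRUE))
    }
    # exponential priors on the flip rates, on log scale with Jacobian
    lp + sum(dexp(exp(s[9:10]), 1 / q_mean, log = TRUE) + s[9:10])
  }
  cur_lik <- loglik_fn(st); cur_pri <- logprior_fn(st)

  # block moves keep the likelihood-evaluation count per generation low:
  # per-coordinate jitter of the lambda block, the mu/delta block, the two
  # flip rates, plus one single-coordinate refinement move
  blocks <- list(lambda = 1:4, mu = 5:8, q = 9:10, single = NA)
  sc <- c(lambda = 0.15, mu = 0.3, q = 0.5, single = 0.5)
  acc <- sc * 0; prp <- sc * 0
  n_rec <- floor(settings$generations / settings$thin)
  cols <- c(paste0("lambda_", state_names), paste0("mu_", state_names),
            "q01", "qAB", paste0("r_", state_names), "loglik")
  samples <- matrix(NA_real_, n_rec, length(cols))
  colnames(samples) <- cols
  maps <- list()
  rec <- 0L
  total <- settings$pre_burn_in + settings$generations

  for (g in seq_len(total)) {
    for (b in names(blocks)) {
      idx <- blocks[[b]]
      if (b == "single") idx <- sample.int(length(st), 1)
      s2 <- st
      s2[idx] <- st[idx] + rnorm(length(idx), 0, sc[[b]])
      prp[[b]] <- prp[[b]] + 1
      pri2 <- logprior_fn(s2)
      lik2 <- loglik_fn(s2)
      if (is.finite(lik2 + pri2) &&
          log(runif(1)) < (lik2 + pri2) - (cur_lik + cur_pri)) {
        st <- s2; cur_lik <- lik2; cur_pri <- pri2
        acc[[b]] <- acc[[b]] + 1
      }
    }
    if (g <= settings$pre_burn_in && g %% settings$tuning_interval == 0) {
      adapt <- prp > 0
      targ <- c(lambda = 0.23, mu = 0.23, q = 0.3, single = 0.44)
      sc[adapt] <- pmin(pmax(sc[adapt] *
                               exp(0.5 * (acc[adapt] / prp[adapt] -
                                            targ[adapt])),
                             1e-3), 10)
      acc[] <- 0; prp[] <- 0
    }
    if (g > settings$pre_burn_in &&
        (g - settings$pre_burn_in) %% settings$thin == 0) {
      rec <- rec + 1L
      lam <- exp(st[1:4]); mu <- mu_of(st)
      samples[rec, ] <- c(lam, mu, exp(st[9]), exp(st[10]), lam - mu,
                          cur_lik)
      if (map_every > 0 && likelihood == "hisse" && rec %% map_every == 0) {
        mp <- sse_map_cpp(td, tips, lam, mu, hisse2_Q(exp(st[9]), exp(st[10])),
                          rho, rep(0.25, 4), TRUE, rtol, atol, 1L,
                          stt_grid$boundaries)
        maps[[length(maps) + 1]] <- list(
          node_state = mp$node_state[1, ],
          lineage_time = mp$lineage_time[, , 1])
      }
    }
  }
  structure(list(samples = samples[seq_len(rec), , drop = FALSE],
                 maps = maps, tree_data = td, stt_grid = stt_grid,
                 state_names = state_names, seed = seed,
                 acceptance = ifelse(prp > 0, acc / prp, NA),
                 settings = settings, burn_in_applied = FALSE),
            class = "hisse_trace")
}

hisse2_Q <- function(q01, qAB) {
  nm <- c("0A", "1A", "0B", "1B")
  Q <- matrix(0, 4, 4, dimnames = list(nm, nm))
  Q["0A", "1A"] <- Q["1A", "0A"] <- q01
  Q["0B", "1B"] <- Q["1B", "0B"] <- q01
  Q["0A", "0B"] <- Q["0B", "0A"] <- qAB
  Q["1A", "1B"] <- Q["1B", "1A"] <- qAB
  diag(Q) <- -rowSums(Q)
  Q
}

#' Posterior fold-change statistic T_ab
#'
#' Fraction of retained posterior generations in which the net
#' diversification of observed state 1 exceeds `a` times that of observed
#' state 0, within hidden state `b`: the posterior probability of an
#' `a`-fold benthic advantage given the hidden background.
#'
#' @param trace A `hisse_trace` (or anything with `samples` containing
#'   `r_0A`, `r_1A`, `r_0B`, `r_1B` columns).
#' @param a Fold threshold (e.g. 1.3, 1.5).
#' @param hidden `"A"` or `"B"`.
#' @param burn_in_fraction Fraction of samples dropped from the front
#'   (default 0.1; ignored when the trace is already burned in).
#' @return The statistic in `[0, 1]`.
#' @export
t_statistic <- function(trace, a, hidden = c("A", "B"),
                        burn_in_fraction = 0.1) {
  hidden <- match.arg(hidden)
  m <- trace$samples
  if (!isTRUE(trace$burn_in_applied) && burn_in_fraction > 0) {
    drop <- floor(nrow(m) * burn_in_fraction)
    if (drop >= nrow(m)) stop("burn-in removed every sample")
    if (drop > 0) m <- m[-seq_len(drop), , drop = FALSE]
  }
  if (nrow(m) == 0) stop("empty trace")
  r0 <- m[, paste0("r_0", hidden)]
  r1 <- m[, paste0("r_1", hidden)]
  mean(r1 > a * r0)
}

#' States-through-time summary from stochastic character maps
#'
#' For each grid interval, the posterior-mean fraction of lineage-time
#' spent in each combined state among lineages alive in that interval.
#'
#' @param traces A `hisse_trace` or list of them.
#' @param burn_in_fraction Fraction of maps dropped from the front of each
#'   run.
#' @return A data.frame: interval ages plus one proportion column per
#'   combined state (rows with no lineage time are NA).
#' @export
states_through_time <- function(traces, burn_in_fraction = 0.1) {
  if (inherits(traces, "hisse_trace")) traces <- list(traces)
  grid <- traces[[1]]$stt_grid
  state_names <- traces[[1]]$state_names
  maps <- unlist(lapply(traces, function(tr) {
    mm <- tr$maps
    drop <- floor(length(mm) * burn_in_fraction)
    if (drop > 0) mm <- mm[-seq_len(drop)]
    mm
  }), recursive = FALSE)
  if (!length(maps)) stop("no stochastic maps present")
  k <- length(state_names)
  nint <- grid$n_intervals
  acc2 <- matrix(0, nint, k)
  cnt <- matrix(0, nint, k)
  for (mp in maps) {
    lt <- mp$lineage_time            # nint x k
    tot <- rowSums(lt)
    ok <- tot > 0
    acc2[ok, ] <- acc2[ok, ] + lt[ok, , drop = FALSE] / tot[ok]
    cnt[ok, ] <- cnt[ok, ] + 1
  }
  prop <- acc2 / cnt
  prop[cnt == 0] <- NA
  colnames(prop) <- paste0("prop_", state_names)
  data.frame(age_young = grid$boundaries[-(nint + 1)],
             age_old = grid$boundaries[-1], prop)
}

#' Marginal ancestral state probabilities from stochastic maps
#'
#' Empirical frequency of each combined state at each node across the
#' retained stochastic maps.
#'
#' @param traces A `hisse_trace` (or `bds_trace`) or list of them.
#' @param burn_in_fraction Fraction of maps dropped per run.
#' @return A matrix (nodes x states) of probabilities summing to 1 per row;
#'   rows are in ape node numbering (tips first).
#' @export
ancestral_states <- function(traces, burn_in_fraction = 0.1) {
  if (!is.null(traces$maps)) traces <- list(traces)
  state_names <- traces[[1]]$state_names
  if (is.null(state_names)) {
    state_names <- paste0("category_", seq_len(traces[[1]]$k))
  }
  maps <- unlist(lapply(traces, function(tr) {
    mm <- tr$maps
    drop <- floor(length(mm) * burn_in_fraction)
    if (drop > 0) mm <- mm[-seq_len(drop)]
    mm
  }), recursive = FALSE)
  if (!length(maps)) stop("no stochastic maps present")
  ns <- do.call(rbind, lapply(maps, `[[`, "node_state"))
  k <- length(state_names)
  out <- t(apply(ns, 2, function(col) tabulate(col, k) / length(col)))
  colnames(out) <- state_names
  out
}
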