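# Lineage-specific birth-death-shift (BDS) model.
#
# Speciation rates take one of k categories from a discretized lognormal;
# extinction is shared across categories; category switches arrive at rate
# eta per lineage per My, uniformly to the other k-1 categories. The
# likelihood marginalizes categories by pruning with coupled D/E ODEs; shift
# detection uses stochastic branch-category maps.

#' Discretize a lognormal into k quantile-bin medians
#'
#' Category `i` is the median of its quantile bin, i.e. the
#' `(i - 0.5)/k` quantile of LogNormal(mean_log, sd_log), ascending.
#'
#' @param mean_log Mean of log rates.
#' @param sd_log SD of log rates (>= 0).
#' @param k Number of categories.
#' @return Numeric vector of k rates, ascending.
#' @export
discretize_lognormal <- function(mean_log, sd_log, k = 6) {
  stopifnot(sd_log >= 0, k >= 1)
  qlnorm((seq_len(k) - 0.5) / k, meanlog = mean_log, sdlog = sd_log)
}

# tree preprocessing shared by the SSE-core callers: postorder edge table
sse_tree_data <- function(phy) {
  phy2 <- ape::reorder.phylo(phy, "postorder")
  age <- node_ages(phy2)
  list(ntip = length(phy2$tip.label), nnode = phy2$Nnode,
       parent = phy2$edge[, 1], child = phy2$edge[, 2],
       age_child = age[phy2$edge[, 2]], age_parent = age[phy2$edge[, 1]],
       tip_label = phy2$tip.label, total_length = sum(phy2$edge.length))
}

bds_Q <- function(k, eta) {
  if (k == 1) return(matrix(0, 1, 1))
  Q <- matrix(eta / (k - 1), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' BDS model container
#'
#' @param categories Speciation rate per category, ascending.
#' @param mu Shared extinction rate.
#' @param eta Category-switch rate (events/lineage/My).
#' @param rho Sampling fraction.
#' @return A list of class `bds_model`.
#' @export
bds_model <- function(categories, mu, eta, rho = 1) {
  stopifnot(all(categories >= 0), mu >= 0, eta >= 0)
  if (is.unsorted(categories)) categories <- sort(categories)
  structure(list(categories = categories, mu = mu, eta = eta,
                 rho = as_rho(rho), k = length(categories)),
            class = "bds_model")
}

#' BDS log-likelihood
#'
#' Pruning likelihood integrating, per branch, the coupled extinction and
#' density ODEs over the k categories with switch rate `eta`; root
#' categories are marginalized with equal weights and the likelihood is
#' conditioned on survival of the two root lineages.
#'
#' @param phy Validated ultrametric tree.
#' @param model A [bds_model()].
#' @param condition_on_survival Condition on both root lineages surviving.
#' @param rtol,atol ODE tolerances per branch.
#' @return Log-likelihood (nats).
#' @export
bds_log_likelihood <- function(phy, model, condition_on_survival = TRUE,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "bds_model"))
  td <- sse_tree_data(phy)
  bds_log_likelihood_td(td, model, condition_on_survival, rtol, atol)
}

bds_log_likelihood_td <- function(td, model, cond = TRUE,
                                  rtol = 1e-8, atol = 1e-10) {
  k <- model$k
  tips <- matrix(1, td$ntip, k)
  sse_loglik_cpp(td, tips, model$categories, rep(model$mu, k),
                 bds_Q(k, model$eta), model$rho, rep(1 / k, k), cond,
                 rtol, atol)
}

#' BDS priors
#'
#' @param lambda_mean_bounds Log-uniform bounds on the lognormal mean of the
#'   speciation categories.
#' @param lambda_sd_rate Exponential rate for the lognormal SD.
#' @param mu_bounds Log-uniform bounds on the shared extinction rate.
#' @param n_shifts_bounds Uniform bounds on the expected number of shifts
#'   across the tree; converted to `eta` by dividing by total tree length.
#' @return A list of class `bds_priors`.
#' @export
bds_priors <- function(lambda_mean_bounds = c(1e-6, 1e2),
                       lambda_sd_rate = 1.7,
                       mu_bounds = c(1e-6, 1e2),
                       n_shifts_bounds = c(0, 100)) {
  stopifnot(all(lambda_mean_bounds > 0), diff(lambda_mean_bounds) > 0,
            lambda_sd_rate > 0, all(mu_bounds > 0),
            n_shifts_bounds[1] >= 0, diff(n_shifts_bounds) > 0)
  structure(as.list(environment()), class = "bds_priors")
}

#' Run the BDS MCMC
#'
#' Samples the lognormal mean and SD of the speciation categories, the
#' shared extinction rate, and the expected shift count (mapped to the
#' switch rate `eta` by dividing by total tree length). At each recorded
#' generation a stochastic branch-category map is drawn by backward-forward
#' sampling conditional on the current parameters.
#'
#' @param phy Validated ultrametric tree.
#' @param priors A [bds_priors()].
#' @param rho Sampling fraction.
#' @param k Number of rate categories (default 6).
#' @param settings An [mcmc_settings()].
#' @param map_every Draw a stochastic map every `map_every`-th recorded
#'   sample (maps dominate runtime).
#' @param likelihood `"bds"` or `"none"` (prior-only validation runs).
#' @param rtol,atol ODE tolerances.
#' @return A list of `bds_trace` objects, one per run, with `samples`
#'   (hyperparameters), `maps` (per-branch event counts and mean rates per
#'   recorded map) and the postorder edge table.
#' @export
run_bds_mcmc <- function(phy, priors = bds_priors(), rho = 1, k = 6,
                         settings = mcmc_settings(), map_every = 5,
                         likelihood = c("bds", "none"),
                         rtol = 1e-7, atol = 1e-9) {
  likelihood <- match.arg(likelihood)
  td <- sse_tree_data(phy)
  rho <- as_rho(rho)
  lapply(seq_len(settings$n_runs), function(run) {
    bds_mcmc_one_run(td, priors, rho, k, settings,
                     substream_seed(settings$seed, 100 + run),
                     map_every, likelihood, rtol, atol)
  })
}

bds_mcmc_one_run <- function(td, priors, rho, k, settings, seed, map_every,
                             likelihood, rtol, atol) {
  set.seed(seed)
  TL <- td$total_length
  lb <- log(priors$lambda_mean_bounds)
  mb <- log(priors$mu_bounds)
  nb <- priors$n_shifts_bounds

  # state: log lambda-mean, sd_log, log mu, n_shifts
  st <- list(lmean = log(0.1), lsd = 0.3, lmu = log(0.03),
             nsh = mean(nb))
  tips <- matrix(1, td$ntip, k)
  loglik_fn <- function(s) {
    if (likelihood == "none") return(0)
    cats <- discretize_lognormal(s$lmean, s$lsd, k)
    sse_loglik_cpp(td, tips, cats, rep(exp(s$lmu), k),
                   bds_Q(k, s$nsh / TL), rho, rep(1 / k, k), TRUE,
                   rtol, atol)
  }
  logprior_fn <- function(s) {
    if (s$lmean < lb[1] || s$lmean > lb[2]) return(-Inf)
    if (s$lmu < mb[1] || s$lmu > mb[2]) return(-Inf)
    if (s$nsh < nb[1] || s$nsh > nb[2]) return(-Inf)
    if (s$lsd < 0) return(-Inf)
    dexp(s$lsd, priors$lambda_sd_rate, log = TRUE)
  }
  cur_lik <- loglik_fn(st); cur_pri <- logprior_fn(st)
  if (!is.finite(cur_lik + cur_pri)) stop("invalid BDS starting state")

  sc <- c(lmean = 0.3, lsd = 0.3, lmu = 0.5, nsh = 5)
  acc <- sc * 0; prp <- sc * 0
  n_rec <- floor(settings$generations / settings$thin)
  samples <- matrix(NA_real_, n_rec, 5 + k)
  colnames(samples) <- c("lambda_mean_log", "lambda_sd_log", "mu", "eta",
                         "n_shifts", paste0("category_", seq_len(k)))
  maps <- list()
  rec <- 0L
  total <- settings$pre_burn_in + settings$generations

  for (g in seq_len(total)) {
    for (p in names(sc)) {
      s2 <- st
      s2[[p]] <- st[[p]] + rnorm(1, 0, sc[[p]])
      prp[[p]] <- prp[[p]] + 1
      pri2 <- logprior_fn(s2)
      if (is.finite(pri2)) {
        lik2 <- loglik_fn(s2)
        if (is.finite(lik2) &&
            log(runif(1)) < (lik2 + pri2) - (cur_lik + cur_pri)) {
          st <- s2; cur_lik <- lik2; cur_pri <- pri2
          acc[[p]] <- acc[[p]] + 1
        }
      }
    }
    if (g <= settings$pre_burn_in && g %% settings$tuning_interval == 0) {
      for (p in names(sc)) {
        if (prp[[p]] > 0) {
          sc[[p]] <- min(max(sc[[p]] * exp(0.5 * (acc[[p]] / prp[[p]] - 0.44)),
                             1e-3), 50)
        }
        acc[[p]] <- 0; prp[[p]] <- 0
      }
    }
    if (g > settings$pre_burn_in &&
        (g - settings$pre_burn_in) %% settings$thin == 0) {
      rec <- rec + 1L
      cats <- discretize_lognormal(st$lmean, st$lsd, k)
      samples[rec, ] <- c(st$lmean, st$lsd, exp(st$lmu), st$nsh / TL,
                          st$nsh, cats)
      if (likelihood == "bds" && rec %% map_every == 0) {
        mp <- sse_map_cpp(td, tips, cats, rep(exp(st$lmu), k),
                          bds_Q(k, st$nsh / TL), rho, rep(1 / k, k), TRUE,
                          rtol, atol, 1L, numeric(0))
        maps[[length(maps) + 1]] <- list(
          events = mp$edge_events[1, ],
          mean_lambda = mp$edge_meanlam[1, ],
          node_state = mp$node_state[1, ])
      }
    }
  }
  structure(list(samples = samples[seq_len(rec), , drop = FALSE],
                 maps = maps, tree_data = td, k = k, seed = seed,
                 acceptance = ifelse(prp > 0, acc / prp, NA),
                 settings = settings),
            class = "bds_trace")
}

#' Detect branch-specific speciation-rate shifts
#'
#' A branch carries a shift when the posterior probability of at least one
#' category-change event on it (fraction of stochastic maps with >= 1
#' event) strictly exceeds `threshold`. The shift magnitude is the
#' multiplier: posterior-mean speciation rate on the branch divided by that
#' on its parent branch. The two root branches have no parent and are
#' excluded.
#'
#' @param traces A `bds_trace` or list of them (runs are pooled).
#' @param threshold Posterior-probability cutoff (strict, default 0.5).
#' @param burn_in_fraction Fraction of maps discarded from the front of
#'   each run.
#' @return A data.frame of class `shift_records`: one row per detected
#'   branch with `branch` (child node id), `pp`, `mean_lambda`,
#'   `parent_mean_lambda`, `multiplier`, `shift_age` (branch midpoint, My).
#'   The full per-branch table is attached as attribute `all_branches`.
#' @export
detect_shifts <- function(traces, threshold = 0.5, burn_in_fraction = 0.5) {
  if (inherits(traces, "bds_trace")) traces <- list(traces)
  td <- traces[[1]]$tree_data
  maps <- unlist(lapply(traces, function(tr) {
    mm <- tr$maps
    drop <- floor(length(mm) * burn_in_fraction)
    if (drop > 0) mm <- mm[-seq_len(drop)]
    mm
  }), recursive = FALSE)
  if (!length(maps)) stop("no stochastic maps present")
  ev <- do.call(rbind, lapply(maps, `[[`, "events"))
  ml <- do.call(rbind, lapply(maps, `[[`, "mean_lambda"))
  pp <- colMeans(ev >= 1)
  mean_lam <- colMeans(ml)
  nedge <- length(pp)
  # parent edge lookup (postorder edge table; root has none)
  parent_edge <- match(td$parent, td$child)
  mult <- mean_lam / mean_lam[parent_edge]
  midpoint <- (td$age_child + td$age_parent) / 2
  all_branches <- data.frame(
    branch = td$child, parent_node = td$parent, pp = pp,
    mean_lambda = mean_lam,
    parent_mean_lambda = mean_lam[parent_edge],
    multiplier = mult, shift_age = midpoint,
    n_maps = nrow(ev))
  has_parent <- !is.na(parent_edge)
  if (any(!has_parent & pp > threshold)) {
    message("root branch excluded from shift records (no parent branch)")
  }
  out <- all_branches[has_parent & pp > threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_branches") <- all_branches
  class(out) <- c("shift_records", "data.frame")
  out
}

#' Compare shift magnitudes between groups
#'
#' Log-transforms the shift multipliers, checks normality per group
#' (Shapiro-Wilk) and runs a one-way ANOVA across groups; also reports the
#' ratio of group geometric means.
#'
#' @param records A `shift_records` data.frame (or any data.frame with a
#'   `multiplier` column).
#' @param group Factor/character vector, one label per record.
#' @return A list of class `shift_group_test`: `anova_F`, `p_value`,
#'   `shapiro_p` (per group), `geometric_means`, `ratio` (largest over
#'   smallest mean).
#' @export
compare_shift_groups <- function(records, group) {
  stopifnot(nrow(records) == length(group))
  y <- log(records$multiplier)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  tab <- table(group)
  if (any(tab < 2)) stop("each group needs >= 2 records")
  sw <- vapply(levels(group), function(g2) {
    v <- y[group == g2]
    if (length(v) >= 3 && sd(v) > 0) shapiro.test(v)$p.value else NA_real_
  }, numeric(1))
  fit <- aov(y ~ group)
  an <- anova(fit)
  gm <- exp(tapply(y, group, mean))
  structure(list(anova_F = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 shapiro_p = sw,
                 geometric_means = gm,
                 ratio = max(gm) / min(gm),
                 n = as.integer(tab)),
            class = "shift_group_test")
}

#' @export
print.shift_group_test <- function(x, ...) {
  cat(sprintf("shift-magnitude ANOVA: F = %.4g, P = %.3g\n",
              x$anova_F, x$p_value))
  cat(sprintf("  group geometric means: %s (ratio %.3g)\n",
              paste(sprintf("%s = %.3g", names(x$geometric_means),
                            x$geometric_means), collapse = ", "),
              x$ratio))
  cat(sprintf("  Shapiro-Wilk on log multipliers: min P = %.3g\n",
              suppressWarnings(min(x$shapiro_p, na.rm = TRUE))))
  invisible(x)
}
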