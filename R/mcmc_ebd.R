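# MCMC for the episodic birth-death model with HSMRF priors.

#' MCMC settings
#'
#' @param generations Post-pre-burn-in generations to run.
#' @param thin Record every `thin`-th generation.
#' @param pre_burn_in Generations of adaptive tuning before recording
#'   (discarded; proposal scales are frozen afterwards).
#' @param tuning_interval Adaptation window length during pre-burn-in.
#' @param n_runs Number of independent runs.
#' @param seed Integer seed; run `i` uses `substream_seed(seed, i)`.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(generations = 50000, thin = 10,
                          pre_burn_in = 5000, tuning_interval = 200,
                          n_runs = 2, seed = 1) {
  stopifnot(generations > 0, thin > 0, pre_burn_in >= 0, tuning_interval > 0,
            n_runs >= 1)
  structure(as.list(environment()), class = "mcmc_settings")
}

# Kendall-Moran style starting estimate of the speciation rate.
kendall_moran_rate <- function(phy) {
  n <- length(phy$tip.label)
  tl <- sum(phy$edge.length)
  max((n - 2) / tl, 1e-4)
}

#' Run the episodic birth-death MCMC
#'
#' Metropolis-within-Gibbs over the log speciation and log extinction
#' trajectories with independent HSMRF priors (same global scale `zeta` for
#' both), half-Cauchy local scales updated by per-increment
#' Metropolis-Hastings, and a shared global half-Cauchy factor per
#' trajectory. Proposal scales adapt only during the pre-burn-in.
#'
#' @param phy Validated ultrametric tree.
#' @param grid A [time_grid()] spanning the root age (default: 1-My grid).
#' @param zeta Global scale hyperparameter (see [calibrate_zeta()]).
#' @param rho Sampling fraction.
#' @param settings An [mcmc_settings()].
#' @param likelihood `"ebd"` or `"none"` (prior-only runs for validation).
#' @param condition_on_survival Passed to the likelihood.
#' @return A list of `posterior_trace` objects (one per run). Each has a
#'   `samples` matrix (`lambda_1..K`, `mu_1..K`, `global_lambda`,
#'   `global_mu`, `loglik`), the generation stamps, and acceptance rates.
#' @export
run_ebd_mcmc <- function(phy, grid = NULL, zeta, rho = 1,
                         settings = mcmc_settings(),
                         likelihood = c("ebd", "none"),
                         condition_on_survival = TRUE) {
  likelihood <- match.arg(likelihood)
  if (is.null(grid)) grid <- time_grid_for_tree(phy)
  bt <- branching_times(phy)
  if (max(grid$boundaries) < bt[1] * (1 - 1e-9)) {
    stop("grid does not span the root age")
  }
  rho <- as_rho(rho)
  lapply(seq_len(settings$n_runs), function(run) {
    ebd_mcmc_one_run(bt, grid, zeta, rho, settings,
                     substream_seed(settings$seed, run),
                     likelihood, condition_on_survival,
                     n_tip = length(phy$tip.label),
                     km = kendall_moran_rate(phy))
  })
}

# One elliptical-slice-sampling update of a Gaussian-prior vector.
# Exact for the prior (likelihood-only slice), no tuning parameters.
ess_update <- function(delta, sds, cur_lik, loglik_fn) {
  nu <- rnorm(length(delta), 0, sds)
  logy <- cur_lik + log(runif(1))
  theta <- runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi; hi <- theta
  for (it in 1:100) {
    prop <- delta * cos(theta) + nu * sin(theta)
    pl <- loglik_fn(prop)
    if (is.finite(pl) && pl > logy) {
      return(list(delta = prop, lik = pl))
    }
    if (theta < 0) lo <- theta else hi <- theta
    theta <- runif(1, lo, hi)
    if (hi - lo < 1e-12) break
  }
  list(delta = delta, lik = cur_lik)
}

ebd_mcmc_one_run <- function(bt, grid, zeta, rho, settings, seed,
                             likelihood, cond, n_tip, km) {
  set.seed(seed)
  K <- grid$n_intervals
  bounds <- grid$boundaries
  m0 <- log(km)

  # parameterization: first log-rate + increments (the HSMRF variables)
  xl1 <- m0; dl <- rep(0, K - 1)
  xm1 <- m0 - log(2); dm <- rep(0, K - 1)
  gam_l <- rep(1, K - 1); gam_m <- rep(1, K - 1)
  G_l <- 1; G_m <- 1

  rates_of <- function(x1, d) exp(x1 + c(0, cumsum(d)))
  lik <- function(l_l, l_m) {
    if (likelihood == "none") return(0)
    ebd_loglik_cpp(bt, bounds, l_l, l_m, rho, cond)
  }
  cur_lik <- lik(rates_of(xl1, dl), rates_of(xm1, dm))

  sc <- c(x1_l = 0.2, x1_m = 0.3)
  acc <- sc * 0; prp <- sc * 0
  n_rec <- floor(settings$generations / settings$thin)
  samples <- matrix(NA_real_, n_rec, 2 * K + 3)
  colnames(samples) <- c(paste0("lambda_", seq_len(K)),
                         paste0("mu_", seq_len(K)),
                         "global_lambda", "global_mu", "loglik")
  rec <- 0L
  total <- settings$pre_burn_in + settings$generations

  update_scales <- function(d, gam, G) {
    # per-increment local scales: independent MH on log gamma
    gn <- gam * exp(rnorm(K - 1, 0, 1.2))
    lr <- dnorm(d, 0, zeta * G * gn, log = TRUE) -
      dnorm(d, 0, zeta * G * gam, log = TRUE) +
      half_cauchy_log_density(gn) - half_cauchy_log_density(gam) +
      log(gn) - log(gam)          # Jacobian of the log-scale walk
    take <- !is.na(lr) & log(runif(K - 1)) < lr
    gam[take] <- gn[take]
    # shared global factor
    Gn <- G * exp(rnorm(1, 0, 0.8))
    lr_g <- sum(dnorm(d, 0, zeta * Gn * gam, log = TRUE) -
                  dnorm(d, 0, zeta * G * gam, log = TRUE)) +
      half_cauchy_log_density(Gn) - half_cauchy_log_density(G) +
      log(Gn) - log(G)
    if (!is.na(lr_g) && log(runif(1)) < lr_g) G <- Gn
    list(gam = gam, G = G)
  }

  for (g in seq_len(total)) {
    # first-rate random walks (these slide the whole trajectory)
    for (w in c("l", "m")) {
      key <- paste0("x1_", w)
      x1n <- (if (w == "l") xl1 else xm1) + rnorm(1, 0, sc[[key]])
      prp[[key]] <- prp[[key]] + 1
      newlik <- if (w == "l") lik(rates_of(x1n, dl), rates_of(xm1, dm))
                else lik(rates_of(xl1, dl), rates_of(x1n, dm))
      pri_new <- dnorm(x1n, m0, 1, log = TRUE)
      pri_old <- dnorm(if (w == "l") xl1 else xm1, m0, 1, log = TRUE)
      if (is.finite(newlik) &&
          log(runif(1)) < (newlik + pri_new) - (cur_lik + pri_old)) {
        if (w == "l") xl1 <- x1n else xm1 <- x1n
        cur_lik <- newlik
        acc[[key]] <- acc[[key]] + 1
      }
    }
    # elliptical slice updates of the increment vectors
    up <- ess_update(dl, zeta * G_l * gam_l, cur_lik, function(d) {
      lik(rates_of(xl1, d), rates_of(xm1, dm))
    })
    dl <- up$delta; cur_lik <- up$lik
    up <- ess_update(dm, zeta * G_m * gam_m, cur_lik, function(d) {
      lik(rates_of(xl1, dl), rates_of(xm1, d))
    })
    dm <- up$delta; cur_lik <- up$lik
    # shrinkage scales (prior-only conditionals)
    slu <- update_scales(dl, gam_l, G_l); gam_l <- slu$gam; G_l <- slu$G
    smu <- update_scales(dm, gam_m, G_m); gam_m <- smu$gam; G_m <- smu$G

    if (g <= settings$pre_burn_in && g %% settings$tuning_interval == 0) {
      for (key in names(sc)) {
        if (prp[[key]] > 0) {
          sc[[key]] <- min(max(sc[[key]] *
                                 exp(0.7 * (acc[[key]] / prp[[key]] - 0.44)),
                               1e-4), 10)
        }
        acc[[key]] <- 0; prp[[key]] <- 0
      }
    }
    if (g > settings$pre_burn_in &&
        (g - settings$pre_burn_in) %% settings$thin == 0) {
      rec <- rec + 1L
      samples[rec, ] <- c(rates_of(xl1, dl), rates_of(xm1, dm),
                          G_l, G_m, cur_lik)
    }
  }

  acc_rates <- ifelse(prp > 0, acc / prp, NA_real_)
  structure(list(samples = samples[seq_len(rec), , drop = FALSE],
                 generation = settings$pre_burn_in +
                   seq_len(rec) * settings$thin,
                 grid = grid, zeta = zeta, rho = rho, seed = seed,
                 settings = settings, acceptance = acc_rates,
                 burn_in_applied = FALSE),
            class = "posterior_trace")
}

# ---------------------------------------------------------------------------
# Convergence diagnostics
# ---------------------------------------------------------------------------

#' Effective sample size (initial monotone sequence estimator)
#'
#' @param x Numeric vector of MCMC samples.
#' @return Estimated ESS (capped at `length(x)`).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  maxlag <- min(n - 1, 10 * floor(sqrt(n)))
  rho <- acf(x, lag.max = maxlag, plot = FALSE)$acf[-1]
  # Geyer: sum of adjacent pairs, truncated at first negative, monotonized
  npair <- floor(length(rho) / 2)
  if (npair == 0) return(n)
  g <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  cut <- which(g < 0)[1]
  if (!is.na(cut)) g <- g[seq_len(cut - 1)]
  if (length(g)) g <- cummin(g)
  tau <- 1 + 2 * sum(g)
  min(n, max(1, n / max(tau, 1e-6)))
}

#' Convergence configuration
#'
#' @param alpha Precision level for the Kolmogorov-Smirnov threshold
#'   (default 0.015).
#' @param min_ess Minimum effective sample size per parameter.
#' @return A list of class `convergence_config`.
#' @export
convergence_config <- function(alpha = 0.015, min_ess = 100) {
  stopifnot(alpha > 0, alpha < 1, min_ess > 0)
  structure(list(alpha = alpha, min_ess = min_ess),
            class = "convergence_config")
}

#' Check convergence between independent MCMC runs
#'
#' For every parameter, the two-sample Kolmogorov-Smirnov statistic between
#' the first and each subsequent run is compared against the critical value
#' at precision `alpha`, with effective sample sizes in place of raw sample
#' counts. Parameters whose ESS falls below `min_ess` are flagged
#' inconclusive rather than failed.
#'
#' @param traces List of at least two `posterior_trace` objects with
#'   identical parameter sets.
#' @param config A [convergence_config()].
#' @param burn_in_fraction Fraction of each trace dropped before testing.
#' @return A list of class `convergence_report`: per-parameter data.frame
#'   and overall `converged` flag.
#' @export
check_convergence <- function(traces, config = convergence_config(),
                              burn_in_fraction = 0) {
  stopifnot(length(traces) >= 2)
  get_mat <- function(tr) {
    m <- if (inherits(tr, "posterior_trace") || inherits(tr, "hisse_trace") ||
             is.list(tr)) tr$samples else tr
    m <- m[, setdiff(colnames(m), "loglik"), drop = FALSE]
    if (burn_in_fraction > 0) {
      drop <- floor(nrow(m) * burn_in_fraction)
      m <- m[(drop + 1):nrow(m), , drop = FALSE]
    }
    m
  }
  mats <- lapply(traces, get_mat)
  pars <- colnames(mats[[1]])
  if (!all(vapply(mats, function(m) identical(colnames(m), pars), TRUE))) {
    stop("traces have different parameter sets")
  }
  c_alpha <- sqrt(-log(config$alpha / 2) / 2)
  rows <- lapply(pars, function(p) {
    x <- mats[[1]][, p]
    worst <- 0; ess_min <- Inf
    for (j in 2:length(mats)) {
      y <- mats[[j]][, p]
      D <- suppressWarnings(ks.test(x, y)$statistic)
      e1 <- effective_size(x); e2 <- effective_size(y)
      ess_min <- min(ess_min, e1, e2)
      worst <- max(worst, D)
    }
    e1 <- effective_size(x)
    thr <- c_alpha * sqrt((e1 + ess_min) / (e1 * ess_min))
    data.frame(parameter = p, ks = unname(worst), threshold = thr,
               ess = ess_min,
               status = if (ess_min < config$min_ess) "inconclusive"
               else if (worst <= thr) "pass" else "fail")
  })
  report <- do.call(rbind, rows)
  structure(list(parameters = report,
                 converged = !any(report$status == "fail"),
                 alpha = config$alpha),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  st <- x$parameters$status
  cat(sprintf(
    "convergence at alpha = %g: %s (%d pass, %d inconclusive, %d fail of %d)\n",
    x$alpha, if (x$converged) "PASS" else "FAIL",
    sum(st == "pass"), sum(st == "inconclusive"), sum(st == "fail"),
    length(st)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Posterior summaries
# ---------------------------------------------------------------------------

#' Combine posterior traces
#' @param traces List of `posterior_trace` objects from the same model.
#' @return A single `posterior_trace` with stacked samples.
#' @export
combine_traces <- function(traces) {
  out <- traces[[1]]
  out$samples <- do.call(rbind, lapply(traces, function(t) t$samples))
  out$generation <- seq_len(nrow(out$samples))
  out
}

#' Summarize rates through time from a posterior trace
#'
#' Per-interval posterior median and central 95% interval for speciation,
#' extinction and net diversification after burn-in removal, optionally
#' truncated to a recent time window, plus the grand median of each rate
#' across retained intervals.
#'
#' @param trace A combined `posterior_trace`.
#' @param burn_in_fraction Fraction of samples removed from the front
#'   (default 0.25).
#' @param truncate_to Retain only intervals younger than this age (My);
#'   `NULL` keeps the whole grid.
#' @return A list of class `rate_summary` with a per-interval data.frame and
#'   grand medians.
#' @export
summarize_rates <- function(trace, burn_in_fraction = 0.25,
                            truncate_to = NULL) {
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  m <- trace$samples
  drop <- floor(nrow(m) * burn_in_fraction)
  if (drop >= nrow(m)) stop("burn-in removed every sample")
  m <- m[(drop + 1):nrow(m), , drop = FALSE]
  K <- trace$grid$n_intervals
  keep_k <- seq_len(K)
  if (!is.null(truncate_to)) {
    if (truncate_to > max(trace$grid$boundaries) + 1e-9) {
      stop("truncation window exceeds the grid span")
    }
    keep_k <- which(trace$grid$boundaries[-1] <= truncate_to + 1e-9)
  }
  lam <- m[, paste0("lambda_", keep_k), drop = FALSE]
  mu <- m[, paste0("mu_", keep_k), drop = FALSE]
  r <- lam - mu
  qs <- function(x) quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  summ <- function(mat) {
    q <- apply(mat, 2, qs)
    data.frame(lower = q[1, ], median = q[2, ], upper = q[3, ])
  }
  sl <- summ(lam); sm <- summ(mu); sr <- summ(r)
  intervals <- data.frame(
    interval = keep_k,
    age_young = trace$grid$boundaries[keep_k],
    age_old = trace$grid$boundaries[keep_k + 1],
    lambda_lower = sl$lower, lambda_median = sl$median, lambda_upper = sl$upper,
    mu_lower = sm$lower, mu_median = sm$median, mu_upper = sm$upper,
    r_lower = sr$lower, r_median = sr$median, r_upper = sr$upper)
  structure(list(
    intervals = intervals,
    grand_median = c(lambda = median(sl$median), mu = median(sm$median),
                     r = median(sr$median)),
    truncate_to = truncate_to,
    n_samples = nrow(m)),
    class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("rate_summary: %d intervals, %d posterior samples%s\n",
              nrow(x$intervals), x$n_samples,
              if (!is.null(x$truncate_to)) {
                sprintf(", truncated to %g My", x$truncate_to)
              } else ""))
  cat(sprintf("  grand medians: lambda %.4g, mu %.4g, r %.4g\n",
              x$grand_median["lambda"], x$grand_median["mu"],
              x$grand_median["r"]))
  invisible(x)
}
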