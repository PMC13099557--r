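# Congruent diversification scenarios.
#
# Two birth-death models are congruent (same reconstructed-tree likelihood
# for every tree) when they share the pulled diversification rate
#   rp(t) = lambda(t) - mu(t) + lambda'(t) / lambda(t),
# with time t increasing toward the past. The package works with the
# discrete analogue on a grid: the derivative is the one-sided (backward,
# toward the past) difference, which makes the constant-rate case exact and
# makes the congruence map an exact inversion of the rp definition. Because
# piecewise-constant representatives of a congruence class only approach
# exact likelihood equality as the grid is refined, congruence construction
# internally refines the reference grid (the refinement leaves the reference
# model, and hence its likelihood, untouched).

#' Pulled diversification rate on the grid
#'
#' `rp_i = lambda_i - mu_i + (lambda_{i+1} - lambda_i) / (h * lambda_i)`
#' with `h` the interval width; index increases toward the past and the last
#' interval uses a zero derivative.
#'
#' @param traj A [rate_trajectory()] with strictly positive `lambda`.
#' @return Per-interval pulled diversification rate (lineages/My).
#' @export
pulled_diversification_rate <- function(traj) {
  if (any(traj$lambda <= 0)) stop("pulled rate requires lambda > 0")
  lam <- traj$lambda
  h <- traj$grid$width
  dldt <- c(diff(lam) / h, 0)
  lam - traj$mu + dldt / lam
}

# refine a trajectory to a finer grid (exactly the same model)
refine_trajectory <- function(traj, factor) {
  if (factor == 1) return(traj)
  g <- time_grid(traj$grid$n_intervals * factor, traj$grid$width / factor)
  rate_trajectory(g, rep(traj$lambda, each = factor),
                  rep(traj$mu, each = factor))
}

#' Congruent speciation trajectory for a given extinction trajectory
#'
#' Solves for `lambda*` on the grid such that the discrete pulled
#' diversification rate of `(lambda*, mu_star)` equals that of the
#' reference: `lambda*_{i+1} = lambda*_i + h * lambda*_i * (rp_i -
#' lambda*_i + mu*_i)`, anchored at the reference's present-day speciation
#' rate. The recursion is the exact inverse of the discrete rp definition,
#' so the pulled rates agree to machine precision; likelihood equality holds
#' up to grid resolution (refine via `refine`).
#'
#' @param reference A [rate_trajectory()].
#' @param mu_star Extinction rates: either on the reference grid (recycled)
#'   or a function of age.
#' @param refine Integer sub-division factor applied to the reference grid
#'   before constructing the partner (default 1: native grid).
#' @return A `rate_trajectory` on the (refined) grid with attribute `valid`
#'   (FALSE when `lambda*` goes negative; negative values are clamped to 0
#'   so the object remains constructible).
#' @export
congruent_lambda_given_mu <- function(reference, mu_star, refine = 1) {
  ref <- refine_trajectory(reference, refine)
  K <- ref$grid$n_intervals
  h <- ref$grid$width
  mids <- ref$grid$boundaries[-1] - h / 2
  mu_s <- if (is.function(mu_star)) mu_star(mids)
          else rep(rep_len(mu_star, reference$grid$n_intervals), each = refine)
  if (any(mu_s < 0)) stop("mu_star must be >= 0")
  rp <- pulled_diversification_rate(ref)
  lam <- congruence_lambda_cpp(rp, mu_s, h, ref$lambda[1])
  valid <- all(lam >= 0)
  out <- rate_trajectory(ref$grid, pmax(lam, 0), mu_s)
  attr(out, "valid") <- valid
  out
}

#' Congruent extinction trajectory for a given speciation trajectory
#'
#' Direct inversion `mu*_i = lambda*_i - rp_i + (lambda*_{i+1} -
#' lambda*_i)/(h * lambda*_i)`.
#'
#' @param reference A [rate_trajectory()].
#' @param lambda_star Speciation rates on the reference grid (recycled) or a
#'   function of age; must be positive.
#' @param refine As in [congruent_lambda_given_mu()].
#' @return A `rate_trajectory` with attribute `valid` (FALSE when `mu*`
#'   goes negative).
#' @export
congruent_mu_given_lambda <- function(reference, lambda_star, refine = 1) {
  ref <- refine_trajectory(reference, refine)
  h <- ref$grid$width
  mids <- ref$grid$boundaries[-1] - h / 2
  lam_s <- if (is.function(lambda_star)) lambda_star(mids)
           else rep(rep_len(lambda_star, reference$grid$n_intervals),
                    each = refine)
  if (any(lam_s <= 0)) stop("lambda_star must be > 0")
  rp <- pulled_diversification_rate(ref)
  dldt <- c(diff(lam_s) / h, 0)
  mu_s <- lam_s - rp + dldt / lam_s
  valid <- all(mu_s >= 0)
  out <- rate_trajectory(ref$grid, lam_s, pmax(mu_s, 0))
  attr(out, "valid") <- valid
  out
}

#' Test a named congruent diversification scenario
#'
#' The four scenarios: `"constant-mu"` (partner extinction pinned at the
#' reference time-average), `"exp-increasing-mu"` (exponential in age,
#' anchored at the reference's present-day extinction), `"constant-lambda"`
#' (speciation pinned at the reference time-average) and
#' `"exp-decreasing-lambda"` (anchored at the present-day speciation).
#' Exponential exponents default to the least-squares fit of the reference's
#' own log-rate trend.
#'
#' @param reference A [rate_trajectory()].
#' @param scenario One of the four scenario labels.
#' @param exponent Exponential rate per My (increase toward the past for mu,
#'   decrease for lambda); `NULL` fits it from the reference.
#' @param refine Grid refinement for the congruence construction.
#' @return A list of class `congruence_member`: `trajectory`, `valid`,
#'   `scenario`, `exponent`.
#' @export
scenario_test <- function(reference,
                          scenario = c("constant-mu", "exp-increasing-mu",
                                       "constant-lambda",
                                       "exp-decreasing-lambda"),
                          exponent = NULL, refine = 1) {
  scenario <- match.arg(scenario)
  fit_exponent <- function(rates) {
    mids <- reference$grid$boundaries[-1] - reference$grid$width / 2
    unname(coef(lm(log(pmax(rates, 1e-12)) ~ mids))[2])
  }
  if (scenario == "constant-mu") {
    partner <- congruent_lambda_given_mu(reference, mean(reference$mu),
                                         refine = refine)
    exponent <- 0
  } else if (scenario == "exp-increasing-mu") {
    if (is.null(exponent)) exponent <- max(fit_exponent(reference$mu), 0)
    mu0 <- reference$mu[1]
    partner <- congruent_lambda_given_mu(
      reference, function(a) mu0 * exp(exponent * a), refine = refine)
  } else if (scenario == "constant-lambda") {
    partner <- congruent_mu_given_lambda(reference, mean(reference$lambda),
                                         refine = refine)
    exponent <- 0
  } else {
    if (is.null(exponent)) exponent <- min(fit_exponent(reference$lambda), 0)
    lam0 <- reference$lambda[1]
    partner <- congruent_mu_given_lambda(
      reference, function(a) lam0 * exp(exponent * a), refine = refine)
  }
  structure(list(trajectory = partner, valid = attr(partner, "valid"),
                 scenario = scenario, exponent = exponent),
            class = "congruence_member")
}

#' Configuration for the joint congruence sampler
#'
#' @param n_sets Number of congruent members to draw (default 20).
#' @param sigma_mrf Scale of the random-walk perturbation component
#'   (total-trajectory standard deviation, default 1).
#' @param beta1 Scale of the constant (level) perturbation (default 0.5).
#' @param beta2 Scale of the linear-trend perturbation (default 0.2).
#' @param seed Integer seed.
#' @param max_retries Redraws allowed per member before giving up.
#' @return A list of class `congruence_sampler_config`.
#' @export
congruence_sampler_config <- function(n_sets = 20, sigma_mrf = 1,
                                      beta1 = 0.5, beta2 = 0.2, seed = 1,
                                      max_retries = 50) {
  stopifnot(n_sets >= 0, sigma_mrf > 0, beta1 > 0, beta2 > 0)
  structure(as.list(environment()), class = "congruence_sampler_config")
}

#' Sample a congruent set by joint perturbation
#'
#' Draws `n_sets` random extinction trajectories by perturbing the reference
#' log extinction with three components (a level shift of scale `beta1`, a
#' linear trend of scale `beta2`, and a random walk of total scale
#' `sigma_mrf`), then solves the congruent speciation partner for each.
#' Invalid draws (negative partner rates) are rejected and redrawn up to
#' `max_retries`; if retries are exhausted a partial set is returned with a
#' warning.
#'
#' @param reference A [rate_trajectory()].
#' @param config A [congruence_sampler_config()].
#' @param refine Grid refinement for the congruence construction.
#' @param member_fn Optional function applied to each accepted member; when
#'   supplied, its return value is stored in place of the member itself
#'   (keeps memory bounded when members live on heavily refined grids).
#' @return A list of class `congruence_set`: `reference` (refined),
#'   `members` (list of `congruence_member`, or of `member_fn` results).
#' @export
sample_congruent_set <- function(reference, config = congruence_sampler_config(),
                                 refine = 1, member_fn = NULL) {
  set.seed(substream_seed(config$seed, "congruence"))
  K <- reference$grid$n_intervals
  tt <- seq(0, 1, length.out = K)
  members <- list()
  if (config$n_sets > 0) {
    for (i in seq_len(config$n_sets)) {
      ok <- FALSE
      for (try in seq_len(config$max_retries)) {
        walk <- cumsum(c(0, rnorm(K - 1, 0, config$sigma_mrf / sqrt(K))))
        f <- config$beta1 * rnorm(1) + config$beta2 * rnorm(1) * tt + walk
        mu_star <- reference$mu * exp(f)
        partner <- congruent_lambda_given_mu(reference, mu_star,
                                             refine = refine)
        if (isTRUE(attr(partner, "valid"))) {
          member <- structure(list(trajectory = partner, valid = TRUE,
                                   scenario = "joint-sampled", exponent = NA),
                              class = "congruence_member")
          members[[length(members) + 1]] <-
            if (is.null(member_fn)) member else member_fn(member)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        warning("congruence sampler: retries exhausted, returning a ",
                "partial set (", length(members), "/", config$n_sets, ")")
        break
      }
    }
  }
  structure(list(reference = refine_trajectory(reference, refine),
                 reference_native = reference,
                 members = members, config = config, refine = refine),
            class = "congruence_set")
}

#' Label per-interval diversification trends across a congruent set
#'
#' Interval-to-interval changes in net diversification (and speciation) are
#' labeled increase/decrease/flat using the reference-specific threshold of
#' twice the mean absolute change in speciation between adjacent intervals.
#' Members constructed on refined grids are aggregated back to the reference
#' grid (interval means) before labeling. Also reports, per interval
#' transition, the fraction of members sharing the reference's net-rate
#' label.
#'
#' @param set A `congruence_set`, or a list with `reference` and `members`.
#' @return A list of class `trend_summary`: `threshold`, `reference_labels`,
#'   `member_labels` (matrix members x transitions), `agreement`.
#' @export
summarize_trends <- function(set) {
  ref <- if (!is.null(set$reference_native)) set$reference_native else set$reference
  members <- set$members
  if (!length(members)) stop("no members to summarize")
  h <- ref$grid$width
  thr <- 2 * mean(abs(diff(ref$lambda)))
  label <- function(x) {
    d <- diff(x)
    ifelse(d > thr, "increase", ifelse(d < -thr, "decrease", "flat"))
  }
  coarsen <- function(traj) {
    f <- traj$grid$n_intervals / ref$grid$n_intervals
    if (f == 1) return(traj)
    idx <- rep(seq_len(ref$grid$n_intervals), each = f)
    rate_trajectory(ref$grid,
                    as.numeric(tapply(traj$lambda, idx, mean)),
                    as.numeric(tapply(traj$mu, idx, mean)))
  }
  ref_r_lab <- label(net_diversification(ref))
  ref_l_lab <- label(ref$lambda)
  mem_lab <- t(vapply(members, function(m) {
    tr <- coarsen(m$trajectory)
    label(net_diversification(tr))
  }, character(ref$grid$n_intervals - 1)))
  agreement <- colMeans(mem_lab == matrix(ref_r_lab, nrow(mem_lab),
                                          length(ref_r_lab), byrow = TRUE))
  structure(list(threshold = thr,
                 reference_labels = data.frame(
                   transition = seq_along(ref_r_lab),
                   r = ref_r_lab, lambda = ref_l_lab),
                 member_labels = mem_lab,
                 agreement = agreement),
            class = "trend_summary")
}
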