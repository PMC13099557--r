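# Episodic birth-death likelihood.

#' Episodic birth-death log-likelihood
#'
#' Reconstructed-tree log-likelihood of an ultrametric tree under
#' piecewise-constant speciation and extinction rates with uniform tip
#' sampling at the present. The extinction probability and per-lineage flow
#' have closed forms within each constant-rate interval, so the computation
#' is exact up to floating point (no ODE error).
#'
#' The likelihood is conditioned on the root split at the crown age (no
#' speciation-rate factor at the root) and, when `condition_on_survival =
#' TRUE` (the default), additionally conditions on both root lineages having
#' sampled descendants. With that convention the conditioned likelihood is a
#' functional of the pulled speciation rate alone, so congruent rate
#' trajectories give equal values.
#'
#' @param phy A validated ultrametric tree (`phylo`).
#' @param traj A [rate_trajectory()] whose grid spans the root age.
#' @param rho Sampling fraction in (0, 1] or a [sampling_fraction()].
#' @param condition_on_survival Condition on survival of the two lineages
#'   descending from the root.
#' @return Log-likelihood in nats; `-Inf` when a branching event falls in an
#'   interval with zero speciation rate.
#' @export
ebd_log_likelihood <- function(phy, traj, rho = 1,
                               condition_on_survival = TRUE) {
  stopifnot(inherits(traj, "rate_trajectory"))
  bt <- branching_times(phy)
  ebd_log_likelihood_bt(bt, traj, rho, condition_on_survival)
}

# Branching-time interface used by the MCMC (avoids re-traversing the tree).
ebd_log_likelihood_bt <- function(bt, traj, rho = 1,
                                  condition_on_survival = TRUE) {
  rho <- as_rho(rho)
  bounds <- traj$grid$boundaries
  if (bounds[length(bounds)] < bt[1] * (1 - 1e-9)) {
    stop("time grid (", bounds[length(bounds)],
         " My) is shorter than the root age (", bt[1], " My)")
  }
  ebd_loglik_cpp(bt, bounds, traj$lambda, traj$mu, rho,
                 condition_on_survival)
}

#' Constant-rate birth-death log-likelihood (closed form)
#'
#' Independent closed-form implementation for a constant-rate birth-death
#' process with sampling fraction `rho`, via the classical single-lineage
#' density `p1(t)` and extinction probability `p0(t)`. Uses the same
#' conventions as [ebd_log_likelihood()] (root speciation term included;
#' optional conditioning on survival of both root lineages), so the two give
#' identical answers for constant rates while sharing no code.
#'
#' @param phy A validated ultrametric tree.
#' @param lambda,mu Constant speciation and extinction rates (lineages/My).
#' @param rho Sampling fraction in (0, 1].
#' @param condition_on_survival As in [ebd_log_likelihood()].
#' @return Log-likelihood in nats.
#' @export
bd_constant_log_likelihood <- function(phy, lambda, mu, rho = 1,
                                       condition_on_survival = TRUE) {
  rho <- as_rho(rho)
  bt <- branching_times(phy)
  n <- length(bt) + 1
  r <- lambda - mu
  denom <- function(t) rho * lambda + (lambda * (1 - rho) - mu) * exp(-r * t)
  log_p1 <- function(t) {
    if (abs(r) < 1e-12 * (lambda + mu)) {
      log(rho) - 2 * log1p(rho * lambda * t)
    } else {
      log(rho) + 2 * log(abs(r)) - r * t - 2 * log(abs(denom(t)))
    }
  }
  p0 <- function(t) {
    if (abs(r) < 1e-12 * (lambda + mu)) {
      1 - rho / (1 + rho * lambda * t)
    } else {
      1 - rho * r / denom(t)
    }
  }
  # no speciation factor at the root (root split conditioned upon)
  ll <- n * log(rho) + (n - 2) * log(lambda) +
    2 * (log_p1(bt[1]) - log(rho)) +
    sum(vapply(bt[-1], log_p1, numeric(1)) - log(rho))
  if (condition_on_survival) ll <- ll - 2 * log(1 - p0(bt[1]))
  ll
}
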