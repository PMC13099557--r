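# Time grids and piecewise-constant rate trajectories.

#' Time grid anchored at the present
#'
#' Intervals cover `[0, n_intervals * width]` in My before present; interval
#' `i` spans ages `[(i-1)*width, i*width)`. The interval containing the root
#' may be partial when the grid is built for a specific tree.
#'
#' @param n_intervals Number of intervals.
#' @param width Interval width in My (default 1).
#' @return An object of class `time_grid` with `boundaries` (length
#'   `n_intervals + 1`), `width` and `n_intervals`.
#' @export
time_grid <- function(n_intervals, width = 1) {
  stopifnot(n_intervals >= 1, width > 0)
  structure(list(
    n_intervals = as.integer(n_intervals),
    width = width,
    boundaries = seq(0, n_intervals * width, by = width)
  ), class = "time_grid")
}

#' Time grid spanning a tree
#'
#' Smallest grid of `width`-My intervals that covers the root age.
#'
#' @param phy A validated tree, or a root age in My.
#' @param width Interval width in My.
#' @return A `time_grid`.
#' @export
time_grid_for_tree <- function(phy, width = 1) {
  ra <- if (inherits(phy, "phylo")) root_age(phy) else phy
  time_grid(ceiling(ra / width - 1e-12), width)
}

#' Piecewise-constant rate trajectory
#'
#' @param grid A `time_grid`.
#' @param lambda Speciation rate per interval (lineages/My, recycled).
#' @param mu Extinction rate per interval (lineages/My, recycled).
#' @return An object of class `rate_trajectory` with fields `grid`, `lambda`,
#'   `mu`; the net diversification `r = lambda - mu` is available via
#'   [net_diversification()].
#' @export
rate_trajectory <- function(grid, lambda, mu) {
  stopifnot(inherits(grid, "time_grid"))
  lambda <- rep_len(as.numeric(lambda), grid$n_intervals)
  mu <- rep_len(as.numeric(mu), grid$n_intervals)
  if (any(lambda < 0) || any(mu < 0)) stop("rates must be >= 0")
  structure(list(grid = grid, lambda = lambda, mu = mu),
            class = "rate_trajectory")
}

#' Net diversification rate of a trajectory
#' @param traj A `rate_trajectory`.
#' @return Per-interval `lambda - mu` (may be negative).
#' @export
net_diversification <- function(traj) traj$lambda - traj$mu

#' Rate at given ages
#'
#' Looks up the interval value for each age; ages at or beyond the last
#' boundary take the last interval's value.
#'
#' @param traj A `rate_trajectory`.
#' @param age Ages in My before present.
#' @param which `"lambda"` or `"mu"`.
#' @return Numeric vector of rates.
#' @export
rate_at <- function(traj, age, which = c("lambda", "mu")) {
  which <- match.arg(which)
  idx <- interval_index(traj$grid, age)
  traj[[which]][idx]
}

interval_index <- function(grid, age) {
  idx <- findInterval(age, grid$boundaries, left.open = TRUE)
  idx[age <= 0] <- 1L
  pmin(pmax(idx, 1L), grid$n_intervals)
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("rate_trajectory: %d intervals of %g My\n",
              x$grid$n_intervals, x$grid$width))
  cat(sprintf("  lambda in [%.4g, %.4g], mu in [%.4g, %.4g]\n",
              min(x$lambda), max(x$lambda), min(x$mu), max(x$mu)))
  invisible(x)
}
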