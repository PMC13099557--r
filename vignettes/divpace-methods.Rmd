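---
title: "Models and methods in divpace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in divpace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

divpace estimates how diversification rates of clades on an ultrametric,
time-calibrated phylogeny have changed through time, and stress-tests those
estimates in three complementary ways: congruence-class robustness checks,
lineage-specific shift detection, and hidden-state state-dependent
diversification. This vignette documents the models, the numerical choices,
and the design decisions behind each module, in enough detail that a reader
could re-derive the implementation. Time is measured in My before present
(present = 0), rates in events per lineage per My.

## The episodic birth-death model

The core model assumes speciation rate $\lambda(t)$ and extinction rate
$\mu(t)$ are piecewise constant on a grid of 1-My intervals anchored at the
present. For a reconstructed tree with $n$ tips, uniform sampling fraction
$\rho$ at the present, and branching ages $x_1 \ge x_2 \ge \dots \ge
x_{n-1}$ (with $x_1$ the crown age), the likelihood uses the standard
extinction probability $E(t)$ — the probability that a lineage alive at age
$t$ leaves no sampled descendant — and the per-lineage flow $q(t)$, with

$$\frac{dE}{dt} = \mu - (\lambda + \mu)E + \lambda E^2, \qquad
  \frac{d \log q}{dt} = \lambda + \mu - 2 \lambda E,$$

integrated from $E(0) = 1 - \rho$, $q(0) = 1$ toward the past. Both
equations have closed-form solutions within each constant-rate interval, so
`ebd_log_likelihood()` is exact to floating point: no ODE solver enters the
core path, and splitting any interval into equal-rate halves changes the
log-likelihood by strictly less than $10^{-8}$ (a tested invariant).

**Conditioning convention.** The likelihood is conditioned on the root
split at the crown age — there is no speciation-rate factor at the root —
and, by default, on survival of both root lineages (division by
$(1-E(x_1))^2$). This combination makes the conditioned likelihood a pure
functional of the pulled speciation rate $\lambda_p(t) =
\lambda(t)\,(1-E(t))$: writing $\tilde q = q\,(1-E)/\rho$ one finds $d\log
\tilde q/dt = \lambda_p$, and every λ-factor in the likelihood pairs with a
$(1-E)$ factor into $\lambda_p$. Two consequences matter. First, the
constant-rate closed form used as an independent oracle
(`bd_constant_log_likelihood()`, built on the classical $p_0/p_1$
functions) must and does use the same convention. Second, congruent rate
trajectories (below) give *equal* conditioned likelihoods; with a root
λ-factor convention they would not, which is how the convention was fixed.

## The HSMRF prior and the global-scale calibration

Log-rate trajectories get a horseshoe Markov random field prior:

$$x_1 \sim \mathrm{N}(m_0, 1), \qquad
  \delta_i = x_{i+1} - x_i \sim \mathrm{N}(0,\; \zeta \, G \, \gamma_i),
  \qquad \gamma_i \sim \mathrm{C}^+(0,1), \quad G \sim \mathrm{C}^+(0,1),$$

with independent copies (same $\zeta$) for $\log\lambda$ and $\log\mu$. The
per-increment half-Cauchy local scales $\gamma_i$ allow rare large jumps
amid near-constancy; the shared half-Cauchy factor $G$ lets the whole
trajectory's variability adapt; the fixed global scale $\zeta$ controls how
much total change the prior expects. $m_0$ is the log of a Kendall–Moran
style starting estimate ($(n-2)/\text{tree length}$); the prior SD of 1 on
the first log rate is a broad default.

**Effective shifts.** `calibrate_zeta()` chooses $\zeta$ so that the prior
expected number of *effective shifts* equals a target (default $\log 2$,
which corresponds to a 50% prior probability of at least one shift under a
Poisson count). An effective shift is counted along the cumulative
trajectory: scanning from the present, a shift registers each time the rate
attains a twofold change (threshold $\log 2$ on the log scale; the shift
size is configurable) relative to its level at the previously registered
shift, at which point the reference level moves to the current rate. This
cumulative definition — rather than counting single-increment exceedances —
reflects that a rate shift spread over a few adjacent intervals is still
one shift; empirically it is also the counting under which the calibration
reproduces published global-scale values across grid sizes from roughly
100 to 400 intervals, which per-increment counting does not (it
mis-scales with grid size).

**Numerics.** The expected count has no closed form; it is estimated by
Monte Carlo (default $2 \times 10^5$ trajectories). The shared global
factor dominates the estimator variance, so it is stratified — one
deterministic quantile draw per trajectory, $G_j = \tan(\pi (j-1/2)/(2R))$
— while local scales and increments stay pseudo-random; this cuts the
seed-to-seed scatter of the calibrated $\zeta$ to a few tenths of a
percent. Root-finding runs in two stages: bracketed `uniroot` on
$\log\zeta$ with a tenth of the sample (common random numbers make the
objective deterministic and monotone), then a log–log secant refinement
with the full sample, exploiting that the count is locally a power law in
$\zeta$ (elasticity near 0.85).

## MCMC for the episodic model

`run_ebd_mcmc()` parameterizes each trajectory by its first log rate plus
the increment vector. Per generation it applies: a random-walk update of
each first rate (which slides the whole trajectory), an elliptical slice
sampling update of each increment vector (exact with respect to the
Gaussian prior given the scales, likelihood-only slice, no tuning
parameters — the natural choice for shrinkage priors whose tiny increment
scales defeat plain random walks), Metropolis updates of every local scale
in parallel (prior-only conditionals), and a Metropolis update of each
global factor. Random-walk proposal scales adapt toward 44% acceptance
only during the pre-burn-in; they are frozen afterwards so the recorded
chain is a valid Markov chain. With the likelihood switched off
(`likelihood = "none"`) the sampler targets the prior exactly — the test
suite verifies that prior-only runs reproduce the effective-shift count
the $\zeta$ calibration promised, closing the loop between the two code
paths.

Two independent runs are the default. `check_convergence()` compares runs
parameter-by-parameter with the two-sample Kolmogorov–Smirnov statistic
against the critical value at precision $\alpha = 0.015$, substituting
effective sample sizes (Geyer initial monotone sequence estimator) for raw
counts; parameters with ESS below a floor are reported inconclusive rather
than passed. `summarize_rates()` removes 25% of the combined runs as
burn-in by default and reports per-interval posterior medians with central
95% intervals, optionally truncated to a recent window (default use case:
193 My) so trees with different root ages are compared on a common
timescale, plus the grand median across retained intervals.

## Congruence classes

Birth–death models are not identifiable from extant-timetree data: all
$(\lambda, \mu)$ pairs sharing the pulled diversification rate

$$r_p(t) = \lambda(t) - \mu(t) + \frac{1}{\lambda(t)}
  \frac{d\lambda}{dt}$$

(time increasing toward the past) and the present-day product $\rho\,
\lambda(0)$ have identical reconstructed-tree likelihoods. The package
works with the discrete analogue on the grid: the derivative is the
one-sided difference toward the past, which makes the constant-rate case
exact ($r_p = \lambda - \mu$) and makes the congruence map — solving
$\lambda^*$ for a proposed $\mu^*$, anchored at the reference's present-day
speciation — the *exact inverse* of the $r_p$ definition, so pulled rates
of constructed partners match to machine precision by construction. The
oldest interval carries a zero-derivative convention (its $r_p$ entry is
reported but unconstrained by the map).

Piecewise-constant representatives of a congruence class approach exact
likelihood equality only as the grid is refined: the exact continuous
partner for a piecewise reference is not itself piecewise constant. The
construction therefore refines the reference grid internally (refinement
leaves the reference model, hence its likelihood, bit-for-bit unchanged)
and builds the partner on the sub-grid. The measured likelihood
discrepancy falls roughly as 1/refinement; at a refinement factor of
$10^5$ it is below $10^{-6}$ for the ~100-tip trees used in the tests,
which is the tolerance the congruence checks assert. Because members on
such grids are large, `sample_congruent_set()` accepts a `member_fn`
callback that evaluates and discards each member, keeping memory flat.

The four named scenarios pin the partner's free rate to the reference
time-average (constant-μ, constant-λ) or to an exponential anchored at the
reference's present-day value; exponential exponents default to the
least-squares fit of the reference's own log-rate trend, since no other
anchoring is implied by the scenario names. A member is outside the
congruence class exactly when its constructed partner rate goes negative
anywhere; negative values are clamped to zero only to keep the returned
object constructible, and the member is flagged invalid. Trend
summarization labels interval-to-interval changes in net diversification
as increase/decrease/flat against a reference-specific threshold of twice
the mean absolute change in λ between adjacent intervals, and reports
per-transition agreement of members with the reference. The joint sampler
perturbs log extinction with three components — a level shift (scale
$\beta_1 = 0.5$), a linear trend (scale $\beta_2 = 0.2$), and a random
walk of total scale $\sigma_{MRF} = 1$ — and solves the congruent
speciation partner, rejecting invalid draws.

## Branch-specific shifts (BDS)

Speciation rates take one of $k = 6$ categories — the quantile-bin medians
(quantiles $(i - 1/2)/k$) of a lognormal whose mean has a log-uniform
$(10^{-6}, 10^2)$ prior and whose SD has an exponential(1.7) prior;
extinction is one shared rate with a log-uniform prior; category switches
arrive at rate $\eta$ per lineage per My, uniformly to the other $k - 1$
categories, with the expected number of shifts across the tree uniform on
$(0, 100)$ and mapped to $\eta$ by dividing by the observed tree length.
The likelihood integrates, per branch, the coupled $E$/$D$ ODE system over
the $k$ categories (adaptive Cash–Karp RK45; default relative tolerance
$10^{-8}$, absolute $10^{-10}$, relaxed one decade inside MCMC loops where
thousands of evaluations amortize the error budget), with root categories
marginalized under equal weights and survival conditioning as in the EBD
convention. For $k = 1$ this collapses to the constant-rate closed form (a
tested 1e-6 agreement), and the likelihood is invariant to category
permutation and continuous in $\eta$ at zero.

Stochastic branch-category maps are drawn backward–forward: the pruning
pass also integrates each branch's fundamental matrix $\Phi$ (the linear
propagator of the $D$ system) and the no-switch stay weights
$\exp\int A_{ss}\,dt$; node states are then sampled root-to-tips from the
exact conditional distributions, the presence of at least one switch on a
branch uses the exact no-switch probability $\text{stay}_s/\Phi_{ss}$, and
*within-branch* event times and intermediate states are filled in by an
endpoint-conditioned homogeneous CTMC bridge (uniformization). The bridge
ignores the diversification-rate weighting inside a single branch; node
states and shift presence/absence — the quantities that drive shift
detection — are exact, while branch-mean rates on the rare multi-switch
branches are approximate. A shift is recorded on a branch when the
posterior probability of at least one switch event strictly exceeds 0.5;
its magnitude is the multiplier — posterior-mean speciation on the branch
over that on its parent branch — and its timing is reported at the branch
midpoint, since finer event-time resolution is not retained. Root branches
have no parent and are excluded. Group comparisons log-transform the
multipliers, check per-group normality (Shapiro–Wilk), and run one-way
ANOVA, reporting the ratio of group geometric means.

## Hidden-state SSE (HiSSE-2)

The benthic/nonbenthic analysis uses four combined states (0A, 1A, 0B,
1B): observed feeding mode crossed with a two-level hidden background.
Transitions flip one factor at a time — a single symmetric observed-flip
rate and a single symmetric hidden-flip rate (two free parameters; only
the expected total of 50 transitions across the tree is externally
specified, split evenly between the two flip types and converted to rate
priors via tree length as exponential means). Dual transitions are
structurally zero. Speciation and extinction rates get normal priors *on
the log scale* with mean $\log(\ln(n/2)/\text{root age})$ — the natural
positive-rate reading of a normal rate prior; a natural-scale normal would
put mass on negative rates — and SD 1. The root prior is equal probability
across the four combined states. In the extinction-floor variant, $\mu_s =
0.5\,\lambda_s + \delta_s$ with $\delta_s \ge 0$ sampled on the log scale
under an exponential prior, so every posterior sample satisfies the floor
by construction. The likelihood is standard SSE pruning over the four
states with the same ODE core, tip partials $\rho$ times the observed-state
indicator marginalized over hidden states (ambiguous tips allowed), and
the same survival-conditioning convention; with all rates equal it
collapses to the constant-rate closed form, and with hidden-state rates
tied it matches an independently coded two-state (BiSSE-style) oracle.

The fold-change statistic $T_{ab}$ is the fraction of retained posterior
generations (after removing the first 10% as burn-in) in which net
diversification of observed state 1 exceeds $a$ times that of state 0
within hidden state $b$ — a posterior probability of an $a$-fold benthic
advantage given the hidden background. States-through-time summaries
average, per 1-My interval, each map's share of lineage-time per combined
state among lineages alive in the interval; ancestral states are empirical
node-state frequencies across maps.

Hidden states are exchangeable a priori, so their labels are not
identified; analyses that need an identified contrast (e.g. the recovery
experiment below) order the hidden states per posterior sample by their
mean net diversification and work with the sorted contrast.

## The simulators

All three generators share one forward Gillespie core: lineages carry a
discrete state; speciation, extinction, and anagenetic state changes
compete; extinct subtrees are pruned; extant tips are kept independently
with probability $\rho$ (uniform-at-present sampling, matching the
likelihood's assumption); and by default simulation repeats until at least
two sampled tips survive — the event the likelihoods condition on. The
reconstructed tree is rebuilt with per-branch truth (time-weighted mean
speciation rate, state-change counts) aggregated along collapsed paths, so
recovery experiments can interrogate exactly what the inference should
find. A lineage cap (default 50,000) refuses runaway supercritical runs,
and the episodic generator refuses up front when the deterministic
expectation $2 e^{\int r}$ already exceeds the cap.

What the generators deliberately do not emulate: diversified or clustered
(non-uniform) taxon sampling, extinct/fossil tips, measurement error in
branch lengths, and cladogenetic (at-speciation) state change. Passing
recovery tests therefore speak to model-consistent data; they do not
certify behaviour under sampling biases or tree-estimation error.

## Recovery experiments and problem sizes

The acceptance suite runs three scaled-down recovery experiments chosen to
fit a single CPU: (1) episodic model, 20 replicate trees of 200–500 tips
simulated with a twofold speciation step at mid-depth (0.2 young / 0.1
old, root age 34 My), 50,000-generation chains, success = posterior median
λ higher in the young than the old epoch, required in at least 18
replicates; (2) branch-shift model, 20 replicates with a single 10×
speciation shift on an internal branch subtending at least 8 tips
(100–450-tip trees), success = the true branch attains the highest shift
posterior probability, required in at least 15; (3) HiSSE-2, 20 replicates
of 150–450-tip trees with a threefold hidden-state speciation asymmetry,
success = posterior median sorted hidden contrast exceeding half the true
contrast ($\lambda_A = 0.1$, so threshold 0.1 lineages/My — fixed a priori
as half the simulated effect), required in at least 15. A companion
false-positive check fits the shift model to 20 shiftless simulations and
requires at most 5% of branches flagged at PP > 0.5.

## Known limitations

Within-branch histories of stochastic maps use a homogeneous bridge
(above). The congruence map's likelihood equality is exact only in the
fine-grid limit, with the measured ~1/refinement error documented above.
The episodic sampler's elliptical slice updates act on each trajectory
separately; strongly correlated λ/μ posteriors (they are only jointly
weakly identified) mix more slowly than a joint sampler would. The
calibration's effective-shift semantics, while validated against
published values across 100–400-interval grids, is a reconstruction of a
convention, not a closed-form derivation; its Monte Carlo nature leaves
a few tenths of a percent of seed dependence in $\zeta$. The habitat
resolver treats species missing habitat data as excluded, the strictest
defensible reading of the classification rules.
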