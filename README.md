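# divpace

Habitat-scale analyses of how fast lineages on a time-calibrated phylogeny
have diversified through time, built for ultrametric trees of extant
species with incomplete, uniform-at-present taxon sampling. The package
targets questions of the form *"did net diversification of this group of
fishes (or any clade) accelerate, and when, and is that signal robust?"*
and answers them with four coordinated model families:

1. **Episodic birth–death (EBD) with horseshoe Markov random field
   priors.** Speciation λ(t) and extinction μ(t) are piecewise constant on
   a 1-My grid; log-rate increments get the hierarchical horseshoe prior
   δᵢ ~ N(0, ζ·G·γᵢ) with half-Cauchy local scales γᵢ and global factor G,
   so rates stay near-constant except where the data demand a jump. The
   fixed global scale ζ is calibrated (`calibrate_zeta()`) so the prior
   expects log(2) effective twofold shifts along the trajectory. Net
   diversification is r = λ − μ.
2. **Congruence-class robustness checks.** All (λ, μ) pairs sharing the
   pulled diversification rate r_p = λ − μ + λ′/λ (and the present-day
   ρ·λ(0)) are likelihood-indistinguishable; the package constructs
   congruent partners for named scenarios (constant μ, exponentially
   increasing μ, constant λ, exponentially decreasing λ), samples whole
   congruent sets, flags members that leave the class (negative rates),
   and summarizes which rate trends survive across the class.
3. **Branch-specific birth–death-shift (BDS) detection.** Speciation takes
   one of k = 6 discretized-lognormal categories with Poisson category
   switches along branches; stochastic branch-category maps give per-branch
   shift posterior probabilities, shift multipliers (branch rate over
   parent-branch rate), and ANOVA comparisons of shift magnitude between
   groups.
4. **Hidden-state state-dependent diversification (HiSSE-2)** for binary
   traits such as benthic vs nonbenthic feeding, with two hidden background
   states, stochastic character maps, ancestral states, states-through-time
   summaries, and the posterior fold-change statistic T_ab — the posterior
   probability that state-1 net diversification exceeds a-fold state-0 net
   diversification within hidden state b.

Forward simulators for all three model families (plus habitat and
feeding-mode trait-table utilities and a configuration-driven pipeline)
make every stage testable end-to-end on synthetic data with known truth.

## Worked example

Simulate a tree whose speciation rate doubles toward the present (0.12 →
0.24 lineages/My at 8 Ma, μ = 0.04, 60% of species sampled), then re-infer
the rate trajectory:

```r
library(divpace)

truth <- rate_trajectory(time_grid(20), c(rep(0.24, 8), rep(0.12, 12)), 0.04)
sim   <- simulate_ebd_tree(truth, root_age = 20, rho = 0.6, seed = 19)
length(sim$phy$tip.label)
#> [1] 42

zeta <- calibrate_zeta(n_intervals = 20, seed = 1)
zeta
#> [1] 0.01375297

traces <- run_ebd_mcmc(sim$phy, time_grid(20), zeta, rho = 0.6,
                       settings = mcmc_settings(generations = 20000,
                                                thin = 10,
                                                pre_burn_in = 2000,
                                                seed = 1))
check_convergence(traces, burn_in_fraction = 0.25)
#> convergence at alpha = 0.015: PASS (40/42 parameters pass)

s <- summarize_rates(combine_traces(traces))
round(s$grand_median, 4)
#> lambda     mu      r
#> 0.2798 0.0957 0.1745
```

`zeta` is the global-scale hyperprior for a 20-interval grid: small,
because with log(2) expected twofold shifts the prior keeps the trajectory
nearly flat unless the tree argues otherwise. The grand medians are the
across-interval medians of the per-interval posterior medians — here λ is
estimated near the (sampling-weighted) truth and r ≈ 0.17/My. On a tree
this small the shrinkage prior flattens the twofold step (posterior median
λ is 0.284 averaged over the young intervals vs 0.274 over the old); the
direction survives, and the package's acceptance experiments show the step
is recovered reliably at 200–500 tips. Congruence checks then ask whether
such a trend could be an artifact of λ/μ non-identifiability:

```r
ref <- rate_trajectory(time_grid(20), s$intervals$lambda_median,
                       s$intervals$mu_median)
scenario_test(ref, "constant-mu")$valid
#> [1] TRUE
```

meaning a constant-extinction explanation stays inside the congruence
class for this trajectory (its congruent λ* stays nonnegative), so the
inferred speciation trend — not a claim about extinction — is the robust
statement.

The same pattern applies to the other stages: `run_bds_mcmc()` +
`detect_shifts()` + `compare_shift_groups()` for branch-specific shifts,
and `run_hisse_mcmc()` + `t_statistic()` + `states_through_time()` for
state-dependent diversification. `run_pipeline()` chains the stages from a
flat key = value config file, and `inst/cli/divpace.R` exposes each stage
as a shell subcommand. See the methods vignette
(`vignettes/divpace-methods.Rmd`) for the models, priors, conventions and
numerical choices.

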