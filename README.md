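# geodisp

Bayesian inference of pathogen dispersal among discrete geographic areas
over a fixed, time-calibrated phylogeny — with explicit, comparable control
over the priors that drive it.

## The problem

Discrete-geographic phylodynamic models infer where an outbreak started,
which dispersal routes connected areas, and how many dispersal events
occurred — from minimal data: the single area in which each sampled
pathogen was collected. Dispersal among `k` areas is a continuous-time
Markov chain along the tree with rate matrix entries

```
q_ij = r_ij * delta_ij
```

where `r_ij` is a relative rate and `delta_ij` a binary indicator that
switches the route between areas `i` and `j` on or off (BSSVS). `Q` is
rescaled so the expected number of dispersal events per unit time is the
average dispersal rate `mu`; over a tree of length `T` the expected event
count is `mu * T`.

Because the data are so thin, the priors matter enormously. The historical
defaults — an offset Poisson on the number of routes concentrated at the
irreducible minimum `k - 1`, and `mu ~ Gamma(0.5, T)`, which expects 0.5
dispersal events in total with 95% interval [0, 3] *regardless of `T` or
`k`* — encode strong, biologically peculiar beliefs. `geodisp` implements
those defaults alongside diffuse alternatives (a Poisson centred at half
the maximum number of routes; a hierarchical exponential prior on `mu`
whose marginal is the K-distribution), plus the full comparison toolkit:
MCMC, stepping-stone marginal likelihoods and `2lnBF`, per-route inclusion
Bayes factors, stochastic mapping of dispersal histories (ancestral areas,
event counts), and posterior-predictive adequacy checks. A synthetic-data
module generates trees, true processes, and tip data with known ground
truth so the whole pipeline is testable end to end.

Intended users: phylodynamics / phylogeography researchers who want to
measure — rather than inherit — the influence of these priors.

## Worked example

Simulate a route-rich 30-tip, 5-area dataset with known truth, fit the
alternative-prior model, and summarize:

```r
library(geodisp)
sc  <- simulation_scenario("demo", n_tips = 30, k = 5,
                           route_density = "dense", events_target = 25,
                           seed = 7)
sim <- simulate_scenario(sc)
#> T = 26.08, true mu = 0.959, true Delta = 10, true events = 25

prior <- resolve_prior_config(k = 5, T = sim$T, symmetric = TRUE,
                              routes_prior = "alternative",
                              rate_prior = "alternative")
fit <- run_mcmc(sim$tree, sim$data, prior,
                mcmc_settings(n_iter = 8000, burnin = 0.25, thin = 2,
                              seed = 42))
mean(fit$mu); quantile(fit$mu, c(.025, .975))
#> posterior mean mu = 1.601, 95% CI 0.572 - 4.18   (covers the truth 0.959)

head(route_bayes_factors(fit, areas = sim$data$areas), 3)
#>     from     to prior_p post_p   bf two_ln_bf category bounded
#> 1 area_1 area_2     0.5  0.786 3.68      2.61 positive   FALSE
#> 2 area_2 area_5     0.5  0.753 3.05      2.23 positive   FALSE
#> 3 area_4 area_5     0.5  0.713 2.48      1.82     none   FALSE

hs <- posterior_histories(sim$tree, sim$data, fit, max_histories = 200)
count_dispersal_events(hs)$source_pct
#>     area mean_pct lower upper
#> 1 area_1    24.50     0  63.0
#> 2 area_2    24.41     0  57.4
#> 3 area_3     5.67     0  29.1
#> 4 area_4    15.37     0  50.0
#> 5 area_5    30.05     0  64.3

posterior_predictive_check(sim$tree, sim$data, fit, n_sim = 150)$parsimony
#> parsimony: observed 14, tails (0.707, 0.420), p = 0.840
```

Reading the output: the route table gives, per dispersal route, the prior
and posterior probability that the route exists and the resulting
`2lnBF` with its Kass–Raftery category (positive/strong/decisive above
2/6/10). The source table is the posterior percentage of all dispersal
events originating from each area, with 95% credible intervals across
conditional histories. The adequacy report compares the observed Fitch
parsimony score against its posterior-predictive distribution; `p = 0.84`
means the fitted model reproduces data like the observed data comfortably.

`run_full_analysis()` chains all of these (plus optional stepping-stone
model comparison) for a list of candidate prior models and writes CSV
tables, an annotated newick with per-node ancestral-area probabilities,
and a JSON manifest. `prior_audit()` tabulates the prior pmfs of the
route count, the route-inclusion probability as a function of `k`, and the
implied event-count distribution — the machine-readable form of the
prior-comparison figures.

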