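---
title: "Discrete-geographic dispersal models and their priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-geographic dispersal models and their priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geodisp)
```

## The model

A pathogen (or any dispersing lineage) is sampled in one of $k$ discrete
geographic areas at each tip of a fixed, time-calibrated phylogeny $\Psi$.
Dispersal among areas along the branches is a continuous-time Markov chain
with instantaneous-rate matrix $Q$, whose off-diagonal entries are

$$q_{ij} = r_{ij}\,\delta_{ij},$$

where $r_{ij} > 0$ is the relative dispersal rate between areas $i$ and $j$
and $\delta_{ij} \in \{0, 1\}$ is an indicator that switches the dispersal
route on or off (Bayesian stochastic search variable selection, BSSVS).
A *symmetric* model ties $q_{ij} = q_{ji}$ and has $K = \binom{k}{2}$
candidate routes; an *asymmetric* model frees the two directions and has
$K = k(k-1)$. The matrix is rescaled so that the expected number of
dispersal events per unit time equals the average dispersal rate $\mu$:
with uniform area weights,

$$\frac{1}{k} \sum_{i \ne j} q_{ij} = \mu .$$

We use fixed uniform weights rather than the stationary distribution of
$Q$ because reducible configurations (which the asymmetric prior permits)
have no unique stationary distribution; uniform weighting keeps the
rescaling well defined for every configuration, and the convention is held
fixed across every module (likelihood, simulation, stochastic mapping).
Over a tree of total branch length $T$ (`tree_length()`), the expected
number of dispersal events is $\mu T$.

The likelihood $P(G \mid Q, \Psi)$ of the observed tip areas $G$ is
computed by Felsenstein pruning with per-node rescaling
(`pruning_log_likelihood()`). Root frequencies default to uniform $1/k$ —
the common discrete-phylogeography choice; they are configurable in every
function that needs them. A tip pattern with probability zero (e.g. an
area unreachable under a reducible $Q$) yields $-\infty$ rather than an
error so that Metropolis–Hastings rejection handles such proposals.
Transition probabilities $P(t) = e^{Qt}$ use a symmetric eigendecomposition
when $Q$ is symmetric, a general eigendecomposition when it is well
conditioned, and Padé scaling-and-squaring otherwise; rows are clamped and
renormalized at the $10^{-12}$ level.

## Priors on the number of dispersal routes

The route-number prior acts on $\Delta = \sum \delta_{ij}$, with all
(irreducible, for symmetric models) configurations of a given $\Delta$
equiprobable:

* **default, symmetric** — offset Poisson,
  $\Delta - (k-1) \sim \text{Poisson}(\ln 2)$: a strong preference for the
  minimal irreducible model. Configurations with $\Delta < k - 1$ routes,
  or whose route graph is not connected, have prior probability zero.
* **alternative, symmetric** — offset Poisson with
  $\lambda = K/2 - (k-1)$, so the expected $\Delta$ is about half the
  maximum $K$. For $k \le 4$ this $\lambda$ would be $\le \ln 2$ (at
  $k = 4$ exactly 0), so it is floored at $\ln 2$; consequently the two
  symmetric prior models coincide for $k \le 4$, and prior-contrast
  experiments in this package use $k \ge 5$.
* **default, asymmetric** — $\Delta \sim \text{Poisson}(k - 1)$, no offset
  and no irreducibility constraint.
* **alternative, asymmetric** — $\Delta \sim \text{Poisson}(K/2)$ with
  $K = k(k-1)$.

Because $\Delta$ is bounded by $K$ (and below by $k-1$ for symmetric
models), the Poisson is renormalized over the attainable range. This
renormalization is what makes the configuration prior sum to one — a
property the test suite verifies by exhaustive enumeration of all $2^K$
configurations for small $k$. Some legacy implementations instead give
every configuration an unnormalized Poisson weight
$e^{-\lambda}\lambda^{\Delta-\text{offset}}/(\Delta-\text{offset})!$ and
normalize over configurations, which induces a slightly different marginal
on $\Delta$ (it multiplies in the configuration counts); both styles are
available through `delta_prior_style` in `resolve_prior_config()`, with
the per-$\Delta$ style as the package default because it is the direct
reading of "a prior on $\Delta$ plus equiprobability given $\Delta$".

Counting the irreducible configurations with a given $\Delta$ — the number
of connected labelled graphs on $k$ vertices with $\Delta$ edges — uses the
standard inclusion–exclusion recurrence over the component containing
vertex 1 (`count_configurations()`). The recurrence is exact at all sizes
in scope and is validated against exhaustive enumeration for $k \le 5$.

The induced prior probability that any given route exists,
$P(\delta_{ij} = 1) = \sum_\Delta p(\Delta)\,\Delta/K$ (by exchangeability
of routes), drops rapidly with $k$ under the default prior and stays near
$1/2$ under the alternative — the mechanism by which the default prior
inflates route-specific Bayes factors. `prior_audit()` tabulates these
curves, the $\Delta$ pmfs, and the event-count pmfs as data frames.

## Priors on the average dispersal rate

* **default** — $\mu \sim \text{Gamma}(0.5,\, \beta = T)$, prior mean
  $0.5/T$. Mixing with $N \mid \mu \sim \text{Poisson}(\mu T)$ gives a
  negative binomial marginal on the total event count with size $0.5$ and
  success probability $1/2$ — *independent of $T$*: the prior expects
  $0.5$ dispersal events with 95% interval $[0, 3]$ no matter how long
  the history is or how many areas are sampled. Since realizing $k$ areas
  requires at least $k - 1$ events, this becomes increasingly unrealistic
  as $k$ grows; that observation motivates the alternative.
* **alternative** — $\mu \mid m \sim \text{Exponential}(\text{mean } m)$
  with $m \sim \text{Gamma}(0.5, 0.5)$. Marginally $\mu$ follows the
  K-distribution; we keep the hyper-mean $m$ as an explicit latent
  parameter so that MCMC needs no Bessel-function density, and verify the
  marginal by simulation ($E[\mu] = E[m] = 1$ by total expectation).
  The implied event-count prior now scales sensibly with $T$
  ($E[N] = T$ for these hyperparameters); its pmf is computed by
  quadrature over $m$ (the inner $\mu$ integral is geometric in closed
  form).

Relative rates $r_{ij}$ are i.i.d. Exponential(1) by default (a
configurable gamma), the standard discrete-phylogeography choice; the main
sources never pin this down, so it is explicit in `resolve_prior_config()`.

## MCMC

`run_mcmc()` targets $\text{prior} \times \text{likelihood}^\beta$ with
$\beta \in [0, 1]$: the posterior at $\beta = 1$, the prior at $\beta = 0$,
and power posteriors in between for stepping-stone estimation. Moves:
log-scale multipliers on $\mu$, on single relative rates, and on $m$;
single-indicator flips on $\delta$ (irreducibility violations auto-reject
through their $-\infty$ prior); and a paired flip exchanging an open and a
closed route, which preserves $\Delta$ and improves mixing across
equal-$\Delta$ models. Multiplier windows adapt towards ~35% acceptance
during burn-in and are frozen afterwards so the inference portion of the
chain is Markovian. Initialization is the all-routes-open configuration
(always irreducible), unit rates, and a prior draw for $\mu$ — a
guaranteed-finite starting density. Chains are reproducible bit-for-bit
given a seed. Effective sample sizes use Geyer's initial-positive-sequence
truncation of the autocorrelation function.

## Marginal likelihoods and Bayes factors

`run_power_posterior()` runs an independent chain at each of
`n_stones` powers on a Beta(0.3, 1)-quantile ladder (stones concentrated
near $\beta = 0$, where the integrand changes fastest), and
`stepping_stone_log_marginal()` combines adjacent stones with
log-sum-exp stabilization; standard errors come from per-stone batch
means. Stepping stone is the sole estimator by design — it is robust where
harmonic-mean style estimators are not. Model comparison reports
$2\ln\text{BF}$, and per-route support uses the posterior-vs-prior odds
ratio of route inclusion with Kass–Raftery categories (positive/strong/
decisive at 2, 6, 10). Posterior inclusion frequencies of exactly 0 or 1
are bounded at the MCMC resolution $1/(N+1)$ and flagged rather than
reported as infinite.

## Conditional histories

`sample_conditional_history()` draws a realized, timed dispersal history
consistent with the tips: a pruning down-pass, joint node-state sampling
root-to-tips, then endpoint-conditioned path sampling on each branch by
uniformization (dominating rate $\max_i |q_{ii}|$; the jump count is drawn
from its exact conditional by series inversion, virtual jumps are
discarded). A forward rejection sampler is retained purely as a test
oracle. Posterior summaries draw one history per retained MCMC sample
(`posterior_histories()`) — unbiased at minimal cost. Ancestral-area
tables, MAP areas, per-pair event counts, and per-source percentages with
credible intervals follow directly; because the input tree is fixed, the
shared-node bookkeeping when comparing two analyses (`compare_ancestral_maps()`,
the fractions $p$ and $f$) reduces to same-tree comparison, and both
fractions are still reported.

## Adequacy checks

`posterior_predictive_check()` simulates replicate tip datasets forward
under retained posterior draws and compares two pluggable statistics
against their predictive distributions: the Fitch parsimony score (minimum
events needed to explain the tips) and the tip-wise multinomial statistic
$\sum_a n_a \ln(n_a/n)$. These are a standard discrete-character adequacy
pair chosen here as defaults — not an attempt to reproduce any particular
published statistic set. Two-sided p-values double the smaller tail, so
adequacy can fail in either direction.

## Synthetic data

The generator is first-class, tested code. `simulate_tree()` produces
Yule trees (grown forward from two lineages; while $j$ lineages are alive
the next split waits $\text{Exp}(j\lambda)$, and a final
$\text{Exp}(n\lambda)$ interval follows the last split so pendant branches
have positive length — for $n = 2$, $E[T] = 1/\lambda$) or coalescent
trees via `ape::rcoal` scaled by population size.
`simulate_history_and_tips()` is exact Gillespie simulation of the CTMC
down the tree, returning both the tip data and the full ground-truth event
history so that stochastic mapping can be validated event-for-event. The
forward simulator doubles as its own likelihood check: simulated node-state
marginals are tested against $e^{Qt}$ propagation.

`make_benchmark_suite()` writes six plain-text fixture scenarios spanning
$k \in \{3, 5, 8\}$, 20–50 tips, sparse (spanning-tree, $\Delta = k-1$)
versus dense (complete, $\Delta = K$) true route sets, and low versus high
event budgets ($\mu T = k$ or $4k$) — the empirically common ranges at
reduced scale. Sparse truths sit below and dense truths above the default
prior mean $k - 1 + \ln 2$ by construction, so prior-contrast experiments
on the fixtures are informative.

## Numerical choices and test scale

Tolerances: matrix exponentials are renormalized at $10^{-12}$; pruning is
verified against exhaustive state enumeration at $10^{-10}$; the
uniformization series is truncated once its cumulative mass reaches the
sampled quantile (cap at a 12-standard-deviation Poisson tail). Event-count
pmfs truncate at `n_max` with the tail checked in tests. Problem sizes in
the test suite — e.g. $10^5$ prior-MCMC samples for the $\Delta$
calibration, 16 stones with 6000-iteration chains for the stepping-stone
check, 20 replicates of 50-tip, 5-area datasets for interval calibration —
were chosen as the smallest sizes at which the Monte-Carlo error bands in
the corresponding checks are meaningful; they are the package's own
validation conditions, and the same machinery scales to larger runs by
changing `mcmc_settings()`.

Simulation-based calibration of the $\mu$ credible intervals draws the
*truth from the fitted prior* (so nominal coverage is exact by
construction) rather than fixing one truth; with 20 replicates the
17–20/20 acceptance band has ~98% power under correct coverage.

## What passing tests do and do not show

The synthetic generator emulates the structure of empirical datasets —
fixed time trees, one sampled area per tip, CTMC dispersal — but not their
complications: no phylogenetic uncertainty (the tree is known by design),
no sampling bias across areas, no rate variation among branches, and no
model misspecification beyond the prior contrasts themselves. Green tests
therefore certify the machinery (likelihood, priors, samplers, estimators)
and the *direction* of prior-induced distortions, not the magnitude of
those distortions in any particular empirical system.

## Known limitations

Polytomies are accepted by the likelihood but not by the Fitch statistic
(binary trees only); route priors do not admit covariates (no GLM
parameterization of $Q$); event counts are sampling-based (no analytic
expected Markov-jump counts); and the asymmetric model's general
eigendecomposition falls back to Padé exponentials, which is noticeably
slower for large $k$.
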