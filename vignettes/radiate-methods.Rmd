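---
title: "Models and methods in radiate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in radiate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiate)
```

`radiate` implements the comparative toolkit needed to confront a dated
phylogeny and species trait data with the predictions of adaptive-radiation
theory: did lineage diversification start fast and slow down, does the focal
clade speciate faster than its sister clade, did phenotypic evolution burst
early and then decelerate, and did phenotypes diverge toward distinct optima
in distinct ecological niches while filling a wider region of ecospace?
This vignette records the models, the numerical choices, and the design
decisions behind each stage, in the spirit of the long-form methods
vignettes of packages like `vegan` or `DESeq2`.

Throughout, time is *age*: My before present, 0 at the present and
increasing into the past. All rates are per lineage per My, and body mass is
analysed on the natural-log gram scale.

## Dated trees

A `dated_tree` is an `ape` phylogeny that has passed validation: rooted,
strictly binary (polytomies are rejected with instructions to resolve them
upstream, because every likelihood below assumes binary branching), branch
lengths present and non-negative, and ultrametric up to a relative tolerance
of `1e-6` of the crown age. Tips that miss the present by less than the
tolerance — in practice, recently extinct species whose last records are
centuries old on a 50-My tree — are snapped to age 0, which mirrors the
convention of treating subfossil species as extant in diversification
analyses. Larger deviations are an error rather than a silent repair:
non-ultrametric inputs usually indicate unpruned fossils or unit mistakes,
and a comparative analysis should not guess.

## Birth--death diversification models

### Likelihood

The reconstructed tree of an ultrametric phylogeny with branching times
$t_1 > t_2 > \dots > t_{n-1}$ (crown age $t_1$) is modelled as a birth--death
process with speciation rate $\lambda(t)$, extinction rate $\mu(t)$ and
sampling fraction $\rho$ applied at the present. Two functions of age carry
the whole computation:

* $F(t)$, the probability that a lineage alive at age $t$ leaves at least
  one sampled descendant, solving
  $F' = (\lambda-\mu)F - \lambda F^2$, $F(0)=\rho$;
* $Q(t)$, the density of a lineage at age $t$ producing exactly the single
  observed reconstructed lineage, which obeys the identity
  $Q(t) = F(t)^2 e^{-\int_0^t(\lambda-\mu)}/\rho$.

Conditioning on the crown age and on survival of both crown lineages, the
log-likelihood is
$$
\log L \;=\; \sum_{i=2}^{n-1}\bigl[\log\lambda(t_i) + \log Q(t_i)\bigr]
\;+\; 2\log Q(t_1) \;-\; 2\log F(t_1).
$$
For constant rates $F$ is logistic and the expression reduces to the
classical closed-form likelihood with sampling (the tests verify agreement
with the textbook $p_0/p_1$ formulas to $10^{-8}$); for time-varying rates
$F$ is integrated with `deSolve::lsoda` at tolerances `rtol = 1e-10`,
`atol = 1e-12`, and the result is verified against an independent
fine-grid Runge--Kutta oracle to $10^{-6}$.

The conditioning convention (crown age + survival of both crown lineages,
$\rho$ at the present) is fixed package-wide. It is the standard choice for
crown-clade analyses; nothing in the interface lets two fits in one
comparison disagree about it, which keeps AICc values commensurable.

### Rate functions

Speciation can be constant, linear in age ($\lambda_0 + a_\lambda t$,
clipped at zero with a likelihood penalty so optimization cannot exploit
negative rates), exponential ($\lambda_0 e^{a_\lambda t}$), or linked to an
interpolated covariate curve ($\lambda_0 e^{\beta V(t)}$ — used for
paleotemperature or competitor lineage-through-time diversity). Extinction
can be zero, constant, linear or exponential. Because the axis is age, a
*negative* slope means rates that *increase toward the present*. At
$a_\lambda = 0$ or $\beta = 0$ every non-constant form collapses exactly
onto its constant counterpart, and the tests assert these identities.

### Fitting, comparison, averaging

`fit_bd()` maximizes the likelihood with rates log-parameterized,
Nelder--Mead with relative tolerance $10^{-12}$, and 10 seeded random
multi-starts jittered around a Yule-based heuristic. AICc uses
$n_\mathrm{obs}$ = number of tips. `compare_and_average()` forms Akaike
weights $w_i \propto e^{-\Delta_i/2}$ and reports model-averaged
$\lambda$ and $\mu$ at a reference age (the weighted sum of each model's
rate function evaluated there) plus the averaged speciation slope, counting
zero for constant models. `rate_through_time()` produces (averaged) net
diversification curves.

### Mass-extinction test

`mass_extinction_test()` asks whether an instantaneous extinction pulse at
a fixed age $t_0$ (for example the Eocene--Oligocene boundary at 33.9 Ma)
improves on a constant-rate background: each lineage alive at $t_0$
survives with probability $s$, which multiplies $F$ across the event and
contributes a single factor $s$ to $Q$. The augmented model (one extra
parameter, $s$ estimated on a logit scale) is compared to the base model by
AICc; "no evidence" is declared when the base model wins or when
$\hat s$ exceeds 0.9 — an estimated survival near 1 is an absent event
regardless of a marginal AICc preference. This is a maximum-likelihood
formulation of the question; a fully Bayesian episodic-rate treatment is
outside the package's scope. On event-free synthetic trees the median
$\hat s$ is 1 and the augmented model is rejected in over 90% of
replicates; a planted pulse with $s = 0.2$ is detected in the majority.

### Adequacy

`adequacy_check()` simulates trees from the fitted model conditioned on the
empirical crown age (accepting tip counts within a factor-two window of the
observed count), computes gamma, Colless imbalance, tip count and median
internal branch length, and reports the empirical tree's two-sided quantile
for each; all quantiles inside $[0.025, 0.975]$ is "adequate". The default
of 1000 simulations matches common practice; tests use smaller counts.

## Rate-shift search with simulation calibration

`stepwise_search()` is a greedy stepwise-AICc breakpoint search. Its
likelihood decomposes edge by edge, which is what makes the search cheap:
an edge from young age $v$ to old age $u$ contributes
$\log Q(u) - \log Q(v)$ under its regime's constant rates, a non-root
internal node contributes $\log\lambda$ of the regime below it, and a tip
standing for $m$ species (unsampled diversity assigned to its genus tip)
contributes $(m-1)\log\beta(\text{stem age})$, the geometric tail of the
constant-rate taxon-count distribution — with $m = 1$ this correction
vanishes identically, which the tests assert. A shift placed on an edge
claims that edge and all descendants not already claimed by a more nested
shift; each regime is fitted independently (pure birth or birth--death,
whichever AIC prefers), and each accepted shift costs one extra parameter
for its location. Within a regime the relative extinction
$\epsilon = \mu/\lambda$ is bounded below 1: the regime left holding the
crown-conditioning term could otherwise inflate its partition likelihood
without limit by driving extinction up — a degeneracy of the partition
approximation, not signal. The per-regime independence of the survival function is
the standard partition approximation of stepwise shift searches; it trades
exactness on extinct-side dynamics for a search that is deterministic and
desk-scale.

Because stepwise searches of this kind are known to accept spurious shifts
under default thresholds, the acceptance threshold is *calibrated*:
`calibrate_threshold()` simulates single-regime trees (default 120 tips at
$\lambda = 0.15$, $\mu = 0.05$), records the best single-shift improvement
on each, and returns the maximum plus a guard epsilon of 0.01 — the
smallest threshold that rejects every shift on rate-homogeneous trees. The
tree size is a parameter so calibration can match the empirical taxon
sampling.

## Continuous-trait models

`fit_trait_model()` fits Brownian motion, Pagel's lambda, single-optimum
OU and ACDC (exponentially time-rescaled Brownian motion; a negative
exponent is an early burst) by maximum likelihood, all as multivariate
normal models whose mean and overall variance scale are profiled
analytically, leaving one shape parameter for bounded one-dimensional
optimization ($\lambda \in [0,1]$; $\alpha \in [10^{-8}, 100/T]$ on a log
scale with a bound-hit flag; ACDC exponent in $[-5/T, 5/T]$ with $T$ the
crown age — beyond those bounds the covariance is numerically
indistinguishable from its limiting case). The OU covariance defaults to
the stationary (root-at-equilibrium) form
$V_{ij} = \tfrac{\sigma^2}{2\alpha}e^{-\alpha d_{ij}}$; the fixed-root form
is exposed as an option. `acdc_rate_through_time()` converts an ACDC fit
into the implied Brownian-rate-through-time curve, the package's stand-in
for rjMCMC phenotypic rate curves, which are out of scope.

`pgls_fit()` regresses the trait on the niche category under BM, Pagel's
lambda, OU or ACDC correlation (via `nlme::gls` with `ape` correlation
structures; the correlation parameter is profiled by ML on a grid-free
`optimize`, which is robust where joint `gls` estimation of exotic
structures can fail). Niche levels use sum-to-zero contrasts, so each
coefficient is a niche's deviation from the grand mean — the natural scale
for statements like "nocturnal folivores are lighter than average".
`pgls_average()` keeps the models with $\Delta\mathrm{AICc} < 3$ and
averages coefficients with Akaike weights; the cutoff-3 candidate rule is
deliberate and fixed.

`trait_adequacy()` rescales the tree so the fitted model becomes unit-rate
Brownian motion, then compares five contrast statistics (mean squared
standardized contrast, which is $\approx 1$ under the true model;
coefficient of variation of absolute contrasts; slopes of absolute
contrasts on node age and on contrast standard deviation; and the
Kolmogorov--Smirnov distance from standard normal) between the observed
data and data simulated from the fitted model.

## Niche history and multi-regime models

`mk_asr()` fits an Mk model (equal-rates by default — one rate is the most
the data usually support for a 6-level niche on ~100 tips; symmetric rates
optional) and computes marginal ancestral-state probabilities; the tests
verify them against exhaustive enumeration over all internal-node
assignments on small trees, to $10^{-10}$. The MAP regime painting gives
every branch its parent node's MAP state with one exception: a terminal
branch whose tip state disagrees with the parent's MAP state is split at
its midpoint, so the painting both follows the ancestral reconstruction and
honours the observed tip state. Mid-branch changes otherwise occur only in
stochastic maps (`stochastic_map()`, which wraps simulation-based character
mapping and returns the same painting structure; the frequency of root
states across maps agrees with the marginal reconstruction within
Monte-Carlo error).

`fit_multiregime()` fits the state-dependent family along a painting:
single BM and OU, state-dependent Brownian rates, and state-dependent OU
with unique optima (`oum`), optima + constraints (`ouma`), optima + rates
(`oumv`), or all three (`oumva`). Moments accumulate segment by segment
along the painted branches, so covariances are exact for any painting,
including mid-branch changes. With a stationary root and one regime the
`oum` model is *identical* to the single stationary OU model — a nested
identity the tests assert at $10^{-6}$. Optima enter the mean linearly and
are profiled by GLS; one variance scale is profiled analytically; the
remaining shape parameters are optimized with warm starts chained from
simpler models plus seeded random restarts. Standard errors of the optima
come from the joint observed information over optima, shape parameters and
scale — not from the GLS covariance conditional on the shape estimates,
which understates uncertainty when $\alpha$ is itself estimated.
`multiregime_over_posterior()` repeats the model comparison across a tree
set and fresh stochastic maps and tallies the AICc-best model, the
robustness loop for topology and ancestral-state uncertainty.

A regime must paint at least two tips for the state-dependent models; the
pipeline falls back to the single-regime candidates when an ancestral-state
painting leaves a regime thinner than that.

## Ecospace

`gower_matrix()` implements the Gower coefficient for mixed data
(range-normalized absolute differences for continuous variables, 0/1
mismatches for categoricals, averaged over variables; zero-range variables
are dropped with a warning). `phylo_residual()` removes shared ancestry by
ordinary least squares of the lower-triangle trait dissimilarities on
patristic distances — patristic distance and an intercept are deliberate
choices where conventions vary, and residuals may be negative.
`nmds_embed()` shifts residuals by their minimum (a rank-preserving
transform, so the non-metric solution is unchanged) and minimizes Kruskal
stress-1 over 50 seeded random starts plus a metric-scaling start,
convergence `1e-6`. `hull_areas()` computes planar convex-hull areas
(shoelace formula) per species group and the contraction ratio
area(extant)/area(all); degenerate groups (< 3 points or collinear) get
area 0 with a flag.

## The synthetic scenario

`make_scenario()` generates the study conditions every stage is tested
against: a 120-tip, 50-My two-clade tree — an island radiation of 101 tips
simulated at $\lambda = 0.15$, $\mu = 0.05$ and a mainland sister clade of
19 tips at $\lambda = 0.08$, $\mu = 0$, joined at a 50-My crown — a
six-state diet-by-activity niche evolving under an equal-rates Mk process
at $q = 0.003$/My (roughly a dozen transitions tree-wide), and ln body mass
under regime-specific OU with optima spanning 5.0--8.5 ln g (nocturnal
niches low, diurnal high, covering ~150 g to ~5 kg), $\alpha = 0.055$/My
(phylogenetic half-life ≈ 12.6 My) and $\sigma^2 = 0.055$ (stationary
standard deviation ≈ 0.7 ln g). One species lacks body mass, the 17
largest-bodied island species carry an extinct flag, a handful of tips
stand for 2--4 unsampled congeners, a Cenozoic-like cooling curve serves as
covariate, and a "posterior" set of trees is produced by multiplicative
lognormal node-age jitter (sd 0.1) with ultrametricity re-enforced — a
cheap surrogate with the right kind of variation for robustness loops,
though not a true Bayesian posterior.

What the generator does *not* emulate matters for interpreting green
tests: empirical trees carry topological error and non-ultrametric noise;
real niches are measured with error and are not Markov on the tree; real
body mass has measurement variance and intraspecific spread; and real
posteriors vary in topology, not only node ages. Passing tests demonstrate
correctness of the estimators under the assumed generating processes, not
robustness to violations of them.

The parameter-recovery study for the state-dependent optima uses a
different, deliberately informative design: three independent clades
painted as the derived regime on a 120-tip tree, with strong constraint
($\alpha = 0.3$/My, half-life ≈ 2.3 My, stationary variance 0.5). Optima
of weakly constrained, recently derived, single-origin regimes are weakly
identified — the likelihood is nearly flat in the optimum, a structural
property of these models, and no estimator can recover them reliably.
The recovery suite therefore tests the regime where the method is meant to
operate, which is also the regime the multi-regime analysis infers when it
prefers unique-optima models.

## Problem sizes and reproducibility

Every stochastic routine takes a `seed` and restores the caller's RNG
state; child seeds are derived from one master seed, so pipelines and the
scenario bundle are byte-identical under a fixed seed. Default problem
sizes in the shipped tests and acceptance script — 100 calibration trees of
120 tips, 100 recovery replicates, 25 + 25 extinction-test replicates,
1000-tree adequacy checks scaled to hundreds in tests — were chosen as the
smallest sizes at which the Monte-Carlo assertions are stable, and the
methods are exercised at exactly the rates ($\lambda = 0.15$,
$\mu = 0.05$) and tree sizes the scenario defines.

## Known limitations

* Diversity-dependent (lineage-count-in-own-clade) diversification models,
  reversible-jump shift inference, and protracted speciation are out of
  scope; the shift search explores greedy nested configurations only and
  has no removal step.
* The shift search's partition likelihood ignores the effect of a regime
  boundary on the survival function of the neighbouring regime (the
  standard approximation of this method class).
* The Mk machinery assumes the niche alphabet is fully observed; states
  absent at the tips are not reconstructed.
* OU standard errors use the observed information at the MLE; profile
  intervals would be more accurate near parameter bounds.
* The covariate link is exponential in the covariate value; other links
  require user-supplied transformed curves.
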