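---
title: "Multilevel models for scan-sampled social behaviour: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel models for scan-sampled social behaviour: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Group-living animals differ in how much they associate, play and groom — at
the individual level (some animals are more sociable), at the dyad level
(particular pairs prefer each other) and, plausibly, at the group level
(whole groups have their own social style). Scan sampling gives clean,
point-in-time observations suited to separating these levels: at each scan
every visible individual's social state is recorded, so each dyad
contributes a binary series of "interacting / not interacting" outcomes.

`scansoc` fits a Bayesian hierarchical model to such data, decomposes the
variance in sociality across levels, estimates dyad-level covariate effects
(kinship, sex combination, age difference), and propagates the full
posterior into social networks, node metrics, group contrasts and a
posterior-predictive test for multi-individual interaction cliques.

## The model

For dyad $ij$ in group $k$ at scan $l$ of day $m$, the outcome
$y_{ijklm} \in \{0,1\}$ is Bernoulli with

$$\mathrm{logit}\, P(y_{ijklm}=1) = \alpha + \beta_{last}\, y_{ijk(l-1)m} + B_{ijk} \;(+\; x_{ijk}'\delta)$$

where $y_{ijk(l-1)m}$ is the same dyad's outcome at the previous scan, set
to zero at the first scan of each day, so $\beta_{last}$ absorbs bout
persistence across successive scans within a day. The dyad propensity is

* undirected behaviours (close proximity, distant proximity, play):
  $B_{ijk} = a_k + b_{ik} + b_{jk} + c_{ijk}$,
* grooming (directional, groomer $i$ → recipient $j$):
  $B_{ijk} = a_k + b_{ik} + d_{jk} + c_{ijk}$,

with $a_k \sim N(0, \sigma_{group}^2)$, $b_{ik} \sim N(0, \sigma_{ind}^2)$,
$c_{ijk} \sim N(0, \sigma_{dyad}^2)$ and, for grooming,
$d_{jk} \sim N(0, \sigma_{rec}^2)$ (the recipient's propensity to be
groomed). The dyad effect $c_{ijk}$ is indexed by the unordered pair, so
both grooming directions share one symmetric bond term. Priors are vague:
$\alpha, \beta_{last}, \delta \sim N(0, 100^2)$ (i.e. variance $10^4$) and
every SD uniform on $(0, 10)$; both are configurable in `model_spec()`.

### Covariate coding

Dyad-level covariates enter $B_{ijk}$ when `include_covariates = TRUE`:

* `age_diff` — undirected: the absolute age difference; grooming: the
  signed difference (groomer − recipient). Both are standardized to mean 0,
  SD 1 across all dyads pooled over groups, so a unit change is one SD of
  the observed age-difference distribution.
* `maternal_kin`, `paternal_kin` — 1 when one member is the other's parent
  of that line or both share the recorded mother/father (parent–offspring
  pairs and half-siblings). Derived from the `mother_id`/`father_id`
  columns.
* sex classes — undirected: `mixed_sex` and `male_male` with female–female
  as reference; grooming: `m_grooms_f`, `f_grooms_m` and `male_male` with
  female-grooms-female as reference. The male–male grooming indicator is
  retained for symmetry of the design; drop it by editing the design if an
  all-female contrast set is wanted.

The coefficient names are package-local; reports back-transform them to
odds multipliers ($e^\delta$) with 95% HPDIs (`odds_effects()`). Note that
with few individuals per group, dyad-level sex indicators are only weakly
separated from the individual random effects (a shift shared by all of one
sex can be absorbed by either term), so sex-effect intervals should be read
with that in mind.

## Sampler

Sampling is adaptive random-walk Metropolis-within-Gibbs over a
non-centred parameterization: every random effect is stored as a
standard-normal z-score and multiplied by its SD inside the linear
predictor. The non-centred form keeps the sampler well behaved when an SD
approaches zero (a flat funnel instead of a collapsing one), which matters
because "no group-level variation" is a hypothesis the package must be able
to support rather than an awkward corner.

Each iteration updates: the intercept; the autocorrelation coefficient
(only rows with a lagged 1 need relikelihooding); each covariate
coefficient over its non-zero design rows; each SD; each z-score over the
rows it touches. Two families of likelihood-free *interweaving* moves are
appended, exploiting directions that leave every linear predictor
unchanged:

* translations — shift a whole z-block by a constant and absorb the shift
  into $\alpha$;
* scale moves — multiply an SD by $e^u$ and divide its z-block by the same
  factor (Metropolis ratio includes the Jacobian $e^{u(1-n_z)}$).

These cost no likelihood evaluations and decorrelate $\alpha$ and the SDs
from their blocks; without them the intercept–group-effect ridge mixes very
slowly. Proposal scales adapt toward 0.44 acceptance during warmup only
(Robbins–Monro, $\gamma_t = (t+2)^{-0.6}$), leaving the post-warmup kernel
fixed. Chains start at zero effects and unit SDs with a small seed-derived
jitter; fits are deterministic given `(seed, spec)`.

Correctness anchors: `log_posterior()` is checked against an independent
naive implementation to $10^{-9}$ relative tolerance; an empty-likelihood
run reproduces its priors (uniform SDs with mean ≈ 5); and
simulation-based calibration at reduced scale (generate from the fitting
priors, rank the truth within the posterior) yields uniform ranks.
Convergence is monitored with split-$\hat R$ and effective sample size;
parameters with $\hat R > 1.05$ are flagged.

## Variance decomposition

Per posterior draw (never as ratios of summaries):

* undirected: $\sigma_{within} = \sqrt{2\sigma_{ind}^2 + \sigma_{dyad}^2}$
  and $\sigma_{IND} = \sqrt{2}\,\sigma_{ind}$ — the individual component
  counts twice because both members' effects enter each dyad;
* grooming: $\sigma_{within} = \sqrt{\sigma_{ind}^2 + \sigma_{rec}^2 +
  \sigma_{dyad}^2}$ and $\sigma_{IND} = \sqrt{\sigma_{ind}^2 +
  \sigma_{rec}^2}$ — giving and receiving are separate components that each
  enter once.

The headline ratios are $\sigma_{group}/\sigma_{within}$ (between- vs
within-group variation) and $\sigma_{dyad}/\sigma_{IND}$ (dyadic
preference vs individual gregariousness), summarized by posterior mean and
95% HPDI. Percent-variance shares divide each squared component by the
total on the log-odds scale; they sum to 100 by construction and are
invariant to rescaling all SDs. If $\sigma_{IND}$ is zero in some draws the
dyad/individual ratio is reported as missing with a `degenerate` flag
rather than erroring.

`hpdi()` returns the shortest window containing $\lceil 0.95 n \rceil$
sorted draws; ties between equally short windows (draws are discrete) are
broken by taking the leftmost, a documented convention verified against an
exhaustive-search oracle.

## Networks and metrics

Because the model is lagged, `plogis(alpha + B)` is the probability of
interacting *given no interaction at the previous scan*, not the proportion
of time interacting. Each dyad's series is a two-state Markov chain with
$p_0 = \mathrm{logit}^{-1}(\alpha + B)$ and $p_1 = \mathrm{logit}^{-1}(\alpha
+ B + \beta_{last})$, whose stationary probability

$$ n_{ijk} = \frac{p_0}{1 - p_1 + p_0} $$

is the internally consistent "probability the dyad is interacting at a
random point in time" and collapses to $\mathrm{logit}^{-1}(\alpha + B)$
when $\beta_{last} = 0$. `derive_networks()` computes this edge weight for
every posterior draw, so every derived metric carries posterior
uncertainty. By default the covariate contribution is included (the network
reflects realized propensities, kin effects and all); pass
`include_covariates = FALSE` for the random-effects-only network.

*Strength* is the sum of a node's edge weights; for directed grooming it is
total involvement, give plus receive (out- and in-strength are recoverable
from the directed edge list). *Clustering* uses the probabilistic form

$$ C_i = \frac{\sum_{j \ne i}\sum_{k \ne i,j} w_{ij} w_{jk} w_{ik}}
             {\sum_{j \ne i}\sum_{k \ne i,j} w_{ij} w_{ik}} $$

— the probability that two random interaction partners of $i$ are
themselves connected, weighting partner pairs by their joint probability.
It equals the binary clustering coefficient on 0/1 graphs (the anchor the
tests use, cross-checked against igraph's local transitivity) and is
computed as $\mathrm{diag}(W^3)_i / (s_i^2 - q_i)$ with $s_i = \sum_j
w_{ij}$, $q_i = \sum_j w_{ij}^2$. Grooming clustering symmetrizes weights
as $(w_{ij} + w_{ji})/2$. Nodes with a zero denominator are missing, and
groups of fewer than three nodes have no clustering.

Group means of each metric are computed per draw, then summarized; pairwise
group differences get 95% HPDIs and an evidence flag when the interval
excludes zero. On truly identical groups this flag fires at roughly the
nominal 5% rate; note that with non-zero individual or dyad variance two
groups generated from the *same hyperparameters* still genuinely differ in
realized sociality, and the flag correctly detects that.

## Clique check

A "clique" is operationalized as a connected component of three or more
simultaneously interacting individuals within one scan — chain
connectivity, not a complete subgraph, because scan data record pairwise
engagement and chains are the observable signature of multi-party
congregation. This definition is an explicit reconstruction and is kept
deliberately simple.

The observed rate is the fraction of a group's scans (among scans with at
least three visible individuals) containing such a component. The
predictive null simulates scans in which every dyad interacts independently
with its posterior edge weight — the rate *predicted by the dyadic rates
alone* — matching the observed scan count and, by default, the observed
per-scan visible counts to avoid visibility bias. Each simulation uses one
posterior draw, so the 95% predictive interval mixes parameter uncertainty
with sampling noise. The default ignores within-day autocorrelation, which
leaves the predictive mean unchanged (scans are marginally stationary) but
slightly narrows the interval; a `lag_aware = TRUE` variant simulates the
fitted two-state chains within days instead. Excess congregation is
`observed − predictive mean`, flagged when the observed rate falls outside
the interval. Under dyadic independence the flag is calibrated near 5%; a
latent "party" process (rare scans where all dyads co-activate, marginals
matched) is detected essentially always in the sparse regimes where cliques
are rare under independence.

## The synthetic generator

`simulate_scans()` runs the model generatively with known truth: six groups
of 8–16 individuals by default, ages uniform on 7–40 years (only
standardized differences enter the model, so the exact age distribution is
immaterial), a configurable sex ratio, and mothers/fathers assigned with a
stated probability among same-group candidates at least 12 years older —
enough structure to exercise the kin indicators without modelling a
pedigree. Default sampling effort is ~870 scans per group (about three
months of daily sampling), and each dyad's outcome series follows the
two-state chain with a day reset.

Visibility is Bernoulli per individual per scan (default 0.9, a free choice
— field visibility rates vary and are not part of the model), with one
convention: interacting individuals are always in sight, since an observed
interaction implies both parties were observable. Censoring therefore drops
only non-interacting records, and a dyad-scan is dropped entirely only when
both members are out of sight. Under this convention the lagged table
rebuilt from the event and visibility files reproduces the generating
series exactly, which the round-trip tests rely on.

What the generator does **not** emulate: demographic turnover within the
study window, observer error, correlated visibility (e.g. whole subgroups
out of sight together), seasonal or diurnal nonstationarity, and any
dependence between behaviours beyond the close/distant proximity
exclusivity applied when events are written. Passing tests therefore show
the pipeline recovers the model's own data-generating process — they cannot
certify robustness to misspecification that real data may carry.

## Handling degenerate inputs

* A dyad never observed keeps its $c_{ijk}$ in the prior (pure shrinkage);
  `log_posterior()` accepts states with unobserved effects.
* SDs outside the prior support give `-Inf`, not an error.
* A single group fits with a warning ($\sigma_{group}$ only weakly
  identified); a single chain fits with a warning but refuses diagnostics.
* Zero-scan dyads are excluded from raw rates with a warning.
* `y_prev` refers to the immediately preceding scan of the day; if the dyad
  has no retained row there, the unknown state is treated as
  non-interaction (0), matching the generator's convention.

## Problem sizes used by the test suite

The suite favours many small, sharply targeted checks: oracle equivalence
on 12-row tables; parameter recovery on 20 replicate studies of 6 groups ×
8 individuals × 200 scans with two chains of 1100 iterations (enough for
HPDI coverage, not for publication-grade effective sample sizes); contrast
calibration on 100 two-group studies with all variance components zero;
clique calibration and power on 100 replicates of a 5-node group at a 1%
edge rate. These sizes are design choices balancing statistical
informativeness against a suite that runs in minutes; analyses of real data
should use longer chains (the study-scale script in `scripts/acceptance.R`
uses 1600 iterations on ~10^5-row tables).

## Known limitations

* The sampler is single-site random walk plus interweaving: adequate at
  these scales, but slowly-mixing individual-level SDs can show
  $\hat R$ around 1.1–1.2 at short run lengths; double the iterations when
  a flag appears.
* Group-level covariates (group size, sex ratio) are deliberately out of
  scope: with a handful of groups they cannot be estimated usefully.
* Edge weights assume the two-state chain is stationary within days; long
  within-day nonstationarity would bias the "random point in time"
  interpretation.
* The clique statistic conditions on visible counts but not on which
  individuals were visible; strong visibility–sociality correlation would
  require the lag-aware, individual-matched variant.
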