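---
title: "Models and methods: retention and divergence of WGD duplicates"
author: "dupdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: retention and divergence of WGD duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupdyn)
```

After a whole-genome duplication (WGD) every gene has a paralog; most
revert to single copy, but transcription factors (TFs) are retained in
duplicate at elevated rates. `dupdyn` implements a chain of analyses for
asking *why*: which group-level features predict retention odds, how the
expression states and cis-regulatory sites of a duplicate pair diverge
from their inferred pre-duplication ancestor, how asymmetric that
divergence is between the two copies, and what loss kinetics best explain
the observed mixture of pair states over time. This vignette documents the
models, the tunable parameters, the synthetic-data generators used for
validation, and the numerical choices the implementation makes.

## Ancestral-state inference

Expression values (log2 scale) are discretized into quartile states 0–3
within each experiment (`discretize_expression()`); binding-site presence
is already binary. States evolve on the family tree under a
continuous-time Markov chain with generator $Q$ ($q_{ij} \ge 0$ off the
diagonal, rows summing to zero), so the transition kernel along a branch
of length $t$ is $e^{Qt}$. Branch lengths are used exactly as given on the
input trees (amino-acid substitution scale); no rescaling is applied, so
fitted rates are per unit of that scale. Trees without a trustworthy
outgroup are midpoint rooted (`midpoint_root()`), which preserves all
leaf-to-leaf path lengths.

The tip likelihood is computed by the pruning recursion
(`tree_loglik()`), with per-item rescaling against underflow; missing or
ambiguous tips contribute a partial likelihood of one in every state,
i.e. they are marginalized rather than treated as a fifth state. (An
alternative treatment makes "ambiguous" itself a state of the chain; we
deliberately marginalize, because a missing microarray value carries no
information about the latent expression level, and a five-state chain
would let missingness itself evolve. The consequence is that heavily
missing items yield flat posteriors and fall out at the calling step
rather than being reconstructed as "ambiguous".)

Three rate parameterizations are available (`build_rate_matrix()`): `ER`
(one rate), `SYM` (one rate per unordered state pair, the default), and
`ARD` (all rates free). The default is the full symmetric model: quartile
states are not obviously ordered once experiments are pooled, and with
typical family sizes (tens of tips) the 12-parameter `ARD` model is
under-determined. `fit_rate_model()` maximizes the likelihood over rates
on the log scale (positivity by construction) from `n_restarts` random
initializations centred on one expected change per unit of total tree
length.

Marginal ancestral posteriors (`marginal_ancestral_states()`) come from
the standard up–down algorithm with a uniform root prior (no prior
information about the pre-duplication state is assumed). Calls are made
by consensus over repeated independent fits
(`consensus_ancestral_calls()`): the model is refit `runs = 100` times
from random starts, and a node–item state is called only when the same
state is the posterior mode in more than `consensus_min = 50` runs *and*
its mean posterior exceeds `posterior_min = 0.5`. Everything else is
ambiguous and excluded downstream. On one fixed tree the restarts usually
agree, so support is typically 100/100; the consensus exists to catch
items whose likelihood surface is multi-modal, where a single fit would
silently pick a basin.

## Pair partitioning and deviation grids

For each pair and item, the pair is in state **O** (both copies retain
the inferred ancestral state), **I** (exactly one does; "partitioned") or
**II** (neither does) — `classify_pairs()`. Items with an ambiguous
ancestor or a missing extant state are dropped per item, not per pair.

Observed state fractions are compared against a re-pairing null
(`pair_expression_summary()`): copy-B retention profiles are shuffled
across pairs (within a stratum, e.g. WGD event × data subset, when
given), keeping each gene's own profile intact. The per-cell z-score is
$(obs - \overline{perm})/sd(perm)$ over `n_rep = 1000` replicates.
A caveat that matters for interpretation: this null assumes pairs are
exchangeable. If pairs differ strongly in age (divergence $d_s$), the
pooled re-pairing mixes old with young pairs and the null is genuinely
off-centre even when the two copies lose states independently — the
excess z then partly reflects age heterogeneity, not coupling.
Calibration checks in the test suite therefore simulate pairs at a
common divergence time; on real data the within-event stratification
plays that role.

Per-gene deviation grids (`permutation_zscores()`,
`deviation_records()`) compare extant vs ancestral quartiles the same
way, permuting the pooled ancestral values against the pooled extant
values; copy 1 of a pair is defined as the copy with the
higher-or-equal extant quartile.

## Asymmetry and the grouped Bernoulli null

For a pair with $n$ partitioned items of which copy A retained $k_A$,
the shares are $F_A = k_A/n$, $F_B = 1 - F_A$ and the asymmetry score is

$$Y = \max(F_A, F_B) - (1 - \max(F_A, F_B)) = |2F_A - 1| \in [0, 1].$$

The copy with the larger share is the "ancestral" copy; exact ties are
assigned randomly from the run's RNG stream so results stay
reproducible. Pairs with fewer than `min_partitioned = 5` partitioned
items (or fewer than `min_sites = 5` ancestral sites, on the
cis-regulatory path — the same scoring code) are excluded: with $n < 5$
the score takes at most three values and dominates any distributional
comparison.

Under the null of independent partitioning, $k_A \sim \mathrm{Bin}(n,
1/2)$, so $E[Y \mid n] = E|2X - n|/n$ is available exactly by enumeration
(`expected_asymmetry()`; e.g. $0.375$ at $n=5$, $0.3125$ at $n=6$,
decreasing to 0 as $n$ grows). `grouped_bernoulli_null()` draws
`bernoulli_reps = 1000` replicates grouped by the observed per-pair $n$
and returns both the replicate-mean distribution and the per-pair draws.
The comparison (`compare_to_null()`) runs Welch's t-test of observed
per-pair scores against the pooled per-pair null draws — comparing
per-pair values rather than means-of-means, which preserves the observed
sample size in the degrees of freedom — plus a two-sample
Kolmogorov–Smirnov test for the site path, whose scores are strongly
discrete. Time-series robustness (`timeseries_robustness_subsets()`)
recomputes the scores using only the first, or only the last, element of
each annotated series.

## Three-state loss kinetics

Two systems share one machinery (`ode_system()`, `ode_solution()`),
written as $\dot p = A p$ with column-conserving generators:

* **pair model**, states $(O, I, II)$ — both / one / neither copy
  retains the ancestral state:
  $$A = \begin{pmatrix} -x & y & 0 \\ x & -(y+w) & z \\ 0 & w & -z \end{pmatrix},$$
  so $x$: O→I, $y$: I→O, $w$: I→II, $z$: II→I.
* **single-copy model**, states $(O, +, -)$ — an extant copy retains the
  ancestral quartile, sits above it, or below it, with $x$: O→+, $y$:
  O→−, $w$: +→O, $z$: −→O. A published variant of this matrix carries a
  sign error in its third row (columns fail to sum to zero, so
  probability mass leaks); the conserving form is used here, which is the
  minimal correction and the only one consistent with the states being a
  partition.

Solutions are analytic via eigen-decomposition, with a
scaling-and-squaring series fallback for the measure-zero repeated-
eigenvalue case. Observations are per-pair (or per-copy) categorical
draws at $t = d_s$, the pairwise synonymous divergence used as a time
proxy; the log-likelihood is $\sum_i \log p_{s_i}(d_{s,i})$ with the
default initial condition $(1, 0, 0)$ — immediately after WGD every pair
retains the ancestral state. Fitting at the observed $d_s$ values avoids
arbitrary time bins; binned Fig-style curves can still be produced from
`predict()` on a time grid.

Constraint variants tie rates together: `one` ($x=y=w=z$), `two`
($x=y$, $w=z$ for the pair model; $\{x,w\}$ vs $\{y,z\}$ — the "+"-side
vs the "−"-side — for the single-copy model, which is what lets the
O→+ and O→− rates differ), `four` (all free); arbitrary groupings can be
passed as a list, since tying conventions differ between publications.
`fit_ode()` optimizes free rates on the log scale (Brent for one
parameter, Nelder–Mead plus a restart-until-stable polish otherwise)
from `n_starts = 20` random initializations centred on $1/\mathrm{median}(d_s)$;
estimates below `1e-4` are flagged as boundary estimates, where the
chi-square reference of the likelihood-ratio test
(`likelihood_ratio_test()`, $2\Delta \ln L$ against $\chi^2_{\Delta df}$)
is only approximate. The LRT's calibration is asymptotic: in the test
suite it is exercised at 1000 observations per simulated data set, below
which the weakly identified backward rates ($y$, $z$) sit at the zero
boundary often enough to make the nominal test conservative.

## Retention odds and the feature model

For function group $g$ and WGD event $w$, with $D$ counting
WGD-duplicates and $S$ WGD-singletons inside ($g$) and outside
($\neg g$) the group,

$$R_{g,w} = \frac{D_{g,w}/S_{g,w}}{D_{\neg g,w}/S_{\neg g,w}},$$

the sample odds ratio of retention relative to the rest of the genome
(`retention_odds()`). Confidence intervals are exact conditional
(central) intervals from inverting the noncentral hypergeometric
distribution; the inversion is done in-package with tight root
tolerances so endpoints are reproducible to well below $10^{-6}$, and
`fisher.test` supplies the p-value. Groups are pre-filtered to 100–2000
genes and at least 20 duplicate pairs (`filter_groups()`): smaller groups
give unstable odds, larger ones are functionally heterogeneous.

Candidate features are pruned before modelling
(`prefilter_features()`): features with more than 50% missing values or
no variance are removed, then correlated clusters ($|r| > 0.7$) are
broken keeping, in priority order, the feature with the stronger
marginal correlation with the odds, then the non-derived feature, then
the one correlated with fewer others. Divergence-derived features should
be excluded by the caller since they are confounded with WGD age.

`fit_retention_model()` regresses the odds on the surviving features
(raw odds by default — linearity on the odds scale is the implicit
choice of the group-level formulation; `log_odds = TRUE` is available,
and `weights` allow size-weighting, which is off by default) and runs
backward elimination: drop the feature with the largest coefficient
p-value, refit, repeat down to one feature, then return the *visited*
model with the largest overall F-statistic. Running the path to the end
rather than stopping at the first local F-maximum makes the rule
unambiguous; ties (e.g. several zero-residual models) break toward fewer
features, and a zero-residual step ranks features by coefficient
magnitude since p-values are undefined there. A constant response
returns the intercept-only model with no features selected. Feature
importance is the drop in $R^2$ on single-feature removal;
`leave_one_out_robustness()` refits the whole elimination per omitted
group and reports parameter dispersion and any selection changes.

## Synthetic data: what it emulates, and what it does not

All generators are seed-deterministic and return their ground truth.

* `simulate_states_on_tree()` draws a root state (uniform by default —
  no prior is assumed) and propagates it with the exact CTMC kernel; it
  emulates quartile or binary states with optional injected missingness.
* `simulate_pair_fates()` draws $d_s$ from event-specific uniform
  windows ordered youngest to oldest (defaults $\alpha$: 0.4–1.0,
  $\beta$: 1.0–2.2, $\gamma$: 2.2–3.5, roughly the relative ages of the
  three Arabidopsis-lineage events on the $d_s$ scale) and samples pair
  states from the analytic kinetics.
* `simulate_pair_items()` produces per-item retention profiles either
  under the coupled pair kinetics (fast first loss / slow second loss
  when $w \ll x$) or as independent per-copy loss with retention
  probability $e^{-\lambda d_s}$ — the exchangeable null regime.
* `simulate_group_feature_table()` draws features uniform on $(0,1)$,
  sets latent odds as a linear predictor plus Gaussian noise
  (defaults: intercept 2, coefficients $f_1 = 1.5$, $f_2 = -0.8$, noise
  sd 0.05, 5000 genes per group against a large balanced complement) and
  draws duplicate/singleton counts binomially, so empirical odds
  converge to the latent odds as group size grows.

What the generators do **not** emulate: microarray noise spectra and
normalization artefacts, correlated conditions within real time series,
gene-tree estimation error, alignment uncertainty, and family-specific
rate variation. Passing the recovery tests therefore shows the
estimators are correct and well-calibrated *under the model*, not that
real microarray or DAP-seq binding data satisfy these models.

## Numerical choices and problem sizes

Matrix exponentials use eigen-decompositions reused across time points,
falling back to scaling-and-squaring when the eigenvector matrix is
ill-conditioned; transition probabilities are clamped of tiny negative
rounding (≤1e-9). Pruning rescales per item; posteriors are renormalized
at the end. Quartile bins are lower-closed/upper-open with ties
collapsing downward, so discretization is deterministic and
order-independent.

The validation suite runs entirely on synthetic data at desk scale:
enumeration oracles on trees of 2–6 tips with 4 states; kinetic
solutions checked against adaptive numerical integration over
$t \in [0, 5]$ for 100 random rate vectors (max deviation below
$10^{-7}$); rate recovery at 5000 pairs × 20 replicates; LRT type-I
calibration at 200 simulations of 1000 observations; retention recovery
on 20 groups × 11 features × 20 seeds; partitioning excess at 500 pairs
× 20 conditions. These sizes are the package's chosen study conditions
and are fixed in the tests and the acceptance script.

## Known limitations

Midpoint rooting is a heuristic; a misplaced root biases which node is
"the" pair ancestor. Consensus support counts restarts on one fixed
tree, not phylogenetic uncertainty. The re-pairing null conflates age
heterogeneity with coupling unless stratified. The kinetic models assume
time-homogeneous rates shared by all pairs within a fit, and $d_s$ is a
noisy clock. The retention model treats groups as independent
observations, which GO-derived groups only approximately are.
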