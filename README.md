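# dupdyn

Dynamics of duplicate gene retention after whole-genome duplication (WGD).

After a WGD every gene has a paralog, yet most revert to single copy;
transcription factors are a conspicuous exception, staying duplicated at
elevated rates. `dupdyn` is an R package for the analysis chain behind
that observation: it quantifies *which* function groups retain duplicates,
*how* the two copies of a retained pair diverge from their inferred
pre-duplication state in expression and cis-regulation, *how asymmetric*
that divergence is, and *what loss kinetics* best explain the mixture of
pair states over evolutionary time. It is aimed at molecular-evolution
researchers with family trees (newick), expression tables, binding-site
tables, and duplicate-pair lists; everything also runs on built-in
synthetic generators with known ground truth.

## The models at the core

**Retention odds.** For function group *g* and WGD event *w*, with *D*
counting WGD-duplicates and *S* WGD-singletons inside and outside the
group,

    R_gw = (D_gw / S_gw) / (D_¬gw / S_¬gw),

with exact conditional 95% intervals. A linear model relates group odds to
group features via backward elimination that maximizes the model
F-statistic, with leave-one-group-out robustness.

**Ancestral states.** Expression quartiles (0–3) or site presence (0/1)
evolve on the family tree under a CTMC with generator *Q*; tip likelihoods
come from the pruning recursion, ancestral nodes from marginal posteriors
(uniform root prior), and calls from a consensus over 100 independent
restarts (support > 50 runs and posterior > 0.5, else ambiguous).

**Pair partitioning and asymmetry.** Per item, a pair is in state O (both
copies retain the ancestral state), I (exactly one), or II (neither),
compared against permutation nulls. For a pair with *n* partitioned items
of which copy A kept *k_A*, the asymmetry score is
`Y = |2 k_A/n − 1|`, tested against a grouped Bernoulli null
(`k_A ~ Bin(n, 1/2)`, exact `E[Y|n]` by enumeration).

**Loss kinetics.** Three-state ODE systems, e.g. for pair states
(O, I, II):

    d/dt (O, I, II)' = [ -x   y   0 ;  x  -(y+w)  z ;  0   w  -z ] (O, I, II)'

solved analytically and fit by maximum likelihood to (state, d_s)
observations; nested constraint variants (x=y=w=z; x=y|w=z; all free) are
compared with likelihood-ratio tests. An analogous single-copy system
(O, +, −) measures whether expression drifts preferentially below the
ancestral level.

## Worked example

Simulate a family, infer ancestral expression states, fit the pair
kinetics, and score asymmetry:

```r
library(dupdyn)
set.seed(42)

tree <- simulate_tree(12)
Q    <- build_rate_matrix(0.3, 4, "ER")
fam  <- simulate_states_on_tree(tree, Q, n_items = 40)

fit <- fit_rate_model(tree, fam$tips, type = "ER", n_restarts = 3)
fit
#> CTMC rate model (ER, 4 states)
#>   rates: 0.319
#>   log-likelihood: -560.79272 over 40 items
```

The fitted rate (0.319) recovers the simulating rate (0.3). Consensus
calls at the family root come with posterior and support:

```r
calls <- consensus_ancestral_calls(tree, fam$tips, type = "ER",
                                   n_states = 4, nodes = 13L,
                                   runs = 20, min_support = 10)
head(calls[!is.na(calls$state), c("item", "state", "posterior", "support")], 4)
#>    item state posterior support
#> 1 item1     2 0.9768533      20
#> 2 item2     3 0.9582940      20
#> 3 item3     3 0.9547994      20
#> 4 item4     0 0.9568834      20
```

(Here every called state equals the recorded simulation truth.) Pair-state
kinetics and model comparison:

```r
fates <- simulate_pair_fates(1500, c(x = 0.9, y = 0.05, w = 0.12, z = 0.02),
                             events = "alpha",
                             ds_samplers = list(alpha = function(n) runif(n, 0.5, 3)))
fit4 <- fit_ode(fates$class, fates$ds, variant = "four", n_starts = 6)
fit4
#> Three-state kinetic fit (pair model, four-parameter variant)
#>   rates:  x=0.9486, y=0.1068, w=0.1623, z=0.3149
#>   log-likelihood: -1249.5463 ( 4 free parameter(s), 1500 observations )

likelihood_ratio_test(fit_ode(fates$class, fates$ds, variant = "one"), fit4)
#> Likelihood ratio test: four vs one variant
#>   2*deltaLnL = 605.684  df = 3  p = < 2.2e-16
```

The first-loss rate `x` (O→I) is estimated an order of magnitude above the
second-loss rate `w` (I→II), and the one-rate model is firmly rejected.
Asymmetry against its Bernoulli null:

```r
n_list <- sample(5:15, 200, replace = TRUE)
rec  <- asymmetry_records(seq_along(n_list), rbinom(200, n_list, 0.9), n_list)
null <- grouped_bernoulli_null(rec$n, reps = 1000)
compare_to_null(rec, null)
#> Observed vs null asymmetry (200 pairs)
#>   mean Y observed: 0.8109  null: 0.2656
#>   Welch t-test p: < 2.2e-16
#>   KS statistic: 0.818  p: < 2.2e-16
```

A mean score of 0.81 against a null mean of 0.27 says partitioned states
concentrate in one copy far beyond independent partitioning. Finally, the
retention feature model on a synthetic group table (two informative
features among eleven):

```r
sim <- simulate_group_feature_table(seed = 3)
fit_retention_model(sim$features, sim$odds)
#> Retention linear model (odds response)
#>   selected: f1, f2
#>   R^2: 0.9743  F: 322.74  p: 3.012e-14
#>   importance (delta R^2): f1=0.570, f2=0.209
```

`run_pipeline(run_config(...))` chains these stages end-to-end and writes
per-stage TSV/JSON plus a manifest recording the seed and all thresholds.
See the vignette (`vignettes/duplicate-retention-dynamics.Rmd`) for the
models, assumptions, and design choices in detail.

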