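# Seed-deterministic generators for every input the pipeline consumes:
# family trees, discrete states evolving along them, duplicate-pair fates
# under the three-state kinetics, per-pair item retention profiles, and
# group feature tables linearly related to retention odds. Ground truth is
# always returned so downstream stages can be tested for recovery.

#' Simulate a random family tree
#'
#' @param n_tips Number of leaves.
#' @param branch_fun Function(n) drawing n branch lengths; default
#'   exponential with mean 0.3, roughly the scale of amino-acid family
#'   trees.
#' @param seed Optional RNG seed.
#' @return A rooted `phylo` with tip labels `g1..gn`.
#' @export
simulate_tree <- function(n_tips, branch_fun = function(n) rexp(n, 1 / 0.3),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_tips, br = branch_fun, tip.label = paste0("g", seq_len(n_tips)))
  tr
}

#' Simulate discrete states along a tree
#'
#' The root state of each item is drawn from `root_distribution` and
#' propagated down every edge with the CTMC transition kernel
#' exp(Q t_edge). True internal-node states are retained for recovery
#' tests; optional missingness is injected at the tips to exercise the
#' ambiguous-state path of inference.
#'
#' @param tree Rooted `phylo`.
#' @param Q Generator matrix (rows sum to 0), e.g. from
#'   [build_rate_matrix()].
#' @param n_items Number of independent items (conditions or sites).
#' @param root_distribution Probabilities over the k states at the root;
#'   default uniform.
#' @param missing_rate Fraction of tip cells replaced by `NA`.
#' @param seed Optional RNG seed.
#' @return List: `tips` (leaves x items integer matrix, 0-based states),
#'   `ancestors` (internal nodes x items, rownames are ape node numbers),
#'   `Q`.
#' @export
simulate_states_on_tree <- function(tree, Q, n_items,
                                    root_distribution = NULL,
                                    missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  k <- nrow(Q)
  if (any(diag(Q) > 1e-12) || any(abs(rowSums(Q)) > 1e-8) ||
      any(Q - diag(diag(Q)) < 0)) {
    stop("Q is not a valid generator (nonnegative off-diagonals, rows sum to 0)")
  }
  if (is.null(root_distribution)) root_distribution <- rep(1 / k, k)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  dec <- mexp_decompose(Q)

  states <- matrix(NA_integer_, n_node, n_items)
  states[root, ] <- sample.int(k, n_items, replace = TRUE,
                               prob = root_distribution) - 1L
  ord <- reorder(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (e in seq_len(nrow(edges))) {
    P <- clamp01(mexp_at(dec, lens[e]))
    parent_state <- states[edges[e, 1], ]
    child <- integer(n_items)
    for (s in seq_len(k)) {
      idx <- which(parent_state == s - 1L)
      if (length(idx)) {
        child[idx] <- sample.int(k, length(idx), replace = TRUE,
                                 prob = pmax(P[s, ], 0)) - 1L
      }
    }
    states[edges[e, 2], ] <- child
  }
  tips <- states[seq_len(n_tip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  colnames(tips) <- paste0("item", seq_len(n_items))
  if (missing_rate > 0) {
    drop <- runif(length(tips)) < missing_rate
    tips[drop] <- NA_integer_
  }
  anc <- states[(n_tip + 1L):n_node, , drop = FALSE]
  rownames(anc) <- as.character((n_tip + 1L):n_node)
  colnames(anc) <- colnames(tips)
  list(tips = tips, ancestors = anc, Q = Q)
}

#' Default synonymous-divergence samplers per WGD event
#'
#' Event-specific uniform windows ordered youngest to oldest
#' (alpha < beta < gamma), mimicking the age ordering of the three
#' Arabidopsis-lineage WGD events on the d_s scale.
#'
#' @return Named list of `function(n)` samplers for `alpha`, `beta`,
#'   `gamma`.
#' @export
default_ds_samplers <- function() {
  list(alpha = function(n) runif(n, 0.4, 1.0),
       beta  = function(n) runif(n, 1.0, 2.2),
       gamma = function(n) runif(n, 2.2, 3.5))
}

#' Simulate duplicate-pair fates under the three-state kinetics
#'
#' For each pair a divergence time d_s is drawn from its event's sampler
#' and the pair's state (O / I / II) is drawn from the analytic state
#' frequencies of the pair model at t = d_s.
#'
#' @param n_pairs Pairs per event (recycled over `events`).
#' @param rates Named vector `x`, `y`, `w`, `z` of true transition rates.
#' @param events Character vector of WGD event labels to simulate.
#' @param ds_samplers Named list of per-event samplers; default
#'   [default_ds_samplers()].
#' @param init Initial condition; default all pairs start in O.
#' @param seed Optional RNG seed.
#' @return Data frame: `pair`, `geneA`, `geneB`, `event`, `ds`, `class`.
#' @export
simulate_pair_fates <- function(n_pairs, rates,
                                events = c("alpha", "beta", "gamma"),
                                ds_samplers = default_ds_samplers(),
                                init = c(1, 0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(rates < 0)) stop("rates must be nonnegative")
  n_pairs <- rep_len(n_pairs, length(events))
  sys <- ode_system(rates, "pair", init)
  out <- lapply(seq_along(events), function(i) {
    ev <- events[i]
    sampler <- ds_samplers[[ev]]
    if (is.null(sampler)) stop("no d_s sampler for event '", ev, "'")
    ds <- sampler(n_pairs[i])
    if (!length(ds) || any(ds <= 0)) stop("d_s sampler must return positive values")
    pmat <- ode_solution(sys, ds)
    cls <- apply(pmat, 1, function(p) sample(sys$states, 1, prob = pmax(p, 0)))
    data.frame(event = ev, ds = ds, class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  n <- nrow(out)
  data.frame(pair = paste0("p", seq_len(n)),
             geneA = paste0("p", seq_len(n), "a"),
             geneB = paste0("p", seq_len(n), "b"),
             out, stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate per-item ancestral-retention profiles for duplicate pairs
#'
#' Generates, for each pair and item, whether each copy retains the
#' ancestral state — the input of [pair_expression_summary()] and the
#' asymmetry analysis. Two regimes:
#'
#' * `"pair"`: items evolve under the coupled pair kinetics (rates `x`,
#'   `y`, `w`, `z`); with `w` well below `x`, partitioned items accumulate
#'   in excess of what independent copies would give.
#' * `"independent"`: each copy loses the ancestral state independently
#'   (retention probability exp(-loss_rate * d_s)), the null regime in
#'   which re-pairing expectations are calibrated.
#'
#' @param n_pairs Number of pairs.
#' @param n_items Items (conditions) per pair.
#' @param mode `"pair"` or `"independent"`.
#' @param rates Pair-model rates (mode `"pair"`).
#' @param loss_rate Per-copy loss rate (mode `"independent"`).
#' @param ds_sampler Function(n) drawing one d_s per pair; default
#'   Uniform(0.4, 1).
#' @param seed Optional RNG seed.
#' @return List: `retention` (data frame `pair`, `item`, `retA`, `retB`),
#'   `pairs` (data frame `pair`, `ds`).
#' @export
simulate_pair_items <- function(n_pairs, n_items,
                                mode = c("pair", "independent"),
                                rates = c(x = 1, y = 0, w = 0.1, z = 0),
                                loss_rate = 0.5,
                                ds_sampler = function(n) runif(n, 0.4, 1),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ds <- ds_sampler(n_pairs)
  pid <- paste0("p", seq_len(n_pairs))
  if (mode == "independent") {
    pret <- exp(-loss_rate * ds)
    retA <- matrix(runif(n_pairs * n_items) < rep(pret, n_items), n_pairs)
    retB <- matrix(runif(n_pairs * n_items) < rep(pret, n_items), n_pairs)
  } else {
    sys <- ode_system(rates, "pair", c(1, 0, 0))
    pmat <- ode_solution(sys, ds)           # n_pairs x 3
    cls <- matrix(0L, n_pairs, n_items)
    for (i in seq_len(n_pairs)) {
      cls[i, ] <- sample.int(3, n_items, replace = TRUE, prob = pmax(pmat[i, ], 0))
    }
    which_copy <- matrix(runif(n_pairs * n_items) < 0.5, n_pairs)
    retA <- cls == 1L | (cls == 2L & which_copy)
    retB <- cls == 1L | (cls == 2L & !which_copy)
  }
  data.frame(
    pair = rep(pid, n_items),
    item = rep(paste0("c", seq_len(n_items)), each = n_pairs),
    retA = as.vector(retA), retB = as.vector(retB),
    stringsAsFactors = FALSE
  ) -> retention
  list(retention = retention, pairs = data.frame(pair = pid, ds = ds))
}

#' Simulate a group feature table with known retention-odds truth
#'
#' Group features are drawn uniformly on (0, 1); the latent retention odds
#' of each group is a linear predictor plus Gaussian noise. Duplicate /
#' singleton counts are then drawn binomially against a large balanced
#' complement so that the empirical R_gw converges to the latent odds as
#' `count_scale` grows.
#'
#' @param n_groups Number of function groups.
#' @param n_features Number of candidate features (named `f1..fk`).
#' @param true_coefficients Named vector of nonzero coefficients (names
#'   among the features); all other features are noise.
#' @param intercept Latent intercept (default 2, keeping odds positive).
#' @param noise_sd Gaussian noise on the latent odds.
#' @param count_scale Genes per group.
#' @param complement_size Genes in the complement (duplicates = singletons).
#' @param seed Optional RNG seed.
#' @return List: `features` (data frame), `counts` (data frame `group`,
#'   `gene_count`, `n_pairs`, `D`, `S`, complement counts), `odds`
#'   (empirical R per group), `latent_odds`, `truth`.
#' @export
simulate_group_feature_table <- function(n_groups = 20, n_features = 11,
                                         true_coefficients = c(f1 = 1.5, f2 = -0.8),
                                         intercept = 2, noise_sd = 0.05,
                                         count_scale = 5000,
                                         complement_size = 5e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_groups < length(true_coefficients) + 2) {
    stop("need at least ", length(true_coefficients) + 2, " groups")
  }
  fnames <- paste0("f", seq_len(n_features))
  if (!all(names(true_coefficients) %in% fnames)) {
    stop("true_coefficients must name features among ", paste(fnames, collapse = ","))
  }
  X <- matrix(runif(n_groups * n_features), n_groups, n_features,
              dimnames = list(paste0("G", seq_len(n_groups)), fnames))
  if (any(apply(X, 2, var) == 0)) warning("degenerate constant feature simulated")
  beta <- setNames(numeric(n_features), fnames)
  beta[names(true_coefficients)] <- true_coefficients
  latent <- as.vector(intercept + X %*% beta + rnorm(n_groups, 0, noise_sd))
  if (any(latent <= 0)) {
    warning("latent odds clipped at 0.01; raise the intercept")
    latent <- pmax(latent, 0.01)
  }
  # balanced complement: odds ratio of the group reduces to its own D/S odds
  D0 <- round(complement_size / 2); S0 <- complement_size - D0
  p <- latent / (1 + latent)
  D <- rbinom(n_groups, count_scale, p)
  S <- count_scale - D
  odds <- (D / S) / (D0 / S0)
  counts <- data.frame(group = rownames(X), gene_count = count_scale,
                       n_pairs = floor(D / 2), D = D, S = S,
                       D_complement = D0, S_complement = S0,
                       stringsAsFactors = FALSE)
  list(features = as.data.frame(X), counts = counts, odds = odds,
       latent_odds = latent,
       truth = list(coefficients = true_coefficients, intercept = intercept,
                    noise_sd = noise_sd))
}
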