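# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, closed form, exhaustive permutation) kept
# separate from the code paths it checks.

# Brute-force tree likelihood and marginal posteriors: sum the joint
# probability over every assignment of states to internal nodes (and to
# missing tips). Only feasible on tiny trees.
enumerate_tree <- function(tree, tip_states, Q, root_prior = NULL) {
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    dupdyn:::expm_ss(Q * tree$edge.length[e])
  })
  free <- c(which(is.na(tip_states)), (n_tip + 1L):n_node)
  fixed <- setdiff(seq_len(n_tip), free)
  grid <- expand.grid(rep(list(seq_len(k)), length(free)))
  lik <- 0
  marg <- matrix(0, n_node, k)
  states <- integer(n_node)
  states[fixed] <- tip_states[fixed] + 1L
  for (g in seq_len(nrow(grid))) {
    states[free] <- as.integer(grid[g, ])
    pr <- root_prior[states[root]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][states[tree$edge[e, 1]], states[tree$edge[e, 2]]]
    }
    lik <- lik + pr
    marg[cbind(seq_len(n_node), states)] <-
      marg[cbind(seq_len(n_node), states)] + pr
  }
  list(lik = lik, posterior = marg / lik)
}

# Exact conditional (central Fisher) 2x2 confidence interval by direct
# inversion of the noncentral hypergeometric distribution.
nchg_pmf <- function(psi, m1, m2, t) {
  k <- max(0, t - m2):min(t, m1)
  logw <- dhyper(k, m1, m2, t, log = TRUE) + k * log(psi)
  logw <- logw - max(logw)
  w <- exp(logw)
  list(k = k, p = w / sum(w))
}
oracle_or_ci <- function(a, b, c, d, conf_level = 0.95) {
  alpha <- (1 - conf_level) / 2
  m1 <- a + b; m2 <- c + d; t <- a + c
  kmin <- max(0, t - m2); kmax <- min(t, m1)
  p_ge <- function(psi) { f <- nchg_pmf(psi, m1, m2, t); sum(f$p[f$k >= a]) }
  p_le <- function(psi) { f <- nchg_pmf(psi, m1, m2, t); sum(f$p[f$k <= a]) }
  lower <- if (a == kmin) 0 else
    uniroot(function(l) p_ge(exp(l)) - alpha, c(-50, 50), tol = 1e-12)$root
  upper <- if (a == kmax) Inf else
    uniroot(function(l) p_le(exp(l)) - alpha, c(-50, 50), tol = 1e-12)$root
  c(if (a == kmin) 0 else exp(lower), if (a == kmax) Inf else exp(upper))
}

# Exhaustive re-pairing oracle for the permutation z-grid: mean cell counts
# over all n! pairings of y against x.
exhaustive_grid_means <- function(x, y, levels_x, levels_y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  ps <- perms(seq_along(y))
  acc <- matrix(0, length(levels_x), length(levels_y))
  for (p in ps) {
    acc <- acc + unclass(table(factor(x, levels_x), factor(y[p], levels_y)))
  }
  acc / length(ps)
}

# small random rooted tree with exponential branch lengths
random_small_tree <- function(n_tips, mean_bl = 0.5) {
  tr <- ape::rtree(n_tips, br = function(n) rexp(n, 1 / mean_bl))
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

# random generator matrix with off-diagonal rates in (0.1, 1)
random_Q <- function(k, type = "ARD") {
  n <- dupdyn:::n_free_rates(k, type)
  build_rate_matrix(runif(n, 0.1, 1), k, type)
}
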