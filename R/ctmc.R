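# Continuous-time Markov model of discrete character evolution on a rooted
# tree: pruning likelihood, ML rate estimation with random restarts, marginal
# ancestral reconstruction, and repeated-restart consensus calling. States
# are 0-based integers (expression quartiles 0..3 or site presence 0/1);
# NA marks a missing/ambiguous tip observation and is marginalized (partial
# likelihood 1 for every state).

#' Build a CTMC rate matrix from a rate vector
#'
#' Three parameterizations are supported, mirroring the usual discrete-trait
#' model hierarchy: `"ER"` (one rate for every transition), `"SYM"`
#' (symmetric, one rate per unordered state pair) and `"ARD"` (all rates
#' distinct). The diagonal is set to minus the row sum so rows sum to zero.
#'
#' @param rates Nonnegative numeric vector: length 1 (ER), k(k-1)/2 (SYM) or
#'   k(k-1) (ARD).
#' @param n_states Number of states k.
#' @param type One of `"ER"`, `"SYM"`, `"ARD"`.
#' @return A k x k generator matrix (rows sum to 0).
#' @export
build_rate_matrix <- function(rates, n_states, type = c("SYM", "ER", "ARD")) {
  type <- match.arg(type)
  k <- n_states
  if (any(rates < 0) || anyNA(rates)) stop("rates must be nonnegative")
  need <- switch(type, ER = 1L, SYM = (k * (k - 1L)) %/% 2L,
                 ARD = k * (k - 1L))
  if (length(rates) != need) {
    stop(sprintf("type %s with %d states needs %d rates, got %d",
                 type, k, need, length(rates)))
  }
  Q <- matrix(0, k, k)
  if (type == "ER") {
    Q[] <- rates[1]
  } else if (type == "SYM") {
    idx <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      idx <- idx + 1L
      Q[i, j] <- Q[j, i] <- rates[idx]
    }
  } else {
    idx <- 0L
    for (i in 1:k) for (j in 1:k) {
      if (i != j) { idx <- idx + 1L; Q[i, j] <- rates[idx] }
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

n_free_rates <- function(n_states, type) {
  switch(type, ER = 1L,
         SYM = (n_states * (n_states - 1L)) %/% 2L,
         ARD = n_states * (n_states - 1L))
}

# Validate the tip-state matrix against the tree and coerce to an integer
# matrix in 0..(k-1) with tips as rows ordered like tree$tip.label.
align_tips <- function(tree, tips, n_states) {
  tips <- as.matrix(tips)
  if (is.null(rownames(tips))) {
    if (nrow(tips) != length(tree$tip.label)) stop("tips rows do not match leaves")
    rownames(tips) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, rownames(tips))
  if (length(missing)) stop("no states for leaves: ", paste(missing, collapse = ", "))
  tips <- tips[tree$tip.label, , drop = FALSE]
  vals <- tips[!is.na(tips)]
  if (length(vals) && (any(vals < 0) || any(vals >= n_states))) {
    stop("tip states outside 0..", n_states - 1)
  }
  storage.mode(tips) <- "integer"
  tips
}

# One post-order pruning pass. Returns per-node partial likelihood arrays and
# the total log-likelihood. Partial likelihoods are rescaled per item to
# avoid underflow; scalers are accumulated in log space.
prune_tree <- function(tree, tips, Q, root_prior = NULL) {
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_item <- ncol(tips)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  dec <- mexp_decompose(Q)

  ord <- reorder(tree, "postorder")
  edges <- ord$edge
  lens <- ord$edge.length

  # transition matrix per edge (row = parent state, col = child state)
  P <- lapply(lens, function(t) clamp01(mexp_at(dec, t)))

  L <- vector("list", n_node)       # k x n_item partial likelihoods
  Msg <- vector("list", nrow(edges))  # message passed up each edge
  logscale <- matrix(0, n_node, n_item)
  for (tip in seq_len(n_tip)) {
    Li <- matrix(0, k, n_item)
    s <- tips[tip, ]
    obs <- !is.na(s)
    Li[cbind(s[obs] + 1L, which(obs))] <- 1
    Li[, !obs] <- 1                  # missing tip: marginalized
    L[[tip]] <- Li
  }
  children_of <- split(seq_len(nrow(edges)), edges[, 1])
  # postorder edge list visits all of a node's subtree before the node
  # appears as a child itself, so parents complete in this order
  for (node in unique(edges[, 1])) {
    eidx <- children_of[[as.character(node)]]
    Li <- matrix(1, k, n_item)
    sc <- numeric(n_item)
    for (e in eidx) {
      child <- edges[e, 2]
      m <- P[[e]] %*% L[[child]]
      Msg[[e]] <- m
      Li <- Li * m
      sc <- sc + logscale[child, ]
    }
    mx <- apply(Li, 2, max)
    mx[mx == 0] <- 1
    L[[node]] <- sweep(Li, 2, mx, "/")
    logscale[node, ] <- sc + log(mx)
  }
  root <- n_tip + 1L
  site_lik <- as.vector(root_prior %*% L[[root]])
  ll <- sum(log(site_lik) + logscale[root, ])
  list(loglik = ll, site_loglik = log(site_lik) + logscale[root, ],
       L = L, Msg = Msg, edges = edges, P = P, logscale = logscale,
       root = root, root_prior = root_prior, k = k, n_item = n_item)
}

#' Log-likelihood of tip states under a CTMC on a tree
#'
#' Felsenstein pruning over all items (conditions or sites) jointly; items
#' are independent given the tree and rates. Missing tips contribute a
#' partial likelihood of 1 in every state.
#'
#' @param tree Rooted `phylo`.
#' @param tips Integer matrix of tip states (rows = leaves, 0-based states,
#'   `NA` = missing).
#' @param Q Generator matrix from [build_rate_matrix()].
#' @param root_prior Prior over root states; default uniform.
#' @return Total log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(tree, tips, Q, root_prior = NULL) {
  tips <- align_tips(tree, tips, nrow(Q))
  prune_tree(tree, tips, Q, root_prior)$loglik
}

#' Fit a CTMC rate model to tip states by maximum likelihood
#'
#' Rates are optimized on the log scale (enforcing positivity) from
#' `n_restarts` random initializations; the best restart is returned.
#' Items whose tips are all missing carry no information and are dropped
#' with a message.
#'
#' @inheritParams tree_loglik
#' @param type Rate parameterization, see [build_rate_matrix()].
#' @param n_restarts Number of random starts.
#' @param n_states Number of states; default inferred from the data (use
#'   explicitly when a state is absent from the tips).
#' @param init_sd Log-scale spread of the random starts.
#' @return An object of class `ctmc_fit` with elements `rates`, `Q`,
#'   `loglik`, `type`, `starts` (per-start results), `tree`, `tips`.
#' @export
fit_rate_model <- function(tree, tips, type = c("SYM", "ER", "ARD"),
                           n_restarts = 5, n_states = NULL,
                           root_prior = NULL, init_sd = 1) {
  type <- match.arg(type)
  tips <- as.matrix(tips)
  if (is.null(n_states)) n_states <- max(tips, na.rm = TRUE) + 1L
  tips <- align_tips(tree, tips, n_states)
  all_missing <- colSums(!is.na(tips)) == 0
  if (any(all_missing)) {
    message("dropping ", sum(all_missing), " item(s) with no observed tips")
    tips <- tips[, !all_missing, drop = FALSE]
  }
  if (ncol(tips) == 0) stop("no informative items")
  p <- n_free_rates(n_states, type)

  # centre the starts on one expected change per unit of total tree length
  r0 <- ncol(tips) / max(sum(tree$edge.length), .Machine$double.eps)
  negll <- function(logr) {
    Q <- build_rate_matrix(exp(logr), n_states, type)
    -prune_tree(tree, tips, Q, root_prior)$loglik
  }
  starts <- vector("list", n_restarts)
  for (s in seq_len(n_restarts)) {
    init <- log(r0) + rnorm(p, 0, init_sd)
    opt <- tryCatch(
      optim(init, negll, method = if (p == 1) "Brent" else "Nelder-Mead",
            lower = if (p == 1) log(r0) - 12 else -Inf,
            upper = if (p == 1) log(r0) + 12 else Inf,
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    starts[[s]] <- opt
  }
  ok <- !vapply(starts, is.null, logical(1))
  if (!any(ok)) stop("all restarts failed")
  lls <- vapply(starts[ok], function(o) -o$value, numeric(1))
  best <- starts[ok][[which.max(lls)]]
  rates <- exp(best$par)
  structure(list(
    rates = rates, type = type, n_states = n_states,
    Q = build_rate_matrix(rates, n_states, type),
    loglik = -best$value, root_prior = root_prior,
    starts = data.frame(restart = which(ok), loglik = lls),
    convergence = best$convergence, tree = tree, tips = tips
  ), class = "ctmc_fit")
}

#' @export
print.ctmc_fit <- function(x, ...) {
  cat("CTMC rate model (", x$type, ", ", x$n_states, " states)\n", sep = "")
  cat("  rates:", format(x$rates, digits = 4), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "over", ncol(x$tips), "items\n")
  invisible(x)
}

#' @export
coef.ctmc_fit <- function(object, ...) object$rates

#' @export
logLik.ctmc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$rates), class = "logLik")
}

#' Marginal ancestral state posteriors
#'
#' For each internal node and item, the marginal posterior over states,
#' integrating over the states of all other internal nodes (up-down
#' algorithm). Posteriors at the root use the model's root prior (uniform by
#' default).
#'
#' @param tree Rooted `phylo`.
#' @param tips Tip-state matrix as in [tree_loglik()].
#' @param model A `ctmc_fit`, or a generator matrix `Q`.
#' @param nodes Internal node numbers (ape numbering, root = Ntip+1); default
#'   all internal nodes.
#' @return A 3-d array nodes x states x items of posterior probabilities,
#'   each node x item slice summing to 1.
#' @export
marginal_ancestral_states <- function(tree, tips, model, nodes = NULL) {
  Q <- if (inherits(model, "ctmc_fit")) model$Q else model
  root_prior <- if (inherits(model, "ctmc_fit")) model$root_prior else NULL
  k <- nrow(Q)
  tips <- align_tips(tree, as.matrix(tips), k)
  pr <- prune_tree(tree, tips, Q, root_prior)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(nodes)) nodes <- (n_tip + 1L):n_node
  if (any(nodes < 1 | nodes > n_node)) stop("node not in tree")

  # pre-order "above" vectors
  A <- vector("list", n_node)
  A[[pr$root]] <- matrix(pr$root_prior, k, pr$n_item)
  edges <- pr$edges
  children_of <- split(seq_len(nrow(edges)), edges[, 1])
  pre <- rev(seq_len(nrow(edges)))  # parents before children
  for (e in pre) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    sib <- setdiff(children_of[[as.character(parent)]], e)
    part <- A[[parent]]
    for (se in sib) part <- part * pr$Msg[[se]]
    A[[child]] <- t(pr$P[[e]]) %*% part
    # rescale per item; posteriors are normalized later
    mx <- apply(A[[child]], 2, max)
    mx[mx == 0] <- 1
    A[[child]] <- sweep(A[[child]], 2, mx, "/")
  }
  out <- array(NA_real_, c(length(nodes), k, pr$n_item),
               dimnames = list(node = nodes, state = 0:(k - 1), item = colnames(tips)))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    post <- A[[v]] * pr$L[[v]]
    tot <- colSums(post)
    tot[tot == 0] <- 1
    out[i, , ] <- sweep(post, 2, tot, "/")
  }
  out
}

#' Consensus ancestral-state calls over repeated restarts
#'
#' The rate model is refit `runs` times from independent random
#' initializations and ancestral states are reconstructed after each fit.
#' A node x item state is called when the same state is the posterior mode
#' in more than `min_support` runs and its average posterior exceeds
#' `posterior_min`; otherwise the call is ambiguous (`NA`) and the item is
#' meant to be excluded downstream. The defaults (100 runs, support > 50,
#' posterior > 0.5) make a call a strict-majority decision twice over.
#'
#' @inheritParams fit_rate_model
#' @param nodes Internal nodes to call; default all.
#' @param runs Number of independent fit+reconstruct replicates.
#' @param min_support Minimum number of supporting runs (strictly greater).
#' @param posterior_min Minimum mean posterior of the modal state (strictly
#'   greater).
#' @return A data frame of class `ancestral_calls` with columns `node`,
#'   `item`, `state` (`NA` when ambiguous), `posterior`, `support`.
#' @export
consensus_ancestral_calls <- function(tree, tips, type = c("SYM", "ER", "ARD"),
                                      n_states = NULL, nodes = NULL,
                                      runs = 100, min_support = 50,
                                      posterior_min = 0.5, init_sd = 1.5) {
  type <- match.arg(type)
  tips <- as.matrix(tips)
  if (is.null(n_states)) n_states <- max(tips, na.rm = TRUE) + 1L
  tips <- align_tips(tree, tips, n_states)
  n_tip <- length(tree$tip.label)
  if (is.null(nodes)) nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  n_item <- ncol(tips)
  items <- colnames(tips)
  if (is.null(items)) items <- as.character(seq_len(n_item))

  mode_count <- array(0L, c(length(nodes), n_states, n_item))
  post_sum <- array(0, c(length(nodes), n_states, n_item))
  for (r in seq_len(runs)) {
    fit <- fit_rate_model(tree, tips, type = type, n_restarts = 1,
                          n_states = n_states, init_sd = init_sd)
    post <- marginal_ancestral_states(tree, tips, fit, nodes = nodes)
    post_sum <- post_sum + post
    for (i in seq_along(nodes)) {
      m <- apply(post[i, , , drop = FALSE], 3, which.max)
      mode_count[cbind(i, m, seq_len(n_item))] <-
        mode_count[cbind(i, m, seq_len(n_item))] + 1L
    }
  }
  res <- expand.grid(node = nodes, item = items, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  res$state <- NA_integer_
  res$posterior <- NA_real_
  res$support <- NA_integer_
  for (i in seq_along(nodes)) for (j in seq_len(n_item)) {
    supp <- mode_count[i, , j]
    modal <- which.max(supp)
    meanpost <- post_sum[i, modal, j] / runs
    row <- (j - 1L) * length(nodes) + i
    res$support[row] <- supp[modal]
    res$posterior[row] <- meanpost
    if (supp[modal] > min_support && meanpost > posterior_min) {
      res$state[row] <- modal - 1L
    }
  }
  attr(res, "runs") <- runs
  attr(res, "min_support") <- min_support
  attr(res, "posterior_min") <- posterior_min
  class(res) <- c("ancestral_calls", "data.frame")
  res
}
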