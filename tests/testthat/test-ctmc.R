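test_that("pruning likelihood and posteriors match exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:12) {
    n_tip <- sample(2:6, 1)
    tr <- random_small_tree(n_tip)
    k <- sample(c(2, 4), 1)
    Q <- random_Q(k, "ARD")
    tips <- matrix(sample(0:(k - 1), n_tip, replace = TRUE), ncol = 1,
                   dimnames = list(tr$tip.label, "i1"))
    if (n_tip > 2 && rep %% 3 == 0) tips[1, 1] <- NA  # exercise missing tips
    oracle <- enumerate_tree(tr, tips[, 1], Q)
    expect_lt(abs(tree_loglik(tr, tips, Q) - log(oracle$lik)), 1e-9)
    nodes <- (n_tip + 1L):(n_tip + tr$Nnode)
    post <- marginal_ancestral_states(tr, tips, Q, nodes = nodes)
    for (i in seq_along(nodes)) {
      expect_lt(max(abs(post[i, , 1] - oracle$posterior[nodes[i], ])), 1e-9)
    }
  }
})

test_that("posteriors are normalized and invariant to leaf order", {
  set.seed(5)
  tr <- random_small_tree(8)
  Q <- random_Q(4, "SYM")
  sim <- simulate_states_on_tree(tr, Q, 30)
  post <- marginal_ancestral_states(tr, sim$tips, Q)
  expect_lt(max(abs(apply(post, c(1, 3), sum) - 1)), 1e-12)

  perm <- sample(nrow(sim$tips))
  ll1 <- tree_loglik(tr, sim$tips, Q)
  ll2 <- tree_loglik(tr, sim$tips[perm, , drop = FALSE], Q)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("unanimous tips give the shared state the top posterior", {
  set.seed(6)
  tr <- ape::stree(6, type = "star")
  tr$edge.length <- rep(0.5, 6)
  tips <- matrix(2L, 6, 1, dimnames = list(tr$tip.label, "i"))
  Q <- build_rate_matrix(0.4, 4, "ER")
  post <- marginal_ancestral_states(tr, tips, Q, nodes = 7L)
  expect_equal(unname(which.max(post[1, , 1])) - 1L, 2L)

  # two leaves, opposite binary states, full symmetry -> (0.5, 0.5)
  tr2 <- read_newick_tree(text = "(A:1,B:1);")
  tips2 <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("A", "B"), "i"))
  post2 <- marginal_ancestral_states(tr2, tips2, build_rate_matrix(0.3, 2, "ER"),
                                     nodes = 3L)
  expect_equal(unname(post2[1, , 1]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("agreement among more tips never lowers the consensus posterior", {
  tr <- ape::stree(6, type = "star")
  tr$edge.length <- rep(0.5, 6)
  Q <- build_rate_matrix(0.4, 2, "ER")
  post_for <- function(n_agree) {
    tips <- matrix(c(rep(1L, n_agree), rep(0L, 6 - n_agree)), 6, 1,
                   dimnames = list(tr$tip.label, "i"))
    marginal_ancestral_states(tr, tips, Q, nodes = 7L)[1, 2, 1]
  }
  ps <- vapply(3:6, post_for, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("ML rate fitting recovers a known symmetric rate", {
  set.seed(77)
  hits <- 0
  for (rep in 1:20) {
    tr <- random_small_tree(16, mean_bl = 0.5)
    Q <- build_rate_matrix(0.5, 2, "ER")
    sim <- simulate_states_on_tree(tr, Q, 500)
    fit <- fit_rate_model(tr, sim$tips, type = "ER", n_restarts = 2)
    if (abs(fit$rates - 0.5) / 0.5 < 0.25) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("no-change data drives fitted rates toward zero", {
  tr <- random_small_tree(8)
  tips <- matrix(1L, 8, 20, dimnames = list(tr$tip.label, NULL))
  set.seed(3)
  fit <- fit_rate_model(tr, tips, type = "ER", n_restarts = 3, n_states = 4)
  expect_lt(fit$rates, 1e-3)
})

test_that("all-missing items are dropped and fully missing data errors", {
  tr <- random_small_tree(5)
  tips <- matrix(c(rep(NA_integer_, 5), sample(0:1, 5, TRUE)), 5, 2,
                 dimnames = list(tr$tip.label, c("gone", "ok")))
  set.seed(4)
  expect_message(fit <- fit_rate_model(tr, tips, type = "ER", n_states = 2,
                                       n_restarts = 2), "dropping 1 item")
  expect_equal(ncol(fit$tips), 1)
  allna <- matrix(NA_integer_, 5, 1, dimnames = list(tr$tip.label, "x"))
  expect_error(suppressMessages(
    fit_rate_model(tr, allna, type = "ER", n_states = 2)), "no informative")
})

test_that("consensus calling is unanimous on clean data and ambiguous on flat data", {
  set.seed(21)
  tr <- random_small_tree(8, mean_bl = 0.3)
  Q <- build_rate_matrix(0.2, 2, "ER")
  sim <- simulate_states_on_tree(tr, Q, 12)
  root <- 9L
  calls <- consensus_ancestral_calls(tr, sim$tips, type = "ER", n_states = 2,
                                     nodes = root, runs = 20, min_support = 10,
                                     posterior_min = 0.5)
  expect_true(all(calls$support <= 20))
  made <- !is.na(calls$state)
  expect_true(any(made))
  expect_true(all(calls$posterior[made] > 0.5))
  expect_true(all(calls$support[made] > 10))

  # perfectly balanced two-leaf case: posterior pinned at 0.5, never called
  tr2 <- read_newick_tree(text = "(A:1,B:1);")
  tips2 <- matrix(c(0L, 1L), 2, 3, dimnames = list(c("A", "B"), NULL))
  calls2 <- consensus_ancestral_calls(tr2, tips2, type = "ER", n_states = 2,
                                      nodes = 3L, runs = 10, min_support = 5)
  expect_true(all(is.na(calls2$state)))
})

test_that("consensus recovers most true ancestral states on simulated trees", {
  set.seed(31)
  correct <- 0; total <- 0
  for (rep in 1:3) {
    tr <- random_small_tree(16, mean_bl = 0.3)
    Q <- build_rate_matrix(0.3, 4, "ER")
    sim <- simulate_states_on_tree(tr, Q, 60)
    root <- 17L
    calls <- consensus_ancestral_calls(tr, sim$tips, type = "ER", n_states = 4,
                                       nodes = root, runs = 30,
                                       min_support = 15, posterior_min = 0.5)
    made <- !is.na(calls$state)
    truth <- sim$ancestors[as.character(root), ]
    correct <- correct + sum(calls$state[made] == truth[made])
    total <- total + sum(made)
  }
  expect_gt(total, 30)
  expect_gte(correct / total, 0.8)
})
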