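test_that("retention odds follow the defining formula with exact intervals", {
  r <- retention_odds(50, 50, 500, 500)
  expect_equal(r$R, 1)
  expect_true(r$lower < 1 && r$upper > 1)
  r2 <- retention_odds(30, 10, 400, 600)
  expect_equal(r2$R, 4.5)
  expect_true(r2$lower <= 4.5 && r2$upper >= 4.5)
  expect_warning(retention_odds(10, 0, 50, 50), "zero singleton")
})

test_that("confidence intervals match an independent conditional inversion", {
  set.seed(29)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, lambda = sample(c(20, 60, 150), 1)) + 1, 2, 2)
    got <- retention_odds(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ora <- oracle_or_ci(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got$lower, ora[1], tolerance = 1e-6)
    expect_equal(got$upper, ora[2], tolerance = 1e-6)
    # cross-check against fisher.test at its looser root tolerance
    ft <- fisher.test(tab)
    expect_equal(got$lower, ft$conf.int[1], tolerance = 1e-3)
    expect_equal(got$upper, ft$conf.int[2], tolerance = 1e-3)
  }
})

test_that("a group and its complement have reciprocal odds", {
  set.seed(31)
  for (rep in 1:10) {
    cc <- rpois(4, 80) + 1
    a <- retention_odds(cc[1], cc[2], cc[3], cc[4])$R
    b <- retention_odds(cc[3], cc[4], cc[1], cc[2])$R
    expect_equal(a * b, 1, tolerance = 1e-12)
  }
})

test_that("group filtering applies the inclusive size and pair bounds", {
  g <- data.frame(group = c("a", "b", "c", "d", "e"),
                  gene_count = c(99, 100, 1500, 2000, 2001),
                  n_pairs = c(30, 20, 19, 25, 30))
  kept <- suppressMessages(filter_groups(g))
  expect_equal(kept$group, c("b", "d"))
})

test_that("feature prefiltering breaks correlated clusters by the stated priorities", {
  set.seed(37)
  n <- 20
  f1 <- runif(n)
  feats <- data.frame(f1 = f1, f1copy = f1, f2 = runif(n), f3 = runif(n))
  odds <- 2 + f1 + rnorm(n, 0, 0.05)
  kept <- prefilter_features(feats, odds)
  expect_true(xor("f1" %in% kept, "f1copy" %in% kept))
  expect_true(all(c("f2", "f3") %in% kept))

  # independent features all survive the 0.7 threshold
  ind <- as.data.frame(matrix(runif(20 * 6), 20))
  expect_setequal(prefilter_features(ind, runif(20)), names(ind))
  cm <- abs(cor(ind)); diag(cm) <- 0
  expect_true(max(cm) < 0.7)  # oracle: nothing to prune at n = 20 here

  # derived features lose against equally-correlated parents
  f <- runif(n)
  feats2 <- data.frame(parent = f, child = f, other = runif(n))
  kept2 <- prefilter_features(feats2, odds = f,
                              derived = c(FALSE, TRUE, FALSE))
  expect_true("parent" %in% kept2)
  expect_false("child" %in% kept2)

  # missing-heavy features are removed
  feats3 <- data.frame(good = runif(n), bad = ifelse(runif(n) < 0.88, NA, 1))
  expect_message(kept3 <- suppressWarnings(
    prefilter_features(feats3, odds)), "missing values")
  expect_false("bad" %in% kept3)

  expect_warning(prefilter_features(data.frame(a = rep(1, n), b = runif(n),
                                               c = runif(n)), odds),
                 "constant")
})

test_that("backward elimination recovers the informative features", {
  set.seed(41)
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_group_feature_table(n_groups = 20, n_features = 11,
                                        true_coefficients = c(f1 = 1.5, f2 = -0.8),
                                        noise_sd = 0.05, seed = 1000 + s)
    fit <- fit_retention_model(sim$features, sim$odds)
    if (setequal(fit$selected, c("f1", "f2")) && fit$r_squared > 0.9) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("degenerate responses and perfect predictors are handled", {
  X <- data.frame(f1 = runif(15), f2 = runif(15))
  flat <- fit_retention_model(X, rep(2, 15))
  expect_length(flat$selected, 0)
  expect_equal(flat$r_squared, 0)

  y <- 1 + 2 * X$f1
  perfect <- suppressWarnings(fit_retention_model(data.frame(f1 = X$f1, junk = X$f2), y))
  expect_equal(perfect$selected, "f1")
  expect_equal(perfect$r_squared, 1, tolerance = 1e-9)

  # noise-free generative data: coefficients recovered to 1e-6
  sim <- simulate_group_feature_table(noise_sd = 0, count_scale = 2e6,
                                      complement_size = 2e6, seed = 5)
  fit <- suppressWarnings(fit_retention_model(sim$features, sim$latent_odds))
  expect_setequal(fit$selected, c("f1", "f2"))
  expect_equal(unname(fit$coefficients[c("f1", "f2")]), c(1.5, -0.8),
               tolerance = 1e-6)

  # elimination never ends below the full model's F
  set.seed(43)
  sim2 <- simulate_group_feature_table(seed = 77)
  fit2 <- fit_retention_model(sim2$features, sim2$odds)
  expect_gte(fit2$f_statistic, fit2$path$f_statistic[1])
})

test_that("aliased designs drop the duplicated column with a warning", {
  set.seed(47)
  f <- runif(15)
  X <- data.frame(f1 = f, f2 = f, f3 = runif(15))
  y <- 2 + f + rnorm(15, 0, 0.01)
  expect_warning(fit <- fit_retention_model(X, y), "aliased")
  expect_true("f1" %in% fit$selected || "f2" %in% fit$selected)
})

test_that("leave-one-out dispersion equals brute-force refits", {
  set.seed(53)
  sim <- simulate_group_feature_table(n_groups = 18, n_features = 6,
                                      seed = 9)
  loo <- leave_one_out_robustness(sim$features, sim$odds)
  # brute force: refit manually for each omission
  for (i in c(1, 7, 18)) {
    ref <- fit_retention_model(sim$features[-i, ], sim$odds[-i])
    expect_equal(loo$fits[[i]]$coefficients, ref$coefficients)
  }
  est <- loo$estimates
  expect_equal(loo$parameters$sd,
               unname(apply(est, 2, sd, na.rm = TRUE)))

  # duplicated groups: omitting one copy changes nothing
  X2 <- rbind(sim$features, sim$features)
  o2 <- c(sim$odds, sim$odds)
  loo2 <- leave_one_out_robustness(X2, o2, groups = as.character(1:36))
  sel <- loo2$parameters[loo2$parameters$parameter %in% loo2$full$selected, ]
  expect_true(all(sel$rel_sd < 0.05))
  expect_length(loo2$changed, 0)
})
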