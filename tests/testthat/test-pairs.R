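test_that("pair-item classification follows the O/I/II definition", {
  expect_equal(classify_pair_item(2, 2, 2), "O")
  expect_equal(classify_pair_item(3, 3, 1), "I")
  expect_equal(classify_pair_item(1, 0, 3), "II")
  expect_equal(classify_pair_item(NA, 1, 1), NA_character_)

  # exactly one class for every state combination
  grid <- expand.grid(anc = 0:3, a = 0:3, b = 0:3)
  cls <- classify_pair_item(grid$anc, grid$a, grid$b)
  expect_true(all(cls %in% c("O", "I", "II")))
  manual <- with(grid, (a == anc) + (b == anc))
  expect_equal(cls, c("II", "I", "O")[manual + 1])

  out <- classify_pairs(c("p1", "p1", "p2"), c("c1", "c2", "c1"),
                        c(2, 3, NA), c(2, 3, 1), c(2, 1, 1))
  expect_equal(nrow(out), 2)   # NA ancestor dropped item-wise
  expect_equal(out$class, c("O", "I"))
  expect_equal(out$retained_by, c("both", "A"))
})

test_that("deviation records order copies by extant quartile", {
  d <- deviation_records("p1", "c1", ancestral = 1, stateA = 0, stateB = 3)
  expect_equal(d$dev1, 2)   # higher copy first
  expect_equal(d$dev2, -1)
  expect_true(all(d$dev1 >= d$dev2))
  set.seed(2)
  anc <- sample(0:3, 50, TRUE); a <- sample(0:3, 50, TRUE); b <- sample(0:3, 50, TRUE)
  dd <- deviation_records(seq_len(50), "c", anc, a, b)
  expect_true(all(dd$dev1 >= dd$dev2))
  expect_true(all(dd$dev1 >= -3 & dd$dev1 <= 3))
})

test_that("permutation z-grid is centred, deterministic, and matches enumeration", {
  set.seed(19)
  x <- sample(0:3, 200, replace = TRUE)
  y <- sample(0:3, 200, replace = TRUE)
  g <- permutation_zscores(x, y, n_perm = 500)
  expect_equal(sum(g$observed), 200)
  # each replicate redistributes the same totals
  expect_equal(sum(g$mean), 200, tolerance = 1e-9)

  set.seed(42); g1 <- permutation_zscores(x, y, n_perm = 200)
  set.seed(42); g2 <- permutation_zscores(x, y, n_perm = 200)
  expect_identical(g1$z, g2$z)

  # 4 genes: Monte Carlo cell means against all 4! pairings
  x4 <- c(0, 1, 1, 2); y4 <- c(2, 0, 1, 1)
  exact <- exhaustive_grid_means(x4, y4, 0:2, 0:2)
  set.seed(7)
  mc <- permutation_zscores(x4, y4, n_perm = 10000, levels_x = 0:2,
                            levels_y = 0:2)
  se <- pmax(mc$sd / sqrt(mc$n_perm), 1e-6)
  expect_true(all(abs(mc$mean - exact) <= 3 * se + 1e-9))

  expect_error(permutation_zscores(NA, NA), "empty pool")
  expect_error(permutation_zscores(x, y, n_perm = 10), "at least 100")
})

test_that("pair-state summary finds partitioning excess only when simulated", {
  set.seed(23)
  # degenerate: everything retained
  allret <- data.frame(pair = rep(paste0("p", 1:10), each = 4),
                       item = rep(paste0("c", 1:4), 10),
                       retA = TRUE, retB = TRUE)
  s0 <- pair_expression_summary(allret, n_rep = 100)
  expect_equal(unname(s0$observed), c(1, 0, 0))
  expect_equal(unname(s0$expected), c(1, 0, 0))

  # coupled fast-first/slow-second loss: partitioned excess
  sim <- simulate_pair_items(500, 20, mode = "pair",
                             rates = c(x = 1.5, y = 0, w = 0.05, z = 0),
                             seed = 101)
  s1 <- pair_expression_summary(sim$retention, n_rep = 300)
  expect_gt(s1$z["I"], 2)

  # independent loss with exchangeable pairs (common divergence time):
  # z calibrated near zero
  zs <- vapply(1:10, function(i) {
    sim0 <- simulate_pair_items(300, 15, mode = "independent",
                                loss_rate = 0.6,
                                ds_sampler = function(n) rep(0.7, n),
                                seed = 200 + i)
    pair_expression_summary(sim0$retention, n_rep = 200)$z["I"]
  }, numeric(1))
  expect_gte(mean(abs(zs) < 2), 0.9)

  expect_error(pair_expression_summary(allret[allret$pair == "p1", ]),
               "at least 2")
})

test_that("novel-site counting and the excess tests behave", {
  anc <- rbind(c(1, 0, 0, NA), c(1, 1, 0, 0))
  A <- rbind(c(1, 1, 0, 1), c(1, 0, 1, 0))
  B <- rbind(c(0, 1, 1, 1), c(1, 1, 0, 0))
  cnt <- novel_site_counts(anc, A, B, ancestral_copy = c("A", "B"))
  # pair 1: A retains site1, novel at site2 (anc 0); site4 ambiguous skipped
  expect_equal(cnt$novel_ancestral[1], 1)      # copy A is ancestral
  expect_equal(cnt$novel_nonancestral[1], 2)   # B: sites 2 and 3
  expect_equal(cnt$retained_ancestral_copy[1], 1)
  # pair 2: B ancestral (retains sites 1 and 2), A has novel site3
  expect_equal(cnt$novel_nonancestral[2], 1)
  expect_equal(cnt$novel_ancestral[2], 0)

  simple <- data.frame(novel_ancestral = 0, novel_nonancestral = 3,
                       retained_ancestral_copy = 2,
                       retained_nonancestral_copy = 1)
  out <- novel_site_analysis(simple)
  expect_equal(out$difference, 3)

  balanced <- data.frame(novel_ancestral = 10, novel_nonancestral = 10,
                         retained_ancestral_copy = 10,
                         retained_nonancestral_copy = 10)
  expect_equal(novel_site_analysis(balanced)$table,
               matrix(10, 2, 2), ignore_attr = TRUE)
  # conditional odds ratio of a balanced table is 1
  expect_equal(novel_site_analysis(balanced)$odds_ratio, 1, tolerance = 1e-6)

  # pairs without novel sites are excluded from the sign test
  mix <- data.frame(novel_ancestral = c(0, 0, 1), novel_nonancestral = c(0, 2, 3),
                    retained_ancestral_copy = 1, retained_nonancestral_copy = 1)
  res <- novel_site_analysis(mix)
  expect_equal(res$n_pairs_with_novel, 2)
  expect_equal(res$n_nonancestral_excess, 2)
})

test_that("the exact binomial sign test matches the binomial tail sum", {
  p <- binom.test(177, 249, p = 0.5, alternative = "greater")$p.value
  # independent oracle: direct upper-tail sum of the Binomial(249, 1/2) pmf
  expect_equal(p, sum(choose(249, 177:249) * 0.5^249), tolerance = 1e-12)
  expect_lt(p, 1e-10)
  # the analysis path computes the same number
  counts <- data.frame(
    novel_ancestral = c(rep(0, 177), rep(2, 72)),
    novel_nonancestral = c(rep(1, 177), rep(0, 72)),
    retained_ancestral_copy = 1, retained_nonancestral_copy = 1)
  expect_equal(novel_site_analysis(counts)$p_sign, p)
})
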