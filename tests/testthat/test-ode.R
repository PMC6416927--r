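test_that("analytic solutions match adaptive numerical integration", {
  skip_if_not_installed("deSolve")
  set.seed(55)
  for (rep in 1:100) {
    rates <- setNames(runif(4, 0, 2), c("x", "y", "w", "z"))
    model <- if (rep %% 2 == 0) "pair" else "single"
    sys <- ode_system(rates, model)
    ts <- sort(runif(8, 0, 5))
    ana <- ode_solution(sys, ts)
    num <- deSolve::ode(y = sys$init, times = c(0, ts),
                        func = function(t, y, p) list(sys$A %*% y),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(ana - num[-1, -1])), 1e-7)
    expect_lt(max(abs(rowSums(ana) - 1)), 1e-10)
    expect_true(all(ana >= 0 & ana <= 1))
  }
})

test_that("closed forms and degenerate systems behave", {
  sys <- ode_system(c(x = 1, y = 0, w = 0, z = 0), "pair")
  expect_equal(as.vector(ode_solution(sys, 0)), c(1, 0, 0))
  ts <- c(0.3, log(2), 2.5)
  sol <- ode_solution(sys, ts)
  expect_equal(sol[, "O"], exp(-ts), tolerance = 1e-10)
  expect_equal(unname(sol[2, ]), c(0.5, 0.5, 0), tolerance = 1e-10)

  frozen <- ode_system(c(x = 0, y = 0, w = 0, z = 0), "pair",
                       init = c(0.2, 0.5, 0.3))
  expect_equal(ode_solution(frozen, c(1, 10, 100)),
               matrix(c(0.2, 0.5, 0.3), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(ode_solution(sys, -1), "nonnegative")
})

test_that("solutions approach the generator's stationary distribution", {
  set.seed(66)
  for (rep in 1:10) {
    rates <- setNames(runif(4, 0.2, 1.5), c("x", "y", "w", "z"))
    sys <- ode_system(rates, "pair")
    pi_inf <- ode_stationary(sys)
    expect_lt(max(abs(ode_solution(sys, 400)[1, ] - pi_inf)), 1e-8)
  }
})

test_that("the two generators conserve mass and carry the printed structure", {
  rates <- c(x = 0.7, y = 0.2, w = 0.4, z = 0.1)
  Ap <- ode_system(rates, "pair")$A
  expect_equal(unname(Ap), matrix(c(-0.7, 0.2, 0, 0.7, -0.6, 0.1, 0, 0.4, -0.1),
                                  3, 3, byrow = TRUE))
  As <- ode_system(rates, "single")$A
  expect_equal(max(abs(colSums(Ap))), 0)
  expect_equal(max(abs(colSums(As))), 0)
  # single-copy: x feeds +, y feeds -, w and z flow back to O
  expect_equal(unname(As[2, 1]), 0.7)
  expect_equal(unname(As[3, 1]), 0.2)
  expect_equal(unname(As[1, 2]), 0.4)
  expect_equal(unname(As[1, 3]), 0.1)
})

test_that("categorical MLE recovers known pair-model rates", {
  set.seed(88)
  hits_x <- 0; hits_w <- 0; reject <- 0
  truth <- c(x = 0.9, y = 0.05, w = 0.12, z = 0.02)
  for (rep in 1:5) {
    fates <- simulate_pair_fates(c(1700, 1700, 1600), truth,
                                 ds_samplers = list(
                                   alpha = function(n) runif(n, 0.5, 3),
                                   beta = function(n) runif(n, 0.5, 3),
                                   gamma = function(n) runif(n, 0.5, 3)))
    fit4 <- fit_ode(fates$class, fates$ds, variant = "four", n_starts = 8)
    if (abs(fit4$rates["x"] - truth["x"]) / truth["x"] < 0.2) hits_x <- hits_x + 1
    if (abs(fit4$rates["w"] - truth["w"]) / truth["w"] < 0.2) hits_w <- hits_w + 1
    fit1 <- fit_ode(fates$class, fates$ds, variant = "one", n_starts = 6)
    lrt <- likelihood_ratio_test(fit1, fit4)
    if (lrt$p.value < 0.05) reject <- reject + 1
  }
  expect_gte(hits_x, 4)
  expect_gte(hits_w, 4)
  expect_equal(reject, 5)
})

test_that("the optimizer beats a coarse grid search", {
  set.seed(99)
  for (rep in 1:10) {
    truth <- setNames(runif(4, 0.05, 1), c("x", "y", "w", "z"))
    fates <- simulate_pair_fates(c(150, 150, 150), truth)
    fit <- fit_ode(fates$class, fates$ds, variant = "four", n_starts = 8)
    grid <- expand.grid(x = c(0.1, 0.5, 1), y = c(0.1, 0.5, 1),
                        w = c(0.1, 0.5, 1), z = c(0.1, 0.5, 1))
    grid_ll <- apply(grid, 1, function(r) {
      ode_loglik(ode_system(unlist(r), "pair"), fates$class, fates$ds)
    })
    expect_gte(fit$loglik, max(grid_ll) - 1e-6)
  }
})

test_that("degenerate and impossible data are flagged", {
  set.seed(12)
  # all O at tiny times: loss rate hits the zero boundary
  fit <- fit_ode(rep("O", 50), runif(50, 0.01, 0.05), variant = "one",
                 n_starts = 4)
  expect_true(any(fit$boundary))

  frozen <- ode_system(c(x = 0, y = 0, w = 0, z = 0), "pair")
  expect_equal(ode_loglik(frozen, rep("O", 5), 1:5), 0)
  expect_identical(ode_loglik(frozen, c("O", "I"), c(1, 2)), -Inf)
  expect_error(ode_loglik(frozen, c("O", "I"), c(1, 2),
                          error_impossible = TRUE), "impossible")
})

test_that("likelihood ratio tests follow the chi-square reference", {
  f1 <- structure(list(n = 100, model = "pair", df = 1, loglik = -500,
                       variant = "one", groups = dupdyn:::variant_groups("one")),
                  class = "ode_fit")
  f4 <- structure(list(n = 100, model = "pair", df = 4, loglik = -497.1,
                       variant = "four", groups = dupdyn:::variant_groups("four")),
                  class = "ode_fit")
  lrt <- likelihood_ratio_test(f1, f4)
  expect_equal(lrt$statistic, 5.8, tolerance = 1e-12)
  expect_equal(lrt$df, 3)
  expect_equal(lrt$p.value, pchisq(5.8, 3, lower.tail = FALSE))

  # df-1 arithmetic oracle: 2*2.9 = 5.8, p ~ 0.016
  f2 <- structure(list(n = 100, model = "pair", df = 2, loglik = -497.1,
                       variant = "two", groups = dupdyn:::variant_groups("two")),
                  class = "ode_fit")
  expect_error(likelihood_ratio_test(f2, f1), "more free")
  lrt2 <- likelihood_ratio_test(f1, f2)
  expect_equal(lrt2$df, 1)
  expect_equal(lrt2$p.value, 0.0160, tolerance = 1e-2)

  same <- likelihood_ratio_test(
    f1, structure(list(n = 100, model = "pair", df = 4, loglik = -500,
                       variant = "four",
                       groups = dupdyn:::variant_groups("four")),
                  class = "ode_fit"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("single-copy fits recover symmetric and asymmetric loss direction", {
  set.seed(123)
  sim_single <- function(n, rates) {
    ts <- runif(n, 0.3, 2.5)
    sys <- ode_system(rates, "single")
    pmat <- ode_solution(sys, ts)
    states <- apply(pmat, 1, function(p) sample(c("O", "+", "-"), 1, prob = p))
    data.frame(state = states, t = ts)
  }
  # symmetric truth: fitted up/down rates close
  d <- sim_single(5000, c(x = 0.4, y = 0.4, w = 0.2, z = 0.2))
  fit <- fit_single_copy_model(d$state, d$t, variant = "two", n_starts = 8)
  ratio <- fit$rates["y"] / fit$rates["x"]
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)

  # 3x downward bias
  hits <- 0
  for (rep in 1:5) {
    d <- sim_single(5000, c(x = 0.2, y = 0.6, w = 0.2, z = 0.6))
    fit <- fit_single_copy_model(d$state, d$t, variant = "two", n_starts = 8)
    r <- unname(fit$rates["y"] / fit$rates["x"])
    if (r >= 2 && r <= 4.5) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
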