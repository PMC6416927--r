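# Three-state kinetic models of ancestral-state loss. Two systems share one
# machinery:
#
#  * pair model   — states (O, I, II): both, one, or neither duplicate of a
#    WGD pair retains the ancestral state. d/dt p = A p with
#        A = [ -x    y    0  ]
#            [  x  -(y+w) z  ]
#            [  0    w   -z  ]
#    so x: O->I, y: I->O, w: I->II, z: II->I.
#
#  * single-copy model — states (O, +, -): an extant copy retains the
#    ancestral expression quartile, sits above it, or below it. The
#    mass-conserving generator is
#        A = [ -(x+y)  w   z  ]
#            [   x    -w   0  ]
#            [   y     0  -z  ]
#    so x: O->+, y: O->-, w: +->O, z: -->O. (A published variant of this
#    matrix carries a sign error in its third row that breaks conservation;
#    the conserving form is used here.)
#
# Columns sum to zero, so the state vector keeps its total mass; solutions
# are computed analytically by eigen-decomposition.

ode_generator <- function(rates, model = c("pair", "single")) {
  model <- match.arg(model)
  x <- rates[["x"]]; y <- rates[["y"]]; w <- rates[["w"]]; z <- rates[["z"]]
  if (any(c(x, y, w, z) < 0)) stop("rates must be nonnegative")
  if (model == "pair") {
    matrix(c(-x,      y,       0,
              x, -(y + w),     z,
              0,      w,      -z), 3, 3, byrow = TRUE,
           dimnames = list(c("O", "I", "II"), c("O", "I", "II")))
  } else {
    matrix(c(-(x + y),  w,  z,
               x,      -w,  0,
               y,       0, -z), 3, 3, byrow = TRUE,
           dimnames = list(c("O", "+", "-"), c("O", "+", "-")))
  }
}

#' Define a three-state kinetic system
#'
#' @param rates Named numeric vector with entries `x`, `y`, `w`, `z` (all
#'   nonnegative); see the model descriptions in [ode_solution()].
#' @param model `"pair"` for the duplicate-pair states (O, I, II) or
#'   `"single"` for the single-copy states (O, +, -).
#' @param init Initial state frequencies at t = 0; default `c(1, 0, 0)`
#'   (everything starts with the ancestral state retained).
#' @return An object of class `ode_system`.
#' @export
ode_system <- function(rates, model = c("pair", "single"),
                       init = c(1, 0, 0)) {
  model <- match.arg(model)
  rates <- rates[c("x", "y", "w", "z")]
  if (anyNA(rates)) stop("rates must be a named vector with x, y, w, z")
  if (length(init) != 3 || any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    stop("init must be 3 nonnegative frequencies summing to 1")
  }
  A <- ode_generator(rates, model)
  structure(list(rates = rates, model = model, init = init, A = A,
                 dec = mexp_decompose(A),
                 states = rownames(A)),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("Three-state kinetic system (", x$model, " model)\n", sep = "")
  cat("  rates: ", paste(names(x$rates), format(unname(x$rates), digits = 4),
                         sep = "=", collapse = ", "), "\n")
  cat("  states:", paste(x$states, collapse = ", "),
      " init:", paste(format(x$init), collapse = "/"), "\n")
  invisible(x)
}

#' State frequencies of a three-state kinetic system at given times
#'
#' Solves d/dt p = A p analytically (matrix exponential via
#' eigen-decomposition, with a series fallback for repeated eigenvalues).
#'
#' @param system An [ode_system()].
#' @param t Nonnegative time(s); for duplicate pairs, synonymous divergence
#'   d_s is the usual time proxy.
#' @return A `length(t)` x 3 matrix of state frequencies; rows sum to 1.
#' @export
ode_solution <- function(system, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  out <- mexp_action(system$dec, system$init, t)
  out <- clamp01(out, tol = 1e-7)
  colnames(out) <- system$states
  rownames(out) <- NULL
  out
}

# Constraint variants: a variant maps a short free-parameter vector onto the
# full (x, y, w, z). The groupings follow the usual notation for these
# models: "one" ties all four, "two" ties x=y and w=z for the pair model and
# the +-side (x, w) vs --side (y, z) rates for the single-copy model, "four"
# leaves all free. Custom groupings can be given as a list of character
# vectors partitioning c("x","y","w","z").
variant_groups <- function(variant, model = "pair") {
  if (is.list(variant)) {
    if (!setequal(unlist(variant), c("x", "y", "w", "z"))) {
      stop("custom groups must partition x, y, w, z")
    }
    return(variant)
  }
  switch(variant,
         one = list(c("x", "y", "w", "z")),
         two = if (model == "pair") list(c("x", "y"), c("w", "z"))
               else list(c("x", "w"), c("y", "z")),
         four = list("x", "y", "w", "z"),
         stop("unknown variant: ", variant))
}

expand_rates <- function(free, groups) {
  rates <- numeric(4)
  names(rates) <- c("x", "y", "w", "z")
  for (i in seq_along(groups)) rates[groups[[i]]] <- free[i]
  rates
}

#' Fit a three-state kinetic model to observed states by maximum likelihood
#'
#' Each observation is a categorical draw from the model's state frequencies
#' at its own time point: log L = sum over observations of
#' log p_state(t = d_s). Rates are optimized on the log scale from
#' `n_starts` random initializations and the best start is returned.
#'
#' @param state Factor/character of observed states: `O`, `I`, `II` for the
#'   pair model; `O`, `+`, `-` for the single-copy model.
#' @param time Positive times (d_s) aligned with `state`.
#' @param variant `"one"`, `"two"`, `"four"`, or a list of character vectors
#'   grouping `x`, `y`, `w`, `z` into tied sets.
#' @param model `"pair"` or `"single"`.
#' @param init Initial condition at t = 0; default `c(1, 0, 0)`.
#' @param n_starts Random restarts for the optimizer.
#' @param boundary_tol Rates below this are flagged as boundary estimates.
#' @return Object of class `ode_fit`: `rates` (full x, y, w, z), `free`
#'   (free parameters), `loglik`, `df`, `variant`, `groups`, `model`,
#'   `starts`, `boundary` flags, and the data.
#' @export
fit_ode <- function(state, time, variant = "four",
                    model = c("pair", "single"), init = c(1, 0, 0),
                    n_starts = 20, boundary_tol = 1e-4) {
  model <- match.arg(model)
  states <- if (model == "pair") c("O", "I", "II") else c("O", "+", "-")
  state <- as.character(state)
  if (!all(state %in% states)) {
    stop("states must be in {", paste(states, collapse = ", "), "}")
  }
  if (length(state) < 10) stop("need at least 10 observations")
  if (length(time) != length(state) || any(time <= 0)) {
    stop("time must be positive and aligned with state")
  }
  groups <- variant_groups(variant, model)
  p <- length(groups)
  sidx <- match(state, states)

  negll <- function(logf) {
    rates <- expand_rates(exp(logf), groups)
    sys <- ode_system(rates, model, init)
    pmat <- ode_solution(sys, time)
    pr <- pmat[cbind(seq_along(time), sidx)]
    -sum(log(pmax(pr, 1e-300)))
  }
  r0 <- 1 / stats::median(time)
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    initpar <- log(r0) + rnorm(p, 0, 1.25)
    starts[[s]] <- tryCatch(
      if (p == 1) {
        optim(initpar, negll, method = "Brent",
              lower = log(r0) - 15, upper = log(r0) + 15,
              control = list(maxit = 3000))
      } else {
        optim(initpar, negll, method = "Nelder-Mead",
              control = list(maxit = 3000, reltol = 1e-10))
      },
      error = function(e) NULL)
  }
  ok <- which(!vapply(starts, is.null, logical(1)))
  if (!length(ok)) stop("all optimizer starts failed; data may be degenerate")
  lls <- vapply(starts[ok], function(o) -o$value, numeric(1))
  if (!any(is.finite(lls))) {
    stop("likelihood is -Inf for every start: observed states are ",
         "impossible under this model/initial condition")
  }
  best <- starts[ok][[which.max(lls)]]
  if (p > 1) {
    # polish: restart the simplex at the best point until it stops improving
    repeat {
      re <- optim(best$par, negll, method = "Nelder-Mead",
                  control = list(maxit = 3000, reltol = 1e-10))
      if (re$value > best$value - 1e-8) break
      best <- re
    }
  }
  free <- exp(best$par)
  names(free) <- vapply(groups, paste, "", collapse = "=")
  rates <- expand_rates(free, groups)
  # boundary estimates are legitimate but chi-square LRT calibration is only
  # approximate there, so they are flagged on the fit object
  boundary <- rates < boundary_tol
  structure(list(
    rates = rates, free = free, loglik = -best$value, df = p,
    variant = if (is.list(variant)) "custom" else variant,
    groups = groups, model = model, init = init,
    boundary = boundary, convergence = best$convergence,
    starts = data.frame(start = ok, loglik = lls),
    n = length(state), data = data.frame(state = state, time = time)
  ), class = "ode_fit")
}

#' Log-likelihood of observed states under a fixed three-state system
#'
#' Evaluates the categorical log-likelihood sum log p_state(t) at fixed
#' rates. Observations that are impossible under the system (zero
#' probability at their time) make the log-likelihood `-Inf`; set
#' `error_impossible = TRUE` to raise an error instead.
#'
#' @param system An [ode_system()].
#' @param state,time Observations as in [fit_ode()].
#' @param error_impossible Error out on probability-zero observations.
#' @return Log-likelihood scalar (possibly `-Inf`).
#' @export
ode_loglik <- function(system, state, time, error_impossible = FALSE) {
  states <- system$states
  sidx <- match(as.character(state), states)
  if (anyNA(sidx)) stop("states must be in {", paste(states, collapse = ", "), "}")
  pmat <- ode_solution(system, time)
  pr <- pmat[cbind(seq_along(time), sidx)]
  if (any(pr <= 0)) {
    if (error_impossible) {
      stop("observation(s) impossible under this system: state ",
           paste(unique(state[pr <= 0]), collapse = ", "),
           " has probability 0 at the observed time")
    }
    return(-Inf)
  }
  sum(log(pr))
}

#' Fit the single-copy expression-deviation model
#'
#' Convenience wrapper around [fit_ode()] with `model = "single"`: extant
#' copies are classified relative to their inferred ancestral expression
#' quartile as retaining it (`O`), above it (`+`) or below it (`-`). In the
#' two-parameter variant the O->+ and O->- rates differ, so the fitted
#' `y/x` ratio measures the bias toward losing expression downward.
#'
#' @inheritParams fit_ode
#' @param direction Observed states `O`, `+`, `-`.
#' @return An `ode_fit`.
#' @export
fit_single_copy_model <- function(direction, time, variant = "two",
                                  init = c(1, 0, 0), n_starts = 20) {
  fit_ode(direction, time, variant = variant, model = "single",
          init = init, n_starts = n_starts)
}

#' @export
print.ode_fit <- function(x, ...) {
  cat("Three-state kinetic fit (", x$model, " model, ",
      x$variant, "-parameter variant)\n", sep = "")
  cat("  rates: ", paste(names(x$rates), format(unname(x$rates), digits = 4),
                         sep = "=", collapse = ", "), "\n")
  if (any(x$boundary)) {
    cat("  note: rate(s)", paste(names(x$rates)[x$boundary], collapse = ", "),
        "at the zero boundary\n")
  }
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "(", x$df, "free parameter(s),", x$n, "observations )\n")
  invisible(x)
}

#' @export
coef.ode_fit <- function(object, ...) object$rates

#' @export
logLik.ode_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
predict.ode_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- sort(unique(object$data$time))
  sys <- ode_system(object$rates, object$model, object$init)
  cbind(t = t, ode_solution(sys, t))
}

#' Simulate observations from a fitted three-state model
#' @param object An `ode_fit`.
#' @param nsim Number of replicate data sets.
#' @param seed Optional RNG seed.
#' @param time Times to simulate at; defaults to the fitted data's times.
#' @param ... Unused.
#' @export
simulate.ode_fit <- function(object, nsim = 1, seed = NULL, time = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(time)) time <- object$data$time
  sys <- ode_system(object$rates, object$model, object$init)
  pmat <- ode_solution(sys, time)
  states <- sys$states
  reps <- lapply(seq_len(nsim), function(i) {
    s <- apply(pmat, 1, function(p) sample(states, 1, prob = pmax(p, 0)))
    data.frame(state = s, time = time)
  })
  if (nsim == 1) reps[[1]] else reps
}

#' Likelihood-ratio test between nested kinetic model fits
#'
#' @param fit_null,fit_alt `ode_fit` objects on the same data, with the null
#'   variant nested in the alternative (its tied-rate groups refine the
#'   null's).
#' @return Object of class `ode_lrt`: `statistic` (2 delta lnL), `df`, and
#'   chi-square upper-tail `p.value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  if (fit_null$n != fit_alt$n || fit_null$model != fit_alt$model) {
    stop("fits must be on the same data and model")
  }
  if (fit_alt$df <= fit_null$df) stop("alternative must have more free parameters")
  # nesting: every alternative group must lie inside one null group
  nested <- all(vapply(fit_alt$groups, function(g) {
    any(vapply(fit_null$groups, function(h) all(g %in% h), logical(1)))
  }, logical(1)))
  if (!nested) stop("variants are not nested")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-6) {
    warning("alternative fit has lower likelihood than the null; refit with ",
            "more starts")
  }
  stat <- max(stat, 0)
  df <- fit_alt$df - fit_null$df
  structure(list(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 null = fit_null$variant, alt = fit_alt$variant),
            class = "ode_lrt")
}

#' @export
print.ode_lrt <- function(x, ...) {
  cat("Likelihood ratio test: ", x$alt, " vs ", x$null, " variant\n", sep = "")
  cat("  2*deltaLnL =", format(x$statistic, digits = 6),
      " df =", x$df, " p =", format.pval(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Stationary distribution of a three-state kinetic system
#'
#' @param system An `ode_system` with all rates positive.
#' @return Length-3 frequency vector in the null space of the generator.
#' @export
ode_stationary <- function(system) {
  ns <- eigen(system$A)
  i <- which.min(abs(ns$values))
  v <- Re(ns$vectors[, i])
  v <- v / sum(v)
  names(v) <- system$states
  v
}
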