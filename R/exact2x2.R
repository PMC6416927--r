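# Exact conditional inference for 2x2 tables, conditioning on both margins
# (the noncentral hypergeometric model). Implemented here with tight root
# tolerances so interval endpoints and the conditional-MLE odds ratio are
# reproducible well below 1e-6; stats::fisher.test solves the same
# equations but with looser root-finding, and is used for p-values.

# pmf of the noncentral hypergeometric at log-odds lp, computed in log space
nchg_support <- function(m1, m2, t) max(0, t - m2):min(t, m1)

nchg_probs <- function(lp, m1, m2, t) {
  k <- nchg_support(m1, m2, t)
  logw <- dhyper(k, m1, m2, t, log = TRUE) + k * lp
  w <- exp(logw - max(logw))
  list(k = k, p = w / sum(w))
}

# conditional MLE of the odds ratio: solves E_psi[X] = a (monotone in psi)
cond_mle_or <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; t <- a + c
  supp <- nchg_support(m1, m2, t)
  if (a <= min(supp)) return(0)
  if (a >= max(supp)) return(Inf)
  f <- function(lp) { pr <- nchg_probs(lp, m1, m2, t); sum(pr$k * pr$p) - a }
  exp(uniroot(f, c(-50, 50), tol = 1e-12)$root)
}

# central exact conditional confidence interval (Fisher-style): endpoints
# solve the alpha/2 tail equations of the conditional distribution
exact_or_ci <- function(a, b, c, d, conf_level = 0.95) {
  alpha <- (1 - conf_level) / 2
  m1 <- a + b; m2 <- c + d; t <- a + c
  supp <- nchg_support(m1, m2, t)
  p_ge <- function(lp) { pr <- nchg_probs(lp, m1, m2, t); sum(pr$p[pr$k >= a]) }
  p_le <- function(lp) { pr <- nchg_probs(lp, m1, m2, t); sum(pr$p[pr$k <= a]) }
  lower <- if (a <= min(supp)) 0 else
    exp(uniroot(function(lp) p_ge(lp) - alpha, c(-50, 50), tol = 1e-12)$root)
  upper <- if (a >= max(supp)) Inf else
    exp(uniroot(function(lp) p_le(lp) - alpha, c(-50, 50), tol = 1e-12)$root)
  c(lower, upper)
}
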