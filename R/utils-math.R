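# Small dense matrix-exponential helpers shared by the tree CTMC engine and
# the three-state kinetic models. Matrices here are at most 4x4, so an
# eigen-decomposition reused across many time points beats a general expm.

# Decompose once; diagonalizability is checked via the conditioning of the
# eigenvector matrix, with a scaling-and-squaring Taylor fallback for the
# (measure-zero) repeated-eigenvalue case.
mexp_decompose <- function(A) {
  eg <- eigen(A)
  V <- eg$vectors
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  ok <- !is.null(Vinv) &&
    max(Mod(V %*% Vinv - diag(nrow(A)))) < 1e-8
  list(A = A, values = eg$values, V = V, Vinv = Vinv, diagonalizable = ok)
}

# exp(A * t) for one t >= 0
mexp_at <- function(dec, t) {
  if (t == 0) return(diag(nrow(dec$A)))
  if (dec$diagonalizable) {
    M <- dec$V %*% (exp(dec$values * t) * dec$Vinv)
    return(Re(M))
  }
  expm_ss(dec$A * t)
}

# exp(A) by scaling-and-squaring with a truncated Taylor series
expm_ss <- function(A) {
  nrm <- max(rowSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))) + 1L)
  As <- A / 2^j
  n <- nrow(A)
  P <- diag(n)
  term <- diag(n)
  for (k in 1:24) {
    term <- term %*% As / k
    P <- P + term
  }
  for (k in seq_len(j)) P <- P %*% P
  P
}

# For a column-convention generator (columns sum to 0) acting on a state
# vector p: p(t) = exp(A t) p0, evaluated at a vector of times at once.
# Returns a length(t) x n matrix of state frequencies.
mexp_action <- function(dec, p0, t) {
  n <- nrow(dec$A)
  if (dec$diagonalizable) {
    c0 <- as.vector(dec$Vinv %*% p0)
    E <- exp(outer(t, dec$values))               # length(t) x n, E[i,j] = e^(lambda_j t_i)
    C <- E * matrix(c0, length(t), n, byrow = TRUE)
    return(Re(C %*% t(dec$V)))
  }
  t(vapply(t, function(ti) as.vector(expm_ss(dec$A * ti) %*% p0), numeric(n)))
}

# clamp tiny numerical negatives in a probability object
clamp01 <- function(x, tol = 1e-9) {
  x[x < 0 & x > -tol] <- 0
  x[x > 1 & x < 1 + tol] <- 1
  x
}
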