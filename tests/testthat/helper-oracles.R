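# Independent oracles used across the suite.  Each deliberately avoids the
# code path it checks.

# Direct Newton-Raphson maximization of the Bernoulli log-likelihood,
# independent of the package's IRLS implementation.
newton_logistic <- function(X, y, tol = 1e-12, max_iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- crossprod(X, y - p)
    hess <- crossprod(X * (p * (1 - p)), X)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

# Eigenvector-subspace CARE solver: selects the stable invariant subspace of
# the Hamiltonian from its (possibly complex) eigendecomposition.  This is
# an independent route to the stabilizing solution (Potter's method), not the
# ordered Schur factorization the package uses.
care_eigen_oracle <- function(F, G, H) {
  d <- nrow(F)
  Phi <- rbind(cbind(F, -G), cbind(-H, -t(F)))
  e <- eigen(Phi)
  sel <- which(Re(e$values) < 0)
  stopifnot(length(sel) == d)
  U <- e$vectors[, sel, drop = FALSE]
  U1 <- U[seq_len(d), , drop = FALSE]
  U2 <- U[d + seq_len(d), , drop = FALSE]
  V <- U2 %*% solve(U1)
  V <- Re(V)
  (V + t(V)) / 2
}

# Brute-force Benjamini-Hochberg step-up: enumerate all k and apply the
# definition k* = max{k : p_(k) <= k * level / m} directly.
bh_bruteforce <- function(pvals, level) {
  m <- length(pvals)
  if (m == 0) return(integer(0))
  ord <- order(pvals)
  ps <- pvals[ord]
  ks <- which(ps <= seq_len(m) * level / m)
  if (length(ks) == 0) return(integer(0))
  kstar <- max(ks)
  sort(ord[seq_len(kstar)])
}

# Random symmetric positive-definite matrix.
random_spd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.5
}

# Random PSD matrix of the A A' type used in CARE test instances.
random_psd <- function(d, rank = d) {
  A <- matrix(rnorm(d * rank), d, rank)
  tcrossprod(A)
}

# Logistic instance fitted on an augmented (X, Xtilde) design; returns the
# pieces needed for transformation tests.
logistic_augmented_fit <- function(n = 500, d = 5, rho = 0.5, seed = 1,
                                   beta = NULL,
                                   strategy = "row_permutation") {
  X <- gts_sim_design(n, d, rho, seed = seed)
  if (is.null(beta)) beta <- rep(0, d)
  y <- gts_sim_response(X, beta, "binomial", seed = seed + 1000L)
  aug <- cbind(X, gts_regenerate(X, strategy, seed = seed + 2000L)$matrix)
  fit <- gts_glm_fit(aug, y, "binomial")
  blocks <- split_omega(fit$covariance)
  list(fit = fit, blocks = blocks, X = X, y = y, d = d)
}

# Assembles Z from a transform and evaluates Z Omega Z'.
z_omega_z <- function(transform, omega) {
  d <- nrow(transform$P)
  Z <- rbind(cbind(diag(d), transform$P), cbind(diag(d), transform$V))
  Z %*% omega %*% t(Z)
}
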