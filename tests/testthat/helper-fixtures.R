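# Shared fixtures and independent oracles used across the suite.

# small two-ROI, two-condition study used by many tests
tiny_study <- function(S = 2, T_scans = 40, seed = 5, groups = "g1",
                       R = 2, K = 1, block = 10) {
  truth <- make_default_truth(R = R, K = K, n_edges = 1, effect_size = 0.4,
                              seed = seed, groups = groups,
                              subjects_per_group = S,
                              design = hvar_block_design(1, T_scans, block))
  simulate_study(truth)
}

# multivariate normal draws via Cholesky (test-side utility)
rmvn <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  matrix(rnorm(n * length(mu)), n) %*% L + rep(mu, each = n)
}

# independent discrete-Lyapunov oracle: solve V = M V M' + Q by the
# vectorized linear system (I - M (x) M) vec(V) = vec(Q)
lyapunov_solve <- function(M, Q) {
  n <- nrow(M)
  v <- solve(diag(n^2) - kronecker(M, M), as.vector(Q))
  matrix(v, n, n)
}

# hand-rolled lag-matrix design for a plain VAR(K) on one series:
# row t has [Y(t-1)', ..., Y(t-K)'] -- the classic textbook construction
classic_var_design <- function(Y, K) {
  T_n <- nrow(Y)
  X <- NULL
  for (k in 1:K) X <- cbind(X, Y[(K + 1 - k):(T_n - k), , drop = FALSE])
  list(X = X, y = Y[(K + 1):T_n, , drop = FALSE])
}

# independent random-walk Metropolis sampler targeting the alpha_j full
# conditional density written as a function of the joint:
#   p(a) propto a^{-3/2} exp(-gamma/(2a) - tau*phi2*a/2)
metropolis_alpha <- function(n, gamma, tau, phi2, step = 1.2, burn = 2000,
                             thin = 5) {
  logp <- function(la) {            # density of log(alpha), with Jacobian
    a <- exp(la)
    -1.5 * la - gamma / (2 * a) - tau * phi2 * a / 2 + la
  }
  la <- log(sqrt(gamma / (tau * phi2)))  # start near the mode scale
  out <- numeric(n)
  tot <- burn + n * thin
  kept <- 0L
  for (i in seq_len(tot)) {
    prop <- la + rnorm(1, 0, step)
    if (log(runif(1)) < logp(prop) - logp(la)) la <- prop
    if (i > burn && (i - burn) %% thin == 0L) {
      kept <- kept + 1L
      out[kept] <- exp(la)
    }
  }
  out
}

# textbook cyclic coordinate descent with soft thresholding for the
# elastic-net criterion 1/2 ||y - X b||^2 + l1 |b|_1 + l2/2 ||b||^2
cd_elastic_net <- function(X, y, l1, l2, iters = 20000, tol = 1e-13) {
  p <- ncol(X); b <- rep(0, p)
  xx <- colSums(X^2); r <- y
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- sum(X[, j] * r) + xx[j] * b[j]
      bn <- sign(rho) * max(abs(rho) - l1, 0) / (xx[j] + l2)
      if (bn != b[j]) {
        r <- r - X[, j] * (bn - b[j])
        delta <- max(delta, abs(bn - b[j]))
      }
      b[j] <- bn
    }
    if (delta < tol) break
  }
  b
}
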