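# Joint-distribution ("getting it right") validation machinery.
#
# Two simulators must agree in distribution if every full conditional is
# consistent with the joint model: (a) the marginal-conditional simulator
# draws parameters from the prior and data from the model, i.i.d.; (b) the
# successive-conditional simulator alternates one Gibbs sweep with a fresh
# data draw given the current parameters.  Test functions of the parameters
# are compared by z-scores (i.i.d. variance for arm a, batch means for the
# autocorrelated arm b).
#
# The joint targeted by the sampler ties the elastic-net latents together
# as prod_j (lambda2 alpha_j/(alpha_j+lambda2))^{1/2} InvGamma(alpha_j; 1,
# gamma/2): exact prior draws come from a block rejection sampler
# (propose gamma ~ Gam(r_gamma, h_gamma), lambda2 ~ Gam(r_lambda + q/2,
# h_lambda), alpha_j ~ InvGamma(1, gamma/2); accept the block when every
# u_j <= sqrt(alpha_j/(alpha_j+lambda2))).  The deviation-precision prior
# implied by the printed conditional is Gam(S(r_d-1)+1, S h_d).
# Hyperparameters keep the prior inside the stationary VAR regime so the
# regenerated series cannot wander into explosive quasi-absorbing states.

gir_setup <- function() {
  spec <- hvar_spec(c("r1", "r2"), lags = 1, conditions = c("A", "B"),
                    groups = "g")
  design <- hvar_block_design(1, 30, 5, conditions = c("A", "B"))
  W <- make_block_indicators(design)
  list(spec = spec, W = W, starts = attr(W, "session_starts"),
       S = 2L, q = spec$q, R = spec$R,
       hyper = hvar_hyper(r_tau = 10, h_tau = 10, r_lambda = 2,
                          h_lambda = 0.1, r_gamma = 40, h_gamma = 0.2,
                          r_d = 5, h_d = 0.045),
       Y1 = c(0.5, -0.3))   # fixed pre-sample values, conditioned on
}

gir_prior_draw <- function(gs) {
  hy <- gs$hyper; q <- gs$q; S <- gs$S
  repeat {
    gam <- rgamma(1, hy$r_gamma, hy$h_gamma)
    lam <- rgamma(1, hy$r_lambda + q / 2, hy$h_lambda)
    alpha <- 1 / rgamma(q, 1, rate = gam / 2)
    if (all(runif(q) <= sqrt(alpha / (alpha + lam)))) break
  }
  tau <- rgamma(gs$R, hy$r_tau, hy$h_tau)
  tau_h <- tau[hvarnet:::tau_index(q, gs$R)]
  phi <- rnorm(q, 0, sqrt(1 / (tau_h * (alpha + lam))))
  d <- matrix(rgamma(q, S * (hy$r_d - 1) + 1, S * hy$h_d), 1, q)
  xi <- t(sapply(seq_len(S), function(s) rnorm(q, 0, sqrt(1 / d[1, ]))))
  list(phi = phi, xi = xi, tau = tau, d = d, alpha = alpha,
       lambda2 = lam, gamma = gam)
}

gir_sim_data <- function(gs, state) {
  lapply(seq_len(gs$S), function(s) {
    Phi <- phi_unflatten(state$phi + state$xi[s, ], gs$spec)[[1]]
    Y <- matrix(0, nrow(gs$W), gs$R)
    Y[1, ] <- gs$Y1
    sd_e <- sqrt(1 / state$tau)
    for (t in 2:nrow(gs$W)) {
      cc <- which(gs$W[t, ] == 1)
      Y[t, ] <- Phi[, , 1, cc] %*% Y[t - 1, ] + rnorm(gs$R, 0, sd_e)
    }
    colnames(Y) <- gs$spec$rois
    hvar_subject(Y, gs$W, paste0("s", s), "g", gs$starts)
  })
}

gir_sweep <- function(gs, state, study) {
  gd <- hvarnet:::gibbs_data(study, gs$spec)
  state$phi <- hvarnet:::sample_phi(state, gd)
  state$xi <- hvarnet:::sample_xi(state, gd)
  state$alpha <- hvarnet:::sample_alpha(state, gd)
  state$tau <- hvarnet:::sample_tau(state, gd, gs$hyper)
  state$lambda2 <- hvarnet:::sample_lambda2(state, gd, gs$hyper)
  state$gamma <- hvarnet:::sample_gamma_hyper(state, gd, gs$hyper)
  state$d <- hvarnet:::sample_d(state, gd, gs$hyper)
  state
}

gir_test_fns <- function(st) c(
  phi1 = st$phi[1], phi8 = st$phi[8], phi_msq = mean(st$phi^2),
  xi11 = st$xi[1, 1], xi_msq = mean(st$xi^2),
  tau1 = st$tau[1], log_tau2 = log(st$tau[2]),
  lambda2 = st$lambda2, log_lambda2 = log(st$lambda2),
  gamma = st$gamma, log_gamma = log(st$gamma),
  inv_alpha = mean(1 / st$alpha), log_alpha1 = log(st$alpha[1]),
  d1 = st$d[1, 1], inv_d = mean(1 / st$d))

# variance of the mean of an autocorrelated chain via batch means
gir_batch_var_mean <- function(x, nb = 100L) {
  bs <- floor(length(x) / nb)
  stats::var(colMeans(matrix(x[seq_len(nb * bs)], bs, nb))) / nb
}

gir_zscores <- function(sweeps = 50000L, seed = 11L) {
  gs <- gir_setup()
  set.seed(seed)
  nfun <- length(gir_test_fns(gir_prior_draw(gs)))
  mc <- matrix(0, sweeps, nfun)
  for (i in seq_len(sweeps)) mc[i, ] <- gir_test_fns(gir_prior_draw(gs))
  sc <- matrix(0, sweeps, nfun)
  state <- gir_prior_draw(gs)          # start at stationarity
  study <- gir_sim_data(gs, state)
  for (i in seq_len(sweeps)) {
    state <- gir_sweep(gs, state, study)
    study <- gir_sim_data(gs, state)
    sc[i, ] <- gir_test_fns(state)
  }
  z <- vapply(seq_len(nfun), function(j) {
    (mean(mc[, j]) - mean(sc[, j])) /
      sqrt(stats::var(mc[, j]) / sweeps + gir_batch_var_mean(sc[, j]))
  }, numeric(1))
  names(z) <- names(gir_test_fns(state))
  z
}
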