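# Full-conditional correctness (moment and oracle checks on fixed inputs)
# and sampler mechanics.  The joint-distribution validation of the whole
# sampler is in test-acceptance.R.

make_state_gd <- function(seed = 7, S = 2, groups = "g1") {
  study <- tiny_study(S = S, seed = seed, groups = groups)
  sp <- study$truth$spec
  gd <- hvarnet:::gibbs_data(study$series, sp)
  state <- hvarnet:::init_state(gd)
  set.seed(seed)
  n <- sp$G * sp$q
  state$phi <- rnorm(n, 0, 0.2)
  state$xi <- matrix(rnorm(gd$S * sp$q, 0, 0.1), gd$S, sp$q)
  state$tau <- runif(sp$R, 0.5, 2)
  state$alpha <- runif(n, 0.5, 4)
  state$lambda2 <- 1.3
  state$gamma <- 2.1
  state$d <- matrix(runif(n, 0.5, 3), sp$G, sp$q)
  list(state = state, gd = gd, stack = stack_study(
    lapply(study$series, build_subject_design, spec = sp), sp))
}

dense_phi_moments <- function(state, gd, stack) {
  w <- state$tau[stack$row_target]
  prior <- state$tau[hvarnet:::tau_index(length(state$phi), gd$spec$R)] *
    (state$alpha + state$lambda2)
  A <- crossprod(stack$X * w, stack$X) + diag(prior)
  b <- crossprod(stack$X * w, stack$y - stack$Z %*% as.vector(t(state$xi)))
  list(mu = solve(A, b), V = solve(A))
}

test_that("phi conditional: no-data limit and scalar conjugate case", {
  ms <- make_state_gd()
  st <- ms$state; gd <- ms$gd
  # X all zeros -> conditional equals the prior N(0, V_tau V_Phi)
  gd0 <- gd
  gd0$P <- lapply(gd0$P, function(p) p * 0)
  gd0$Gram_s <- lapply(gd0$P, crossprod)
  gd0$Gram_g <- list(Reduce(`+`, gd0$Gram_s))
  set.seed(1)
  draws <- t(replicate(4000, hvarnet:::sample_phi(st, gd0)))
  prior_sd <- 1 / sqrt(st$tau[hvarnet:::tau_index(ncol(draws), gd$spec$R)] *
                         (st$alpha + st$lambda2))
  expect_lt(max(abs(colMeans(draws))), 4 * max(prior_sd) / sqrt(4000))
  expect_equal(apply(draws, 2, sd), prior_sd, tolerance = 0.1)
  # scalar case X = (1), y = (2), prior precision 1, tau = 1:
  # mean 2/(1+1) = 1, variance 1/2 (hand evaluation)
  sp1 <- hvar_spec("a", 1, "c1")
  su <- hvar_subject(matrix(c(1, 2)), matrix(1, 2, 1,
                     dimnames = list(NULL, "c1")), "s")
  gd1 <- hvarnet:::gibbs_data(list(su), sp1)
  st1 <- hvarnet:::init_state(gd1)
  st1$alpha <- 0.6; st1$lambda2 <- 0.4       # prior precision 1
  set.seed(2)
  dr <- replicate(50000, hvarnet:::sample_phi(st1, gd1))
  expect_equal(mean(dr), 1, tolerance = 3 * sqrt(0.5 / 50000) / 1 * 1.1)
  expect_equal(var(dr), 0.5, tolerance = 0.02)
})

test_that("phi and xi conditionals match the dense-matrix formulas", {
  ms <- make_state_gd(seed = 11, S = 2, groups = c("gA", "gB"))
  st <- ms$state; gd <- ms$gd
  mom <- dense_phi_moments(st, gd, ms$stack)
  set.seed(3)
  n <- 20000
  draws <- t(replicate(n, hvarnet:::sample_phi(st, gd)))
  se <- sqrt(diag(mom$V) / n)
  expect_true(all(abs(colMeans(draws) - mom$mu) < 4 * se))
  expect_equal(cov(draws), mom$V, tolerance = 0.05)
  # xi: dense formula with per-subject-group D blocks
  w <- st$tau[ms$stack$row_target]
  Dvec <- unlist(lapply(seq_len(gd$S), function(s) st$d[gd$g_of[s], ]))
  Ax <- crossprod(ms$stack$Z * w, ms$stack$Z) + diag(Dvec)
  bx <- crossprod(ms$stack$Z * w, ms$stack$y - ms$stack$X %*% st$phi)
  mux <- solve(Ax, bx)
  drx <- t(replicate(n, as.vector(t(hvarnet:::sample_xi(st, gd)))))
  sex <- sqrt(diag(solve(Ax)) / n)
  expect_true(all(abs(colMeans(drx) - mux) < 4 * sex))
})

test_that("xi conditional: no-data and infinite-precision limits", {
  ms <- make_state_gd()
  st <- ms$state; gd <- ms$gd
  gd0 <- gd
  gd0$P <- lapply(gd0$P, function(p) p * 0)
  gd0$Gram_s <- lapply(gd0$P, crossprod)
  set.seed(4)
  drx <- t(replicate(3000, as.vector(hvarnet:::sample_xi(st, gd0))))
  # with no data, xi^(s) ~ N(0, D) independently per subject
  sd_cols <- matrix(apply(drx, 2, sd), nrow = gd$S, byrow = FALSE)
  for (s in seq_len(gd$S))
    expect_equal(unname(sd_cols[s, ]), unname(1 / sqrt(st$d[1, ])),
                 tolerance = 0.12)
  # huge precisions shrink deviations to zero
  st2 <- st; st2$d[] <- 1e10
  xi2 <- hvarnet:::sample_xi(st2, gd)
  expect_lt(max(abs(xi2)), 1e-3)
})

test_that("alpha conditional matches an independent Metropolis oracle (KS)", {
  ms <- make_state_gd()
  st <- ms$state; gd <- ms$gd
  st$gamma <- 2.5
  j <- 3
  st$phi[] <- 0; st$phi[j] <- 0.8
  tau_h <- st$tau[hvarnet:::tau_index(length(st$phi), gd$spec$R)[j]]
  set.seed(6)
  n <- 20000
  mine <- replicate(n, hvarnet:::sample_alpha(st, gd)[j])
  oracle <- metropolis_alpha(n, gamma = st$gamma, tau = tau_h, phi2 = 0.64)
  expect_true(all(mine > 0))
  ks <- suppressWarnings(ks.test(mine, oracle))
  expect_gt(ks$p.value, 0.01)
  # larger |phi_j| stochastically decreases alpha_j
  st_big <- st; st_big$phi[j] <- 5
  big <- replicate(4000, hvarnet:::sample_alpha(st_big, gd)[j])
  expect_lt(median(big), median(mine))
})

test_that("tau conditional: printed shape and degenerate rate", {
  # T=100, K=2, S=5, R=3, C=2, one session, r_tau = 1:
  # shape = ((T-K)S + 2RK + 2 r_tau)/2 = (98*5 + 12 + 2)/2 = 252
  sp <- hvar_spec(paste0("r", 1:3), lags = 2)
  W <- make_block_indicators(hvar_block_design(1, 100, 10))
  set.seed(8)
  study <- lapply(1:5, function(s)
    hvar_subject(matrix(rnorm(300), 100, 3), W, paste0("s", s)))
  gd <- hvarnet:::gibbs_data(study, sp)
  hy <- hvar_hyper(r_tau = 1)
  expect_equal((gd$N + sp$G * gd$p) / 2 + hy$r_tau, 252)
  # zero residuals and zero phi -> rate = h_tau exactly, so
  # tau ~ Gamma(shape, h_tau); check the mean at huge shape via draws
  study0 <- lapply(study, function(su)
    hvar_subject(su$Y * 0, su$W, su$subject_id))
  gd0 <- hvarnet:::gibbs_data(study0, sp)
  st0 <- hvarnet:::init_state(gd0)
  set.seed(9)
  dr <- t(replicate(2000, hvarnet:::sample_tau(st0, gd0, hy)))
  expect_equal(colMeans(dr), rep(252 / hy$h_tau, 3), tolerance = 0.01)
})

test_that("tau draws concentrate near the true precision with much data", {
  truth <- make_default_truth(R = 2, K = 1, n_edges = 1, effect_size = 0.3,
                              seed = 31, groups = "g1", subjects_per_group = 4,
                              design = hvar_block_design(1, 600, 12),
                              dev_sd = 0.01, noise_var = c(1, 0.25))
  study <- simulate_study(truth)
  fit <- run_gibbs(study$series, truth$spec,
                   control = hvar_control(600, 300, 1, seed = 2))
  expect_equal(unname(colMeans(fit$tau)), c(1, 4), tolerance = 0.12)
})

test_that("lambda2 and gamma conditionals: printed shapes and moments", {
  ms <- make_state_gd()
  st <- ms$state; gd <- ms$gd
  hy <- hvar_hyper(r_lambda = 1, r_gamma = 2)
  # printed shapes: r_lambda + q/2 (=51 for q=100), r_gamma + q (=102)
  expect_equal(1 + 100 / 2, 51)
  expect_equal(2 + 100, 102)
  n <- 20000
  set.seed(10)
  lam <- replicate(n, hvarnet:::sample_lambda2(st, gd, hy))
  tau_h <- st$tau[hvarnet:::tau_index(length(st$phi), gd$spec$R)]
  sh <- hy$r_lambda + length(st$phi) / 2
  rt <- hy$h_lambda + 0.5 * sum(tau_h * st$phi^2)
  # the whole conditional distribution must be Gamma(sh, rt)
  expect_gt(ks.test(lam, pgamma, shape = sh, rate = rt)$p.value, 0.001)
  # exact draw identity: the conditional IS a Gamma draw with the printed
  # shape and rate (no Monte-Carlo slack; rgamma under an identical RNG
  # state must reproduce it bitwise)
  shg <- hy$r_gamma + length(st$alpha)
  rtg <- hy$h_gamma + 0.5 * sum(1 / st$alpha)
  st0 <- st; st0$phi[] <- 0          # phi = 0 -> lambda2 rate = h_lambda
  stA <- st; stA$alpha[] <- Inf      # alpha -> Inf -> gamma rate = h_gamma
  for (seed in c(77, 78, 79)) {
    set.seed(seed); a <- hvarnet:::sample_lambda2(st, gd, hy)
    set.seed(seed); b <- rgamma(1, sh, rt)
    expect_identical(a, b)
    set.seed(seed); a <- hvarnet:::sample_lambda2(st0, gd, hy)
    set.seed(seed); b <- rgamma(1, sh, hy$h_lambda)
    expect_identical(a, b)
    set.seed(seed); a <- hvarnet:::sample_gamma_hyper(st, gd, hy)
    set.seed(seed); b <- rgamma(1, shg, rtg)
    expect_identical(a, b)
    set.seed(seed); a <- hvarnet:::sample_gamma_hyper(stA, gd, hy)
    set.seed(seed); b <- rgamma(1, shg, hy$h_gamma)
    expect_identical(a, b)
  }
})

test_that("d conditional: printed shape, degenerate rate, recovery", {
  ms <- make_state_gd(S = 10)
  st <- ms$state; gd <- ms$gd
  hy <- hvar_hyper(r_d = 1)
  # S=10, r_d=1 -> shape = S(r_d - 1/2) + 1 = 6
  expect_equal(gd$S_g[1] * (hy$r_d - 0.5) + 1, 6)
  st0 <- st; st0$xi[] <- 0
  set.seed(12)
  d0 <- t(replicate(4000, as.vector(hvarnet:::sample_d(st0, gd, hy))))
  # all xi = 0 -> rate = S h_d exactly, mean = shape / (S h_d)
  expect_equal(mean(colMeans(d0)), 6 / (10 * hy$h_d), tolerance = 0.02)
  expect_equal(unname(colMeans(d0)), rep(6 / (10 * hy$h_d), ncol(d0)),
               tolerance = 0.05)
  # simulated xi with known variance: posterior mean of 1/d near truth
  v_true <- 0.5
  stv <- st
  set.seed(13)
  stv$xi <- matrix(rnorm(gd$S * ncol(st$xi), 0, sqrt(v_true)), gd$S)
  dv <- t(replicate(4000, as.vector(hvarnet:::sample_d(stv, gd, hy))))
  expect_equal(mean(colMeans(1 / dv)), v_true, tolerance = 0.2)
  expect_error(hvar_hyper(r_d = 0.4), "r_d")
})

test_that("run_gibbs: retention count, determinism, error on bad config", {
  study <- tiny_study()
  sp <- study$truth$spec
  ctl <- hvar_control(200, 100, 5, seed = 42)
  f1 <- run_gibbs(study$series, sp, control = ctl)
  expect_identical(f1$n_draws, 20L)
  expect_identical(nrow(f1$phi), 20L)
  # the printed protocol: 80000 iterations, burn-in 60000, thin 5 -> 4000
  expect_identical((80000L - 60000L) %/% 5L, 4000L)
  f2 <- run_gibbs(study$series, sp, control = ctl)
  expect_identical(f1$phi, f2$phi)       # bitwise-identical chains
  expect_identical(f1$xi, f2$xi)
  expect_true(all(f1$tau > 0) && all(f1$d > 0) && all(f1$alpha > 0))
  expect_error(hvar_control(100, 100, 1), "burn_in")
  expect_error(hvar_control(100, 50, 0), "thin")
})

test_that("tiny model runs end-to-end quickly", {
  study <- tiny_study(S = 2, T_scans = 40)
  t0 <- proc.time()[[3]]
  fit <- run_gibbs(study$series, study$truth$spec,
                   control = hvar_control(500, 250, 5, seed = 1))
  expect_lt(proc.time()[[3]] - t0, 60)
  expect_identical(fit$n_draws, 50L)
})

test_that("inverse-Gaussian sampler has the right moments", {
  set.seed(14)
  n <- 200000
  for (par in list(c(2, 3), c(0.5, 8), c(1000, 2))) {
    x <- hvarnet:::rinvgauss(n, par[1], par[2])
    expect_true(all(x > 0))
    se_rel <- sqrt(par[1]^3 / par[2] / n) / par[1]
    expect_equal(mean(x), par[1], tolerance = 4 * se_rel)
  }
  # second moment checked where the 4th moment is not extreme
  x <- hvarnet:::rinvgauss(n, 2, 3)
  expect_equal(var(x), 8 / 3, tolerance = 0.1)
  # large mean/shape ratio exercises the stabilized branch
  x <- hvarnet:::rinvgauss(n, 1e6, 1)
  expect_true(all(is.finite(x)) && all(x > 0))
})

test_that("Geweke diagnostic: null calibration, step change, affine invariance", {
  set.seed(15)
  z_null <- replicate(1000, geweke_diagnostic(rnorm(400)))
  expect_gte(mean(abs(z_null) < 4), 0.99)
  ch <- c(rnorm(300), rnorm(300, 5))       # constructed nonconvergence
  expect_gt(abs(geweke_diagnostic(ch)), 6)
  ch2 <- rnorm(500)
  expect_equal(geweke_diagnostic(ch2), geweke_diagnostic(10 * ch2 - 3),
               tolerance = 1e-8)
  expect_true(is.na(geweke_diagnostic(rep(1, 200))))
  expect_error(geweke_diagnostic(rnorm(50)), "100")
})
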