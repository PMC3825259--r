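# Condition indicators, regression structures, coefficient indexing,
# stationarity utilities.

test_that("block indicators follow the alternating block layout", {
  W <- make_block_indicators(hvar_block_design(1, 48, 12))
  expect_identical(which(W[, "rest"] == 1L), c(1:12, 25:36))
  expect_identical(which(W[, "active"] == 1L), c(13:24, 37:48))
  expect_equal(colSums(W), c(rest = 24, active = 24))
})

test_that("indicator rows always partition time, sessions restart the cycle", {
  for (bd in list(hvar_block_design(2, 48, 12),
                  hvar_block_design(3, 48, 12),
                  hvar_block_design(2, 30, 5, conditions = c("a", "b", "c")))) {
    W <- make_block_indicators(bd)
    expect_true(all(rowSums(W) == 1))
    starts <- attr(W, "session_starts")
    # every session opens with the first condition
    expect_true(all(W[starts, 1L] == 1L))
  }
  # single condition: the one column is all ones
  W1 <- make_block_indicators(hvar_block_design(1, 20, 5, conditions = "only"))
  expect_true(all(W1 == 1))
})

test_that("invalid block designs are rejected", {
  expect_error(hvar_block_design(1, 47, 12), "multiple")
  expect_error(hvar_block_design(1, 48, 12, TR = -1), "TR")
})

test_that("spec dimensions: q = R^2*K*C", {
  sp <- hvar_spec(paste0("r", 1:5), lags = 2)
  expect_identical(sp$q, 100L)           # 25 per lag per condition, 2 x 2 x 25
  expect_identical(hvar_spec("a", 1, "c1")$q, 1L)
})

test_that("scalar example reproduces the stacked-regression formula", {
  # R=1, K=1, one condition, Y = (1,2,3): usable rows t=2,3;
  # design column (1, 2), response (2, 3) -- direct hand evaluation
  sp <- hvar_spec("a", lags = 1, conditions = "c1")
  su <- hvar_subject(matrix(1:3), matrix(1, 3, 1,
                     dimnames = list(NULL, "c1")), "s1")
  d <- build_subject_design(su, sp)
  expect_equal(as.vector(d$X), c(1, 2))
  expect_equal(d$y, c(2, 3))
  expect_equal(d$X, d$Z)   # G = 1
})

test_that("design dimensions, session-boundary lag dropping, zero linearity", {
  sp <- hvar_spec(paste0("r", 1:5), lags = 2)
  bd <- hvar_block_design(2, 48, 12)
  W <- make_block_indicators(bd)
  Y <- matrix(rnorm(96 * 5), 96, 5)
  su <- hvar_subject(Y, W, "s1", session_starts = attr(W, "session_starts"))
  d <- build_subject_design(su, sp)
  # q = 100 per group; the first K scans of each session are dropped
  expect_identical(ncol(d$X), 100L)
  expect_identical(nrow(d$X), 5L * (96L - 2L * 2L))
  su0 <- hvar_subject(Y * 0, W, "s0", session_starts = attr(W, "session_starts"))
  d0 <- build_subject_design(su0, sp)
  expect_true(all(d0$X == 0) && all(d0$y == 0))
  # sessions shorter than K+1 scans are an error
  sp_big <- hvar_spec(paste0("r", 1:5), lags = 30)
  expect_error(build_subject_design(
    hvar_subject(Y[1:20, ], W[1:20, ], "s", session_starts = 1), sp_big),
    "session")
})

test_that("constant condition reproduces the classic VAR(K) lag design", {
  set.seed(3)
  for (K in 1:3) {
    Y <- matrix(rnorm(40 * 2), 40, 2)
    sp <- hvar_spec(c("r1", "r2"), lags = K, conditions = "c1")
    su <- hvar_subject(Y, matrix(1, 40, 1, dimnames = list(NULL, "c1")), "s")
    d <- build_subject_design(su, sp)
    oracle <- classic_var_design(Y, K)
    # row for (t, target r) must equal the classic design row placed on
    # target-r coefficients, and responses must match
    n <- nrow(oracle$X)
    for (r in 1:2) {
      rows <- (seq_len(n) - 1L) * 2L + r
      cols <- (seq_len(ncol(oracle$X)) - 1L) * 2L + r
      # canonical order is (lag, source); classic oracle builds (lag, source)
      expect_equal(d$Z[rows, cols], oracle$X, ignore_attr = TRUE)
      expect_equal(d$y[rows], oracle$y[, r])
    }
  }
})

test_that("multi-group stacking places blocks by group membership", {
  sp2 <- hvar_spec(c("r1", "r2"), 1, groups = c("gA", "gB"))
  W <- make_block_indicators(hvar_block_design(1, 20, 5))
  set.seed(1)
  mk <- function(id, g) hvar_subject(matrix(rnorm(40), 20, 2), W, id, g)
  dA <- build_subject_design(mk("a", "gA"), sp2)
  dB <- build_subject_design(mk("b", "gB"), sp2)
  q <- sp2$q
  expect_true(all(dA$X[, q + seq_len(q)] == 0))   # group-1 subject: slot 2 empty
  expect_true(all(dB$X[, seq_len(q)] == 0))       # group-2 subject: slot 1 empty
  expect_equal(dB$X[, q + seq_len(q)], dB$Z)
  stk <- stack_study(list(dA, dB), sp2)
  expect_identical(nrow(stk$X), nrow(dA$X) + nrow(dB$X))
  expect_equal(stk$Z[seq_len(nrow(dA$X)), seq_len(q)], dA$Z)
  expect_true(all(stk$Z[seq_len(nrow(dA$X)), q + seq_len(q)] == 0))
  expect_error(stack_study(list(build_subject_design(mk("c", "gA"), sp2),
                                list(X = dA$X, Z = dA$Z, y = dA$y,
                                     subject_id = "x", group = "nope")), sp2),
               "unknown group")
})

test_that("single-group path and multi-group machinery agree for G = 1", {
  study <- tiny_study(S = 2)
  sp <- study$truth$spec
  designs <- lapply(study$series, build_subject_design, spec = sp)
  stk <- stack_study(designs, sp)
  expect_equal(stk$X, do.call(rbind, lapply(designs, `[[`, "X")))
  for (d in designs) expect_equal(d$X, d$Z)
})

test_that("flatten/unflatten is a bijection and places entries correctly", {
  sp <- hvar_spec(paste0("r", 1:3), lags = 2, groups = c("gA", "gB"))
  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(sp$G * sp$q)
    expect_equal(unname(phi_flatten(phi_unflatten(v, sp), sp)), v)
  }
  cs <- phi_unflatten(seq_len(sp$G * sp$q), sp)
  # canonical index: condition-major, lag, source, target (target fastest)
  expect_equal(cs$gA["r2", "r1", 1, "rest"], 2)
  expect_equal(cs$gB["r1", "r1", 1, "rest"], sp$q + 1)
})

test_that("companion spectral radius matches closed forms", {
  expect_equal(companion_spectral_radius(0.5 * diag(3)), 0.5)
  expect_equal(companion_spectral_radius(matrix(0, 2, 2)), 0)
  # R=1, K=2: largest root of z^2 - 0.5 z - 0.3 = 0 by the quadratic formula
  root <- (0.5 + sqrt(0.25 + 4 * 0.3)) / 2
  expect_equal(companion_spectral_radius(list(matrix(0.5), matrix(0.3))),
               root, tolerance = 1e-12)
  expect_equal(round(root, 4), 0.8521)
  expect_error(companion_spectral_radius(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "square")
})

test_that("stationary covariance: AR(1) closed form and zero dynamics", {
  expect_equal(stationary_covariance(matrix(0.5), 1)[1, 1], 4 / 3,
               tolerance = 1e-9)
  Sig <- stationary_covariance(matrix(0, 2, 2), c(2, 3))
  expect_equal(Sig, diag(c(2, 3)))
  expect_error(stationary_covariance(matrix(1.01), 1), "onstationary")
})

test_that("stationary covariance agrees with the Lyapunov-solve oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    K <- sample(1:2, 1)
    lags <- replicate(K, matrix(rnorm(4, 0, 0.4), 2, 2), simplify = FALSE)
    repeat {
      rho <- companion_spectral_radius(lags)
      if (rho < 0.95) break
      lags <- lapply(lags, function(m) m * 0.9 / rho)
    }
    s2 <- runif(2, 0.5, 2)
    V <- stationary_covariance(lags, s2, tol = 1e-14)
    M <- hvarnet:::companion_matrix(lags)
    Q <- matrix(0, 2 * K, 2 * K); diag(Q)[1:2] <- s2
    V_oracle <- lyapunov_solve(M, Q)[1:2, 1:2]
    worst <- max(worst, max(abs(V - V_oracle)))
  }
  expect_lt(worst, 1e-8)
})
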