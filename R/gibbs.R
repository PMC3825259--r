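## Gibbs sampler for the hierarchical elastic-net VAR.
##
## The full conditionals exploit two exact factorizations: (i) the design
## row for target ROI r' only loads coefficients whose target is r', and
## (ii) the shrinkage prior and random-effect covariances are diagonal.
## The group-coefficient and deviation updates therefore decompose into
## independent (group x target-ROI) and (subject x target-ROI) blocks of
## size p = R*K*C, each drawn via a Cholesky factorization of its precision
## (no explicit inverses anywhere).

#' Prior hyperparameters of the hierarchical elastic-net VAR
#'
#' Shape/rate pairs of the Gamma priors on the ROI noise precisions
#' `tau_r`, the ridge weight `lambda2`, the sparsity weight `gamma`, and the
#' between-subject precisions `d_j`.  Defaults are weakly informative
#' (shape 1, rate 0.01).  `r_d` must exceed 1/2 for the deviation-precision
#' conditional to have a positive shape for any number of subjects.
#'
#' @param r_tau,h_tau Gamma shape/rate for each noise precision.
#' @param r_lambda,h_lambda Gamma shape/rate for `lambda2` (ridge part).
#' @param r_gamma,h_gamma Gamma shape/rate for `gamma` (lasso part).
#' @param r_d,h_d Gamma shape/rate for the between-subject precisions.
#' @return Object of class `"hvar_hyper"`.
#' @export
hvar_hyper <- function(r_tau = 1, h_tau = 0.01,
                       r_lambda = 1, h_lambda = 0.01,
                       r_gamma = 1, h_gamma = 0.01,
                       r_d = 1, h_d = 0.01) {
  vals <- c(r_tau = r_tau, h_tau = h_tau, r_lambda = r_lambda,
            h_lambda = h_lambda, r_gamma = r_gamma, h_gamma = h_gamma,
            r_d = r_d, h_d = h_d)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be strictly positive")
  if (r_d <= 0.5)
    stop("'r_d' must exceed 1/2 (deviation-precision conditional shape)")
  structure(as.list(vals), class = "hvar_hyper")
}

#' Sampler settings
#'
#' @param iterations Total Gibbs iterations.
#' @param burn_in Iterations discarded before retention
#'   (`burn_in < iterations`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; fixes the chain exactly.
#' @param verbose Print per-stage progress.
#' @return Object of class `"hvar_control"`.  The retained draw count is
#'   `floor((iterations - burn_in) / thin)`.
#' @export
hvar_control <- function(iterations = 80000L, burn_in = 60000L, thin = 5L,
                         seed = 1L, verbose = FALSE) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in < 0L || burn_in >= iterations)
    stop("need 0 <= burn_in < iterations")
  if (thin < 1L) stop("'thin' must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "hvar_control")
}

## Precomputed per-study regression structures (compact form).
gibbs_data <- function(study, spec) {
  stopifnot(inherits(spec, "hvar_spec"))
  S <- length(study)
  if (S < 1L) stop("empty study")
  g_of <- integer(S); P <- vector("list", S); Yr <- vector("list", S)
  t_idx <- vector("list", S)
  n_s <- integer(S)
  for (s in seq_len(S)) {
    su <- study[[s]]
    stopifnot(inherits(su, "hvar_subject"))
    g <- match(su$group, spec$groups)
    if (is.na(g)) stop(sprintf("subject '%s' has unknown group '%s'",
                               su$subject_id, su$group))
    g_of[s] <- g
    sp <- subject_predictors(su, spec)
    P[[s]] <- sp$P; Yr[[s]] <- sp$Yresp; n_s[s] <- sp$n
    t_idx[[s]] <- sp$t_idx
  }
  p <- spec$R * spec$K * spec$C
  Gram_s <- lapply(P, crossprod)
  Gram_g <- vector("list", spec$G)
  for (g in seq_len(spec$G)) {
    Gram_g[[g]] <- matrix(0, p, p)
    for (s in which(g_of == g)) Gram_g[[g]] <- Gram_g[[g]] + Gram_s[[s]]
  }
  list(S = S, p = p, spec = spec, g_of = g_of,
       subjects = unname(vapply(study, `[[`, "", "subject_id")),
       P = P, Yresp = Yr, t_idx = t_idx, n_s = n_s, N = sum(n_s),
       Gram_s = Gram_s, Gram_g = Gram_g,
       S_g = tabulate(g_of, spec$G))
}

init_state <- function(gd) {
  spec <- gd$spec
  list(phi = numeric(spec$G * spec$q),
       xi = matrix(0, gd$S, spec$q),
       tau = rep(1, spec$R),
       d = matrix(1, spec$G, spec$q),
       alpha = rep(1, spec$G * spec$q),
       lambda2 = 1, gamma = 1)
}

# coefficient vector of length q -> R x p matrix (rows = target ROI), so
# that P %*% t(M) gives the fitted values for all targets at once
coef_mat <- function(v, R) matrix(v, nrow = R)

# column indices (within a q-block) of the coefficients targeting ROI r
tgt_block <- function(r, p, R) (seq_len(p) - 1L) * R + r

# index of the noise precision tied to coefficient j of the full G*q vector
# (the target ROI of j; target varies fastest in the canonical ordering)
tau_index <- function(nphi, R) ((seq_len(nphi) - 1L) %% R) + 1L

chol_or_stop <- function(A, what) {
  U <- tryCatch(chol(A), error = function(e)
    stop(sprintf("non-positive-definite precision in %s update: %s",
                 what, conditionMessage(e)), call. = FALSE))
  U
}

## -- full conditionals ------------------------------------------------------

# group effective connectivity phi | rest: independent (group, target) blocks
sample_phi <- function(state, gd) {
  spec <- gd$spec
  R <- spec$R; p <- gd$p; q <- spec$q
  phi <- state$phi
  # per-subject random-effect fitted values, computed once
  fit_xi <- lapply(seq_len(gd$S), function(s)
    gd$P[[s]] %*% t(coef_mat(state$xi[s, ], R)))
  for (g in seq_len(spec$G)) {
    subj <- which(gd$g_of == g)
    for (r in seq_len(R)) {
      jb <- tgt_block(r, p, R)
      jg <- (g - 1L) * q + jb
      Cmat <- gd$Gram_g[[g]]
      diag(Cmat) <- diag(Cmat) + state$alpha[jg] + state$lambda2
      b <- numeric(p)
      for (s in subj)
        b <- b + crossprod(gd$P[[s]], gd$Yresp[[s]][, r] - fit_xi[[s]][, r])
      U <- chol_or_stop(Cmat, "phi")
      mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
      phi[jg] <- mu + backsolve(U, stats::rnorm(p)) / sqrt(state$tau[r])
    }
  }
  phi
}

# subject deviations xi | rest: independent (subject, target) blocks
sample_xi <- function(state, gd) {
  spec <- gd$spec
  R <- spec$R; p <- gd$p; q <- spec$q
  xi <- state$xi
  for (s in seq_len(gd$S)) {
    g <- gd$g_of[s]
    phi_g <- state$phi[(g - 1L) * q + seq_len(q)]
    fit_phi <- gd$P[[s]] %*% t(coef_mat(phi_g, R))
    for (r in seq_len(R)) {
      jb <- tgt_block(r, p, R)
      Cmat <- state$tau[r] * gd$Gram_s[[s]]
      diag(Cmat) <- diag(Cmat) + state$d[g, jb]
      b <- state$tau[r] *
        crossprod(gd$P[[s]], gd$Yresp[[s]][, r] - fit_phi[, r])
      U <- chol_or_stop(Cmat, "xi")
      mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
      xi[s, jb] <- mu + backsolve(U, stats::rnorm(p))
    }
  }
  xi
}

# elastic-net latents alpha_j | rest ~ inverse-Gaussian with
# mean sqrt(gamma / (tau_h(j) phi_j^2)) and shape gamma; phi_j^2 floored at
# 1e-12 (the argument degenerates at exactly zero, reachable at init)
sample_alpha <- function(state, gd) {
  tau_h <- state$tau[tau_index(length(state$phi), gd$spec$R)]
  mu <- sqrt(state$gamma / (tau_h * pmax(state$phi^2, 1e-12)))
  rinvgauss(length(mu), mean = mu, shape = state$gamma)
}

# noise precisions tau_r | rest.  Shape counts the residual rows targeting
# ROI r plus the G*C*R*K prior terms tied to tau_r (the printed 2-condition
# one-session case gives ((T-K)S + 2RK + 2 r_tau)/2); the rate adds half the
# residual sum of squares and half the prior quadratic form.
sample_tau <- function(state, gd, hyper) {
  spec <- gd$spec
  R <- spec$R; p <- gd$p; q <- spec$q
  ssr <- numeric(R)
  for (s in seq_len(gd$S)) {
    g <- gd$g_of[s]
    M <- coef_mat(state$phi[(g - 1L) * q + seq_len(q)] + state$xi[s, ], R)
    E <- gd$Yresp[[s]] - gd$P[[s]] %*% t(M)
    ssr <- ssr + colSums(E^2)
  }
  tau <- numeric(R)
  pen <- state$alpha + state$lambda2
  for (r in seq_len(R)) {
    jg <- as.vector(outer(tgt_block(r, p, R), (seq_len(spec$G) - 1L) * q, `+`))
    zeta2 <- sum(pen[jg] * state$phi[jg]^2)
    shape <- (gd$N + spec$G * p) / 2 + hyper$r_tau
    rate <- ssr[r] / 2 + zeta2 / 2 + hyper$h_tau
    tau[r] <- stats::rgamma(1L, shape = shape, rate = rate)
  }
  tau
}

# ridge weight lambda2 | rest ~ Gamma(r_lambda + (#coef)/2, ...)
sample_lambda2 <- function(state, gd, hyper) {
  tau_h <- state$tau[tau_index(length(state$phi), gd$spec$R)]
  stats::rgamma(1L, shape = hyper$r_lambda + length(state$phi) / 2,
                rate = hyper$h_lambda + 0.5 * sum(tau_h * state$phi^2))
}

# sparsity weight gamma | rest ~ Gamma(r_gamma + #coef, ...)
sample_gamma_hyper <- function(state, gd, hyper) {
  stats::rgamma(1L, shape = hyper$r_gamma + length(state$alpha),
                rate = hyper$h_gamma + 0.5 * sum(1 / state$alpha))
}

# between-subject precisions d_j | rest, per group:
# Gamma(S_g (r_d - 1/2) + 1, half the squared deviations + S_g h_d)
sample_d <- function(state, gd, hyper) {
  spec <- gd$spec
  d <- state$d
  for (g in seq_len(spec$G)) {
    Sg <- gd$S_g[g]
    if (Sg == 0L) next
    xg <- state$xi[gd$g_of == g, , drop = FALSE]
    shape <- Sg * (hyper$r_d - 0.5) + 1
    rate <- 0.5 * colSums(xg^2) + Sg * hyper$h_d
    d[g, ] <- stats::rgamma(spec$q, shape = shape, rate = rate)
  }
  d
}

## -- sampler driver ---------------------------------------------------------

#' Run the Gibbs sampler
#'
#' Cycles the seven full-conditional blocks in the fixed order
#' phi, xi, alpha, tau, lambda2, gamma, d; retains every `thin`-th
#' post-burn-in draw.  Chains are exactly reproducible under a fixed seed.
#' Most users call [hvar()], which wraps this around data preparation.
#'
#' @param study List of [hvar_subject()] objects.
#' @param spec A [hvar_spec()].
#' @param hyper A [hvar_hyper()].
#' @param control A [hvar_control()].
#' @return Object of class `"hvar_samples"`: matrices of retained draws
#'   (`phi`, `xi`, `alpha`, `tau`, `d`, `lambda2`, `gamma`, one row per
#'   draw) with labelled columns, plus the spec, subject table, control and
#'   per-block timings (seconds).
#' @export
run_gibbs <- function(study, spec, hyper = hvar_hyper(),
                      control = hvar_control()) {
  stopifnot(inherits(hyper, "hvar_hyper"), inherits(control, "hvar_control"))
  gd <- gibbs_data(study, spec)
  set.seed(control$seed)
  state <- init_state(gd)
  nkeep <- (control$iterations - control$burn_in) %/% control$thin
  nphi <- spec$G * spec$q
  keep <- list(
    phi = matrix(NA_real_, nkeep, nphi),
    xi = matrix(NA_real_, nkeep, gd$S * spec$q),
    alpha = matrix(NA_real_, nkeep, nphi),
    tau = matrix(NA_real_, nkeep, spec$R),
    d = matrix(NA_real_, nkeep, nphi),
    lambda2 = numeric(nkeep), gamma = numeric(nkeep))
  colnames(keep$phi) <- colnames(keep$alpha) <- colnames(keep$d) <-
    phi_labels(spec)
  colnames(keep$tau) <- spec$rois
  colnames(keep$xi) <- as.vector(vapply(gd$subjects, function(sid)
    paste(sid, phi_labels(spec, groups = "s")[seq_len(spec$q)], sep = "|"),
    character(spec$q)))
  timings <- c(phi = 0, xi = 0, alpha = 0, tau = 0,
               lambda2 = 0, gamma = 0, d = 0)
  at <- 0L
  for (it in seq_len(control$iterations)) {
    t0 <- proc.time()[[3L]]
    state$phi <- sample_phi(state, gd); t1 <- proc.time()[[3L]]
    state$xi <- sample_xi(state, gd); t2 <- proc.time()[[3L]]
    state$alpha <- sample_alpha(state, gd)
    state$tau <- sample_tau(state, gd, hyper)
    state$lambda2 <- sample_lambda2(state, gd, hyper)
    state$gamma <- sample_gamma_hyper(state, gd, hyper)
    state$d <- sample_d(state, gd, hyper)
    t3 <- proc.time()[[3L]]
    timings["phi"] <- timings["phi"] + (t1 - t0)
    timings["xi"] <- timings["xi"] + (t2 - t1)
    timings["d"] <- timings["d"] + (t3 - t2)  # scalar blocks pooled here
    if (it > control$burn_in &&
        (it - control$burn_in) %% control$thin == 0L) {
      at <- at + 1L
      keep$phi[at, ] <- state$phi
      keep$xi[at, ] <- as.vector(t(state$xi))
      keep$alpha[at, ] <- state$alpha
      keep$tau[at, ] <- state$tau
      keep$d[at, ] <- as.vector(t(state$d))
      keep$lambda2[at] <- state$lambda2
      keep$gamma[at] <- state$gamma
    }
    if (control$verbose && it %% max(1L, control$iterations %/% 10L) == 0L)
      message(sprintf("gibbs: iteration %d / %d", it, control$iterations))
  }
  structure(c(keep,
              list(spec = spec, subjects = gd$subjects,
                   groups_of_subjects = spec$groups[gd$g_of],
                   hyper = hyper, control = control, n_draws = nkeep,
                   timings = timings)),
            class = "hvar_samples")
}

#' @export
print.hvar_samples <- function(x, ...) {
  cat(sprintf("hvar posterior samples: %d draws, %d group coefficients, %d subjects\n",
              x$n_draws, ncol(x$phi), length(x$subjects)))
  invisible(x)
}

## -- profile objective used by the elastic-net correspondence --------------

# Negative log conditional density of phi given (tau, lambda2, gamma), with
# xi fixed at zero and the elastic-net latents alpha integrated out:
#   1/2 sum_r tau_r ||resid_r||^2
#     + sum_j sqrt(gamma tau_h(j)) |phi_j| + 1/2 lambda2 sum_j tau_h(j) phi_j^2
# (up to an additive constant).  Minimizing it reproduces the penalized
# least-squares elastic-net criterion.
phi_en_objective <- function(phi, gd, tau, lambda2, gamma) {
  spec <- gd$spec
  R <- spec$R; q <- spec$q
  ssr <- numeric(R)
  for (s in seq_len(gd$S)) {
    g <- gd$g_of[s]
    M <- coef_mat(phi[(g - 1L) * q + seq_len(q)], R)
    E <- gd$Yresp[[s]] - gd$P[[s]] %*% t(M)
    ssr <- ssr + colSums(E^2)
  }
  tau_h <- tau[tau_index(length(phi), R)]
  0.5 * sum(tau * ssr) +
    sum(sqrt(gamma * tau_h) * abs(phi)) +
    0.5 * lambda2 * sum(tau_h * phi^2)
}

## -- inverse-Gaussian sampler ----------------------------------------------

# Michael-Schucany-Haas transform sampler, written in the rationalized form
# x1 = 2*mean / (2 + w + sqrt(w*(w+4))), w = mean*z^2/shape, which avoids the
# catastrophic cancellation of the textbook formula for large mean/shape.
rinvgauss <- function(n, mean, shape) {
  if (any(mean <= 0) || any(shape <= 0))
    stop("inverse-Gaussian parameters must be positive")
  mean <- rep_len(mean, n); shape <- rep_len(shape, n)
  w <- mean * stats::rnorm(n)^2 / shape
  x1 <- 2 * mean / (2 + w + sqrt(w * (w + 4)))
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x1), x1, mean^2 / x1)
}

## -- convergence diagnostic --------------------------------------------------

#' Geweke convergence diagnostic
#'
#' Compares the means of the first `frac1` and last `frac2` portions of each
#' chain with variances estimated from the spectral density at frequency
#' zero (autoregressive estimate), returning one z-score per parameter.
#' Large absolute values indicate lack of convergence.  Constant chains are
#' flagged with `NA` rather than an error.
#'
#' @param x Numeric vector (one chain) or matrix (chains in columns).
#' @param frac1 Fraction of the chain in the early window (default 0.1).
#' @param frac2 Fraction in the late window (default 0.5).
#' @return Named numeric vector of z-scores.
#' @export
geweke_diagnostic <- function(x, frac1 = 0.1, frac2 = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) < 100L) stop("chain length must be at least 100")
  if (frac1 + frac2 > 1) stop("windows overlap: frac1 + frac2 > 1")
  apply(x, 2L, function(ch) {
    n <- length(ch)
    a <- ch[seq_len(max(2L, floor(frac1 * n)))]
    b <- ch[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
    va <- spectrum0_ar(a); vb <- spectrum0_ar(b)
    if (!is.finite(va) || !is.finite(vb) || va + vb <= 0) return(NA_real_)
    (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
  })
}

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(ch) {
  if (stats::var(ch) == 0) return(NA_real_)
  fit <- tryCatch(
    stats::ar(ch, aic = TRUE,
              order.max = min(length(ch) - 1L,
                              floor(10 * log10(length(ch))))),
    error = function(e) NULL)
  if (is.null(fit)) return(stats::var(ch))
  fit$var.pred / (1 - sum(fit$ar))^2
}
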