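## Synthetic multi-subject condition-switching VAR studies with known
## ground truth.  The generative path is exactly the model the sampler
## assumes: group coefficients, diagonal-normal subject deviations,
## condition-switching VAR recursion, diagonal Gaussian noise.  There is no
## hemodynamic forward model: simulation lives at the VAR level.

#' Construct a sparse ground truth for a simulated study
#'
#' The group truth has self-lags of 0.3 on the lag-1 diagonal of every
#' condition, `n_edges` cross-edges of magnitude `effect_size` (random
#' placement and sign, shared across groups) distributed over conditions
#' and lags, and zeros elsewhere.  If a condition's companion spectral
#' radius exceeds 0.9 the condition's matrices are rescaled to radius 0.9.
#'
#' @param R,K Number of ROIs and VAR order.
#' @param n_edges Number of nonzero cross-edges (`<= R*(R-1)*K*C`).
#' @param effect_size Magnitude of each cross-edge.
#' @param seed Integer seed; fully determines the truth and the study.
#' @param conditions,groups Labels (defaults: rest/active; two groups).
#' @param subjects_per_group Subjects simulated per group.
#' @param design A [hvar_block_design()]; default mirrors a classic
#'   block-design acquisition (2 sessions x 48 scans, 12-scan blocks,
#'   TR 2 s).
#' @param dev_sd Between-subject standard deviation per coefficient
#'   (scalar or length-q vector).
#' @param noise_var Observation noise variance per ROI (scalar or
#'   length-R vector).
#' @return Object of class `"hvar_truth"`: the spec, design, per-group
#'   coefficient arrays (`phi`, see [phi_flatten()]), `dev_sd`,
#'   `noise_var`, `subjects_per_group`, `seed`.
#' @export
make_default_truth <- function(R, K, n_edges, effect_size, seed,
                               conditions = c("rest", "active"),
                               groups = c("group1", "group2"),
                               subjects_per_group = 13L,
                               design = hvar_block_design(2, 48, 12,
                                                          conditions = conditions),
                               dev_sd = 0.1, noise_var = 1) {
  spec <- hvar_spec(paste0("roi", seq_len(R)), lags = K,
                    conditions = conditions, groups = groups)
  C <- spec$C
  ncross <- R * (R - 1L) * K * C
  if (n_edges > ncross)
    stop(sprintf("n_edges exceeds the %d available cross-edge slots", ncross))
  set.seed(as.integer(seed))
  Phi <- array(0, dim = c(R, R, K, C),
               dimnames = list(spec$rois, spec$rois, NULL, conditions))
  for (cc in seq_len(C)) Phi[, , 1L, cc] <- diag(0.3, R)
  if (n_edges > 0L) {
    slots <- which(array(rep(!diag(R), K * C), dim = dim(Phi)))
    pick <- sample(slots, n_edges)
    Phi[pick] <- effect_size * sample(c(-1, 1), n_edges, replace = TRUE)
  }
  for (cc in seq_len(C)) {
    # for K > 1 the companion radius is not homogeneous in a common scale
    # factor, so rescale iteratively (cap 50 rounds)
    for (rnd in seq_len(50L)) {
      rho <- companion_spectral_radius(
        lapply(seq_len(K), function(k) Phi[, , k, cc]))
      if (rho <= 0.9) break
      Phi[, , , cc] <- Phi[, , , cc] * (0.9 / rho)
    }
    if (rho > 0.9)
      stop("could not rescale the truth to spectral radius 0.9")
  }
  phi <- stats::setNames(rep(list(Phi), spec$G), spec$groups)
  if (length(dev_sd) == 1L) dev_sd <- rep(dev_sd, spec$q)
  if (length(dev_sd) != spec$q) stop("dev_sd must be scalar or length q")
  if (length(noise_var) == 1L) noise_var <- rep(noise_var, R)
  if (length(noise_var) != R) stop("noise_var must be scalar or length R")
  structure(list(spec = spec, design = design, phi = phi,
                 dev_sd = dev_sd, noise_var = noise_var,
                 subjects_per_group = as.integer(subjects_per_group),
                 seed = as.integer(seed)),
            class = "hvar_truth")
}

#' @export
print.hvar_truth <- function(x, ...) {
  cat("Synthetic study truth\n")
  print(x$spec)
  nz <- sum(phi_flatten(x$phi, x$spec) != 0) / x$spec$G
  cat(sprintf("  nonzero coefficients per group: %d; deviation SD %.3g; noise var %.3g\n",
              nz, x$dev_sd[1L], x$noise_var[1L]))
  invisible(x)
}

# iterate the condition-switching VAR over the sessions of a design;
# each session starts from a 200-step warm-up under its opening condition
simulate_switching_var <- function(Phi, W, session_starts, noise_sd,
                                   warmup = 200L) {
  R <- dim(Phi)[1L]; K <- dim(Phi)[3L]
  Tn <- nrow(W)
  Y <- matrix(0, Tn, R)
  for (rg in session_ranges(Tn, session_starts)) {
    open_cond <- which(W[rg[1L], ] == 1)
    buf <- matrix(0, warmup + (rg[2] - rg[1] + 1L), R)
    for (t in seq_len(nrow(buf))) {
      cc <- if (t <= warmup) open_cond else which(W[rg[1L] + t - warmup - 1L, ] == 1)
      acc <- stats::rnorm(R, sd = noise_sd)
      for (k in seq_len(K))
        if (t - k >= 1L) acc <- acc + Phi[, , k, cc] %*% buf[t - k, ]
      buf[t, ] <- acc
    }
    Y[rg[1L]:rg[2L], ] <- buf[-seq_len(warmup), , drop = FALSE]
  }
  Y
}

#' Simulate a multi-subject study from a ground truth
#'
#' For every subject: draw the deviation vector from the truth's diagonal
#' normal, form subject coefficients (group truth plus deviation), resample
#' the deviation (up to 100 tries) if any condition's companion spectral
#' radius reaches 1, then iterate the condition-switching VAR per session
#' from a 200-step warm-up under the session's opening condition, adding
#' diagonal Gaussian noise.  Fully reproducible from `truth$seed`.
#'
#' @param truth A [make_default_truth()] object (or hand-built
#'   `"hvar_truth"`).
#' @return Object of class `"hvar_study"`: `series` (list of
#'   [hvar_subject()]), the `truth`, and `xi` (the realized deviation
#'   vectors, subjects in rows).
#' @export
simulate_study <- function(truth) {
  stopifnot(inherits(truth, "hvar_truth"))
  spec <- truth$spec
  set.seed(truth$seed)
  W <- make_block_indicators(truth$design)
  starts <- attr(W, "session_starts")
  series <- list(); xi_all <- NULL
  noise_sd <- sqrt(truth$noise_var)
  for (g in spec$groups) {
    flat_g <- phi_flatten(truth$phi, spec)[
      (match(g, spec$groups) - 1L) * spec$q + seq_len(spec$q)]
    for (i in seq_len(truth$subjects_per_group)) {
      sid <- sprintf("%s_s%02d", g, i)
      ok <- FALSE
      for (try in seq_len(100L)) {
        xi <- stats::rnorm(spec$q, sd = truth$dev_sd)
        Phi_s <- phi_unflatten(flat_g + xi,
                               hvar_spec(spec$rois, spec$K, spec$conditions,
                                         groups = "s"))[[1L]]
        rho <- max(vapply(seq_len(spec$C), function(cc)
          companion_spectral_radius(lapply(seq_len(spec$K),
                                           function(k) Phi_s[, , k, cc])),
          numeric(1)))
        if (rho < 1) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("subject %s: no stationary deviation found in 100 tries", sid))
      Y <- simulate_switching_var(Phi_s, W, starts, noise_sd)
      colnames(Y) <- spec$rois
      series[[sid]] <- hvar_subject(Y, W, sid, group = g,
                                    session_starts = starts)
      xi_all <- rbind(xi_all, xi)
    }
  }
  rownames(xi_all) <- names(series)
  structure(list(series = series, truth = truth, xi = xi_all),
            class = "hvar_study")
}

#' @export
print.hvar_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d subjects, T = %d scans each\n",
              length(x$series), nrow(x$series[[1L]]$Y)))
  print(x$truth)
  invisible(x)
}
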