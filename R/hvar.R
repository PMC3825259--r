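#' Fit the hierarchical Bayesian VAR for multi-subject effective connectivity
#'
#' The model: each subject's ROI time series follows a VAR(K) whose
#' coefficient matrices switch with the experimental condition; subject
#' coefficients are group coefficients plus diagonal-normal random
#' deviations; observation noise is diagonal with ROI-specific precisions
#' shared across subjects; and the group coefficients carry a hierarchical
#' shrinkage prior whose conditional posterior mode reproduces the
#' elastic-net penalized least-squares criterion (an L1 term controlled by
#' `gamma` and an L2 term controlled by `lambda2`, both learned from the
#' data).  All unknowns are drawn by a Gibbs sampler with closed-form full
#' conditionals; see [run_gibbs()].
#'
#' @param study List of [hvar_subject()] objects (all groups pooled).
#' @param spec A [hvar_spec()] shared by every subject.
#' @param hyper Prior settings, a [hvar_hyper()].
#' @param control Sampler settings, a [hvar_control()].
#' @param detrend If `TRUE`, each subject's series is first residualized
#'   against the nuisance design (expected condition responses, polynomial
#'   drift, seasonal components) via [preprocess_subject()].
#' @param detrend_options Named list passed to [preprocess_subject()]
#'   (`TR`, `poly_order`, `frequencies`, HRF parameters).
#' @return Object of class `"hvar"`; components include the retained draws
#'   (`samples`), the spec, and the study.  Methods: `print`, `summary`,
#'   `coef` (posterior-mean coefficient arrays), `confint`, `fitted`,
#'   `residuals`, `plot` (traces), `simulate` (posterior-mean generative
#'   replicates).
#' @seealso [group_network()], [contrast_network()], [subject_network()],
#'   [variance_summaries()], [make_default_truth()], [simulate_study()]
#' @examples
#' truth <- make_default_truth(R = 2, K = 1, n_edges = 1, effect_size = 0.4,
#'                             seed = 7, groups = "g1", subjects_per_group = 2,
#'                             design = hvar_block_design(1, 24, 12))
#' study <- simulate_study(truth)
#' fit <- hvar(study$series, truth$spec,
#'             control = hvar_control(400, 200, 2, seed = 1))
#' fit
#' @export
hvar <- function(study, spec, hyper = hvar_hyper(),
                 control = hvar_control(), detrend = FALSE,
                 detrend_options = list()) {
  stopifnot(inherits(spec, "hvar_spec"))
  if (detrend)
    study <- lapply(study, function(su)
      do.call(preprocess_subject, c(list(subject = su), detrend_options)))
  samples <- run_gibbs(study, spec, hyper, control)
  structure(list(samples = samples, spec = spec, study = study,
                 call = match.call()),
            class = "hvar")
}

# N x K matrix of lag-joint draws for one (group, condition, target, source)
phi_draws <- function(fit, group, condition, target, source,
                      subject = NULL) {
  spec <- fit$spec
  tgt <- match(target, spec$rois); src <- match(source, spec$rois)
  if (is.na(tgt) || is.na(src)) stop("unknown ROI label")
  cols <- vapply(seq_len(spec$K), function(k)
    phi_index(spec, group, condition, k, tgt, src), numeric(1))
  draws <- fit$samples$phi[, cols, drop = FALSE]
  if (!is.null(subject)) {
    s <- match(subject, fit$samples$subjects)
    if (is.na(s)) stop(sprintf("unknown subject '%s'", subject))
    jb <- cols - (match(group, spec$groups) - 1L) * spec$q
    draws <- draws + fit$samples$xi[, (s - 1L) * spec$q + jb, drop = FALSE]
  }
  draws
}

#' @export
print.hvar <- function(x, ...) {
  s <- x$samples
  cat("Hierarchical elastic-net VAR fit\n")
  print(x$spec)
  cat(sprintf("  subjects: %d (%s)\n", length(s$subjects),
              paste(sprintf("%s: %d", x$spec$groups,
                            tabulate(match(s$groups_of_subjects, x$spec$groups),
                                     x$spec$G)), collapse = ", ")))
  cat(sprintf("  retained draws: %d (of %d iterations, burn-in %d, thin %d)\n",
              s$n_draws, s$control$iterations, s$control$burn_in,
              s$control$thin))
  invisible(x)
}

#' @export
summary.hvar <- function(object, level = 0.95, ...) {
  s <- object$samples
  pr <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  zg <- if (s$n_draws >= 100L)
    suppressWarnings(geweke_diagnostic(s$phi)) else NA_real_
  noise <- t(apply(1 / s$tau, 2L, stats::quantile, probs = pr))
  colnames(noise) <- quantile_labels(pr)
  out <- list(
    spec = object$spec,
    n_draws = s$n_draws,
    phi_mean = colMeans(s$phi),
    phi_ci = t(apply(s$phi, 2L, stats::quantile, probs = pr[c(1L, 3L)])),
    noise_variance = noise,
    lambda2 = stats::quantile(s$lambda2, pr),
    gamma = stats::quantile(s$gamma, pr),
    geweke_max_abs_z = if (all(is.na(zg))) NA_real_ else
      max(abs(zg), na.rm = TRUE),
    level = level)
  class(out) <- "summary.hvar"
  out
}

#' @export
print.summary.hvar <- function(x, ...) {
  cat(sprintf("Hierarchical VAR posterior summary (%d draws)\n", x$n_draws))
  cat("\nROI noise variances (posterior quantiles):\n")
  print(round(x$noise_variance, 4))
  cat("\nShrinkage weights:\n")
  print(round(rbind(lambda2 = x$lambda2, gamma = x$gamma), 4))
  nz <- sum(sign(x$phi_ci[, 1L]) == sign(x$phi_ci[, 2L]) &
              x$phi_ci[, 1L] != 0)
  cat(sprintf("\n%d of %d group coefficients have a %g%% interval excluding 0\n",
              nz, length(x$phi_mean), 100 * x$level))
  cat(sprintf("max |Geweke z| over group coefficients: %.2f\n",
              x$geweke_max_abs_z))
  invisible(x)
}

#' @export
coef.hvar <- function(object, ...) {
  phi_unflatten(colMeans(object$samples$phi), object$spec)
}

#' @export
confint.hvar <- function(object, parm, level = 0.95, ...) {
  ci <- t(apply(object$samples$phi, 2L, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

# posterior-mean fitted values / residuals, per subject, on the usable rows
hvar_fitted <- function(object) {
  spec <- object$spec
  gd <- gibbs_data(object$study, spec)
  phi_bar <- colMeans(object$samples$phi)
  xi_bar <- colMeans(object$samples$xi)
  lapply(seq_len(gd$S), function(s) {
    g <- gd$g_of[s]
    v <- phi_bar[(g - 1L) * spec$q + seq_len(spec$q)] +
      xi_bar[(s - 1L) * spec$q + seq_len(spec$q)]
    fit <- gd$P[[s]] %*% t(coef_mat(v, spec$R))
    dimnames(fit) <- list(gd$t_idx[[s]], spec$rois)
    list(subject_id = gd$subjects[s], fitted = fit,
         observed = gd$Yresp[[s]])
  })
}

#' @export
fitted.hvar <- function(object, ...) lapply(hvar_fitted(object), `[[`, "fitted")

#' @export
residuals.hvar <- function(object, ...)
  lapply(hvar_fitted(object), function(f) f$observed - f$fitted)

#' @export
plot.hvar <- function(x, pars = c("lambda2", "gamma"), ...) {
  s <- x$samples
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    v <- if (p %in% c("lambda2", "gamma")) s[[p]] else s$phi[, p]
    graphics::plot(v, type = "l", ylab = p, xlab = "draw", main = p, ...)
  }
  invisible(x)
}

#' @export
simulate.hvar <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- object$spec
  coefs <- coef.hvar(object)
  tau_bar <- colMeans(object$samples$tau)
  replicate(nsim, simplify = FALSE, {
    lapply(object$study, function(su) {
      Phi <- coefs[[su$group]]
      Y <- simulate_switching_var(Phi, su$W, su$session_starts,
                                  noise_sd = sqrt(1 / tau_bar),
                                  warmup = 200L)
      hvar_subject(Y, su$W, su$subject_id, su$group, su$session_starts)
    })
  })
}
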