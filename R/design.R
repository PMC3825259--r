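## Deterministic regression structures of the condition-switching VAR.
##
## Coefficient vector ordering (fixed once, used everywhere):
## within one group's block of length q = R^2*K*C, index
##   j = ((c-1)*K + (k-1)) * R^2 + (src-1) * R + tgt
## i.e. condition-major, then lag, then the column-major unrolling of each
## R x R matrix Phi (target row varies fastest).  Phi[tgt, src] multiplies
## the past value of source ROI `src` to predict target ROI `tgt`; network
## edges therefore point src -> tgt.  Groups are stacked blocks of length q.

phi_index <- function(spec, group, condition, lag, target, source) {
  g <- match(group, spec$groups)
  cc <- match(condition, spec$conditions)
  if (anyNA(g)) stop("unknown group label")
  if (anyNA(cc)) stop("unknown condition label")
  stopifnot(lag >= 1, lag <= spec$K)
  (g - 1L) * spec$q +
    ((cc - 1L) * spec$K + (lag - 1L)) * spec$R^2 +
    (source - 1L) * spec$R + target
}

# labels for the G*q coefficient columns: group.condition.lagK.target.source
phi_labels <- function(spec, groups = spec$groups) {
  lab <- character(0)
  for (g in groups)
    for (cc in spec$conditions)
      for (k in seq_len(spec$K))
        for (src in spec$rois)
          for (tgt in spec$rois)
            lab <- c(lab, paste(g, cc, paste0("lag", k), tgt, src, sep = "."))
  lab
}

# decode within-group coefficient index j (1..q) -> condition, lag, source, target
phi_decode <- function(spec, j) {
  j0 <- j - 1L
  tgt <- j0 %% spec$R + 1L
  src <- (j0 %/% spec$R) %% spec$R + 1L
  k <- (j0 %/% spec$R^2) %% spec$K + 1L
  cc <- j0 %/% (spec$R^2 * spec$K) + 1L
  data.frame(condition = spec$conditions[cc], lag = k,
             source = spec$rois[src], target = spec$rois[tgt],
             stringsAsFactors = FALSE)
}

#' Flatten condition/lag coefficient matrices to the canonical vector
#'
#' A coefficient set is a named list with one element per group, each an
#' `R x R x K x C` array `Phi` where `Phi[tgt, src, k, c]` is the lag-`k`
#' coefficient of source ROI `src` predicting target ROI `tgt` under
#' condition `c`.  `phi_flatten()` maps it to the length-`G*q` vector used by
#' the sampler (condition-major, then lag, then column-major unrolling);
#' `phi_unflatten()` is its exact inverse.
#'
#' @param coef_set Named list (one element per group in `spec$groups`) of
#'   `R x R x K x C` arrays.
#' @param spec A [hvar_spec()].
#' @return `phi_flatten()`: numeric vector of length `G*q`;
#'   `phi_unflatten()`: a coefficient set.
#' @export
phi_flatten <- function(coef_set, spec) {
  stopifnot(inherits(spec, "hvar_spec"))
  if (!setequal(names(coef_set), spec$groups))
    stop("coef_set must have one element per group")
  out <- numeric(0)
  for (g in spec$groups) {
    Phi <- coef_set[[g]]
    if (!all(dim(Phi) == c(spec$R, spec$R, spec$K, spec$C)))
      stop("each coefficient array must be R x R x K x C")
    v <- numeric(spec$q)
    for (cc in seq_len(spec$C))
      for (k in seq_len(spec$K)) {
        off <- ((cc - 1L) * spec$K + (k - 1L)) * spec$R^2
        v[off + seq_len(spec$R^2)] <- as.vector(Phi[, , k, cc])
      }
    out <- c(out, v)
  }
  names(out) <- phi_labels(spec)
  out
}

#' @rdname phi_flatten
#' @param phi Numeric vector of length `G*q` (or length `q` for one group).
#' @export
phi_unflatten <- function(phi, spec) {
  stopifnot(inherits(spec, "hvar_spec"))
  if (length(phi) == spec$q && spec$G > 1L)
    stop("phi has length q; expected G*q")
  if (length(phi) != spec$G * spec$q && length(phi) != spec$q)
    stop("phi must have length G*q")
  ngrp <- length(phi) %/% spec$q
  out <- vector("list", ngrp)
  names(out) <- spec$groups[seq_len(ngrp)]
  for (g in seq_len(ngrp)) {
    Phi <- array(0, dim = c(spec$R, spec$R, spec$K, spec$C),
                 dimnames = list(spec$rois, spec$rois, NULL, spec$conditions))
    vg <- phi[(g - 1L) * spec$q + seq_len(spec$q)]
    for (cc in seq_len(spec$C))
      for (k in seq_len(spec$K)) {
        off <- ((cc - 1L) * spec$K + (k - 1L)) * spec$R^2
        Phi[, , k, cc] <- matrix(vg[off + seq_len(spec$R^2)], spec$R, spec$R)
      }
    out[[g]] <- Phi
  }
  out
}

## Compact per-subject predictor representation.
##
## For every usable time point t (lagged values never cross a session
## boundary, so the first K scans of each session are dropped) the row of P
## holds the R*K*C regressor values
##   P[t, pc] = W[t, c] * Y[t - k, src],  pc = ((c-1)*K + (k-1))*R + src.
## The design row of the full model for (t, target tgt) loads P[t, ] on the
## coefficients with target tgt, so the regression factorizes by target ROI.
subject_predictors <- function(subject, spec) {
  Y <- subject$Y; W <- subject$W
  R <- spec$R; K <- spec$K; C <- spec$C
  if (ncol(Y) != R) stop("Y has wrong number of ROI columns")
  if (ncol(W) != C) stop("W has wrong number of condition columns")
  rows <- integer(0)
  for (rg in session_ranges(nrow(Y), subject$session_starts)) {
    if (rg[2] - rg[1] + 1L < K + 1L)
      stop(sprintf("subject '%s': a session is shorter than K+1 scans",
                   subject$subject_id))
    rows <- c(rows, (rg[1] + K):rg[2])
  }
  n <- length(rows)
  P <- matrix(0, n, R * K * C)
  for (cc in seq_len(C))
    for (k in seq_len(K)) {
      cols <- ((cc - 1L) * K + (k - 1L)) * R + seq_len(R)
      P[, cols] <- W[rows, cc] * Y[rows - k, , drop = FALSE]
    }
  list(P = P, Yresp = Y[rows, , drop = FALSE], t_idx = rows, n = n)
}

#' Per-subject regression matrices of the stacked VAR
#'
#' Rewrites one subject's condition-switching VAR as a linear model
#' `y_s = X_s phi + Z_s xi_s + noise`.  Each usable time point contributes
#' `R` rows (one per target ROI, target varying fastest); rows whose lagged
#' predictors would cross a session boundary are dropped, so each session
#' loses its first `K` scans.  `Z_s` carries the subject's random-effect
#' design (`n_s*R x q`); `X_s` is the group-expanded fixed-effects design
#' (`n_s*R x G*q`), equal to `Z_s` placed in the subject's group block and
#' zero elsewhere.  For `G = 1`, `X_s` and `Z_s` are entrywise equal.
#'
#' @param subject A [hvar_subject()].
#' @param spec A [hvar_spec()].
#' @return List with `X`, `Z`, `y`, the subject id and group, and `n` (number
#'   of usable time points).
#' @examples
#' sp <- hvar_spec("a", lags = 1, conditions = "c1")
#' su <- hvar_subject(matrix(1:3), matrix(1, 3, 1,
#'                    dimnames = list(NULL, "c1")), "s1")
#' build_subject_design(su, sp)  # X = (1, 2)', y = (2, 3)'
#' @export
build_subject_design <- function(subject, spec) {
  stopifnot(inherits(subject, "hvar_subject"), inherits(spec, "hvar_spec"))
  g <- match(subject$group, spec$groups)
  if (is.na(g)) stop(sprintf("subject '%s' has unknown group '%s'",
                             subject$subject_id, subject$group))
  sp <- subject_predictors(subject, spec)
  R <- spec$R; p <- ncol(sp$P); q <- spec$q
  Z <- matrix(0, sp$n * R, q)
  y <- numeric(sp$n * R)
  for (tgt in seq_len(R)) {
    ridx <- (seq_len(sp$n) - 1L) * R + tgt       # time-major, target fastest
    Z[ridx, (seq_len(p) - 1L) * R + tgt] <- sp$P
    y[ridx] <- sp$Yresp[, tgt]
  }
  X <- matrix(0, sp$n * R, spec$G * q)
  X[, (g - 1L) * q + seq_len(q)] <- Z
  list(X = X, Z = Z, y = y, subject_id = subject$subject_id,
       group = subject$group, n = sp$n)
}

#' Stack per-subject designs into the pooled study regression
#'
#' Row-stacks the group-expanded fixed-effects designs `X_s` and responses
#' `y_s`, and assembles the block-diagonal random-effects design `Z`
#' (one block per subject).
#'
#' @param designs List of outputs of [build_subject_design()].
#' @param spec A [hvar_spec()].
#' @return List with pooled `X` (`N x G*q`), block-diagonal `Z` (`N x S*q`),
#'   `y`, `subjects`, `groups` (per subject), and `row_subject` /
#'   `row_target` index vectors.
#' @export
stack_study <- function(designs, spec) {
  stopifnot(inherits(spec, "hvar_spec"))
  S <- length(designs)
  q <- spec$q
  nrows <- vapply(designs, function(d) nrow(d$X), integer(1))
  N <- sum(nrows)
  X <- matrix(0, N, spec$G * q)
  Z <- matrix(0, N, S * q)
  y <- numeric(N)
  at <- 0L
  for (s in seq_len(S)) {
    d <- designs[[s]]
    if (is.na(match(d$group, spec$groups)))
      stop(sprintf("subject '%s' has unknown group '%s'", d$subject_id, d$group))
    idx <- at + seq_len(nrows[s])
    X[idx, ] <- d$X
    Z[idx, (s - 1L) * q + seq_len(q)] <- d$Z
    y[idx] <- d$y
    at <- at + nrows[s]
  }
  list(X = X, Z = Z, y = y,
       subjects = vapply(designs, `[[`, "", "subject_id"),
       groups = vapply(designs, `[[`, "", "group"),
       row_subject = rep(seq_len(S), times = nrows),
       row_target = unlist(lapply(nrows, function(n) rep_len(seq_len(spec$R), n))))
}

#' Spectral radius of the VAR companion matrix
#'
#' Embeds the lag matrices of one condition into the `RK x RK` companion
#' matrix and returns its spectral radius; a value below 1 certifies a
#' stationary regime for that condition.
#'
#' @param Phi_lags List of `K` square `R x R` matrices (lag 1 first), or a
#'   single matrix for `K = 1`.
#' @return Nonnegative scalar.
#' @examples
#' companion_spectral_radius(0.5 * diag(2))  # 0.5
#' @export
companion_spectral_radius <- function(Phi_lags) {
  M <- companion_matrix(Phi_lags)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

companion_matrix <- function(Phi_lags) {
  if (is.matrix(Phi_lags)) Phi_lags <- list(Phi_lags)
  if (is.array(Phi_lags) && length(dim(Phi_lags)) == 3L)
    Phi_lags <- lapply(seq_len(dim(Phi_lags)[3]), function(k) Phi_lags[, , k])
  K <- length(Phi_lags)
  R <- nrow(Phi_lags[[1L]])
  for (Phi in Phi_lags)
    if (!is.matrix(Phi) || nrow(Phi) != R || ncol(Phi) != R)
      stop("lag matrices must all be square with matching dimension")
  M <- matrix(0, R * K, R * K)
  for (k in seq_len(K))
    M[seq_len(R), (k - 1L) * R + seq_len(R)] <- Phi_lags[[k]]
  if (K > 1L)
    M[R + seq_len(R * (K - 1L)), seq_len(R * (K - 1L))] <-
      diag(R * (K - 1L))
  M
}

#' Stationary covariance of a fixed-condition VAR regime
#'
#' Computes the stationary covariance of the observed `R`-vector under one
#' condition's coefficients and diagonal noise, as the convergent series
#' `sum_i M^i Sigma (M^i)'` over the companion embedding `M`, truncated when
#' the largest absolute entry of a term falls below `tol` (cap 10000 terms).
#' Agrees with the exact discrete-Lyapunov solution.
#'
#' @inheritParams companion_spectral_radius
#' @param sigma2 Noise variances per ROI (vector of length `R`, positive),
#'   i.e. the diagonal of the observation covariance.
#' @param tol Truncation tolerance on the largest absolute entry of a term.
#' @return `R x R` covariance matrix.
#' @examples
#' stationary_covariance(matrix(0.5), 1)  # AR(1): 1/(1-0.25) = 4/3
#' @export
stationary_covariance <- function(Phi_lags, sigma2, tol = 1e-10) {
  M <- companion_matrix(Phi_lags)
  R <- if (is.matrix(Phi_lags)) nrow(Phi_lags) else
    nrow(if (is.array(Phi_lags) && length(dim(Phi_lags)) == 3L)
      Phi_lags[, , 1] else Phi_lags[[1L]])
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, R)
  if (length(sigma2) != R || any(sigma2 <= 0))
    stop("'sigma2' must be positive, one value per ROI")
  rho <- max(Mod(eigen(M, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("nonstationary regime: companion spectral radius %.4f >= 1", rho))
  Sig <- matrix(0, nrow(M), nrow(M))
  diag(Sig)[seq_len(R)] <- sigma2
  V <- Sig
  term <- Sig
  for (i in seq_len(10000L)) {
    term <- M %*% term %*% t(M)
    if (max(abs(term)) < tol) break
    V <- V + term
  }
  V[seq_len(R), seq_len(R), drop = FALSE]
}
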