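## Nuisance regression: remove the expected condition-locked BOLD response,
## slow scanner drift and periodic physiological components from each ROI
## series before VAR fitting, so the VAR models the residual dynamics.

#' Canonical double-gamma hemodynamic response function
#'
#' The standard BOLD impulse response: a gamma-density response minus a
#' scaled gamma-density undershoot, evaluated on a time grid in seconds and
#' normalized to a peak of 1.  With the default parameters (response delay
#' 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 1/6,
#' 32 s support) the maximum falls near 5 s.
#'
#' @param t Nonnegative time grid in seconds.
#' @param peak_delay,peak_disp Delay and dispersion of the response gamma.
#' @param under_delay,under_disp Delay and dispersion of the undershoot.
#' @param ratio Undershoot ratio (subtracted fraction).
#' @param duration Support in seconds; the response is 0 beyond it.
#' @return Numeric vector, `max(.) == 1` when the grid covers the peak.
#' @examples
#' h <- canonical_hrf(seq(0, 32, by = 0.1))
#' seq(0, 32, by = 0.1)[which.max(h)]  # about 5 s
#' @export
canonical_hrf <- function(t, peak_delay = 6, peak_disp = 1,
                          under_delay = 16, under_disp = 1,
                          ratio = 1 / 6, duration = 32) {
  if (length(t) == 0L) stop("empty time grid")
  if (any(t < 0)) stop("time grid must be nonnegative")
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = under_delay / under_disp,
                          scale = under_disp)
  h[t > duration] <- 0
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

#' Nuisance design for one session
#'
#' Columns: (1) one expected-response column per condition, the discrete
#' convolution of that condition's indicator with the canonical HRF sampled
#' at the TR; (2) polynomial drift columns of order 0..`poly_order`,
#' constructed on a time grid rescaled to \[-1, 1\] and orthogonalized for
#' conditioning (order 0 is the explicit intercept); and (3) a sine and
#' cosine pair at every requested frequency.  Frequencies at or above the
#' Nyquist limit `1/(2 TR)` cannot be represented and are dropped with a
#' warning (recorded in the `dropped_frequencies` attribute).
#'
#' @param W Binary condition-indicator matrix for the session (`T x C`).
#' @param TR Seconds per scan.
#' @param poly_order Highest polynomial drift order (default 3).
#' @param frequencies Seasonal frequencies in Hz (default a single 0.10 Hz
#'   band; the respiratory/cardiac bands proper lie above Nyquist at
#'   typical fMRI TRs and must be chosen per acquisition).
#' @param ... Passed to [canonical_hrf()].
#' @return Numeric matrix `T x (C + poly_order + 1 + 2 * #kept frequencies)`
#'   with named columns and attribute `dropped_frequencies`.
#' @export
build_nuisance_design <- function(W, TR, poly_order = 3,
                                  frequencies = 0.10, ...) {
  W <- as.matrix(W)
  Tn <- nrow(W); C <- ncol(W)
  nyq <- 1 / (2 * TR)
  drop <- frequencies >= nyq
  if (any(drop))
    warning(sprintf("dropping frequencies at/above Nyquist (%.3f Hz): %s",
                    nyq, paste(frequencies[drop], collapse = ", ")))
  keep <- frequencies[!drop]
  if (Tn < C + poly_order + 1 + 2 * length(keep) + 1)
    stop("series too short for the requested nuisance design")
  hrf <- canonical_hrf(seq(0, 32, by = TR), ...)
  resp <- matrix(0, Tn, C)
  for (cc in seq_len(C)) {
    conv <- stats::convolve(W[, cc], rev(hrf), type = "open")
    resp[, cc] <- conv[seq_len(Tn)]
  }
  colnames(resp) <- paste0("resp.", colnames(W) %||% seq_len(C))
  tt <- seq(-1, 1, length.out = Tn)
  polys <- matrix(1, Tn, 1)
  if (poly_order >= 1)
    polys <- cbind(polys, stats::poly(tt, poly_order))
  colnames(polys) <- paste0("poly", 0:poly_order)
  seas <- NULL
  if (length(keep)) {
    seas <- do.call(cbind, lapply(keep, function(f) {
      ph <- 2 * pi * f * (seq_len(Tn) - 1) * TR
      cbind(sin(ph), cos(ph))
    }))
    colnames(seas) <- as.vector(rbind(paste0("sin.", keep),
                                      paste0("cos.", keep)))
  }
  X <- cbind(resp, polys, seas)
  if (any(apply(X, 2L, function(v) all(v == 0))))
    stop("nuisance design contains an identically zero column")
  attr(X, "dropped_frequencies") <- frequencies[drop]
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residualize ROI series against a nuisance design
#'
#' Ordinary least squares of every ROI column on the design; returns the
#' residual matrix.  Residuals are numerically orthogonal to each design
#' column, and detrending is idempotent.
#'
#' @param Y Numeric `T x R` matrix (one session).
#' @param design Nuisance design from [build_nuisance_design()]; an
#'   intercept column is added only if the design has no constant column.
#' @return Residual matrix with attribute `r_squared` (per-ROI nuisance
#'   R^2).
#' @export
detrend_subject <- function(Y, design) {
  Y <- as.matrix(Y)
  X <- as.matrix(design)
  if (!any(apply(X, 2L, function(v) stats::sd(v) == 0 && v[1] != 0)))
    X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) != nrow(Y)) stop("design and series lengths differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qrX$pivot[seq_len(qrX$rank)])]
    stop(sprintf("nuisance design is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qrX, Y)
  tot <- apply(Y, 2L, function(y) sum((y - mean(y))^2))
  rss <- colSums(res^2)
  attr(res, "r_squared") <- ifelse(tot > 0, 1 - rss / tot, 0)
  dimnames(res) <- dimnames(Y)
  res
}

#' Detrend a subject, session by session
#'
#' Sessions differ in baseline, so the nuisance regression is performed per
#' session independently and the residual sessions are re-concatenated with
#' the original session boundaries preserved.
#'
#' @param subject A [hvar_subject()].
#' @inheritParams build_nuisance_design
#' @return A new [hvar_subject()] holding residual series, with a
#'   `preprocess_report` attribute (per-session dropped frequencies and
#'   per-ROI nuisance R^2).
#' @export
preprocess_subject <- function(subject, TR = 2, poly_order = 3,
                               frequencies = 0.10, ...) {
  stopifnot(inherits(subject, "hvar_subject"))
  out <- subject$Y
  report <- list()
  for (rg in session_ranges(nrow(subject$Y), subject$session_starts)) {
    idx <- rg[1]:rg[2]
    X <- suppressWarnings(
      build_nuisance_design(subject$W[idx, , drop = FALSE], TR = TR,
                            poly_order = poly_order,
                            frequencies = frequencies, ...))
    res <- detrend_subject(subject$Y[idx, , drop = FALSE], X)
    out[idx, ] <- res
    report[[length(report) + 1L]] <-
      list(session_start = rg[1],
           dropped_frequencies = attr(X, "dropped_frequencies"),
           r_squared = attr(res, "r_squared"))
  }
  res_subj <- hvar_subject(out, subject$W, subject$subject_id,
                           subject$group, subject$session_starts)
  attr(res_subj, "preprocess_report") <- report
  res_subj
}
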