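## Granger-causality network construction from posterior draws.
##
## An edge src -> tgt is declared for a condition when the lag-joint
## posterior distribution of [Phi_1(tgt,src), ..., Phi_K(tgt,src)] excludes
## the origin at the requested credibility level, judged on the highest-
## density region of a K-dimensional histogram of the draws.

#' Does the highest-density region of a sample exclude the origin?
#'
#' Builds a K-dimensional histogram of the draws, finds the smallest count
#' threshold whose super-level set of bins holds at least `level` of the
#' draws (the empirical highest-density region), and reports whether the
#' origin's bin falls outside that set.  The histogram grid is aligned so
#' the origin sits at the center of a bin, with the range padded 5% beyond
#' the sample extremes.  For more than three dimensions the histogram is
#' unreliable and a Gaussian-approximation Mahalanobis test at the same
#' level is used instead (flagged in the result).  In one symmetric
#' unimodal dimension the HDR rule reduces to the familiar equal-tail
#' credible-interval check.
#'
#' @param samples Numeric vector or `N x K` matrix of posterior draws
#'   (rows = draws, columns = lags or contrast components).
#' @param level Credibility level in (0, 1), default 0.95.
#' @param method `"auto"` (histogram HDR for K <= 3, Mahalanobis above),
#'   `"hdr"`, `"mahalanobis"`, or `"contour"` (the literal fixed-height
#'   rule: bins with count below `(1 - level)/2` of the modal bin count are
#'   outside -- the 0.025 contour at level 0.95).
#' @return Logical: `TRUE` when the origin is excluded (a significant
#'   edge).  Attributes carry diagnostics (`method`, `level`, origin bin
#'   count and threshold, bins per dimension).
#' @examples
#' set.seed(1)
#' hdr_excludes_origin(cbind(rnorm(4000, 5), rnorm(4000, 5)))  # TRUE
#' hdr_excludes_origin(cbind(rnorm(4000), rnorm(4000)))        # FALSE
#' @export
hdr_excludes_origin <- function(samples, level = 0.95,
                                method = c("auto", "hdr", "mahalanobis",
                                           "contour")) {
  method <- match.arg(method)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("non-finite draws")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  N <- nrow(samples); K <- ncol(samples)

  # degenerate (zero-variance) dimensions are decided analytically: a
  # constant nonzero coordinate excludes the origin outright; constant-zero
  # coordinates carry no information and are dropped
  v <- apply(samples, 2L, stats::var)
  if (any(v == 0)) {
    const <- samples[1L, v == 0]
    if (any(const != 0))
      return(structure(TRUE, method = "degenerate", level = level))
    samples <- samples[, v > 0, drop = FALSE]
    if (ncol(samples) == 0L)
      return(structure(FALSE, method = "degenerate", level = level))
    K <- ncol(samples)
  }

  if (method == "auto") method <- if (K <= 3L) "hdr" else "mahalanobis"
  if (method == "mahalanobis" || (method == "hdr" && K > 3L)) {
    m2 <- stats::mahalanobis(rep(0, K), colMeans(samples), stats::cov(samples))
    return(structure(m2 > stats::qchisq(level, df = K),
                     method = "mahalanobis", level = level,
                     mahalanobis = m2))
  }

  h <- hdr_histogram(samples)
  if (method == "contour") {
    # literal fixed-height rule: the region is delimited by the contour at
    # (1 - level)/2 of the modal bin height (0.025 for level 0.95)
    thr <- (1 - level) / 2 * max(h$counts)
    excluded <- h$counts[h$origin_bin] < thr
  } else {
    srt <- sort(h$counts[h$counts > 0L], decreasing = TRUE)
    k <- which(cumsum(srt) >= level * N)[1L]
    thr <- srt[k]
    excluded <- h$counts[h$origin_bin] < thr
  }
  structure(as.logical(excluded), method = method, level = level,
            origin_count = h$counts[h$origin_bin], threshold = thr,
            bins_per_dim = h$nb)
}

# K-dim histogram with origin-centered bins; per-dimension bin count
# ceil(N^(1/(K+2))) capped to [10, 50], range padded 5% beyond the extremes
# and forced to cover the origin
hdr_histogram <- function(samples) {
  N <- nrow(samples); K <- ncol(samples)
  nb_target <- min(50L, max(10L, ceiling(N^(1 / (K + 2)))))
  nb <- integer(K); bin <- matrix(0L, N, K); origin <- integer(K)
  for (k in seq_len(K)) {
    x <- samples[, k]
    lo <- min(x, 0); hi <- max(x, 0)
    pad <- 0.05 * (hi - lo)
    lo <- lo - pad; hi <- hi + pad
    w <- (hi - lo) / nb_target
    # shift the left edge so 0 falls at the center of a bin
    m <- round((0 - lo) / w - 0.5)
    lo2 <- -(m + 0.5) * w
    while (lo2 > lo) { m <- m + 1L; lo2 <- -(m + 0.5) * w }
    nb[k] <- ceiling((hi - lo2) / w)
    bin[, k] <- pmin(pmax(floor((x - lo2) / w) + 1L, 1L), nb[k])
    origin[k] <- m + 1L
  }
  mult <- cumprod(c(1L, nb[-K]))
  lin <- as.integer(1L + (bin - 1L) %*% mult)
  counts <- tabulate(lin, nbins = prod(nb))
  list(counts = counts, nb = nb,
       origin_bin = as.integer(1L + (origin - 1L) %*% mult))
}

edge_frame <- function(spec, draws_fun, condition, group_label, level,
                       method, adjust) {
  eff_level <- if (adjust == "bonferroni")
    1 - (1 - level) / spec$R^2 else level
  rows <- vector("list", spec$R^2)
  i <- 0L
  for (src in spec$rois)
    for (tgt in spec$rois) {
      i <- i + 1L
      draws <- draws_fun(tgt, src)
      dec <- hdr_excludes_origin(draws, level = eff_level, method = method)
      lag_means <- colMeans(draws)
      row <- data.frame(source = src, target = tgt,
                        condition = condition, group = group_label,
                        stringsAsFactors = FALSE)
      for (k in seq_along(lag_means))
        row[[paste0("mean.lag", k)]] <- lag_means[k]
      row$significant <- as.logical(dec)
      row$self_edge <- src == tgt
      row$level <- level
      rows[[i]] <- row
    }
  do.call(rbind, rows)
}

#' Group-level Granger-causality network
#'
#' Tests every ordered ROI pair (self-edges included) for the given
#' condition and group: the edge src -> tgt is significant when the
#' lag-joint credible region of its group coefficients excludes the origin.
#' No multiple-comparison correction is applied by default; an optional
#' Bonferroni-style adjustment over the R^2 tests is available.
#'
#' @param fit An [hvar()] fit (or [run_gibbs()] samples wrapped by `hvar`).
#' @param condition Condition label.
#' @param group Group label (defaults to the only group).
#' @param level Credibility level (default 0.95).
#' @param method Passed to [hdr_excludes_origin()].
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Object of class `"hvar_network"`: a data frame of all ordered
#'   pairs with per-lag posterior means and the significance flag, plus
#'   metadata attributes.
#' @export
group_network <- function(fit, condition, group = NULL, level = 0.95,
                          method = "auto", adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  spec <- fit$spec
  if (is.null(group)) {
    if (spec$G > 1L) stop("'group' must be given for a multi-group fit")
    group <- spec$groups
  }
  if (!condition %in% spec$conditions) stop("unknown condition label")
  if (!group %in% spec$groups) stop("unknown group label")
  ef <- edge_frame(spec, function(tgt, src)
    phi_draws(fit, group, condition, tgt, src),
    condition, group, level, method, adjust)
  structure(ef, class = c("hvar_network", "data.frame"),
            type = "group", level = level, adjust = adjust)
}

#' Condition- or group-difference Granger-causality network
#'
#' Forms per-draw, per-lag differences of connectivity coefficients between
#' two conditions (within one group) or two groups (within one condition)
#' and applies the same lag-joint credible-region test to the differences.
#' By symmetry the decisions do not depend on the order of the pair.
#'
#' @param fit An [hvar()] fit.
#' @param conditions Length-2 condition pair (give `group`), or
#' @param groups Length-2 group pair (give `condition`); exactly one of the
#'   two pairs must be supplied.
#' @param condition,group The fixed level of the other factor.
#' @inheritParams group_network
#' @return `"hvar_network"` data frame; `mean.lagK` columns hold posterior
#'   mean differences.
#' @export
contrast_network <- function(fit, conditions = NULL, groups = NULL,
                             condition = NULL, group = NULL, level = 0.95,
                             method = "auto",
                             adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  spec <- fit$spec
  if (is.null(conditions) == is.null(groups))
    stop("supply exactly one of 'conditions' (length 2) or 'groups' (length 2)")
  if (!is.null(conditions)) {
    stopifnot(length(conditions) == 2L)
    if (is.null(group)) {
      if (spec$G > 1L) stop("'group' must be given")
      group <- spec$groups
    }
    lab_cond <- paste(conditions, collapse = " - ")
    lab_grp <- group
    fun <- function(tgt, src)
      phi_draws(fit, group, conditions[1L], tgt, src) -
        phi_draws(fit, group, conditions[2L], tgt, src)
  } else {
    stopifnot(length(groups) == 2L)
    if (is.null(condition)) stop("'condition' must be given")
    lab_cond <- condition
    lab_grp <- paste(groups, collapse = " - ")
    fun <- function(tgt, src)
      phi_draws(fit, groups[1L], condition, tgt, src) -
        phi_draws(fit, groups[2L], condition, tgt, src)
  }
  ef <- edge_frame(spec, fun, lab_cond, lab_grp, level, method, adjust)
  structure(ef, class = c("hvar_network", "data.frame"),
            type = "contrast", level = level, adjust = adjust)
}

#' Subject-level Granger-causality network
#'
#' Uses the subject's individual coefficients -- group coefficients plus the
#' subject's deviation draws -- and proceeds exactly as [group_network()].
#'
#' @param fit An [hvar()] fit.
#' @param subject Subject identifier.
#' @inheritParams group_network
#' @return `"hvar_network"` data frame.
#' @export
subject_network <- function(fit, subject, condition, level = 0.95,
                            method = "auto",
                            adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  spec <- fit$spec
  s <- match(subject, fit$samples$subjects)
  if (is.na(s)) stop(sprintf("unknown subject '%s'", subject))
  group <- fit$samples$groups_of_subjects[s]
  ef <- edge_frame(spec, function(tgt, src)
    phi_draws(fit, group, condition, tgt, src, subject = subject),
    condition, paste0(group, "/", subject), level, method, adjust)
  structure(ef, class = c("hvar_network", "data.frame"),
            type = "subject", level = level, adjust = adjust)
}

#' @export
print.hvar_network <- function(x, ...) {
  sig <- x[x$significant, , drop = FALSE]
  cat(sprintf("%s network (%s, level %.2f): %d of %d directed edges significant\n",
              attr(x, "type"), x$condition[1L], attr(x, "level"),
              nrow(sig), nrow(x)))
  if (nrow(sig)) {
    cross <- sig[!sig$self_edge, , drop = FALSE]
    if (nrow(cross)) {
      cat("cross-edges (source -> target):\n")
      print.data.frame(cross[, !(names(cross) %in% c("self_edge", "level"))],
                       row.names = FALSE, digits = 3)
    }
    if (any(sig$self_edge))
      cat(sprintf("plus %d significant self-lags\n", sum(sig$self_edge)))
  }
  invisible(x)
}

# quantile column labels in the conventional Q.025 / Q.50 / Q.975 style
quantile_labels <- function(probs) {
  s <- sub("0$", "", sub("^0\\.", "", sprintf("%.3f", probs)))
  paste0("Q.", s)
}

#' Between-subject variability and ROI noise summaries
#'
#' The between-subject variance of each connectivity coefficient is the
#' reciprocal deviation precision `1/d_j`; its posterior mean is reported
#' per coefficient, mapped back to (group, condition, lag, source, target)
#' and ranked, with the top `k` per group flagged.  ROI noise variances
#' `1/tau_r` are summarized at the 0.025 / 0.50 / 0.975 posterior quantiles,
#' one ROI per row.
#'
#' @param fit An [hvar()] fit.
#' @param k Number of top-variance edges flagged per group (default 3).
#' @param probs Quantiles for the noise table.
#' @return List of class `"hvar_varsum"` with elements `edge_variances`
#'   (ranked data frame) and `noise_variances` (quantile table).
#' @export
variance_summaries <- function(fit, k = 3L,
                               probs = c(0.025, 0.5, 0.975)) {
  spec <- fit$spec
  dbar <- colMeans(1 / fit$samples$d)
  tabs <- vector("list", spec$G)
  for (g in seq_len(spec$G)) {
    idx <- (g - 1L) * spec$q + seq_len(spec$q)
    tab <- phi_decode(spec, seq_len(spec$q))
    tab$group <- spec$groups[g]
    tab$variance <- dbar[idx]
    tab <- tab[order(-tab$variance), ]
    tab$rank <- seq_len(nrow(tab))
    tab$top <- tab$rank <= k
    tabs[[g]] <- tab
  }
  edge <- do.call(rbind, tabs)
  rownames(edge) <- NULL
  noise <- t(apply(1 / fit$samples$tau, 2L, stats::quantile, probs = probs))
  colnames(noise) <- quantile_labels(probs)
  rownames(noise) <- spec$rois
  structure(list(edge_variances = edge, noise_variances = noise, k = k),
            class = "hvar_varsum")
}

#' @export
print.hvar_varsum <- function(x, ...) {
  cat("ROI noise variances (posterior quantiles):\n")
  print(round(x$noise_variances, 4))
  cat(sprintf("\nTop %d between-subject coefficient variances per group:\n", x$k))
  top <- x$edge_variances[x$edge_variances$top, , drop = FALSE]
  print.data.frame(top[, c("group", "condition", "lag", "source", "target",
                           "variance")], row.names = FALSE, digits = 4)
  invisible(x)
}
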