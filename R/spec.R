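#' Model specification for a condition-switching hierarchical VAR
#'
#' Defines the dimensions of the model: the ROIs (nodes of the connectivity
#' network), the VAR order, the experimental conditions whose presentation
#' switches the coefficient matrices, and the subject groups.  The number of
#' group-level connectivity parameters per group is `q = R^2 * K * C`, which
#' grows quadratically in the number of ROIs; the elastic-net prior of
#' [hvar()] exists to make that parameter count manageable.
#'
#' @param rois Character vector of ROI labels (length `R >= 1`).
#' @param lags VAR order `K >= 1`.
#' @param conditions Ordered character vector of condition labels
#'   (length `C >= 1`).  Default two conditions, `"rest"` and `"active"`.
#' @param groups Ordered character vector of subject-group labels
#'   (length `G >= 1`).
#'
#' @return An object of class `"hvar_spec"`: a list with elements `rois`,
#'   `K`, `conditions`, `groups`, the counts `R`, `C`, `G`, and
#'   `q = R^2 * K * C`.
#' @examples
#' sp <- hvar_spec(paste0("roi", 1:5), lags = 2)
#' sp$q  # 100 parameters per group: 25 per lag per condition
#' @export
hvar_spec <- function(rois, lags = 1L, conditions = c("rest", "active"),
                      groups = "group1") {
  rois <- as.character(rois)
  conditions <- as.character(conditions)
  groups <- as.character(groups)
  lags <- as.integer(lags)
  if (length(rois) < 1L || anyDuplicated(rois))
    stop("'rois' must be a non-empty vector of unique labels")
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("'conditions' must be a non-empty vector of unique labels")
  if (length(groups) < 1L || anyDuplicated(groups))
    stop("'groups' must be a non-empty vector of unique labels")
  if (is.na(lags) || lags < 1L) stop("'lags' must be a positive integer")
  R <- length(rois); C <- length(conditions); G <- length(groups)
  structure(list(rois = rois, K = lags, conditions = conditions,
                 groups = groups, R = R, C = C, G = G,
                 q = as.integer(R^2 * lags * C)),
            class = "hvar_spec")
}

#' @export
print.hvar_spec <- function(x, ...) {
  cat("Hierarchical VAR specification\n")
  cat(sprintf("  ROIs (R = %d): %s\n", x$R, paste(x$rois, collapse = ", ")))
  cat(sprintf("  VAR order K = %d\n", x$K))
  cat(sprintf("  conditions (C = %d): %s\n", x$C,
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  groups (G = %d): %s\n", x$G, paste(x$groups, collapse = ", ")))
  cat(sprintf("  parameters per group q = R^2*K*C = %d\n", x$q))
  invisible(x)
}

#' Block design of a condition-switching experiment
#'
#' Describes sessions of equal length in which experimental conditions are
#' presented in fixed-length alternating blocks, e.g. the classic fMRI
#' block design of 48-scan sessions alternating 12 scans of rest and active
#' condition, always opening with rest.
#'
#' @param sessions Number of sessions.
#' @param scans_per_session Scans (time points) per session; must be a
#'   positive multiple of `block_length`.
#' @param block_length Scans per condition block.
#' @param conditions Ordered condition labels; blocks within a session cycle
#'   through this order, starting with the first label.
#' @param TR Repetition time in seconds per scan (positive).
#'
#' @return Object of class `"hvar_block_design"` with fields as given plus
#'   the total length `T = sessions * scans_per_session`.
#' @examples
#' bd <- hvar_block_design(sessions = 2, scans_per_session = 48,
#'                         block_length = 12)
#' bd$T_total  # 96
#' @export
hvar_block_design <- function(sessions, scans_per_session, block_length,
                              conditions = c("rest", "active"), TR = 2) {
  sessions <- as.integer(sessions)
  scans_per_session <- as.integer(scans_per_session)
  block_length <- as.integer(block_length)
  if (sessions < 1L) stop("'sessions' must be >= 1")
  if (block_length < 1L) stop("'block_length' must be >= 1")
  if (scans_per_session < 1L || scans_per_session %% block_length != 0L)
    stop("'scans_per_session' must be a positive multiple of 'block_length'")
  if (!is.numeric(TR) || TR <= 0) stop("'TR' must be a positive number")
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("'conditions' must be unique labels")
  structure(list(sessions = sessions,
                 scans_per_session = scans_per_session,
                 block_length = block_length,
                 conditions = conditions,
                 TR = TR,
                 T_total = sessions * scans_per_session),
            class = "hvar_block_design")
}

#' @export
print.hvar_block_design <- function(x, ...) {
  cat(sprintf("Block design: %d session(s) x %d scans (TR = %gs), blocks of %d: %s ...\n",
              x$sessions, x$scans_per_session, x$TR, x$block_length,
              paste(x$conditions, collapse = " -> ")))
  invisible(x)
}

#' Condition indicator matrix of a block design
#'
#' Expands a block design into a binary matrix `W` of size `T x C` with one
#' column per condition.  The indicator of a condition is 1 from its block
#' onset until the next block onset; every session restarts the block cycle
#' with the first condition.  Each row has exactly one 1: the conditions
#' partition time.
#'
#' @param design A [hvar_block_design()].
#' @return Binary matrix `T x C` with condition labels as column names and
#'   attribute `session_starts` (1-based first scan of each session).
#' @examples
#' W <- make_block_indicators(hvar_block_design(1, 48, 12))
#' which(W[, "rest"] == 1)  # scans 1-12 and 25-36
#' @export
make_block_indicators <- function(design) {
  stopifnot(inherits(design, "hvar_block_design"))
  C <- length(design$conditions)
  nblock <- design$scans_per_session %/% design$block_length
  cond_of_block <- ((seq_len(nblock) - 1L) %% C) + 1L
  session_cond <- rep(cond_of_block, each = design$block_length)
  cond_idx <- rep(session_cond, times = design$sessions)
  W <- matrix(0L, nrow = design$T_total, ncol = C,
              dimnames = list(NULL, design$conditions))
  W[cbind(seq_len(design$T_total), cond_idx)] <- 1L
  attr(W, "session_starts") <-
    seq(1L, by = design$scans_per_session, length.out = design$sessions)
  W
}

#' One subject's multi-ROI time series with condition indicators
#'
#' Bundles a detrended `T x R` ROI time-series matrix with the per-timepoint
#' condition indicators and session boundaries needed to build the
#' condition-switching VAR regression.
#'
#' @param Y Numeric matrix, rows = scans, columns = ROIs (all finite).
#' @param W Binary indicator matrix `T x C`, one column per condition, each
#'   row summing to exactly 1 (e.g. from [make_block_indicators()]).
#' @param subject_id Subject identifier.
#' @param group Group label.
#' @param session_starts Sorted integer vector of 1-based first scans of
#'   each session; defaults to `attr(W, "session_starts")` or a single
#'   session.
#' @return Object of class `"hvar_subject"`.
#' @export
hvar_subject <- function(Y, W, subject_id, group = "group1",
                         session_starts = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (!all(is.finite(Y)))
    stop(sprintf("subject '%s': non-finite values in Y", subject_id))
  W <- as.matrix(W)
  if (nrow(W) != nrow(Y))
    stop("Y and W must have the same number of rows")
  if (!all(W %in% c(0, 1)) || !all(rowSums(W) == 1))
    stop("each row of W must contain exactly one 1 (conditions partition time)")
  if (is.null(session_starts))
    session_starts <- attr(W, "session_starts")
  if (is.null(session_starts)) session_starts <- 1L
  session_starts <- sort(as.integer(session_starts))
  if (session_starts[1L] != 1L)
    stop("session_starts must begin at the first time index")
  if (any(session_starts > nrow(Y)))
    stop("session_starts outside the series")
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 Y = Y, W = W,
                 session_starts = session_starts),
            class = "hvar_subject")
}

#' @export
print.hvar_subject <- function(x, ...) {
  cat(sprintf("Subject '%s' (group '%s'): T = %d scans, R = %d ROIs, %d session(s)\n",
              x$subject_id, x$group, nrow(x$Y), ncol(x$Y),
              length(x$session_starts)))
  invisible(x)
}

# session index boundaries: list of (start, end) per session
session_ranges <- function(T_total, session_starts) {
  ends <- c(session_starts[-1L] - 1L, T_total)
  Map(function(s, e) c(s, e), session_starts, ends)
}
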