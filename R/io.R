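## Plain-text readers and writers: wide CSV time series (one file per
## subject per session, header row of ROI labels), YAML configuration,
## CSV posterior tables, JSON manifests, TSV edge lists, GraphML export.
## Everything a writer produces is readable by the matching reader.

#' Read one session of ROI time series from a delimited text file
#'
#' Wide format: one row per scan, one column per ROI, header row with ROI
#' labels.  Any non-numeric cell is reported with its file, row and column.
#'
#' @param file Path to a CSV (or TSV, by `sep`) file.
#' @param sep Field separator.
#' @return Numeric matrix with ROI labels as column names.
#' @export
read_series <- function(file, sep = ",") {
  if (!file.exists(file)) stop(sprintf("no such file: %s", file))
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  M <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) M <- matrix(M, nrow = 1L, dimnames = list(NULL, names(df)))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value in %s at data row %d, column '%s'",
                 file, bad[1L], colnames(M)[bad[2L]]))
  }
  M
}

#' @rdname read_series
#' @param Y Numeric matrix (rows = scans, columns = ROIs).
#' @param file Output path.
#' @export
write_series <- function(Y, file, sep = ",") {
  utils::write.table(as.matrix(Y), file, sep = sep, row.names = FALSE,
                     col.names = colnames(Y) %||% paste0("roi", seq_len(ncol(Y))),
                     quote = FALSE)
  invisible(file)
}

check_outdir <- function(dir, force) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop(sprintf("output directory '%s' is not empty (use force = TRUE to overwrite)",
                 dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  invisible(dir)
}

#' Write / read a simulated or assembled study as plain text
#'
#' `write_study()` writes one CSV per subject per session plus `study.yaml`
#' (ROIs, conditions, design, subject-to-group map) and, when ground truth
#' is attached, `truth.json` (flattened true coefficients, deviation SDs,
#' noise variances, realized subject deviations) for recovery scoring.
#' `read_study()` reconstructs the subject list.
#'
#' @param study An `"hvar_study"` from [simulate_study()], or a plain list
#'   of [hvar_subject()] objects (then `design` must be given).
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @param design A [hvar_block_design()] (only needed for plain lists).
#' @return The directory (invisibly) / a list with `series` and metadata.
#' @export
write_study <- function(study, dir, force = FALSE, design = NULL) {
  if (inherits(study, "hvar_study")) {
    series <- study$series
    design <- study$truth$design
    spec <- study$truth$spec
  } else {
    series <- study
    if (is.null(design)) stop("'design' required for a plain subject list")
    spec <- NULL
  }
  check_outdir(dir, force)
  for (su in series) {
    for (i in seq_along(su$session_starts)) {
      rg <- session_ranges(nrow(su$Y), su$session_starts)[[i]]
      write_series(su$Y[rg[1]:rg[2], , drop = FALSE],
                   file.path(dir, sprintf("%s_session%d.csv",
                                          su$subject_id, i)))
    }
  }
  meta <- list(
    rois = as.list(colnames(series[[1L]]$Y) %||%
                     paste0("roi", seq_len(ncol(series[[1L]]$Y)))),
    conditions = as.list(design$conditions),
    sessions = design$sessions,
    scans_per_session = design$scans_per_session,
    block_length = design$block_length,
    TR = design$TR,
    subjects = lapply(series, function(su)
      list(id = su$subject_id, group = su$group)))
  yaml::write_yaml(meta, file.path(dir, "study.yaml"))
  if (inherits(study, "hvar_study")) {
    truth <- study$truth
    jsonlite::write_json(
      list(seed = truth$seed,
           phi = as.list(phi_flatten(truth$phi, spec)),
           dev_sd = truth$dev_sd, noise_var = truth$noise_var,
           xi = apply(study$xi, 1L, as.list)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "study.yaml"))
  design <- hvar_block_design(meta$sessions, meta$scans_per_session,
                              meta$block_length,
                              conditions = unlist(meta$conditions),
                              TR = meta$TR)
  W <- make_block_indicators(design)
  series <- lapply(meta$subjects, function(su) {
    Y <- do.call(rbind, lapply(seq_len(meta$sessions), function(i)
      read_series(file.path(dir, sprintf("%s_session%d.csv", su$id, i)))))
    hvar_subject(Y, W, su$id, su$group,
                 session_starts = attr(W, "session_starts"))
  })
  names(series) <- vapply(meta$subjects, `[[`, "", "id")
  list(series = series, design = design,
       rois = unlist(meta$rois), conditions = unlist(meta$conditions))
}

# md5 digest of the numeric content of a study (order-sensitive)
data_digest <- function(series) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  for (su in series) {
    writeBin(su$subject_id, con)
    writeBin(as.vector(su$Y), con)
    writeBin(as.integer(su$W), con)
  }
  close(con)
  unname(tools::md5sum(f))
}

#' Write / read posterior samples as plain-text tables
#'
#' One CSV per parameter family (rows = retained draws; `phi`, `alpha` and
#' `d` columns labelled `group.condition.lag.target.source`), a
#' `scalars.csv` for `lambda2`/`gamma`, and `manifest.json` recording the
#' model spec, subjects, sampler settings, seed, data digest, and a Geweke
#' z-score summary.  `read_posterior()` reconstructs an object usable by
#' [group_network()], [contrast_network()], [subject_network()] and
#' [variance_summaries()].
#'
#' @param fit An [hvar()] fit.
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return The directory (invisibly) / an object of class `"hvar"`.
#' @export
write_posterior <- function(fit, dir, force = FALSE) {
  stopifnot(inherits(fit, "hvar"))
  check_outdir(dir, force)
  s <- fit$samples
  wr <- function(M, name)
    utils::write.table(M, file.path(dir, paste0(name, ".csv")), sep = ",",
                       row.names = FALSE, quote = FALSE)
  wr(s$phi, "phi"); wr(s$xi, "xi"); wr(s$alpha, "alpha")
  wr(s$tau, "tau"); wr(s$d, "d")
  wr(cbind(lambda2 = s$lambda2, gamma = s$gamma), "scalars")
  zg <- if (s$n_draws >= 100L)
    suppressWarnings(geweke_diagnostic(s$phi)) else NA_real_
  manifest <- list(
    spec = list(rois = fit$spec$rois, lags = fit$spec$K,
                conditions = fit$spec$conditions, groups = fit$spec$groups),
    subjects = s$subjects, groups_of_subjects = s$groups_of_subjects,
    control = unclass(s$control), hyper = unclass(s$hyper),
    n_draws = s$n_draws,
    data_digest = if (!is.null(fit$study)) data_digest(fit$study) else NA,
    geweke = if (all(is.na(zg))) list(max_abs_z = NA, frac_abs_z_gt_2 = NA)
      else list(max_abs_z = max(abs(zg), na.rm = TRUE),
                frac_abs_z_gt_2 = mean(abs(zg) > 2, na.rm = TRUE)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  spec <- hvar_spec(man$spec$rois, man$spec$lags, man$spec$conditions,
                    man$spec$groups)
  rd <- function(name)
    as.matrix(utils::read.csv(file.path(dir, paste0(name, ".csv")),
                              check.names = FALSE))
  sc <- rd("scalars")
  samples <- structure(
    list(phi = rd("phi"), xi = rd("xi"), alpha = rd("alpha"),
         tau = rd("tau"), d = rd("d"),
         lambda2 = sc[, "lambda2"], gamma = sc[, "gamma"],
         spec = spec, subjects = man$subjects,
         groups_of_subjects = man$groups_of_subjects,
         control = man$control, n_draws = man$n_draws),
    class = "hvar_samples")
  structure(list(samples = samples, spec = spec, study = NULL,
                 manifest = man),
            class = "hvar")
}

#' Write a network as a TSV edge list or GraphML
#'
#' The TSV has columns source, target, condition, group, per-lag posterior
#' means, significance flag and level.  The GraphML export carries the
#' significant edges (self-edges marked) for graph tools.
#'
#' @param network An `"hvar_network"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, file) {
  utils::write.table(as.data.frame(network), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, file) {
  sig <- network[network$significant, , drop = FALSE]
  nodes <- unique(c(network$source, network$target))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="self" for="edge" attr.name="self_edge" attr.type="boolean"/>',
    '  <graph edgedefault="directed">'), con)
  for (n in nodes)
    writeLines(sprintf('    <node id="%s"/>', esc(n)), con)
  if (nrow(sig))
    for (i in seq_len(nrow(sig)))
      writeLines(sprintf(
        '    <edge source="%s" target="%s"><data key="self">%s</data></edge>',
        esc(sig$source[i]), esc(sig$target[i]),
        tolower(sig$self_edge[i])), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(file)
}

## -- run configuration -------------------------------------------------------

config_blocks <- list(
  model = c("rois", "lags", "conditions", "groups"),
  design = c("sessions", "scans_per_session", "block_length", "TR"),
  truth = c("n_edges", "effect_size", "dev_sd", "noise_var",
            "subjects_per_group", "seed"),
  sampler = c("iterations", "burn_in", "thin", "seed", "hyperparameters"),
  network = c("level", "method", "adjust"),
  preprocess = c("enabled", "poly_order", "frequencies"),
  paths = c("input_dir", "output_dir"))

#' Read and validate a YAML run configuration
#'
#' Recognized blocks: `model` (rois, lags, conditions, groups), `design`
#' (sessions, scans_per_session, block_length, TR), `truth`, `sampler`
#' (iterations, burn_in, thin, seed, hyperparameters), `network`,
#' `preprocess`, `paths`.  Unknown blocks or keys are rejected before any
#' computation.
#'
#' @param path YAML file.
#' @return Validated configuration list of class `"hvar_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(config_blocks))
  if (length(unknown))
    stop(sprintf("unknown config block(s): %s", paste(unknown, collapse = ", ")))
  for (blk in names(cfg)) {
    bad <- setdiff(names(cfg[[blk]]), config_blocks[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(bad, collapse = ", ")))
  }
  if (!is.null(cfg$sampler$hyperparameters)) {
    bad <- setdiff(names(cfg$sampler$hyperparameters),
                   names(formals(hvar_hyper)))
    if (length(bad))
      stop(sprintf("unknown hyperparameter(s): %s", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "hvar_config")
}

config_spec <- function(cfg) {
  m <- cfg$model
  hvar_spec(unlist(m$rois), m$lags %||% 1L,
            unlist(m$conditions) %||% c("rest", "active"),
            unlist(m$groups) %||% "group1")
}

config_design <- function(cfg) {
  d <- cfg$design
  hvar_block_design(d$sessions, d$scans_per_session, d$block_length,
                    conditions = unlist(cfg$model$conditions) %||%
                      c("rest", "active"),
                    TR = d$TR %||% 2)
}
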