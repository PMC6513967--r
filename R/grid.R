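# Orchestration over the model-class grid and the datasets: independent
# TMCMC runs per (class, dataset) cell, MAP/interval tables, range
# aggregation, export, and replay diagnostics.

# deterministic per-cell seed below 2^31, derived from the master seed and
# the cell coordinates
cell_seed <- function(master, fiber_content, helix_angle, dataset_id) {
  master <- as.double(master) %% 2147483629
  h <- (master * 1000003 +
          round(fiber_content * 1000) * 7919 +
          round(helix_angle * 100) * 104729 +
          sum(utf8ToInt(dataset_id))) %% 2147483629
  as.integer(h) + 1L
}

#' Grid inference over model classes and datasets
#'
#' Runs one independent [fit_fascicle()] per (class, dataset) cell with a
#' deterministic per-cell seed derived from `seed`, and collects MAP values,
#' 95% central credible intervals, log evidence and stage counts into a
#' results table (one row per cell).  A failing cell is flagged in its row
#' and the grid continues.
#'
#' @param datasets list of [fascicle_dataset()] objects.
#' @param classes list of [fascicle_class()] objects (see
#'   [fascicle_classes()]).
#' @param priors a [prior_spec()].
#' @param control a [tmcmc_control()]; its seed field is overridden per
#'   cell.
#' @param observables observable blocks, as in [fit_fascicle()].
#' @param seed master seed for the per-cell seed derivation.
#' @param keep_fits retain the individual fit objects (needed by
#'   [export_tables()] for per-cell posterior samples)?
#' @param ... further arguments passed to [fit_fascicle()].
#' @return An object of class `"fascicle_grid"`: a list with `table` (the
#'   results data frame), `fits` (named list, if kept), and the shared run
#'   settings.
#' @export
fit_fascicle_grid <- function(datasets, classes, priors = prior_spec(),
                              control = tmcmc_control(),
                              observables = c("elastic", "poisson", "relaxation"),
                              seed = 1, keep_fits = TRUE, ...) {
  if (length(datasets) == 0L || length(classes) == 0L)
    stop("datasets and classes must be non-empty", call. = FALSE)
  if (inherits(datasets, "fascicle_dataset")) datasets <- list(datasets)
  if (inherits(classes, "fascicle_class")) classes <- list(classes)
  rows <- list(); fits <- list(); k <- 0L
  for (cls in classes) for (d in datasets) {
    k <- k + 1L
    s <- cell_seed(seed, cls$fiber_content, cls$helix_angle, d$dataset_id)
    ctl <- control; ctl$seed <- s
    fit <- tryCatch(fit_fascicle(d, cls, priors = priors, control = ctl,
                                 observables = observables, ...),
                    error = function(e) e)
    key <- sprintf("fr%03.0f_th%02.0f_%s", 1000 * cls$fiber_content,
                   cls$helix_angle, d$dataset_id)
    if (inherits(fit, "error")) {
      row <- data.frame(fiber_content = cls$fiber_content,
                        helix_angle = cls$helix_angle,
                        dataset_id = d$dataset_id,
                        matrix(NA_real_, 1L, 15L,
                               dimnames = list(NULL, map_col_names())),
                        log_evidence = NA_real_, n_stages = NA_integer_,
                        seed = s, ok = FALSE,
                        message = conditionMessage(fit))
    } else {
      ints <- fit$intervals
      vals <- as.numeric(rbind(fit$map, ints))  # map, lo, hi per parameter
      row <- data.frame(fiber_content = cls$fiber_content,
                        helix_angle = cls$helix_angle,
                        dataset_id = d$dataset_id,
                        matrix(vals, 1L, 15L,
                               dimnames = list(NULL, map_col_names())),
                        log_evidence = fit$log_evidence,
                        n_stages = nrow(fit$stage_record),
                        seed = s, ok = TRUE, message = "")
      if (keep_fits) fits[[key]] <- fit
    }
    rows[[k]] <- row
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 priors = priors, control = control,
                 observables = observables, seed = seed),
            class = "fascicle_grid")
}

map_col_names <- function() {
  as.vector(vapply(PARAM_NAMES,
                   function(p) paste0(p, c("_map", "_lo", "_hi")),
                   character(3L)))
}

#' @export
print.fascicle_grid <- function(x, ...) {
  cat(sprintf("Fascicle grid inference: %d cells (%d failed), observables %s\n",
              nrow(x$table), sum(!x$table$ok),
              paste(x$observables, collapse = "+")))
  print(utils::head(x$table[, c("fiber_content", "helix_angle", "dataset_id",
                                "E_f_map", "eta_f_map", "E_m_map",
                                "log_evidence")], 10L))
  if (nrow(x$table) > 10L) cat("  ...\n")
  invisible(x)
}

#' Parameter MAP ranges across the grid
#'
#' Per-parameter minimum and maximum of the MAP values over all successful
#' (class x dataset) cells -- the envelope of most probable values across
#' fiber contents, angles and datasets.
#'
#' @param x a `"fascicle_grid"` or its results table.
#' @return Data frame with columns `parameter`, `min_map`, `max_map`.
#' @export
summarize_ranges <- function(x) {
  tab <- if (inherits(x, "fascicle_grid")) x$table else x
  tab <- tab[tab$ok, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no successful cells to summarize", call. = FALSE)
  out <- data.frame(parameter = PARAM_NAMES,
                    min_map = vapply(PARAM_NAMES, function(p)
                      min(tab[[paste0(p, "_map")]]), 0),
                    max_map = vapply(PARAM_NAMES, function(p)
                      max(tab[[paste0(p, "_map")]]), 0))
  rownames(out) <- NULL
  out
}

#' Export grid results to CSV files
#'
#' Writes `grid_results.csv` (the per-cell table), `range_summary.csv`
#' (from [summarize_ranges()]), per-cell posterior sample CSVs under
#' `samples/` (one row per sample: parameters, log prior, log likelihood),
#' and a `manifest.json` recording the sampler settings, observables,
#' master seed, per-cell seeds and package version.  Re-export of identical
#' inputs is byte-identical.
#'
#' @param grid a `"fascicle_grid"`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(grid, out_dir) {
  stopifnot(inherits(grid, "fascicle_grid"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir,
                                 call. = FALSE)
  paths <- character()
  p <- file.path(out_dir, "grid_results.csv")
  utils::write.csv(grid$table, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "range_summary.csv")
  utils::write.csv(summarize_ranges(grid), p, row.names = FALSE)
  paths <- c(paths, p)
  if (length(grid$fits)) {
    sdir <- file.path(out_dir, "samples")
    dir.create(sdir, showWarnings = FALSE)
    for (key in names(grid$fits)) {
      fit <- grid$fits[[key]]
      df <- data.frame(fit$ensemble$samples,
                       log_prior = fit$ensemble$log_prior,
                       log_likelihood = fit$ensemble$log_likelihood)
      p <- file.path(sdir, paste0(key, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fasciclefit")),
    master_seed = grid$seed,
    observables = grid$observables,
    control = grid$control[c("samples_per_stage", "target_weight_cov",
                             "proposal_scale", "max_stages", "mh_steps")],
    prior_bounds = as.data.frame(grid$priors$bounds),
    cells = grid$table[, c("fiber_content", "helix_angle", "dataset_id",
                           "seed", "ok")])
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Replay a fitted relaxation curve against its data
#'
#' Recomputes the normalized relaxation curve at a fit's MAP (or at given
#' parameters) and pairs it with the dataset's observed points, reporting
#' the maximum absolute and relative deviations.
#'
#' @param fit a [fit_fascicle()] result, or a length-5 parameter vector in
#'   reporting units.
#' @param data the dataset to replay against (default: the fit's own).
#' @param cls model class, required when `fit` is a bare parameter vector.
#' @return An object of class `"fascicle_replay"`: a list with `curve` (a
#'   data frame `time_s`, `observed`, `predicted`), `max_abs_deviation`
#'   and `max_rel_deviation`.
#' @export
replay_fit <- function(fit, data = NULL, cls = NULL) {
  if (inherits(fit, "fascicle_fit")) {
    params <- fit$map
    if (is.null(data)) data <- fit$data
    if (is.null(cls)) cls <- fit$class
  } else {
    params <- fit
    if (is.null(data) || is.null(cls))
      stop("data and cls are required when replaying a bare parameter vector",
           call. = FALSE)
  }
  pred <- normalized_relaxation(params, cls, data$times)
  dev <- data$Ebar - pred
  structure(list(curve = data.frame(time_s = data$times,
                                    observed = data$Ebar,
                                    predicted = pred),
                 max_abs_deviation = max(abs(dev)),
                 max_rel_deviation = max(abs(dev / pred))),
            class = "fascicle_replay")
}

#' @export
print.fascicle_replay <- function(x, ...) {
  cat(sprintf("Relaxation replay over %d points: max |dev| = %.4g, max |rel dev| = %.4g\n",
              nrow(x$curve), x$max_abs_deviation, x$max_rel_deviation))
  invisible(x)
}
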