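#' Assemble a full pipeline run configuration
#'
#' Collects every knob of the simulate -> connectivity -> classify ->
#' discriminative chain in one validated list that round-trips losslessly
#' through YAML. Defaults mirror the package's reference analysis: band-pass
#' 0.01-0.08 Hz, 5 discarded volumes, global-signal regression on, dimension
#' grid starting at 2, top 5% consensus edges.
#'
#' @param simulate A [sim_config()] (or the list of arguments to build one);
#'   `NULL` when reading subjects from `manifest`.
#' @param manifest Optional path to a subject manifest TSV (used when
#'   `simulate` is `NULL`).
#' @param low_hz,high_hz,filter_order Band-pass settings.
#' @param global_signal_regression,use_motion,discard_volumes,filter_first
#'   Preprocessing toggles (see [connectivity_dataset()]).
#' @param reducer `"ida"` or `"pca"`.
#' @param epsilon IDA perturbation constant (`NULL` = scale-based default).
#' @param d Fixed embedding dimension; `NULL` runs the grid search.
#' @param d_min,d_max Grid bounds when `d` is `NULL` (`d_max = NULL` means
#'   N - 2).
#' @param C SVM regularization constant.
#' @param top_fraction Consensus edge fraction.
#' @param patient_classes Length-2 character vector naming the two
#'   patient-versus-rest classifiers combined into convergent/divergent sets;
#'   `NULL` skips that step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = sim_config(), manifest = NULL,
                       low_hz = 0.01, high_hz = 0.08, filter_order = 4,
                       global_signal_regression = TRUE, use_motion = TRUE,
                       discard_volumes = NULL, filter_first = TRUE,
                       reducer = c("ida", "pca"), epsilon = NULL,
                       d = NULL, d_min = 2, d_max = NULL, C = 1,
                       top_fraction = 0.05,
                       patient_classes = c("mdd", "scz")) {
  reducer <- match.arg(reducer)
  if (is.null(simulate) && is.null(manifest)) {
    stop("either `simulate` or `manifest` must be given.", call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  cfg <- structure(list(
    simulate = simulate, manifest = manifest,
    low_hz = low_hz, high_hz = high_hz, filter_order = filter_order,
    global_signal_regression = isTRUE(global_signal_regression),
    use_motion = isTRUE(use_motion),
    discard_volumes = discard_volumes, filter_first = isTRUE(filter_first),
    reducer = reducer, epsilon = epsilon, d = d,
    d_min = d_min, d_max = d_max, C = C,
    top_fraction = top_fraction, patient_classes = patient_classes
  ), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$low_hz <= 0 || cfg$high_hz <= cfg$low_hz) {
    stop("need 0 < low_hz < high_hz.", call. = FALSE)
  }
  if (cfg$C <= 0) stop("`C` must be positive.", call. = FALSE)
  if (!is.null(cfg$epsilon) && cfg$epsilon <= 0) {
    stop("`epsilon` must be positive.", call. = FALSE)
  }
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1) {
    stop("`top_fraction` must lie in (0, 1].", call. = FALSE)
  }
  if (!is.null(cfg$d) && cfg$d < 1) stop("`d` must be >= 1.", call. = FALSE)
  if (is.null(cfg$d) && cfg$d_min < 2) {
    stop("`d_min` must be >= 2.", call. = FALSE)
  }
  if (!is.null(cfg$patient_classes) && length(cfg$patient_classes) != 2L) {
    stop("`patient_classes` must name exactly two classes.", call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  payload <- unclass(config)
  if (!is.null(payload$simulate)) {
    sim <- unclass(payload$simulate)
    sim$n_subjects_per_class <- as.list(sim$n_subjects_per_class)
    sim$perturbed_edges <- if (nrow(sim$perturbed_edges)) {
      lapply(seq_len(nrow(sim$perturbed_edges)), function(k) {
        as.list(sim$perturbed_edges[k, ])
      })
    } else list()
    if (is.matrix(sim$base_correlation)) {
      sim$base_correlation <- as.list(as.data.frame(sim$base_correlation))
    }
    payload$simulate <- sim
  }
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  payload <- yaml::read_yaml(path)
  if (!is.null(payload$simulate)) {
    sim <- payload$simulate
    sim$n_subjects_per_class <- unlist(sim$n_subjects_per_class)
    sim$perturbed_edges <- if (length(sim$perturbed_edges)) {
      dplyr::bind_rows(lapply(sim$perturbed_edges, tibble::as_tibble))
    } else NULL
    if (is.list(sim$base_correlation)) {
      sim$base_correlation <- as.matrix(as.data.frame(sim$base_correlation))
    }
    payload$simulate <- do.call(sim_config, sim)
  }
  payload_args <- payload[names(payload) %in% names(formals(run_config))]
  do.call(run_config, payload_args)
}

pipeline_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  writeLines(line, con)
  invisible(line)
}

#' Run the full discriminative-connectivity pipeline
#'
#' Chains simulation (or manifest reading), connectivity feature extraction,
#' LOOCV classification (with the dimension grid search when no fixed `d` is
#' given), and discriminative edge mapping, writing every artifact — subject
#' TSVs, the feature table, the CV report JSON/TSV, discriminative edge and
#' region tables, convergent/divergent sets, a log, and a copy of the
#' resolved configuration — into one run directory. Deterministic under the
#' configuration's seed; on error, partial outputs are removed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must not already contain a run).
#' @return Invisibly, a list with the `dataset`, `report`, `maps`,
#'   `contrast` (convergent/divergent sets or `NULL`), and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok && created) unlink(out_dir, recursive = TRUE)
  })

  write_run_config(config, file.path(out_dir, "config.yaml"))
  pipeline_log(con, "pipeline start")

  if (!is.null(config$simulate)) {
    subjects <- simulate_subjects(config$simulate)
    write_subjects(subjects, file.path(out_dir, "subjects"))
    pipeline_log(con, "simulated ", length(subjects), " subjects (seed ",
                 config$simulate$seed, ")")
  } else {
    subjects <- read_subjects(config$manifest)
    pipeline_log(con, "read ", length(subjects), " subjects from manifest")
  }

  dataset <- connectivity_dataset(
    subjects,
    low_hz = config$low_hz, high_hz = config$high_hz,
    tr_seconds = if (!is.null(config$simulate)) config$simulate$tr_seconds else 2,
    filter_order = config$filter_order,
    global_signal_regression = config$global_signal_regression,
    use_motion = config$use_motion,
    discard_volumes = config$discard_volumes,
    filter_first = config$filter_first)
  write_connectivity_dataset(dataset, file.path(out_dir, "connectivity.tsv"))
  pipeline_log(con, "connectivity: ", nrow(dataset$features), " subjects x ",
               ncol(dataset$features), " edges")

  n <- nrow(dataset$features)
  if (is.null(config$d)) {
    d_max <- config$d_max %||% (n - 2L)
    t0 <- proc.time()[["elapsed"]]
    grid_rep <- grid_search_dimension(dataset, d_min = config$d_min,
                                      d_max = d_max, epsilon = config$epsilon,
                                      C = config$C, reducer = config$reducer)
    elapsed <- proc.time()[["elapsed"]] - t0
    pipeline_log(con, sprintf(
      "grid search [%d, %d]: best d = %d (%.1f%%), %.2fs (%.3fs/fold)",
      config$d_min, min(d_max, n - 2L), grid_rep$d, grid_rep$accuracy,
      elapsed, elapsed / n))
    chosen_d <- grid_rep$d
    curve <- grid_rep$curve
  } else {
    chosen_d <- config$d
    curve <- NULL
  }
  t0 <- proc.time()[["elapsed"]]
  report <- loocv(dataset, d = chosen_d, epsilon = config$epsilon,
                  C = config$C, reducer = config$reducer,
                  collect_weights = TRUE)
  elapsed <- proc.time()[["elapsed"]] - t0
  report$curve <- curve
  pipeline_log(con, sprintf(
    "loocv at d = %d: accuracy %.1f%%, %.2fs (%.3fs/fold)",
    chosen_d, report$accuracy, elapsed, elapsed / n))
  write_cv_report(report, file.path(out_dir, "cv_report.json"))

  maps <- NULL
  contrast <- NULL
  if (config$reducer == "ida") {
    maps <- discriminative_maps(report, dataset,
                                fraction = config$top_fraction)
    for (cl in names(maps)) {
      write_discriminative_map(maps[[cl]],
                               file.path(out_dir, paste0("map_", cl)))
    }
    pipeline_log(con, "discriminative maps: ",
                 paste(names(maps), collapse = ", "))
    pc <- config$patient_classes
    if (!is.null(pc) && all(pc %in% names(maps))) {
      contrast <- convergent_divergent_sets(maps[[pc[1L]]], maps[[pc[2L]]])
      write.table(as.data.frame(contrast$convergent),
                  file.path(out_dir, "convergent_edges.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(as.data.frame(contrast$divergent),
                  file.path(out_dir, "divergent_edges.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      pipeline_log(con, "convergent/divergent sets: ",
                   nrow(contrast$convergent), "/", nrow(contrast$divergent),
                   " edges")
    }
  }
  pipeline_log(con, "pipeline done")
  ok <- TRUE
  invisible(list(dataset = dataset, report = report, maps = maps,
                 contrast = contrast, out_dir = out_dir))
}
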