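#' Extract regional mean time series from a 4-D volume and a label atlas
#'
#' Averages the volume series over all voxels sharing each positive integer
#' atlas label; row k of the result is the mean series of label k (labels in
#' ascending order). Label 0 is background. This is the parcellation step that
#' turns a registered functional image into a regions-by-volumes matrix.
#'
#' @param volume_series 4-D numeric array (x, y, z, time).
#' @param atlas_labels 3-D integer array of the same spatial dimensions;
#'   0 marks background voxels.
#' @return A regions-by-volumes matrix, rows ordered by ascending label and
#'   named by label.
#' @export
extract_regional_timeseries <- function(volume_series, atlas_labels) {
  dv <- dim(volume_series)
  da <- dim(atlas_labels)
  if (length(dv) != 4L || length(da) != 3L || !all(dv[1:3] == da)) {
    stop("`volume_series` must be 4-D and spatially match the 3-D atlas.",
         call. = FALSE)
  }
  max_lab <- max(as.integer(atlas_labels))
  if (max_lab < 1L) stop("atlas contains no positive labels.", call. = FALSE)
  labs <- seq_len(max_lab)   # labels must cover 1..max; gaps are errors
  n_vox <- prod(da)
  n_t <- dv[4L]
  flat <- matrix(volume_series, n_vox, n_t)
  lab_vec <- as.integer(atlas_labels)
  out <- matrix(NA_real_, length(labs), n_t)
  for (k in seq_along(labs)) {
    idx <- which(lab_vec == labs[k])
    if (!length(idx)) {
      stop("atlas label ", labs[k], " covers zero voxels; its mean is undefined.",
           call. = FALSE)
    }
    out[k, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  rownames(out) <- labs
  out
}

#' Zero-phase Chebyshev band-pass filter for regional time series
#'
#' Filters every row of a regions-by-volumes matrix with a Chebyshev Type I
#' band-pass filter (default order 4, 0.5 dB passband ripple) applied
#' forward-backward for zero phase. The default 0.01-0.08 Hz band isolates the
#' low-frequency fluctuations conventionally used for resting-state
#' functional connectivity.
#'
#' @param ts Regions-by-volumes numeric matrix.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)`.
#' @param tr_seconds Repetition time in seconds (sampling interval).
#' @param order Filter order (default 4).
#' @param ripple_db Passband ripple in dB (default 0.5).
#' @return Matrix of the same shape, each row filtered identically.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08, tr_seconds = 2,
                            order = 4, ripple_db = 0.5) {
  if (!is.matrix(ts)) ts <- matrix(ts, nrow = 1L)
  nyquist <- 1 / (2 * tr_seconds)
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyquist) {
    stop(sprintf(
      "band (%g, %g) Hz must satisfy 0 < low < high < Nyquist = %g Hz for TR = %g s.",
      low_hz, high_hz, nyquist, tr_seconds), call. = FALSE)
  }
  if (ncol(ts) <= 3 * order) {
    stop("time series too short for the filter order.", call. = FALSE)
  }
  flt <- signal::cheby1(order, Rp = ripple_db,
                        W = c(low_hz, high_hz) / nyquist, type = "pass")
  # demean first: DC lies outside any band-pass, and removing it up front
  # avoids the long low-frequency edge transient of the recursive filter
  out <- t(apply(ts, 1L, function(row) {
    signal::filtfilt(flt, row - mean(row))
  }))
  dimnames(out) <- dimnames(ts)
  out
}

# Squared magnitude response of the zero-phase (forward-backward) filter at
# frequency f_hz; used by tests as an analytic oracle.
bandpass_response <- function(f_hz, low_hz = 0.01, high_hz = 0.08,
                              tr_seconds = 2, order = 4, ripple_db = 0.5) {
  nyquist <- 1 / (2 * tr_seconds)
  flt <- signal::cheby1(order, Rp = ripple_db,
                        W = c(low_hz, high_hz) / nyquist, type = "pass")
  w <- pi * f_hz / nyquist
  z <- exp(1i * w)
  h <- vapply(z, function(zz) {
    num <- sum(flt$b * zz^-(seq_along(flt$b) - 1))
    den <- sum(flt$a * zz^-(seq_along(flt$a) - 1))
    Mod(num / den)
  }, 0)
  h^2
}

#' Regress nuisance signals out of regional time series
#'
#' Replaces each region's series with its ordinary-least-squares residual
#' against an intercept, the global mean signal (optional), and six motion
#' parameters (optional). Residuals are exactly orthogonal to every included
#' design column.
#'
#' @param ts Regions-by-volumes matrix.
#' @param global_signal Optional numeric vector (the whole-brain mean course);
#'   `NULL` omits global-signal regression.
#' @param motion Optional 6-by-volumes matrix of motion parameters.
#' @return Residual matrix of the same shape.
#' @export
regress_nuisance <- function(ts, global_signal = NULL, motion = NULL) {
  if (!is.matrix(ts)) ts <- matrix(ts, nrow = 1L)
  n_t <- ncol(ts)
  design <- cbind(intercept = rep(1, n_t))
  if (!is.null(global_signal)) {
    if (length(global_signal) != n_t) {
      stop("`global_signal` length must match the number of volumes.",
           call. = FALSE)
    }
    design <- cbind(design, global = global_signal)
  }
  if (!is.null(motion)) {
    if (!is.matrix(motion) || ncol(motion) != n_t) {
      stop("`motion` must be a 6 x volumes matrix.", call. = FALSE)
    }
    mo <- t(motion)
    colnames(mo) <- paste0("motion_", seq_len(ncol(mo)))
    design <- cbind(design, mo)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[-qrd$pivot[seq_len(qrd$rank)]]
    stop("nuisance design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- t(qr.resid(qrd, t(ts)))
  dimnames(res) <- dimnames(ts)
  res
}

#' Pearson connectivity feature vector of one subject
#'
#' Computes the Pearson correlation of every region pair and lays the upper
#' triangle out along the edge map. For a 116-region parcellation this is the
#' 6670-dimensional functional-connectivity feature vector.
#'
#' @param ts Regions-by-volumes matrix with at least 3 volumes.
#' @param edge_map An [edge_index_map()] for `nrow(ts)` regions.
#' @return Numeric vector of length `nrow(edge_map)`, values in [-1, 1].
#' @export
connectivity_vector <- function(ts, edge_map) {
  p <- edge_map_regions(edge_map)
  if (!is.matrix(ts) || nrow(ts) != p) {
    stop("`ts` must have one row per edge-map region (", p, ").", call. = FALSE)
  }
  if (ncol(ts) < 3L) stop("need at least 3 time points.", call. = FALSE)
  sds <- apply(ts, 1L, sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(which(sds == 0), collapse = ", "),
         "; correlation is undefined.", call. = FALSE)
  }
  edge_vectorize(cor(t(ts)), edge_map)
}

#' Build the subjects-by-edges connectivity dataset
#'
#' Runs the per-subject preprocessing chain (optional discard of initial
#' volumes, band-pass filter, nuisance regression, Pearson correlation) and
#' stacks the resulting edge vectors into an N-by-P feature matrix. The
#' pipeline order is filter, then nuisance regression, then correlation;
#' `filter_first = FALSE` swaps the first two steps.
#'
#' @param subjects A `subject_set` (see [simulate_subjects()] /
#'   [read_subjects()]).
#' @param edge_map Optional [edge_index_map()]; built from the data when
#'   `NULL`.
#' @param low_hz,high_hz,tr_seconds,filter_order Band-pass settings (see
#'   [bandpass_filter()]); `low_hz = NULL` disables filtering.
#' @param global_signal_regression Remove the whole-brain mean course
#'   (default `TRUE`).
#' @param use_motion Include the subject's 6 motion parameters as nuisance
#'   regressors when available (default `TRUE`).
#' @param discard_volumes Number of initial volumes to drop for saturation;
#'   `NULL` (default) discards 5 when at least 20 volumes are present.
#' @param filter_first Apply the band-pass before nuisance regression
#'   (default `TRUE`).
#' @return A `connectivity_dataset`: list with `features` (N x P matrix),
#'   `labels`, `subject_ids`, `edge_map`, and `region_names`.
#' @examples
#' cfg <- sim_config(n_subjects_per_class = c(a = 3, b = 3), n_regions = 10,
#'                   n_volumes = 80, seed = 2)
#' ds <- connectivity_dataset(simulate_subjects(cfg))
#' dim(ds$features) # 6 x 45
#' @export
connectivity_dataset <- function(subjects, edge_map = NULL,
                                 low_hz = 0.01, high_hz = 0.08,
                                 tr_seconds = 2, filter_order = 4,
                                 global_signal_regression = TRUE,
                                 use_motion = TRUE,
                                 discard_volumes = NULL,
                                 filter_first = TRUE) {
  stopifnot(length(subjects) >= 1L)
  p <- nrow(subjects[[1L]]$timeseries)
  if (is.null(edge_map)) edge_map <- edge_index_map(p)
  feats <- matrix(NA_real_, length(subjects), n_edges(edge_map))
  for (k in seq_along(subjects)) {
    s <- subjects[[k]]
    ts <- s$timeseries
    motion <- if (use_motion) s$motion else NULL
    nd <- discard_volumes
    if (is.null(nd)) nd <- if (ncol(ts) >= 20L) 5L else 0L
    if (nd > 0L) {
      ts <- ts[, -seq_len(nd), drop = FALSE]
      if (!is.null(motion)) motion <- motion[, -seq_len(nd), drop = FALSE]
    }
    steps <- list(
      filter = function(m) {
        if (is.null(low_hz)) m else {
          bandpass_filter(m, low_hz, high_hz, tr_seconds, order = filter_order)
        }
      },
      nuisance = function(m) {
        gs <- if (global_signal_regression) colMeans(m) else NULL
        if (is.null(gs) && is.null(motion)) m else {
          regress_nuisance(m, global_signal = gs, motion = motion)
        }
      }
    )
    if (!filter_first) steps <- rev(steps)
    for (f in steps) ts <- f(ts)
    feats[k, ] <- connectivity_vector(ts, edge_map)
  }
  rownames(feats) <- vapply(subjects, `[[`, "", "subject_id")
  structure(list(
    features = feats,
    labels = vapply(subjects, `[[`, "", "label"),
    subject_ids = rownames(feats),
    edge_map = edge_map,
    region_names = unique(c(edge_map$name_i, edge_map$name_j))
  ), class = "connectivity_dataset")
}

#' @export
print.connectivity_dataset <- function(x, ...) {
  cat("<connectivity_dataset> ", nrow(x$features), " subjects x ",
      ncol(x$features), " edges (", edge_map_regions(x$edge_map),
      " regions)\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Connectivity dataset as a long tibble
#'
#' @param x A `connectivity_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `label`, `edge`, `name_i`,
#'   `name_j`, `correlation`.
#' @method tidy connectivity_dataset
#' @export
tidy.connectivity_dataset <- function(x, ...) {
  wide <- tibble::as_tibble(x$features, .name_repair = "minimal")
  names(wide) <- as.character(x$edge_map$edge)
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_ids, label = x$labels), wide
  ) |>
    tidyr::pivot_longer(-c("subject_id", "label"), names_to = "edge",
                        values_to = "correlation") |>
    dplyr::mutate(edge = as.integer(.data$edge)) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(x$edge_map), "edge", "name_i", "name_j"),
      by = "edge") |>
    dplyr::relocate("correlation", .after = "name_j")
}

#' Write / read a connectivity dataset as TSV
#'
#' `write_connectivity_dataset()` writes a features table (`subject_id`,
#' `label`, `edge_0001` ...) and an edge-map table alongside it;
#' `read_connectivity_dataset()` reloads them.
#'
#' @param dataset A `connectivity_dataset`.
#' @param path Output TSV path for the feature table; the edge map goes to
#'   `<path>_edges.tsv`.
#' @return `path`, invisibly (writer); a `connectivity_dataset` (reader).
#' @export
write_connectivity_dataset <- function(dataset, path) {
  df <- data.frame(subject_id = dataset$subject_ids, label = dataset$labels,
                   dataset$features, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("edge_%04d", dataset$edge_map$edge)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  edge_path <- sub("(\\.tsv)?$", "_edges.tsv", path)
  write.table(as.data.frame(dataset$edge_map), edge_path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_dataset
#' @export
read_connectivity_dataset <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  edge_path <- sub("(\\.tsv)?$", "_edges.tsv", path)
  em_df <- read.delim(edge_path, stringsAsFactors = FALSE)
  p <- max(em_df$region_j)
  region_names <- character(p)
  region_names[em_df$region_i] <- em_df$name_i
  region_names[em_df$region_j] <- em_df$name_j
  edge_map <- edge_index_map(p, region_names)
  feats <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(feats) <- list(df$subject_id, NULL)
  structure(list(features = feats, labels = df$label,
                 subject_ids = df$subject_id, edge_map = edge_map,
                 region_names = region_names),
            class = "connectivity_dataset")
}

#' Read a subject's regional time series from a 4-D NIfTI pair
#'
#' Convenience reader: loads a 4-D functional image and a 3-D integer label
#' image with \pkg{RNifti} and calls [extract_regional_timeseries()].
#'
#' @param volume_path Path to the 4-D NIfTI image.
#' @param atlas_path Path to the 3-D integer-labelled parcellation image.
#' @return Regions-by-volumes matrix.
#' @export
read_nifti_timeseries <- function(volume_path, atlas_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required to read NIfTI images.", call. = FALSE)
  }
  vol <- as.array(RNifti::readNifti(volume_path))
  atlas <- as.array(RNifti::readNifti(atlas_path))
  storage.mode(atlas) <- "integer"
  extract_regional_timeseries(vol, atlas)
}
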