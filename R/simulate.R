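#' Configure a synthetic multi-group resting-state simulation
#'
#' Describes a simulated multi-subject BOLD study: per-class sample sizes, a
#' base inter-regional correlation structure, class-specific correlation
#' perturbations on chosen edges, AR(1) temporal autocorrelation, an additive
#' shared global signal, and head-motion regressor tables. The defaults
#' emulate the study conditions this package is designed around: three groups
#' of 19/38/32 subjects, 116 regions, 180 volumes at TR = 2 s.
#'
#' @param n_subjects_per_class Named integer vector, one entry per class
#'   (names are the class labels). Default `c(mdd = 19, hc = 38, scz = 32)`.
#' @param n_regions Number of parcellation regions (default 116).
#' @param n_volumes Number of acquired volumes per subject (default 180).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param base_correlation Either a single correlation in (-1, 1) applied to
#'   every region pair, or a full symmetric unit-diagonal correlation matrix.
#'   Default 0.1, a weak uniform background coupling.
#' @param perturbed_edges Data frame with columns `class`, `region_i`,
#'   `region_j`, `delta`: additive changes to the target correlation of that
#'   pair in that class. Default: none.
#' @param ar_coefficient AR(1) coefficient of the regional noise in [0, 1)
#'   (default 0.3, a typical BOLD autocorrelation at TR = 2 s).
#' @param global_signal_sd Standard deviation of the shared per-subject global
#'   time course added to every region (default 0.5).
#' @param motion_sd Standard deviation of the six simulated motion parameters
#'   (default 0.1).
#' @param seed Master integer seed; per-subject substreams are derived from it
#'   so subject sets are reproducible under subsetting.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects_per_class = c(a = 5, b = 5), n_regions = 10,
#'                   n_volumes = 60, seed = 1)
#' @export
sim_config <- function(n_subjects_per_class = c(mdd = 19, hc = 38, scz = 32),
                       n_regions = 116,
                       n_volumes = 180,
                       tr_seconds = 2,
                       base_correlation = 0.1,
                       perturbed_edges = NULL,
                       ar_coefficient = 0.3,
                       global_signal_sd = 0.5,
                       motion_sd = 0.1,
                       seed = 1L) {
  cfg <- structure(list(
    n_subjects_per_class = n_subjects_per_class,
    n_regions = as.integer(n_regions),
    n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds,
    base_correlation = base_correlation,
    perturbed_edges = if (is.null(perturbed_edges)) {
      tibble::tibble(class = character(), region_i = integer(),
                     region_j = integer(), delta = numeric())
    } else tibble::as_tibble(perturbed_edges),
    ar_coefficient = ar_coefficient,
    global_signal_sd = global_signal_sd,
    motion_sd = motion_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Number of volumes acquired in a resting-state session
#'
#' Acquisition arithmetic: a session of the given duration at repetition
#' time `tr_seconds` yields `floor(duration * 60 / tr)` volumes — 180 for
#' the default 6-minute session at TR = 2 s.
#'
#' @param duration_minutes Session length in minutes (default 6).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @return Integer volume count.
#' @export
session_volumes <- function(duration_minutes = 6, tr_seconds = 2) {
  if (duration_minutes <= 0 || tr_seconds <= 0) {
    stop("duration and TR must be positive.", call. = FALSE)
  }
  as.integer(floor(duration_minutes * 60 / tr_seconds))
}

validate_sim_config <- function(cfg) {
  n <- cfg$n_subjects_per_class
  if (length(n) < 1L || is.null(names(n)) || any(names(n) == "") ||
      any(n < 1) || any(n != round(n))) {
    stop("`n_subjects_per_class` must be a named vector of positive integers.",
         call. = FALSE)
  }
  if (cfg$n_regions < 2L) stop("`n_regions` must be >= 2.", call. = FALSE)
  if (cfg$n_volumes < 2L) stop("`n_volumes` must be >= 2.", call. = FALSE)
  if (cfg$tr_seconds <= 0) stop("`tr_seconds` must be positive.", call. = FALSE)
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1) {
    stop("`ar_coefficient` must be in [0, 1).", call. = FALSE)
  }
  if (cfg$global_signal_sd < 0) stop("`global_signal_sd` must be >= 0.", call. = FALSE)
  if (cfg$motion_sd < 0) stop("`motion_sd` must be >= 0.", call. = FALSE)
  pe <- cfg$perturbed_edges
  if (nrow(pe)) {
    if (!all(c("class", "region_i", "region_j", "delta") %in% names(pe))) {
      stop("`perturbed_edges` needs columns class, region_i, region_j, delta.",
           call. = FALSE)
    }
    bad_class <- setdiff(unique(pe$class), names(n))
    if (length(bad_class)) {
      stop("perturbed_edges reference unknown class(es): ",
           paste(bad_class, collapse = ", "), call. = FALSE)
    }
    if (any(pe$region_i < 1) || any(pe$region_j > cfg$n_regions) ||
        any(pe$region_i >= pe$region_j)) {
      stop("perturbed_edges must satisfy 1 <= region_i < region_j <= n_regions.",
           call. = FALSE)
    }
  }
  base <- base_correlation_matrix(cfg)
  targets <- base[cbind(pe$region_i, pe$region_j)] + pe$delta
  out_of_range <- which(targets <= -1 | targets >= 1)
  if (length(out_of_range)) {
    k <- out_of_range[1L]
    stop(sprintf(
      "perturbed edge (%d, %d) in class '%s' targets correlation %.3f outside (-1, 1).",
      pe$region_i[k], pe$region_j[k], pe$class[k], targets[k]), call. = FALSE)
  }
  invisible(cfg)
}

base_correlation_matrix <- function(cfg) {
  p <- cfg$n_regions
  b <- cfg$base_correlation
  if (is.matrix(b)) {
    if (nrow(b) != p || ncol(b) != p || any(abs(b - t(b)) > 1e-12) ||
        any(abs(diag(b) - 1) > 1e-12)) {
      stop("`base_correlation` matrix must be symmetric, unit-diagonal, ",
           p, "x", p, ".", call. = FALSE)
    }
    return(b)
  }
  if (abs(b) >= 1) stop("`base_correlation` must lie in (-1, 1).", call. = FALSE)
  m <- matrix(b, p, p)
  diag(m) <- 1
  m
}

#' Per-class target correlation matrices
#'
#' Applies each class's edge perturbations to the base correlation matrix and
#' repairs positive definiteness when a perturbation breaks it (eigenvalues
#' clipped at 1e-6, then re-normalization to unit diagonal). Entries away from
#' perturbed edges equal the base matrix.
#'
#' @param config A [sim_config()].
#' @return Named list of symmetric positive-definite unit-diagonal matrices,
#'   one per class, in the order of `n_subjects_per_class`.
#' @export
make_group_covariances <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  base <- base_correlation_matrix(config)
  pe <- config$perturbed_edges
  out <- lapply(names(config$n_subjects_per_class), function(cl) {
    m <- base
    rows <- pe[pe$class == cl, , drop = FALSE]
    if (nrow(rows)) {
      idx <- cbind(rows$region_i, rows$region_j)
      m[idx] <- m[idx] + rows$delta
      m[idx[, 2:1, drop = FALSE]] <- m[idx]
    }
    repair_positive_definite(m)
  })
  names(out) <- names(config$n_subjects_per_class)
  out
}

# Clip eigenvalues at 1e-6 and rescale back to a correlation matrix. A no-op
# for matrices that are already PD.
repair_positive_definite <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) > floor) return(m)
  v <- pmax(e$values, floor)
  m2 <- e$vectors %*% (v * t(e$vectors))
  m2 <- stats::cov2cor(m2)
  (m2 + t(m2)) / 2
}

# Deterministic per-subject substream seed below 2^31.
subject_seed <- function(master_seed, subject_index) {
  as.integer((as.numeric(master_seed) * 1000003 +
                as.numeric(subject_index) * 7919) %% 2147483629)
}

#' Simulate a cohort of subjects with class-structured connectivity
#'
#' Each subject's region-by-time matrix is built as
#' `L %*% E + global_signal_sd * g`, where `L` is the Cholesky factor of the
#' subject's class correlation target, `E` holds AR(1)-autocorrelated standard
#' Gaussian noise (unit marginal variance) per region, and `g` is a shared
#' per-subject Gaussian time course added to all regions (the target the
#' global-signal regression step removes). A 6-row motion-parameter table
#' (3 translations, 3 rotations) is drawn independently. Deterministic given
#' the config seed; each subject has its own derived substream.
#'
#' @param config A [sim_config()].
#' @return A list of class `subject_set`: each element is a `subject_record`
#'   list with `subject_id`, `label`, `timeseries` (regions x volumes), and
#'   `motion` (6 x volumes).
#' @examples
#' cfg <- sim_config(n_subjects_per_class = c(a = 2, b = 2), n_regions = 8,
#'                   n_volumes = 40, seed = 7)
#' subs <- simulate_subjects(cfg)
#' length(subs) # 4
#' @export
simulate_subjects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  covs <- make_group_covariances(config)
  chols <- lapply(covs, function(m) {
    ch <- tryCatch(chol(m), error = function(e) {
      stop("class covariance not positive definite after repair.", call. = FALSE)
    })
    t(ch)
  })
  p <- config$n_regions
  tt <- config$n_volumes
  phi <- config$ar_coefficient
  labels <- rep(names(config$n_subjects_per_class),
                times = config$n_subjects_per_class)
  out <- vector("list", length(labels))
  within_class_idx <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  for (s in seq_along(labels)) {
    set.seed(subject_seed(config$seed, s))
    innov <- matrix(rnorm(p * tt), p, tt)
    if (phi > 0) {
      # unit-marginal-variance AR(1) per region
      e <- innov * sqrt(1 - phi^2)
      e[, 1] <- innov[, 1]
      for (t in 2:tt) e[, t] <- phi * e[, t - 1] + e[, t]
    } else {
      e <- innov
    }
    ts <- chols[[labels[s]]] %*% e
    if (config$global_signal_sd > 0) {
      g <- rnorm(tt, sd = config$global_signal_sd)
      ts <- ts + matrix(g, p, tt, byrow = TRUE)
    }
    motion <- matrix(rnorm(6 * tt, sd = config$motion_sd), 6, tt)
    rownames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    out[[s]] <- structure(list(
      subject_id = sprintf("%s_%03d", labels[s], within_class_idx[s]),
      label = labels[s],
      timeseries = ts,
      motion = motion
    ), class = "subject_record")
  }
  structure(out, class = "subject_set", config = config)
}

#' Summarize a simulated cohort as a tibble
#'
#' @param x A `subject_set` from [simulate_subjects()].
#' @param ... Unused.
#' @return A tibble with one row per subject: `subject_id`, `label`,
#'   `n_regions`, `n_volumes`.
#' @method tidy subject_set
#' @export
tidy.subject_set <- function(x, ...) {
  tibble::tibble(
    subject_id = vapply(x, `[[`, "", "subject_id"),
    label = vapply(x, `[[`, "", "label"),
    n_regions = vapply(x, function(s) nrow(s$timeseries), 0L),
    n_volumes = vapply(x, function(s) ncol(s$timeseries), 0L)
  )
}

#' @export
print.subject_set <- function(x, ...) {
  cat("<subject_set> ", length(x), " subjects, ",
      nrow(x[[1]]$timeseries), " regions x ", ncol(x[[1]]$timeseries),
      " volumes\n", sep = "")
  print(table(vapply(x, `[[`, "", "label")))
  invisible(x)
}

#' Write a simulated cohort to disk as TSV tables
#'
#' Writes one region-by-volume TSV per subject, one 6-row motion TSV per
#' subject, and a `manifest.tsv` (columns `subject_id`, `label`, `path`,
#' `motion_path`) in the layout the connectivity readers consume.
#'
#' @param subjects A `subject_set`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_subjects <- function(subjects, dir) {
  stopifnot(inherits(subjects, "subject_set") || is.list(subjects))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(subjects, function(s) {
    ts_path <- file.path(dir, paste0(s$subject_id, "_timeseries.tsv"))
    mo_path <- file.path(dir, paste0(s$subject_id, "_motion.tsv"))
    write.table(s$timeseries, ts_path, sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    write.table(s$motion, mo_path, sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    data.frame(subject_id = s$subject_id, label = s$label,
               path = basename(ts_path), motion_path = basename(mo_path))
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(manifest_path)
}

#' Read a cohort written by [write_subjects()]
#'
#' @param manifest_path Path to a `manifest.tsv`.
#' @return A `subject_set` list of `subject_record`s.
#' @export
read_subjects <- function(manifest_path) {
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  out <- lapply(seq_len(nrow(manifest)), function(k) {
    ts <- as.matrix(read.delim(file.path(base, manifest$path[k]),
                               header = FALSE))
    dimnames(ts) <- NULL
    motion <- NULL
    if (!is.null(manifest$motion_path) && nzchar(manifest$motion_path[k])) {
      motion <- as.matrix(read.delim(file.path(base, manifest$motion_path[k]),
                                     header = FALSE))
      dimnames(motion) <- NULL
    }
    structure(list(subject_id = manifest$subject_id[k],
                   label = manifest$label[k],
                   timeseries = ts, motion = motion),
              class = "subject_record")
  })
  structure(out, class = "subject_set")
}
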