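#' Class means and scatter factor matrices
#'
#' Computes the building blocks of the intrinsic model: the global mean, the
#' per-class means, the class-common factor `H_cc` (class-mean deviations
#' about the global mean, by default weighted by `sqrt(n_i)` so that
#' `H_cc %*% t(H_cc)` is the standard between-class scatter), and the
#' individual factor `H_ind` (each sample's deviation from its class mean,
#' so `H_ind %*% t(H_ind)` is the within-class scatter).
#'
#' @param X P-by-N numeric matrix, one sample per column.
#' @param y Length-N class labels.
#' @param sqrt_weighting Weight class deviations by `sqrt(n_i)` (default
#'   `TRUE`).
#' @return A list with `global_mean` (length P), `class_means` (P x c,
#'   columns named by class), `H_cc` (P x c), `H_ind` (P x N), `classes`,
#'   and `n_per_class`.
#' @export
class_statistics <- function(X, y, sqrt_weighting = TRUE) {
  stopifnot(is.matrix(X), ncol(X) == length(y))
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 1L) stop("need at least one class.", call. = FALSE)
  n_i <- vapply(classes, function(cl) sum(y == cl), 0L)
  if (any(n_i == 1L)) {
    warning("class(es) with a single sample contribute only zero columns ",
            "to the individual scatter: ",
            paste(classes[n_i == 1L], collapse = ", "), call. = FALSE)
  }
  gm <- rowMeans(X)
  cm <- vapply(classes, function(cl) rowMeans(X[, y == cl, drop = FALSE]),
               numeric(nrow(X)))
  H_cc <- cm - gm
  if (sqrt_weighting) H_cc <- sweep(H_cc, 2L, sqrt(n_i), `*`)
  H_ind <- X - cm[, match(y, classes), drop = FALSE]
  list(global_mean = gm, class_means = cm, H_cc = H_cc, H_ind = H_ind,
       classes = classes, n_per_class = n_i)
}

#' Intrinsic three-way decomposition of a sample
#'
#' Writes a sample as the sum of a common component (the global mean of the
#' training data), a class-common component (its class mean minus the global
#' mean), and an individual component (the sample minus its class mean). The
#' three parts reconstruct the sample exactly.
#'
#' @param x Length-P sample vector.
#' @param X,y Training data as in [class_statistics()].
#' @param class_of_x The class `x` belongs to; must occur in `y`.
#' @return A list with `common`, `class_common`, `individual` (each length P).
#' @export
intrinsic_decompose <- function(x, X, y, class_of_x) {
  st <- suppressWarnings(class_statistics(X, y))
  cl <- as.character(class_of_x)
  if (!cl %in% st$classes) {
    stop("unknown class '", cl, "'.", call. = FALSE)
  }
  cm <- st$class_means[, cl]
  list(common = st$global_mean,
       class_common = cm - st$global_mean,
       individual = x - cm)
}

#' Maximal admissible embedding dimension
#'
#' The training scatter of `n` samples has rank at most `n - 1`, so [fit_ida()]
#' admits embedding dimensions up to `n - 1`; with 89 subjects this is the
#' grid ceiling of 88. Within a leave-one-out fold one sample is held out,
#' so the per-fold bound is one lower.
#'
#' @param n_samples Number of samples in the dataset.
#' @param per_fold Return the bound inside a leave-one-out training fold
#'   (default `FALSE`).
#' @return An integer dimension bound.
#' @export
max_embedding_dimension <- function(n_samples, per_fold = FALSE) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L) stop("need at least 3 samples.", call. = FALSE)
  if (per_fold) n_samples - 2L else n_samples - 1L
}

default_epsilon <- function(H_ind) {
  mean_diag <- sum(H_ind^2) / nrow(H_ind)
  if (mean_diag > 0) 1e-4 * mean_diag else 1e-8
}

#' Fit intrinsic discriminant analysis
#'
#' Finds the linear map that maximizes class-common variation relative to
#' individual (within-class) variation by solving the perturbed generalized
#' eigenproblem `S_cc w = lambda (S_ind + epsilon I) w`, where `S_cc` and
#' `S_ind` are the class-common and individual scatter matrices. The
#' perturbation `epsilon` regularizes `S_ind`, which is singular whenever the
#' number of training samples is smaller than the feature dimensionality (the
#' usual situation with 6670 connectivity edges and fewer than a hundred
#' subjects).
#'
#' The solver works in the span of the training data: every eigenvector with
#' a nonzero eigenvalue lies in that span, so the eigenproblem is projected
#' onto an orthonormal basis of at most N dimensions and no P-by-P matrix is
#' ever formed. Columns of the returned transformation matrix are the
#' "intrinsicconnectomes" when the features are connectivity edges.
#'
#' @param X P-by-N training matrix (samples in columns).
#' @param y Length-N class labels.
#' @param d Embedding dimension, `1 <= d <= N - 1`.
#' @param epsilon Positive perturbation constant; default
#'   `1e-4 * mean(diag(S_ind))` (falling back to `1e-8` when the individual
#'   scatter vanishes), a scale-free conditioning choice.
#' @param sqrt_weighting Passed to [class_statistics()].
#' @return An `ida_model`: `W` (P x d, unit-norm columns with the
#'   largest-magnitude entry positive), `eigenvalues` (non-increasing),
#'   `global_mean`, `class_means`, `epsilon`, `d`, `classes`.
#' @examples
#' X <- cbind(matrix(rnorm(20, 0), 2, 10), matrix(rnorm(20, 3), 2, 10))
#' y <- rep(c("a", "b"), each = 10)
#' fit <- fit_ida(X, y, d = 1)
#' @export
fit_ida <- function(X, y, d, epsilon = NULL, sqrt_weighting = TRUE) {
  stopifnot(is.matrix(X))
  n <- ncol(X)
  if (length(y) != n) stop("`y` must have one label per column.", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("need at least two classes.", call. = FALSE)
  }
  if (d < 1 || d > n - 1) {
    stop("`d` must satisfy 1 <= d <= N - 1 = ", n - 1,
         " (the scatter has rank at most N - 1).", call. = FALSE)
  }
  st <- class_statistics(X, y, sqrt_weighting = sqrt_weighting)
  if (is.null(epsilon)) epsilon <- default_epsilon(st$H_ind)
  if (epsilon <= 0) stop("`epsilon` must be positive.", call. = FALSE)

  # Orthonormal basis of span(H_ind, H_cc) = span of the centered data.
  sv <- svd(cbind(st$H_ind, st$H_cc))
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r == 0L) stop("training data has zero scatter.", call. = FALSE)
  if (d > r) {
    stop("`d` = ", d, " exceeds the rank of the training scatter (", r, ").",
         call. = FALSE)
  }
  Q <- sv$u[, seq_len(r), drop = FALSE]

  # Project both scatters onto the span; the denominator stays PD there.
  Qcc <- crossprod(Q, st$H_cc)          # r x c
  Qind <- crossprod(Q, st$H_ind)        # r x N
  A <- tcrossprod(Qcc)
  B <- tcrossprod(Qind) + diag(epsilon, r)

  eb <- eigen(B, symmetric = TRUE)
  B_half_inv <- eb$vectors %*% (t(eb$vectors) / sqrt(eb$values))
  M <- B_half_inv %*% A %*% B_half_inv
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)

  lambda <- em$values[seq_len(d)]
  # a tie at the cut only matters when the tied eigenvalues are nonzero;
  # beyond rank(S_cc) the spectrum is identically ~0 by construction
  lam_tol <- 1e-10 * max(em$values[1L], 1e-300)
  if (d < r && em$values[d] > lam_tol &&
      abs(em$values[d] - em$values[d + 1L]) < lam_tol) {
    warning("tied generalized eigenvalues at the embedding cut; keeping the ",
            "first computed basis.", call. = FALSE)
  }
  Z <- B_half_inv %*% em$vectors[, seq_len(d), drop = FALSE]
  W <- Q %*% Z
  # unit columns, largest-magnitude component positive (reproducible signs)
  for (k in seq_len(d)) {
    w <- W[, k]
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    W[, k] <- w
  }
  structure(list(W = W, eigenvalues = lambda,
                 global_mean = st$global_mean, class_means = st$class_means,
                 epsilon = epsilon, d = as.integer(d),
                 classes = st$classes, n_per_class = st$n_per_class,
                 sqrt_weighting = sqrt_weighting),
            class = "ida_model")
}

#' Project samples into the IDA embedding
#'
#' Applies the fitted transformation `t(W) %*% X`. The map is linear; no
#' centering is applied.
#'
#' @param model An `ida_model`.
#' @param X P-by-M matrix of samples in columns (or a length-P vector).
#' @return d-by-M matrix of embedded coordinates.
#' @export
ida_transform <- function(model, X) {
  stopifnot(inherits(model, "ida_model"))
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (nrow(X) != nrow(model$W)) {
    stop("feature dimension ", nrow(X), " does not match the model (",
         nrow(model$W), ").", call. = FALSE)
  }
  crossprod(model$W, X)
}

#' @export
predict.ida_model <- function(object, newdata, ...) ida_transform(object, newdata)

#' @export
print.ida_model <- function(x, ...) {
  cat("<ida_model> ", nrow(x$W), " features -> ", x$d, " dimensions, ",
      length(x$classes), " classes (", paste(x$classes, collapse = ", "),
      "), epsilon = ", format(x$epsilon, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_ida One row per embedding component: `component`,
#'   `eigenvalue`, `share` (eigenvalue / total).
#' @param x,object An `ida_model`.
#' @param ... Unused.
#' @method tidy ida_model
#' @export
tidy.ida_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$d),
                 eigenvalue = x$eigenvalues,
                 share = x$eigenvalues / sum(x$eigenvalues))
}

#' @describeIn fit_ida One-row model summary.
#' @method glance ida_model
#' @export
glance.ida_model <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$W), d = x$d,
                 n_classes = length(x$classes), epsilon = x$epsilon,
                 leading_eigenvalue = x$eigenvalues[1L])
}

#' Intrinsicconnectome patterns as an edge table
#'
#' Each column of the fitted transformation matrix, read over the
#' connectivity edges, is one intrinsicconnectome: a pattern over region
#' pairs whose combinations represent any functional-connectivity profile.
#' Loadings are unit-normalized per pattern.
#'
#' @param model An `ida_model` fitted on edge features.
#' @param edge_map The [edge_index_map()] used to build the features; its
#'   length must equal the model's feature dimension.
#' @param patterns Which components to return (default all `d`).
#' @return A tibble with columns `pattern`, `edge`, `name_i`, `name_j`,
#'   `loading`.
#' @export
intrinsicconnectomes <- function(model, edge_map,
                                 patterns = seq_len(model$d)) {
  stopifnot(inherits(model, "ida_model"))
  if (nrow(model$W) != n_edges(edge_map)) {
    stop("model feature dimension does not match the edge map.", call. = FALSE)
  }
  purrr::map_dfr(patterns, function(k) {
    w <- model$W[, k]
    w <- w / sqrt(sum(w^2))
    tibble::tibble(pattern = as.integer(k), edge = edge_map$edge,
                   name_i = edge_map$name_i, name_j = edge_map$name_j,
                   loading = w)
  })
}

#' Residual of the generalized eigen-equation for a fitted model
#'
#' Recomputes, from the training data, the relative residual
#' `||S_cc w - lambda (S_ind + epsilon I) w||` for each fitted eigenpair,
#' scaled by `trace(S_cc)`, without forming either P-by-P scatter matrix.
#' Useful as a numerical health check of the solver.
#'
#' @param model An `ida_model`.
#' @param X,y The training data the model was fitted on.
#' @return Numeric vector of `d` relative residuals.
#' @export
ida_eigen_residual <- function(model, X, y) {
  st <- suppressWarnings(
    class_statistics(X, y, sqrt_weighting = model$sqrt_weighting))
  scale <- sum(st$H_cc^2)   # trace of S_cc
  vapply(seq_len(model$d), function(k) {
    w <- model$W[, k]
    lhs <- st$H_cc %*% crossprod(st$H_cc, w)
    rhs <- model$eigenvalues[k] *
      (st$H_ind %*% crossprod(st$H_ind, w) + model$epsilon * w)
    sqrt(sum((lhs - rhs)^2)) / scale
  }, 0)
}

#' Save / load a fitted IDA model
#'
#' Serializes the full model state (version tag, transformation matrix,
#' means, epsilon, embedding dimension, eigenvalues) with an exact
#' round-trip.
#'
#' @param model An `ida_model`.
#' @param path File path.
#' @return `path` invisibly (writer); an `ida_model` (reader).
#' @export
write_ida_model <- function(model, path) {
  stopifnot(inherits(model, "ida_model"))
  payload <- unclass(model)
  payload$format_version <- 1L
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_ida_model
#' @export
read_ida_model <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$format_version)) {
    stop("not an ida_model archive.", call. = FALSE)
  }
  payload$format_version <- NULL
  structure(payload, class = "ida_model")
}
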