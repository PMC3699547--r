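#' PCA baseline reducer
#'
#' Leading principal axes of mean-centered data, the unsupervised baseline
#' the supervised embedding is compared against.
#'
#' @param X P-by-N matrix, samples in columns.
#' @param d Number of axes, `d <= min(P, N - 1)`.
#' @return P-by-d matrix whose columns are the top principal directions,
#'   variance-ordered, with the largest-magnitude entry positive.
#' @export
pca_reducer <- function(X, d) {
  stopifnot(is.matrix(X))
  if (d < 1 || d > min(nrow(X), ncol(X) - 1L)) {
    stop("`d` must satisfy 1 <= d <= min(P, N - 1) = ",
         min(nrow(X), ncol(X) - 1L), ".", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  sv <- svd(Xc, nu = d, nv = 0)
  W <- sv$u
  for (k in seq_len(d)) {
    if (W[which.max(abs(W[, k])), k] < 0) W[, k] <- -W[, k]
  }
  W
}

#' Train one-against-rest linear SVMs in the embedding
#'
#' Fits one binary linear max-margin classifier per class: the classifier for
#' class i is trained with class-i samples labelled positive and everything
#' else negative. Decision functions are stored explicitly as embedding-space
#' weight vectors plus biases, so prediction is the argmax of `Z' w_i + b_i`
#' and the weights can be back-projected to edge space.
#'
#' @param Z d-by-N matrix of embedded training samples (columns).
#' @param y Length-N class labels; every class must be present.
#' @param C SVM regularization constant (default 1).
#' @param classes Optional class order; defaults to order of first
#'   appearance in `y`.
#' @return An `ovr_classifier`: `weights` (classes x d), `bias` (length
#'   classes), `classes`, `C`.
#' @export
train_ovr <- function(Z, y, C = 1, classes = NULL) {
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1L)
  stopifnot(ncol(Z) == length(y))
  y <- as.character(y)
  if (is.null(classes)) classes <- unique(y)
  missing_cl <- setdiff(classes, unique(y))
  if (length(missing_cl)) {
    stop("class(es) absent from training data: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  d <- nrow(Z)
  weights <- matrix(NA_real_, length(classes), d,
                    dimnames = list(classes, NULL))
  bias <- stats::setNames(numeric(length(classes)), classes)
  Xs <- t(Z)
  for (cl in classes) {
    yf <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(x = Xs, y = yf, kernel = "linear", cost = C,
                      scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    b <- -fit$rho
    # e1071's decision value is positive for its first internal label
    if (fit$levels[fit$labels[1L]] != "pos") {
      w <- -w
      b <- -b
    }
    weights[cl, ] <- w
    bias[cl] <- b
  }
  structure(list(weights = weights, bias = bias, classes = classes, C = C),
            class = "ovr_classifier")
}

#' Decision values of a one-against-rest classifier
#'
#' @param clf An `ovr_classifier`.
#' @param Z d-by-M matrix of embedded samples.
#' @return M-by-classes matrix of real-valued decision outputs.
#' @export
decision_values <- function(clf, Z) {
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = 1L)
  if (nrow(Z) != ncol(clf$weights)) {
    stop("embedding dimension mismatch.", call. = FALSE)
  }
  t(clf$weights %*% Z + clf$bias)
}

#' Predict class labels by highest one-against-rest output
#'
#' The predicted class maximizes the decision value; exact ties resolve to
#' the lowest class index.
#'
#' @inheritParams decision_values
#' @return Character vector of M predicted labels.
#' @export
predict_ovr <- function(clf, Z) {
  dv <- decision_values(clf, Z)
  clf$classes[max.col(dv, ties.method = "first")]
}

#' @export
predict.ovr_classifier <- function(object, newdata, ...) {
  predict_ovr(object, newdata)
}

fit_reducer <- function(X_tr, y_tr, d, epsilon, reducer) {
  if (reducer == "ida") {
    model <- fit_ida(X_tr, y_tr, d = d, epsilon = epsilon)
    list(W = model$W, center = rep(0, nrow(X_tr)), model = model)
  } else {
    list(W = pca_reducer(X_tr, d), center = rowMeans(X_tr), model = NULL)
  }
}

embed_with <- function(red, X, d = ncol(red$W)) {
  crossprod(red$W[, seq_len(d), drop = FALSE], X - red$center)
}

new_cv_report <- function(folds, classes, d, reducer, C, epsilon,
                          curve = NULL, fold_weights = NULL,
                          edge_weight_mean = NULL) {
  cm <- table(factor(folds$true, levels = classes),
              factor(folds$predicted, levels = classes))
  confusion <- 100 * prop.table(unclass(cm), margin = 1L)
  per_class <- diag(confusion)
  structure(list(
    folds = folds,
    confusion = confusion,
    per_class_accuracy = per_class,
    accuracy = 100 * mean(folds$predicted == folds$true),
    classes = classes, d = as.integer(d), reducer = reducer,
    C = C, epsilon = epsilon, curve = curve,
    fold_weights = fold_weights, edge_weight_mean = edge_weight_mean
  ), class = "cv_report")
}

#' Leave-one-out cross-validation of the embed-then-classify pipeline
#'
#' Runs N folds; in each, the dimensionality reduction (IDA or PCA) and the
#' one-against-rest SVMs are fitted on the N - 1 training subjects only, and
#' the held-out subject is embedded and classified with those fold-specific
#' models, so the held-out subject never influences means, eigenvectors, or
#' the SVMs. Per-fold embedding-space SVM weight vectors are retained (and,
#' optionally, their per-fold back-projections accumulated) for the
#' discriminative-connection analysis.
#'
#' @param dataset A `connectivity_dataset` (or any list with an N x P
#'   `features` matrix and `labels`).
#' @param d Embedding dimension, at most N - 2.
#' @param epsilon IDA perturbation constant (`NULL` = scale-based default).
#' @param C SVM regularization constant.
#' @param reducer `"ida"` or `"pca"`.
#' @param collect_weights Keep per-fold weight vectors and the per-fold
#'   edge-space back-projection average (default `TRUE`).
#' @return A `cv_report` with the fold table, row-stochastic confusion matrix
#'   (percentages), per-class and overall accuracies, and (when collected)
#'   `fold_weights` (list of classes x d matrices) plus `edge_weight_mean`
#'   (P x classes matrix: fold back-projections averaged in edge space).
#' @examples
#' cfg <- sim_config(n_subjects_per_class = c(a = 6, b = 6), n_regions = 12,
#'                   n_volumes = 60, seed = 3)
#' ds <- connectivity_dataset(simulate_subjects(cfg))
#' rep <- loocv(ds, d = 2)
#' rep$accuracy
#' @export
loocv <- function(dataset, d, epsilon = NULL, C = 1,
                  reducer = c("ida", "pca"), collect_weights = TRUE) {
  reducer <- match.arg(reducer)
  feats <- dataset$features
  labels <- as.character(dataset$labels)
  n <- nrow(feats)
  classes <- unique(labels)
  if (n < length(classes) + 1L) stop("need N >= c + 1 subjects.", call. = FALSE)
  if (d > n - 2L) {
    stop("`d` = ", d, " exceeds N - 2 = ", n - 2L,
         " (training folds have N - 1 samples).", call. = FALSE)
  }
  preds <- character(n)
  fold_weights <- if (collect_weights) vector("list", n) else NULL
  edge_sum <- if (collect_weights) {
    matrix(0, ncol(feats), length(classes), dimnames = list(NULL, classes))
  } else NULL
  for (i in seq_len(n)) {
    X_tr <- t(feats[-i, , drop = FALSE])
    y_tr <- labels[-i]
    red <- fit_reducer(X_tr, y_tr, d, epsilon, reducer)
    Z_tr <- embed_with(red, X_tr)
    clf <- train_ovr(Z_tr, y_tr, C = C, classes = classes)
    z_te <- embed_with(red, matrix(feats[i, ], ncol = 1L))
    preds[i] <- predict_ovr(clf, z_te)
    if (collect_weights) {
      fold_weights[[i]] <- clf$weights
      edge_sum <- edge_sum + red$W %*% t(clf$weights)
    }
  }
  folds <- tibble::tibble(
    fold = seq_len(n),
    subject_id = dataset$subject_ids %||% as.character(seq_len(n)),
    true = labels, predicted = preds
  )
  new_cv_report(folds, classes, d, reducer, C, epsilon,
                fold_weights = fold_weights,
                edge_weight_mean = if (collect_weights) {
                  edge_sum / n
                } else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid search over the embedding dimension
#'
#' Evaluates LOOCV accuracy at every integer dimension in `[d_min, d_max]`
#' and reports the best-performing dimension (smallest on ties). Each fold's
#' reduction is fitted once at the grid ceiling and truncated to each `d`
#' (the leading components of the fitted basis do not depend on how many
#' trailing ones are kept), so the search costs one reduction plus
#' `|grid|` SVM fits per fold.
#'
#' @inheritParams loocv
#' @param d_min,d_max Grid bounds; `d_max` defaults to N - 2 and is capped
#'   there (with a warning) when set higher.
#' @return A `cv_report` for the best dimension, with `curve` holding the
#'   accuracy-vs-dimension tibble (`d`, `accuracy`).
#' @export
grid_search_dimension <- function(dataset, d_min = 2, d_max = NULL,
                                  epsilon = NULL, C = 1,
                                  reducer = c("ida", "pca")) {
  reducer <- match.arg(reducer)
  feats <- dataset$features
  labels <- as.character(dataset$labels)
  n <- nrow(feats)
  classes <- unique(labels)
  if (is.null(d_max)) d_max <- n - 2L
  if (d_max > n - 2L) {
    warning("`d_max` capped at N - 2 = ", n - 2L, ".", call. = FALSE)
    d_max <- n - 2L
  }
  if (d_min < 1 || d_min > d_max) stop("empty dimension grid.", call. = FALSE)
  grid <- seq.int(d_min, d_max)
  pred_mat <- matrix(NA_character_, n, length(grid))
  for (i in seq_len(n)) {
    X_tr <- t(feats[-i, , drop = FALSE])
    y_tr <- labels[-i]
    red <- fit_reducer(X_tr, y_tr, d_max, epsilon, reducer)
    x_te <- matrix(feats[i, ], ncol = 1L)
    for (g in seq_along(grid)) {
      d <- grid[g]
      Z_tr <- embed_with(red, X_tr, d = d)
      clf <- train_ovr(Z_tr, y_tr, C = C, classes = classes)
      pred_mat[i, g] <- predict_ovr(clf, embed_with(red, x_te, d = d))
    }
  }
  acc <- 100 * colMeans(pred_mat == labels)
  curve <- tibble::tibble(d = grid, accuracy = acc)
  best_g <- which.max(acc)   # first maximum = smallest d on ties
  folds <- tibble::tibble(
    fold = seq_len(n),
    subject_id = dataset$subject_ids %||% as.character(seq_len(n)),
    true = labels, predicted = pred_mat[, best_g]
  )
  new_cv_report(folds, classes, grid[best_g], reducer, C, epsilon,
                curve = curve)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$reducer, " embedding, d = ", x$d, ", ",
      nrow(x$folds), " LOOCV folds\n", sep = "")
  cat("overall accuracy: ", sprintf("%.1f%%", x$accuracy), "\n", sep = "")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Fold-level results of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The per-fold tibble (`fold`, `subject_id`, `true`, `predicted`,
#'   `correct`).
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::mutate(x$folds, correct = .data$true == .data$predicted)
}

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, per-class accuracies, `d`, `reducer`,
#'   `n_folds`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  per_cl <- tibble::as_tibble_row(
    stats::setNames(as.list(x$per_class_accuracy),
                    paste0("accuracy_", names(x$per_class_accuracy))))
  dplyr::bind_cols(
    tibble::tibble(accuracy = x$accuracy, d = x$d, reducer = x$reducer,
                   n_folds = nrow(x$folds)),
    per_cl
  )
}

#' Plot a cross-validation report
#'
#' With a grid-search curve present, draws accuracy against embedding
#' dimension; otherwise draws the row-normalized confusion matrix.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  if (!is.null(object$curve)) {
    ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$d,
                                               y = .data$accuracy)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_vline(xintercept = object$d, linetype = "dashed") +
      ggplot2::labs(x = "embedding dimension",
                    y = "LOOCV accuracy (%)",
                    title = paste0(toupper(object$reducer),
                                   " accuracy vs dimension (best d = ",
                                   object$d, ")")) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::as_tibble(as.table(object$confusion), .name_repair = "minimal")
    names(df) <- c("true", "predicted", "percent")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                     fill = .data$percent)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(
        label = sprintf("%.1f", .data$percent)), size = 3) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
      ggplot2::labs(x = "predicted", y = "true group",
                    fill = "% of group",
                    title = "LOOCV confusion matrix") +
      ggplot2::theme_minimal()
  }
}

#' Export a cross-validation report
#'
#' Writes the report as JSON (fold table, confusion matrix, accuracy curve)
#' plus a TSV confusion matrix (rows = true groups, columns = predictions,
#' percentages).
#'
#' @param report A `cv_report`.
#' @param path JSON output path; the confusion TSV goes to
#'   `<path>_confusion.tsv`.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  payload <- list(
    reducer = report$reducer, d = report$d, C = report$C,
    accuracy = report$accuracy,
    per_class_accuracy = as.list(report$per_class_accuracy),
    confusion = as.data.frame.matrix(report$confusion),
    folds = report$folds,
    curve = report$curve
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  tsv <- sub("(\\.json)?$", "_confusion.tsv", path)
  cm <- as.data.frame.matrix(round(report$confusion, 1))
  cm <- cbind(group = rownames(cm), cm)
  write.table(cm, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
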