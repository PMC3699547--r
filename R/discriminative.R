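#' Average per-fold classifier weight vectors
#'
#' Arithmetic mean of the embedding-space weight vectors a one-against-rest
#' classifier produced across cross-validation folds; no normalization is
#' applied before averaging.
#'
#' @param fold_weights Non-empty list of equal-length numeric vectors.
#' @return The mean weight vector.
#' @export
average_fold_weights <- function(fold_weights) {
  if (!length(fold_weights)) stop("no fold weights supplied.", call. = FALSE)
  lens <- lengths(fold_weights)
  if (length(unique(lens)) != 1L) {
    stop("fold weight vectors differ in length.", call. = FALSE)
  }
  Reduce(`+`, fold_weights) / length(fold_weights)
}

#' Back-project an embedding-space weight vector to edge space
#'
#' Maps a classifier weight vector from the d-dimensional embedding back to
#' the original edge space through the transformation matrix: the composite
#' direction `W %*% w` satisfies `(W w)' x = w' (W' x)` for every sample `x`,
#' so decision values are identical whether computed in embedding or edge
#' space.
#'
#' @param model An `ida_model` (or any P x d numeric matrix used as the
#'   transformation).
#' @param w_embedded Length-d weight vector.
#' @return Length-P edge-space weight vector.
#' @export
backproject_weights <- function(model, w_embedded) {
  W <- if (inherits(model, "ida_model")) model$W else model
  stopifnot(is.matrix(W))
  if (length(w_embedded) != ncol(W)) {
    stop("weight vector length ", length(w_embedded),
         " does not match the embedding dimension ", ncol(W), ".",
         call. = FALSE)
  }
  drop(W %*% w_embedded)
}

#' Select the top fraction of edges by absolute weight
#'
#' Ranks edges by `|weight|` descending (ties broken by ascending edge id)
#' and keeps `floor(fraction * P)` of them — the "consensus" connections of a
#' classifier. A negative weight is as discriminative as a positive one for a
#' linear decision, so magnitude, not sign, drives the ranking.
#'
#' @param edge_weights Length-P numeric vector of edge-space weights.
#' @param fraction Fraction to keep, in (0, 1] (default 0.05).
#' @return Tibble with columns `edge`, `weight`, `rank`, ordered by rank.
#' @export
top_fraction_edges <- function(edge_weights, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1].", call. = FALSE)
  }
  p <- length(edge_weights)
  k <- floor(fraction * p)
  ord <- order(-abs(edge_weights), seq_len(p))
  keep <- ord[seq_len(k)]
  tibble::tibble(edge = keep, weight = edge_weights[keep],
                 rank = seq_len(k))
}

#' Region occurrence weights of a consensus edge set
#'
#' Counts, for every region, the number of consensus edges incident to it —
#' the region's degree within the consensus set, used as its relative
#' contribution to the classification. Counts sum to twice the number of
#' edges.
#'
#' @param consensus_edges Integer edge ids (or a tibble with an `edge`
#'   column, as returned by [top_fraction_edges()]).
#' @param edge_map The [edge_index_map()] the ids refer to.
#' @return Tibble with one row per region: `region`, `name`, `weight`.
#' @export
region_occurrence_weights <- function(consensus_edges, edge_map) {
  if (is.data.frame(consensus_edges)) consensus_edges <- consensus_edges$edge
  if (length(consensus_edges) &&
      (any(consensus_edges < 1) || any(consensus_edges > n_edges(edge_map)))) {
    stop("edge id(s) outside the edge map.", call. = FALSE)
  }
  p <- edge_map_regions(edge_map)
  counts <- tabulate(c(edge_map$region_i[consensus_edges],
                       edge_map$region_j[consensus_edges]), nbins = p)
  region_names <- character(p)
  region_names[edge_map$region_i] <- edge_map$name_i
  region_names[edge_map$region_j] <- edge_map$name_j
  tibble::tibble(region = seq_len(p), name = region_names, weight = counts)
}

#' Discriminative edge maps from a cross-validated pipeline
#'
#' For each one-against-rest classifier, averages its per-fold
#' embedding-space weight vectors and back-projects the average to edge
#' space, then extracts the top-fraction consensus edges and per-region
#' occurrence weights. Back-projection uses, by default, the transformation
#' refitted on all N subjects (`"full_model"`); alternatively each fold's
#' weights are back-projected through that fold's own transformation and
#' averaged in edge space (`"per_fold"`, taken from the report).
#'
#' @param report A `cv_report` from [loocv()] run with
#'   `collect_weights = TRUE`.
#' @param dataset The `connectivity_dataset` the report was computed on
#'   (needed to refit the full-data model; ignored for `"per_fold"`).
#' @param fraction Top fraction of edges to keep (default 0.05).
#' @param backprojection `"full_model"` or `"per_fold"`.
#' @return Named list (one per class) of `discriminative_map` objects:
#'   `classifier`, `edge_weights`, `consensus` (tibble with region names),
#'   `region_weights`, `fraction`, `edge_map`.
#' @export
discriminative_maps <- function(report, dataset, fraction = 0.05,
                                backprojection = c("full_model", "per_fold")) {
  backprojection <- match.arg(backprojection)
  stopifnot(inherits(report, "cv_report"))
  if (is.null(report$fold_weights)) {
    stop("the cv_report holds no fold weights; rerun loocv() with ",
         "`collect_weights = TRUE`.", call. = FALSE)
  }
  edge_map <- dataset$edge_map
  classes <- report$classes
  if (backprojection == "full_model") {
    full_model <- fit_ida(t(dataset$features), dataset$labels, d = report$d,
                          epsilon = report$epsilon)
    mean_w <- lapply(classes, function(cl) {
      average_fold_weights(lapply(report$fold_weights, function(m) m[cl, ]))
    })
    edge_w <- lapply(mean_w, function(w) backproject_weights(full_model, w))
  } else {
    if (is.null(report$edge_weight_mean)) {
      stop("per-fold edge weights were not collected.", call. = FALSE)
    }
    edge_w <- lapply(classes, function(cl) report$edge_weight_mean[, cl])
  }
  names(edge_w) <- classes
  out <- lapply(classes, function(cl) {
    cons <- top_fraction_edges(edge_w[[cl]], fraction) |>
      dplyr::left_join(
        dplyr::select(tibble::as_tibble(edge_map),
                      "edge", "region_i", "region_j", "name_i", "name_j"),
        by = "edge")
    structure(list(
      classifier = paste0(cl, "_vs_rest"),
      class_label = cl,
      edge_weights = edge_w[[cl]],
      consensus = cons,
      region_weights = region_occurrence_weights(cons, edge_map),
      fraction = fraction,
      edge_map = edge_map,
      backprojection = backprojection
    ), class = "discriminative_map")
  })
  names(out) <- classes
  out
}

#' @export
print.discriminative_map <- function(x, ...) {
  cat("<discriminative_map> ", x$classifier, ": ", nrow(x$consensus),
      " consensus edges (top ", 100 * x$fraction, "% of ",
      length(x$edge_weights), ")\n", sep = "")
  print(head(x$consensus, 5))
  invisible(x)
}

#' Consensus edges of a discriminative map as a tibble
#'
#' @param x A `discriminative_map`.
#' @param ... Unused.
#' @return The consensus edge tibble with a `classifier` column.
#' @method tidy discriminative_map
#' @export
tidy.discriminative_map <- function(x, ...) {
  dplyr::mutate(x$consensus, classifier = x$classifier)
}

#' Plot the region occurrence weights of a discriminative map
#'
#' @param object A `discriminative_map`.
#' @param top_n Number of highest-weight regions to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discriminative_map
#' @export
autoplot.discriminative_map <- function(object, top_n = 20, ...) {
  df <- object$region_weights |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::slice_max(.data$weight, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$weight,
    y = stats::reorder(.data$name, .data$weight))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "consensus-edge incidence", y = NULL,
                  title = paste("Region weights:", object$classifier)) +
    ggplot2::theme_minimal()
}

#' Convergent and divergent discriminative connection sets
#'
#' Combines the two patient-versus-rest classifiers: the convergent set
#' holds edges in both classifiers' consensus sets (connections that help
#' separate each patient group from the rest), and the divergent set holds
#' the top-fraction edges of the combined difference profile
#' `|w_A - w_B|` over the back-projected weights, excluding convergent edges
#' and exact zeros (connections that tell the two patient groups apart).
#'
#' An edge can sit in both consensus sets for two reasons: both disorders
#' shift the connection the same way (a truly convergent alteration), or the
#' connection separates the two disorders so strongly that each
#' one-versus-rest classifier uses it with opposite sign. By default the
#' convergent set therefore keeps only edges whose back-projected weights
#' agree in sign across the two classifiers; opposite-sign edges are left to
#' the divergent selection, where they belong.
#'
#' @param map_a,map_b `discriminative_map`s of the two patient classifiers,
#'   sharing one edge map.
#' @param fraction Fraction for the divergent selection (default: the maps'
#'   fraction).
#' @param convergent_rule `"intersection"` (default) or `"union"` of the two
#'   consensus sets.
#' @param divergent_rule `"difference"` (default: magnitude of the weight
#'   difference profile) or `"rank_sum"` (edges ranked most discordantly by
#'   the two classifiers, scored by absolute rank difference).
#' @param require_sign_agreement Keep only same-sign edges in the convergent
#'   set (default `TRUE`).
#' @return List with `convergent` and `divergent` tibbles (edge ids with
#'   region annotations and scores).
#' @export
convergent_divergent_sets <- function(map_a, map_b, fraction = NULL,
                                      convergent_rule = c("intersection",
                                                          "union"),
                                      divergent_rule = c("difference",
                                                         "rank_sum"),
                                      require_sign_agreement = TRUE) {
  convergent_rule <- match.arg(convergent_rule)
  divergent_rule <- match.arg(divergent_rule)
  stopifnot(inherits(map_a, "discriminative_map"),
            inherits(map_b, "discriminative_map"))
  if (!identical(dim(map_a$edge_map), dim(map_b$edge_map)) ||
      !identical(map_a$edge_map$edge, map_b$edge_map$edge)) {
    stop("the two maps use different edge maps.", call. = FALSE)
  }
  edge_map <- map_a$edge_map
  if (is.null(fraction)) fraction <- map_a$fraction
  conv_edges <- if (convergent_rule == "intersection") {
    intersect(map_a$consensus$edge, map_b$consensus$edge)
  } else {
    union(map_a$consensus$edge, map_b$consensus$edge)
  }
  if (require_sign_agreement) {
    agree <- sign(map_a$edge_weights[conv_edges]) ==
      sign(map_b$edge_weights[conv_edges])
    conv_edges <- conv_edges[agree]
  }
  conv_edges <- sort(conv_edges)

  if (divergent_rule == "difference") {
    score <- abs(map_a$edge_weights - map_b$edge_weights)
  } else {
    r_a <- rank(-abs(map_a$edge_weights), ties.method = "first")
    r_b <- rank(-abs(map_b$edge_weights), ties.method = "first")
    score <- abs(r_a - r_b)
  }
  div <- top_fraction_edges(score, fraction)
  div <- div[!(div$edge %in% conv_edges) & div$weight > 0, , drop = FALSE]
  annotate <- function(edges, scores = NULL) {
    df <- tibble::tibble(edge = edges)
    if (!is.null(scores)) df$score <- scores
    dplyr::left_join(df, dplyr::select(tibble::as_tibble(edge_map),
                                       "edge", "region_i", "region_j",
                                       "name_i", "name_j"),
                     by = "edge")
  }
  list(convergent = annotate(conv_edges),
       divergent = annotate(div$edge, div$weight))
}

#' Export a discriminative map
#'
#' Writes the consensus edge table as TSV (`edge`, region pair, `weight`,
#' `rank`, `classifier`), the region-weight table as TSV, and the full map as
#' JSON. When \pkg{igraph} is available, `write_consensus_graph()`
#' additionally exports the consensus set as a GraphML network for external
#' brain-network viewers.
#'
#' @param map A `discriminative_map`.
#' @param path Base output path (without extension).
#' @return `path`, invisibly.
#' @export
write_discriminative_map <- function(map, path) {
  edges <- tidy(map)
  write.table(as.data.frame(edges), paste0(path, "_edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(map$region_weights),
              paste0(path, "_region_weights.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(classifier = map$classifier, fraction = map$fraction,
         backprojection = map$backprojection, consensus = edges,
         region_weights = map$region_weights),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}

#' @rdname write_discriminative_map
#' @export
write_consensus_graph <- function(map, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for graph export.", call. = FALSE)
  }
  rw <- map$region_weights
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = map$consensus$name_i, to = map$consensus$name_j,
                   weight = abs(map$consensus$weight)),
    directed = FALSE,
    vertices = data.frame(name = rw$name, occurrence = rw$weight))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
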