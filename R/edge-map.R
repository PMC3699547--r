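#' Enumerate the edges of a region parcellation
#'
#' Builds the fixed upper-triangle edge enumeration used throughout the
#' package: all unordered region pairs (i, j) with i < j, in row-major order
#' (all partners of region 1 first, then region 2, ...). For the 116-region
#' whole-brain parcellation this yields the 6670 connectivity features each
#' subject contributes.
#'
#' @param n_regions Number of parcellation regions (positive integer >= 2).
#' @param region_names Optional character vector of region names, length
#'   `n_regions`. Defaults to `region_001 ... region_<n>`.
#'
#' @return A tibble of class `edge_map` with columns `edge` (1-based edge id),
#'   `region_i`, `region_j` (1-based region indices, `region_i < region_j`),
#'   `name_i` and `name_j`. The `n_regions` value is kept as an attribute.
#' @examples
#' em <- edge_index_map(4)
#' nrow(em) # 6
#' @export
edge_index_map <- function(n_regions, region_names = NULL) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 2 ||
      n_regions != round(n_regions)) {
    stop("`n_regions` must be a single integer >= 2.", call. = FALSE)
  }
  n_regions <- as.integer(n_regions)
  if (is.null(region_names)) {
    region_names <- sprintf("region_%03d", seq_len(n_regions))
  }
  if (length(region_names) != n_regions) {
    stop("`region_names` must have length `n_regions`.", call. = FALSE)
  }
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(k) (k + 1L):n_regions),
              use.names = FALSE)
  out <- tibble::tibble(
    edge = seq_along(i),
    region_i = i,
    region_j = j,
    name_i = region_names[i],
    name_j = region_names[j]
  )
  attr(out, "n_regions") <- n_regions
  class(out) <- c("edge_map", class(out))
  out
}

#' Synthetic 116-region name lookup
#'
#' Returns the bundled synthetic naming scheme for a 116-region whole-brain
#' parcellation (90 cerebral + 26 cerebellar/vermis labels). The names are a
#' stand-in invented for this package — they follow the usual
#' lobe/hemisphere convention but are not the labels of any published atlas,
#' which cannot be redistributed here.
#'
#' @return A character vector of 116 region names, ordered by atlas label.
#' @export
synthetic_region_names <- function() {
  path <- system.file("extdata", "synthetic_region_names_116.tsv",
                      package = "idaconn", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)$name
}

n_edges <- function(edge_map) nrow(edge_map)

edge_map_regions <- function(edge_map) attr(edge_map, "n_regions")

#' Vectorize the upper triangle of a symmetric matrix along an edge map
#'
#' @param m A square symmetric matrix with one row/column per region.
#' @param edge_map An [edge_index_map()] for the same number of regions.
#' @return Numeric vector of length `nrow(edge_map)`.
#' @export
edge_vectorize <- function(m, edge_map) {
  p <- edge_map_regions(edge_map)
  if (!is.matrix(m) || nrow(m) != p || ncol(m) != p) {
    stop("`m` must be a ", p, "x", p, " matrix matching the edge map.",
         call. = FALSE)
  }
  m[cbind(edge_map$region_i, edge_map$region_j)]
}

#' Rebuild a symmetric region-by-region matrix from an edge vector
#'
#' Inverse of [edge_vectorize()]; the diagonal is set to `diag`.
#'
#' @param v Numeric vector of length `nrow(edge_map)`.
#' @param edge_map An [edge_index_map()].
#' @param diag Diagonal value (default 1, a self-correlation).
#' @return A symmetric matrix.
#' @export
edge_unvectorize <- function(v, edge_map, diag = 1) {
  p <- edge_map_regions(edge_map)
  if (length(v) != n_edges(edge_map)) {
    stop("`v` must have length ", n_edges(edge_map), ".", call. = FALSE)
  }
  m <- matrix(diag, p, p)
  m[cbind(edge_map$region_i, edge_map$region_j)] <- v
  m[cbind(edge_map$region_j, edge_map$region_i)] <- v
  m
}
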