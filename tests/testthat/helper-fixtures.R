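# Shared fixtures: everything is generated in code at test time.

# Small labeled sample matrix (features x samples) with class mean offsets.
make_labeled_data <- function(p = 10, n_per_class = c(a = 6, b = 5, c = 4),
                              offset = 2, noise = 1, seed = 100) {
  set.seed(seed)
  classes <- names(n_per_class)
  X <- do.call(cbind, lapply(seq_along(classes), function(k) {
    mu <- rnorm(p, sd = offset)
    matrix(rnorm(p * n_per_class[k], sd = noise), p) + mu
  }))
  list(X = X, y = rep(classes, times = n_per_class))
}

# Tiny simulated cohort -> connectivity dataset, defaults scaled down.
make_small_dataset <- function(n_per_class = c(a = 8, b = 8, c = 8),
                               n_regions = 20, n_volumes = 100,
                               perturbed = NULL, seed = 5, ...) {
  cfg <- sim_config(n_subjects_per_class = n_per_class,
                    n_regions = n_regions, n_volumes = n_volumes,
                    perturbed_edges = perturbed, seed = seed, ...)
  connectivity_dataset(simulate_subjects(cfg))
}

# The reference planted-effect design: 10 shared patient edges plus 10
# disorder-specific edges per patient class, all at the same delta.
planted_design <- function(delta = 0.4) {
  dplyr::bind_rows(
    tibble::tibble(class = "mdd", region_i = 1:10, region_j = 11:20,
                   delta = delta),
    tibble::tibble(class = "scz", region_i = 1:10, region_j = 11:20,
                   delta = delta),
    tibble::tibble(class = "mdd", region_i = 21:30, region_j = 31:40,
                   delta = delta),
    tibble::tibble(class = "scz", region_i = 41:50, region_j = 51:60,
                   delta = delta))
}

planted_edge_ids <- function(edge_map) {
  eid <- function(i, j) {
    edge_map$edge[edge_map$region_i == i & edge_map$region_j == j]
  }
  list(shared = mapply(eid, 1:10, 11:20),
       mdd = mapply(eid, 21:30, 31:40),
       scz = mapply(eid, 41:50, 51:60))
}

# Brute-force between/within scatter matrices by explicit double loops.
scatter_oracle <- function(X, y) {
  classes <- unique(y)
  m <- rowMeans(X)
  Sb <- matrix(0, nrow(X), nrow(X))
  Sw <- matrix(0, nrow(X), nrow(X))
  for (cl in classes) {
    Xc <- X[, y == cl, drop = FALSE]
    mi <- rowMeans(Xc)
    Sb <- Sb + ncol(Xc) * tcrossprod(mi - m)
    for (j in seq_len(ncol(Xc))) Sw <- Sw + tcrossprod(Xc[, j] - mi)
  }
  list(between = Sb, within = Sw)
}

# Trace-ratio objective tr(W' S_cc W) / tr(W' (S_ind + eps I) W).
trace_ratio <- function(W, Sb, Sw, eps) {
  sum(diag(crossprod(W, Sb %*% W))) /
    sum(diag(crossprod(W, (Sw + eps * diag(nrow(Sw))) %*% W)))
}
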