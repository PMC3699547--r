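test_that("class statistics reproduce between/within scatter (loop oracle)", {
  dat <- make_labeled_data(p = 10, n_per_class = c(a = 12, b = 10, c = 8))
  st <- class_statistics(dat$X, dat$y)
  oracle <- scatter_oracle(dat$X, dat$y)
  expect_equal(tcrossprod(st$H_cc), oracle$between, tolerance = 1e-10)
  expect_equal(tcrossprod(st$H_ind), oracle$within, tolerance = 1e-10)
  expect_equal(ncol(st$H_ind), ncol(dat$X))
  expect_equal(ncol(st$H_cc), 3L)
  # size-weighted class-mean deviations cancel
  dev <- sweep(st$class_means - st$global_mean, 2,
               st$n_per_class[colnames(st$class_means)], `*`)
  expect_lt(max(abs(rowSums(dev))), 1e-10)
})

test_that("degenerate class layouts behave as stated", {
  X <- matrix(rnorm(20), 4)
  st <- class_statistics(X, rep("only", 5))
  expect_equal(st$class_means[, 1], st$global_mean)
  expect_lt(max(abs(st$H_cc)), 1e-12)

  # two singleton classes in 2-D: hand-computed means, zero H_ind
  X2 <- cbind(c(0, 0), c(2, 0))
  expect_warning(st2 <- class_statistics(X2, c("a", "b")), "single sample")
  expect_equal(st2$global_mean, c(1, 0))
  expect_equal(unname(st2$H_cc), cbind(c(-1, 0), c(1, 0)))
  expect_lt(max(abs(st2$H_ind)), 1e-12)
})

test_that("intrinsic components reconstruct the sample exactly", {
  dat <- make_labeled_data(p = 15, n_per_class = c(a = 5, b = 7))
  x <- dat$X[, 9]
  dec <- intrinsic_decompose(x, dat$X, dat$y, dat$y[9])
  expect_equal(dec$common + dec$class_common + dec$individual, x,
               tolerance = 1e-12)
  st <- class_statistics(dat$X, dat$y)
  expect_equal(dec$common, st$global_mean)
  expect_equal(dec$class_common,
               st$class_means[, dat$y[9]] - st$global_mean)
  # a sample equal to its class mean has zero individual part
  cm <- st$class_means[, "a"]
  Xa <- dat$X
  Xa[, 1] <- cm
  deca <- intrinsic_decompose(cm, Xa, dat$y, "a")
  sta <- class_statistics(Xa, dat$y)
  expect_equal(deca$individual, cm - sta$class_means[, "a"],
               tolerance = 1e-12)
  expect_error(intrinsic_decompose(x, dat$X, dat$y, "nope"), "unknown class")
})

test_that("fitted eigenpairs satisfy the perturbed generalized eigen-equation", {
  dat <- make_labeled_data(p = 40, n_per_class = c(a = 8, b = 8, c = 8))
  fit <- fit_ida(dat$X, dat$y, d = 5)
  expect_lt(max(ida_eigen_residual(fit, dat$X, dat$y)), 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))
  expect_equal(colSums(fit$W^2), rep(1, 5), tolerance = 1e-10)
})

test_that("span solver agrees with a dense generalized eigensolver", {
  dat <- make_labeled_data(p = 60, n_per_class = c(a = 10, b = 9, c = 7))
  eps <- 0.5
  fit <- fit_ida(dat$X, dat$y, d = 4, epsilon = eps)
  st <- class_statistics(dat$X, dat$y)
  Sb <- tcrossprod(st$H_cc)
  Sw <- tcrossprod(st$H_ind) + eps * diag(60)
  # dense oracle via the symmetric whitened problem
  ew <- eigen(Sw, symmetric = TRUE)
  Whalf <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  ed <- eigen(Whalf %*% Sb %*% Whalf, symmetric = TRUE)
  expect_equal(fit$eigenvalues, ed$values[1:4], tolerance = 1e-6)
  dense_W <- Whalf %*% ed$vectors[, 1:4]
  for (k in 1:2) {   # compare the well-separated leading eigenvectors
    a <- fit$W[, k]
    b <- dense_W[, k] / sqrt(sum(dense_W[, k]^2))
    expect_gt(abs(sum(a * b)), 1 - 1e-6)
  }
})

test_that("two separated classes recover the discriminative axis", {
  # class means differ along axis 1; within-class noise only along axis 2
  set.seed(11)
  n <- 30
  X <- rbind(c(rep(-2, n), rep(2, n)), rnorm(2 * n, sd = 1))
  y <- rep(c("a", "b"), each = n)
  fit <- fit_ida(X, y, d = 1)
  expect_gt(abs(fit$W[1, 1]) / sqrt(sum(fit$W[, 1]^2)), 0.99)

  # oracle: brute-force maximization of the trace-ratio objective over a
  # 1-degree angular grid
  st <- class_statistics(X, y)
  Sb <- tcrossprod(st$H_cc)
  Sw <- tcrossprod(st$H_ind)
  angles <- seq(0, 179) * pi / 180
  obj <- vapply(angles, function(a) {
    trace_ratio(cbind(c(cos(a), sin(a))), Sb, Sw, fit$epsilon)
  }, 0)
  best <- c(cos(angles[which.max(obj)]), sin(angles[which.max(obj)]))
  expect_gt(abs(sum(fit$W[, 1] * best)), 0.99)
})

test_that("zero individual scatter gives eigenvalues scaled by 1/epsilon", {
  # every sample equals its class mean
  means <- cbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  X <- means[, rep(1:3, each = 4)]
  y <- rep(c("a", "b", "c"), each = 4)
  eps <- 0.01
  fit <- fit_ida(X, y, d = 2, epsilon = eps)
  st <- class_statistics(X, y)
  ecc <- eigen(tcrossprod(st$H_cc), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$eigenvalues, ecc[1:2] / eps, tolerance = 1e-8)
})

test_that("fitted projection beats random projections on the trace ratio", {
  dat <- make_labeled_data(p = 50, n_per_class = c(a = 10, b = 10, c = 10),
                           offset = 1.2)
  fit <- fit_ida(dat$X, dat$y, d = 2)
  st <- class_statistics(dat$X, dat$y)
  Sb <- tcrossprod(st$H_cc)
  Sw <- tcrossprod(st$H_ind)
  obj_fit <- trace_ratio(fit$W, Sb, Sw, fit$epsilon)
  set.seed(42)
  best_rand <- max(vapply(seq_len(1000), function(i) {
    trace_ratio(qr.Q(qr(matrix(rnorm(50 * 2), 50))), Sb, Sw, fit$epsilon)
  }, 0))
  expect_gte(obj_fit, best_rand)
})

test_that("model is invariant to constant shifts and within-class relabeling", {
  dat <- make_labeled_data(p = 12, n_per_class = c(a = 6, b = 6))
  fit <- fit_ida(dat$X, dat$y, d = 2, epsilon = 0.1)
  fit_shift <- fit_ida(dat$X + 3.7, dat$y, d = 2, epsilon = 0.1)
  expect_equal(fit$W, fit_shift$W, tolerance = 1e-8)
  expect_equal(fit$eigenvalues, fit_shift$eigenvalues, tolerance = 1e-8)

  # permuting samples within a class leaves the model unchanged
  perm <- c(sample(1:6), sample(7:12))
  fit_perm <- fit_ida(dat$X[, perm], dat$y[perm], d = 2, epsilon = 0.1)
  expect_equal(fit$W, fit_perm$W, tolerance = 1e-8)
})

test_that("large epsilon drives the solution to the class-common eigenvectors", {
  dat <- make_labeled_data(p = 20, n_per_class = c(a = 8, b = 8, c = 8))
  st <- class_statistics(dat$X, dat$y)
  Sb <- tcrossprod(st$H_cc)
  big_eps <- 1e6 * sum(diag(tcrossprod(st$H_ind)))
  fit <- fit_ida(dat$X, dat$y, d = 2, epsilon = big_eps)
  eb <- eigen(Sb, symmetric = TRUE)
  for (k in 1:2) {
    expect_gt(abs(sum(fit$W[, k] * eb$vectors[, k])), 0.999)
  }
})

test_that("dimension and epsilon bounds are enforced", {
  dat <- make_labeled_data(p = 10, n_per_class = c(a = 4, b = 4))
  expect_error(fit_ida(dat$X, dat$y, d = 8), "N - 1")
  expect_error(fit_ida(dat$X, dat$y, d = 2, epsilon = -1), "positive")
  expect_error(fit_ida(dat$X, dat$y, d = 0), "N - 1")
  expect_identical(max_embedding_dimension(89), 88L)
  expect_identical(max_embedding_dimension(89, per_fold = TRUE), 87L)
})

test_that("transform is the linear map t(W) X", {
  dat <- make_labeled_data(p = 20, n_per_class = c(a = 6, b = 6))
  fit <- fit_ida(dat$X, dat$y, d = 3)
  M <- matrix(rnorm(20 * 7), 20)
  Z <- ida_transform(fit, M)
  oracle <- matrix(0, 3, 7)
  for (i in 1:3) for (j in 1:7) oracle[i, j] <- sum(fit$W[, i] * M[, j])
  expect_equal(Z, oracle, tolerance = 1e-12)
  # linearity
  A <- matrix(rnorm(20 * 4), 20); B <- matrix(rnorm(20 * 4), 20)
  expect_equal(ida_transform(fit, 2 * A - 3 * B),
               2 * ida_transform(fit, A) - 3 * ida_transform(fit, B),
               tolerance = 1e-10)
  expect_equal(ida_transform(fit, matrix(0, 20, 2)), matrix(0, 3, 2))
  expect_error(ida_transform(fit, matrix(0, 19, 2)), "dimension")
})

test_that("intrinsicconnectome export indexes edges correctly", {
  ds <- make_small_dataset(n_per_class = c(a = 5, b = 5), n_regions = 8,
                           n_volumes = 60)
  fit <- fit_ida(t(ds$features), ds$labels, d = 3)
  ic <- intrinsicconnectomes(fit, ds$edge_map)
  expect_equal(nrow(ic), 3 * 28)
  for (k in 1:3) {
    lk <- ic$loading[ic$pattern == k]
    expect_equal(lk, fit$W[, k] / sqrt(sum(fit$W[, k]^2)), tolerance = 1e-12)
    expect_equal(sum(lk^2), 1, tolerance = 1e-10)
  }
  expect_error(intrinsicconnectomes(fit, edge_index_map(5)), "edge map")
})

test_that("model archive round-trips exactly", {
  dat <- make_labeled_data(p = 14, n_per_class = c(a = 5, b = 5))
  fit <- fit_ida(dat$X, dat$y, d = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  write_ida_model(fit, path)
  back <- read_ida_model(path)
  expect_identical(back$W, fit$W)
  expect_identical(back$eigenvalues, fit$eigenvalues)
  expect_identical(back$epsilon, fit$epsilon)
  expect_identical(class(back), "ida_model")
})

test_that("tidy and glance summarize the fitted model", {
  dat <- make_labeled_data(p = 10, n_per_class = c(a = 5, b = 5, c = 5))
  fit <- fit_ida(dat$X, dat$y, d = 2)
  td <- tidy(fit)
  expect_equal(td$eigenvalue, fit$eigenvalues)
  expect_equal(sum(td$share), 1)
  gl <- glance(fit)
  expect_equal(gl$n_features, 10L)
  expect_equal(gl$n_classes, 3L)
})
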