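test_that("regional extraction averages voxels per label", {
  # single label covering everything: row equals the volume-wise constants
  dims <- c(3, 3, 2)
  n_t <- 6
  cvals <- seq_len(n_t) * 1.5
  vol <- array(rep(cvals, each = prod(dims)), c(dims, n_t))
  atlas <- array(1L, dims)
  out <- extract_regional_timeseries(vol, atlas)
  expect_equal(dim(out), c(1L, n_t))
  expect_equal(unname(out[1, ]), cvals)

  # two single-voxel labels reproduce those voxels' series verbatim
  set.seed(2)
  vol2 <- array(rnorm(prod(dims) * n_t), c(dims, n_t))
  atlas2 <- array(0L, dims)
  atlas2[1, 1, 1] <- 1L
  atlas2[3, 2, 2] <- 2L
  out2 <- extract_regional_timeseries(vol2, atlas2)
  expect_equal(unname(out2[1, ]), vol2[1, 1, 1, ])
  expect_equal(unname(out2[2, ]), vol2[3, 2, 2, ])
})

test_that("regional extraction matches a per-label loop oracle", {
  set.seed(3)
  vol <- array(rnorm(6 * 6 * 4 * 20), c(6, 6, 4, 20))
  atlas <- array(sample(0:3, 6 * 6 * 4, replace = TRUE), c(6, 6, 4))
  out <- extract_regional_timeseries(vol, atlas)
  for (lab in 1:3) {
    oracle <- sapply(1:20, function(t) {
      vals <- c()
      for (i in 1:6) for (j in 1:6) for (k in 1:4) {
        if (atlas[i, j, k] == lab) vals <- c(vals, vol[i, j, k, t])
      }
      mean(vals)
    })
    expect_equal(unname(out[lab, ]), oracle, tolerance = 1e-12)
  }
  expect_error(
    extract_regional_timeseries(vol, array(c(2L, rep(0L, 143)), c(6, 6, 4))),
    "label 1 covers zero voxels")
})

test_that("band-pass removes DC and matches its analytic frequency response", {
  n_t <- 600
  tr <- 2
  t_sec <- (seq_len(n_t) - 1) * tr
  trim <- 51:(n_t - 50)   # drop forward-backward edge transients

  # constant row: pure DC lies outside the passband
  dc <- bandpass_filter(matrix(5, 1, n_t), 0.01, 0.08, tr)
  expect_lt(max(abs(dc[1, trim])), 1e-6)

  amp_of <- function(x, f) {
    fit <- lm(x[trim] ~ sin(2 * pi * f * t_sec[trim]) +
                cos(2 * pi * f * t_sec[trim]))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  # in-band 0.04 Hz sinusoid passes within the design ripple
  x_in <- sin(2 * pi * 0.04 * t_sec)
  y_in <- bandpass_filter(matrix(x_in, 1), 0.01, 0.08, tr)[1, ]
  gain_in <- amp_of(y_in, 0.04) / amp_of(x_in, 0.04)
  oracle_in <- bandpass_response(0.04, 0.01, 0.08, tr)
  expect_equal(gain_in, oracle_in, tolerance = 0.02)
  # zero-phase squared response: ripple at most twice 0.5 dB
  expect_gte(gain_in, 10^(-1 / 20))
  expect_lte(gain_in, 1.01)

  # out-of-band 0.2 Hz sinusoid is strongly attenuated
  x_out <- sin(2 * pi * 0.2 * t_sec)
  y_out <- bandpass_filter(matrix(x_out, 1), 0.01, 0.08, tr)[1, ]
  gain_out <- amp_of(y_out, 0.2) / amp_of(x_out, 0.2)
  oracle_out <- bandpass_response(0.2, 0.01, 0.08, tr)
  expect_lte(gain_out, 10^(-20 / 20))
  expect_equal(gain_out, oracle_out, tolerance = 0.1 * oracle_out + 1e-6)

  expect_error(bandpass_filter(matrix(0, 1, 100), 0.01, 0.3, tr), "Nyquist")
})

test_that("nuisance regression projects exactly onto the design complement", {
  set.seed(4)
  n_t <- 200
  gs <- rnorm(n_t)
  motion <- matrix(rnorm(6 * n_t), 6)

  # a row equal to the global signal vanishes
  out <- regress_nuisance(matrix(gs, 1), global_signal = gs, motion = motion)
  expect_lt(max(abs(out)), 1e-10)

  # a mean-zero row orthogonal to all regressors is unchanged
  design <- cbind(1, gs, t(motion))
  raw <- rnorm(n_t)
  ortho <- drop(qr.resid(qr(design), raw))
  out2 <- regress_nuisance(matrix(ortho, 1), global_signal = gs,
                           motion = motion)
  expect_equal(out2[1, ], ortho, tolerance = 1e-10)

  # random multi-row case matches an explicit normal-equations solve
  ts <- matrix(rnorm(5 * n_t), 5)
  res <- regress_nuisance(ts, global_signal = gs, motion = motion)
  beta <- solve(crossprod(design), crossprod(design, t(ts)))
  oracle <- t(t(ts) - design %*% beta)
  expect_equal(res, oracle, tolerance = 1e-9)
  # residual orthogonality to every design column
  expect_lt(max(abs(res %*% design)), 1e-8 * max(abs(ts)) * sqrt(n_t))

  expect_error(regress_nuisance(ts, global_signal = rep(1, n_t)),
               "collinear")
})

test_that("connectivity vector is the upper-triangle Pearson correlation", {
  em <- edge_index_map(2)
  expect_equal(connectivity_vector(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8)), em), 1)
  expect_equal(connectivity_vector(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)), em), -1)

  set.seed(5)
  em5 <- edge_index_map(5)
  ts <- matrix(rnorm(5 * 50), 5)
  v <- connectivity_vector(ts, em5)
  oracle <- vapply(seq_len(nrow(em5)), function(k) {
    a <- ts[em5$region_i[k], ]; b <- ts[em5$region_j[k], ]
    sum((a - mean(a)) * (b - mean(b))) /
      (sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2)))
  }, 0)
  expect_equal(v, oracle, tolerance = 1e-12)

  # shift invariance
  ts2 <- ts
  ts2[3, ] <- ts2[3, ] + 100
  expect_equal(connectivity_vector(ts2, em5), v, tolerance = 1e-10)

  ts_bad <- ts
  ts_bad[2, ] <- 7
  expect_error(connectivity_vector(ts_bad, em5), "zero-variance region")
})

test_that("a 116-region time series yields the 6670-edge feature vector", {
  set.seed(6)
  em <- edge_index_map(116)
  ts <- matrix(rnorm(116 * 40), 116)
  v <- connectivity_vector(ts, em)
  expect_length(v, 6670L)
  expect_true(all(abs(v) <= 1))
})

test_that("dataset assembly runs filter -> regression -> correlation and the
           global-signal toggle changes only that design column", {
  cfg <- sim_config(n_subjects_per_class = c(a = 3, b = 3), n_regions = 10,
                    n_volumes = 80, seed = 8)
  subs <- simulate_subjects(cfg)
  ds <- connectivity_dataset(subs)
  expect_equal(dim(ds$features), c(6L, 45L))
  expect_true(all(abs(ds$features) <= 1))

  # manual reproduction of one subject's chain (discard 5, filter, regress)
  s <- subs[[1]]
  ts <- s$timeseries[, -(1:5)]
  mo <- s$motion[, -(1:5)]
  ts_f <- bandpass_filter(ts, 0.01, 0.08, 2)
  ts_r <- regress_nuisance(ts_f, global_signal = colMeans(ts_f), motion = mo)
  expect_equal(ds$features[1, ],
               connectivity_vector(ts_r, ds$edge_map), tolerance = 1e-10)

  # disabling global-signal regression only drops that regressor
  ds_nogs <- connectivity_dataset(subs, global_signal_regression = FALSE)
  ts_r2 <- regress_nuisance(ts_f, global_signal = NULL, motion = mo)
  expect_equal(ds_nogs$features[1, ],
               connectivity_vector(ts_r2, ds$edge_map), tolerance = 1e-10)

  # order knob: regression before filtering
  ds_swap <- connectivity_dataset(subs, filter_first = FALSE)
  ts_r3 <- regress_nuisance(ts, global_signal = colMeans(ts), motion = mo)
  ts_f3 <- bandpass_filter(ts_r3, 0.01, 0.08, 2)
  expect_equal(ds_swap$features[1, ],
               connectivity_vector(ts_f3, ds$edge_map), tolerance = 1e-10)
})

test_that("connectivity dataset TSV round-trip is faithful", {
  ds <- make_small_dataset(n_per_class = c(a = 2, b = 2), n_regions = 8,
                           n_volumes = 40)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_dataset(ds, path)
  back <- read_connectivity_dataset(path)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
  expect_equal(back$edge_map$edge, ds$edge_map$edge)
})

test_that("tidy() gives one row per subject-edge pair", {
  ds <- make_small_dataset(n_per_class = c(a = 2, b = 2), n_regions = 6,
                           n_volumes = 40)
  td <- tidy(ds)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4 * 15)
  expect_named(td, c("subject_id", "label", "edge", "name_i", "name_j",
                     "correlation"))
})

test_that("NIfTI volume + label pair round-trips through the reader", {
  skip_if_not_installed("RNifti")
  dims <- c(5, 5, 3)
  n_t <- 10
  set.seed(9)
  vol <- array(rnorm(prod(dims) * n_t), c(dims, n_t))
  atlas <- array(sample(0:2, prod(dims), replace = TRUE), dims)
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "func.nii.gz")
  ap <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), vp)
  RNifti::writeNifti(RNifti::asNifti(atlas), ap)
  ts <- read_nifti_timeseries(vp, ap)
  expect_equal(unname(ts), unname(extract_regional_timeseries(vol, atlas)),
               tolerance = 1e-6)
})

test_that("the synthetic region-name lookup covers all 116 labels", {
  nm <- synthetic_region_names()
  expect_length(nm, 116L)
  expect_equal(anyDuplicated(nm), 0L)
  em <- edge_index_map(116, nm)
  expect_equal(nrow(em), 6670L)
})
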