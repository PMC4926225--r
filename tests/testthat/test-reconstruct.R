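test_that("ideal chain inverts exactly; delta scenes expose single patterns", {
  scn <- random_scene(8, 71)
  rec <- simulate_acquisition(scn, basis8)
  out <- inverse_transform(rec, basis8)
  expect_equal(out$image, scn$frames[[1]], tolerance = 1e-12)
  expect_gt(corr2(out$image, scn$frames[[1]]), 1 - 1e-12)

  # one bright pixel: every coefficient is that pixel's pattern value
  delta <- matrix(0, 8, 8); delta[3, 5] <- 1
  rec_d <- simulate_acquisition(scene(delta), basis8,
                                illum = illumination_model(p0 = 2))
  vals <- vapply(seq_len(64), function(i) 2 * basis_function(basis8, i)[3, 5],
                 numeric(1))
  expect_equal(rec_d$coefficients, vals, tolerance = 1e-12)

  ss <- select_low_sequency_subset(basis8, 0.5)
  rec_u <- simulate_acquisition(scn, basis8, ss)
  expect_error(inverse_transform(rec_u, basis8), "zero_fill")
})

test_that("gain and illumination scaling are undone before synthesis", {
  scn <- random_scene(8, 72)
  rec <- simulate_acquisition(scn, basis8,
                              illum = illumination_model(p0 = 3.2),
                              det = detection_config(gain = 0.45))
  expect_equal(inverse_transform(rec, basis8)$image, scn$frames[[1]],
               tolerance = 1e-10)
})

test_that("zero-fill: full-subset limit, DC-only mean, partial credit in between", {
  scn <- random_scene(8, 81)
  full <- simulate_acquisition(scn, basis8)
  expect_equal(zero_fill_reconstruct(full, basis8)$image,
               inverse_transform(full, basis8)$image, tolerance = 1e-12)

  dc_only <- structure(list(indices = 1L, ratio = 1 / 64, size = 8L),
                       class = "pattern_subset")
  rec_dc <- simulate_acquisition(scn, basis8, dc_only)
  img <- zero_fill_reconstruct(rec_dc, basis8)$image
  expect_equal(img, matrix(mean(scn$frames[[1]]), 8, 8), tolerance = 1e-12)

  # a 20% low-sequency acquisition of a disc scene: imperfect, but the
  # min-TV recovery beats plain zero filling
  X <- disc32$frames[[1]]
  ss <- select_low_sequency_subset(basis32, 0.2)
  rec <- simulate_acquisition(disc32, basis32, ss)
  zf <- corr2(zero_fill_reconstruct(rec, basis32)$image, X)
  mt <- corr2(min_tv_reconstruct(rec, sensing_operator(basis32, ss))$image, X)
  expect_gt(zf, 0); expect_lt(zf, 1)
  expect_gt(mt, zf)
})

test_that("min-TV solver: degenerate and limit cases", {
  # zero measurements -> zero image (TV and constraints both minimal)
  ss <- select_low_sequency_subset(basis8, 0.25)
  rec0 <- simulate_acquisition(scene(matrix(0, 8, 8)), basis8, ss)
  out0 <- min_tv_reconstruct(rec0, sensing_operator(basis8, ss))
  expect_equal(out0$image, matrix(0, 8, 8))
  expect_equal(out0$objective, 0)

  # full sampling: the constraint set is a single point = inverse transform
  scn <- random_scene(8, 91)
  full <- simulate_acquisition(scn, basis8)
  mt <- min_tv_reconstruct(full, sensing_operator(basis8, full_subset(basis8)))
  expect_gt(corr2(mt$image, inverse_transform(full, basis8)$image), 1 - 1e-6)
  expect_lte(mt$residual, 1e-6 * sqrt(sum(signed_coefficients(full)^2)))

  # operator/record mismatch is refused
  other <- sensing_operator(basis8, select_low_sequency_subset(basis8, 0.5))
  expect_error(min_tv_reconstruct(rec0, other), "does not match")
})

test_that("min-TV reconstructions are feasible, deterministic and flagged honestly", {
  X <- bars32$frames[[1]]
  ss <- select_low_sequency_subset(basis32, 0.2)
  rec <- simulate_acquisition(bars32, basis32, ss)
  op <- sensing_operator(basis32, ss)
  a <- min_tv_reconstruct(rec, op)
  b <- min_tv_reconstruct(rec, op)
  expect_identical(a$image, b$image)                      # deterministic
  expect_lte(a$residual, 1e-6 * sqrt(sum(signed_coefficients(rec)^2)))
  expect_true(a$converged)
  # near-optimal at the default stopping rule: the truth is feasible, so the
  # minimized TV cannot meaningfully exceed the truth's TV
  expect_lte(a$objective, total_variation(X) * (1 + 1e-3))

  starved <- min_tv_reconstruct(rec, op, tv_params(1e-12, max_iter = 5))
  expect_false(starved$converged)                          # flagged, not silent
  expect_identical(starved$iterations, 5L)

  # relaxed constraints: the residual honours epsilon
  relaxed <- min_tv_reconstruct(rec, op, tv_params(epsilon = 2))
  expect_lte(relaxed$residual, 2 + 1e-9)
  expect_lte(relaxed$objective, a$objective + 1e-9)        # larger feasible set
})

test_that("min-TV optimum matches an independent LP solve on tiny instances", {
  b8 <- basis8
  ss <- select_low_sequency_subset(b8, 0.25)   # M = 16 of N = 64
  ops <- dense_operators(b8, ss)
  for (seed in c(1, 2)) {
    set.seed(seed)
    X <- matrix(0, 8, 8)
    X[3:6, 2:4] <- 1                      # piecewise-constant block
    if (seed == 2) X[1:2, 6:8] <- 0.5
    rec <- simulate_acquisition(scene(X), b8, ss)
    mine <- min_tv_reconstruct(rec, sensing_operator(b8, ss),
                               tv_params(1e-10, 20000))
    y <- signed_coefficients(rec)
    expect_equal(as.vector(ops$Phi %*% as.vector(mine$image)), y,
                 tolerance = 1e-8)
    oracle_obj <- tv_lp_oracle(ops$Phi, ops$Dh, ops$Dv, y)
    expect_equal(mine$objective, oracle_obj,
                 tolerance = 1e-4 * max(abs(oracle_obj), 1))
  }
})

test_that("display normalization: linear stretch, fixed points, constant convention", {
  expect_identical(normalize_display(matrix(c(0, 1, 0.5, 0.25), 2, 2, byrow = TRUE)),
                   matrix(c(0L, 255L, 128L, 64L), 2, 2, byrow = TRUE))
  already <- matrix(as.numeric(0:255), 16, 16)
  expect_identical(normalize_display(already), matrix(0:255, 16, 16))
  expect_identical(normalize_display(matrix(7, 3, 3)), matrix(0L, 3, 3))
})

test_that("reconstruction files: display PNG, float TIFF, diagnostics log", {
  dir <- withr::local_tempdir()
  scn <- random_scene(8, 101)
  rec <- simulate_acquisition(scn, basis8)
  res <- inverse_transform(rec, basis8)
  write_reconstruction(res, file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out.png")))
  expect_true(file.exists(file.path(dir, "out.tif")))
  log <- yaml::read_yaml(file.path(dir, "out_log.yaml"))
  expect_identical(log$method, "inverse")
  tif <- tiff::readTIFF(file.path(dir, "out.tif"))
  expect_equal(tif, res$image, tolerance = 1e-6)
})
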