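test_that("project is the masked flux sum", {
  expect_equal(project(matrix(1, 4, 4), shift_rescale(basis8, 1)[1:4, 1:4]), 16)
  expect_equal(project(matrix(c(1, 3, 2, 4), 2, 2), diag(2)), 5)
  expect_equal(project(matrix(runif(16), 4, 4), matrix(0, 4, 4)), 0)
  expect_equal(project(matrix(1, 2, 2), diag(2), p0 = 2.5), 5)
  expect_error(project(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("noiseless balanced coefficients equal direct signed projections", {
  scn <- random_scene(8, 11)
  X <- scn$frames[[1]]
  p0 <- 1.7
  rec <- simulate_acquisition(scn, basis8,
                              illum = illumination_model(p0 = p0))
  direct <- vapply(seq_len(64), function(i)
    p0 * sum(X * basis_function(basis8, i)), numeric(1))
  expect_equal(rec$coefficients, direct, tolerance = 1e-12)
})

test_that("balanced detection cancels homogeneous parasite light on non-DC patterns", {
  dark <- scene(matrix(0, 8, 8))
  il <- illumination_model(p0 = 0, parasite_baseline = 3, ripple_amplitude = 2)
  rec <- simulate_acquisition(dark, basis8, illum = il)
  expect_identical(max(abs(rec$coefficients[-1])), 0)

  # property: non-DC balanced coefficients are independent of every
  # parasite parameter, exactly, for arbitrary scenes
  scn <- random_scene(8, 21)
  base <- simulate_acquisition(scn, basis8)$coefficients
  set.seed(99)
  for (k in 1:5) {
    amp <- runif(1, 0, 2)
    il <- illumination_model(1, parasite_baseline = amp + runif(1, 0, 3),
                             ripple_amplitude = amp,
                             ripple_phase = runif(1, 0, 2 * pi))
    got <- simulate_acquisition(scn, basis8, illum = il)$coefficients
    expect_equal(got[-1], base[-1], tolerance = 1e-12)
  }
})

test_that("single-detector coefficients carry the analytic parasite term", {
  scn <- random_scene(4, 5)
  b4 <- build_basis_2d(4)
  il <- illumination_model(1, parasite_baseline = 1, ripple_amplitude = 0.5)
  acq <- acquisition_config(samples_per_pattern = 4)
  rec_s <- simulate_acquisition(scn, b4, illum = il,
                                det = detection_config("single"), acq = acq)
  # recompute the expected mean parasite flux per pattern from the sample
  # midpoints the acquisition clock defines
  spp <- acq$samples_per_pattern
  for (m in seq_along(rec_s$indices)) {
    i <- rec_s$indices[m]
    tt <- (m - 1 + (seq_len(spp) - 0.5) / spp) / acq$pattern_rate
    open <- sum(complementary_pair(b4, i)$plus)
    parasite <- mean(1 + 0.5 * sin(2 * pi * 100 * tt)) * open
    obj <- sum(scn$frames[[1]] * complementary_pair(b4, i)$plus)
    expect_equal(rec_s$coefficients[m], obj + parasite, tolerance = 1e-10)
  }
})

test_that("energy accounting: the two arms share the total collected flux", {
  scn <- random_scene(8, 31)
  il <- illumination_model(1.3, parasite_baseline = 0.7, ripple_amplitude = 0.2)
  rec <- simulate_acquisition(scn, basis8, illum = il)
  spp <- rec$acq$samples_per_pattern
  for (m in c(1, 2, 30, 64)) {
    tt <- (m - 1 + (seq_len(spp) - 0.5) / spp) / rec$acq$pattern_rate
    total <- 1.3 * sum(scn$frames[[1]]) +
      mean(0.7 + 0.2 * sin(2 * pi * 100 * tt)) * 64
    expect_equal(rec$arm_plus[m] + rec$arm_minus[m], total, tolerance = 1e-10)
  }
})

test_that("static-scene mode equivalence and fixed-seed determinism", {
  scn <- random_scene(8, 41)
  bal <- simulate_acquisition(scn, basis8)
  seq_rec <- simulate_acquisition(scn, basis8,
                                  det = detection_config("sequential_complementary"))
  expect_equal(seq_rec$coefficients, bal$coefficients, tolerance = 1e-12)
  # sequential consumes two pattern slots per coefficient
  expect_equal(nrow(seq_rec$time_trace), 2 * nrow(bal$time_trace))
  expect_true(all(diff(seq_rec$timestamps) > 0))

  noisy <- function() simulate_acquisition(
    scn, basis8, det = detection_config(read_noise_sd = 0.1, shot_noise = TRUE),
    acq = acquisition_config(seed = 7))
  expect_identical(noisy(), noisy())
})

test_that("quantizer: grid snapping, idempotence, saturation, half-step error", {
  one_bit <- adc_config(1, 0, 1)
  expect_equal(quantize(0.4, one_bit), 0.25)   # lower of the two cell centres
  expect_equal(quantize(0.6, one_bit), 0.75)
  expect_equal(quantize(c(-3, 3), one_bit), c(0.25, 0.75))  # saturation

  adc <- adc_config(16, -5, 5)
  set.seed(3)
  x <- runif(2000, -5, 5)
  q <- quantize(x, adc)
  expect_identical(quantize(q, adc), q)                   # idempotent
  expect_lte(max(abs(q - x)), 10 / 2^17)                  # half-step bound
  expect_lte(length(unique(quantize(runif(5000, -5, 5), adc))), 2^16)
  expect_identical(quantize(x, NULL), x)                  # ideal converter
})

test_that("autoranged ADC spans are bipolar for balanced, unipolar for single", {
  ss <- full_subset(basis8)
  il <- illumination_model(1, parasite_baseline = 0.5, ripple_amplitude = 0.3)
  adc_b <- adc_autorange(disc32, basis32, full_subset(basis32), il,
                         detection_config("balanced"), bits = 8)
  expect_s3_class(adc_b, "adc_pair")
  expect_equal(adc_b$ac$v_min, -adc_b$ac$v_max)       # fine AC span, bipolar
  expect_gt(adc_b$dc$v_max, adc_b$ac$v_max)           # coarse total-flux span
  # the fine span quantizes the informative signal more finely than the
  # single-detector span, which must cover the DC pedestal too
  adc_s <- adc_autorange(disc32, basis32, full_subset(basis32), il,
                         detection_config("single"), bits = 8)
  expect_identical(adc_s$v_min, 0)
  expect_gt(adc_s$v_max, 0)
})

test_that("time trace: square wave when clean, 100 Hz line only for single detection", {
  scn <- random_scene(8, 51)
  idx <- c(2L, 5L)
  clean <- illumination_model(1)
  ripple <- illumination_model(1, parasite_baseline = 1, ripple_amplitude = 0.8)

  for (mode in c("balanced", "single")) {
    tr <- detector_time_trace(basis8, scn, idx, clean, detection_config(mode))
    expect_lte(length(unique(round(tr$volts, 9))), 2)  # two-level square wave
  }
  tr_s_on <- detector_time_trace(basis8, scn, idx, ripple, detection_config("single"))
  tr_s_off <- detector_time_trace(basis8, scn, idx, clean, detection_config("single"))
  expect_gt(trace_spectral_magnitude(tr_s_on, 100),
            10 * trace_spectral_magnitude(tr_s_off, 100))

  tr_b_on <- detector_time_trace(basis8, scn, idx, ripple, detection_config("balanced"))
  tr_b_off <- detector_time_trace(basis8, scn, idx, clean, detection_config("balanced"))
  expect_equal(trace_spectral_magnitude(tr_b_on, 100),
               trace_spectral_magnitude(tr_b_off, 100), tolerance = 1e-8)
  expect_error(detector_time_trace(basis8, scn, idx, duration = 0.05),
               "alternation periods")
})

test_that("records round-trip through CSV + metadata files", {
  dir <- withr::local_tempdir()
  scn <- random_scene(8, 61)
  ss <- select_low_sequency_subset(basis8, 0.25)
  rec <- simulate_acquisition(scn, basis8, ss,
                              det = detection_config(read_noise_sd = 0.01),
                              adc = adc_config(12, -200, 200),
                              acq = acquisition_config(seed = 5))
  write_record(rec, dir)
  back <- read_record(dir)
  expect_equal(back$coefficients, rec$coefficients)
  expect_equal(back$indices, rec$indices)
  expect_identical(back$mode, rec$mode)
  expect_equal(back$adc$bits, 12L)
  # a reconstruction from the re-read record matches the in-memory one
  expect_equal(zero_fill_reconstruct(back, basis8)$image,
               zero_fill_reconstruct(rec, basis8)$image)
})
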