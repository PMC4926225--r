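# Image-fidelity measures: 2D Pearson correlation (the classic corr2) and
# mean squared error, plus the undersampling fidelity sweep.

#' 2D correlation coefficient between two images
#'
#' Pearson correlation over all pixels: the centered cross-sum divided by
#' the root of the product of the centered self-sums.  Affine rescalings
#' with positive slope leave it at 1; sign inversion gives -1, so the
#' value lies in [-1, 1] (it is not clamped at zero).
#'
#' @param a,b Numeric matrices of identical shape; both must be
#'   non-constant, otherwise the correlation is undefined and an error is
#'   raised (never a silent zero).
#' @return Scalar in [-1, 1].
#' @export
corr2 <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical shape")
  da <- a - mean(a)
  db <- b - mean(b)
  sa <- sum(da^2); sb <- sum(db^2)
  if (sa == 0 || sb == 0)
    stop("corr2 is undefined for a constant image")
  sum(da * db) / sqrt(sa * sb)
}

#' Mean squared error between two images
#'
#' @inheritParams corr2
#' @return Non-negative scalar.
#' @export
image_mse <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical shape")
  mean((a - b)^2)
}

#' Fidelity report for one image pair
#'
#' @inheritParams corr2
#' @param reference_id,test_id Free-form labels.
#' @return A one-row data frame with `corr2`, `mse` and the labels.
#' @export
fidelity_report <- function(a, b, reference_id = "reference", test_id = "test") {
  data.frame(reference = reference_id, test = test_id,
             corr2 = corr2(a, b), mse = image_mse(a, b))
}

#' Fidelity versus measurement ratio, balanced against single detection
#'
#' For each detection mode, acquires a lossless (ratio 1) reference record,
#' reconstructs it by the inverse transform, then re-acquires the scene at
#' each requested ratio (low-sequency subsets, shared seed) and scores the
#' min-TV reconstruction against that mode's own lossless reference image.
#' This mirrors the experimental comparison in which undersampled images
#' are correlated with the image acquired at the Nyquist criterion.
#'
#' @param scn A static [scene()].
#' @param ratios Measurement ratios in (0, 1]; must be non-empty.
#' @param basis Basis to use; defaults to a sequency basis of the scene
#'   side.
#' @param illum,det_args,acq Scenario settings; `det_args` is a list of
#'   arguments (other than `mode`) passed to [detection_config()].
#' @param adc_bits If not `NULL`, each acquisition runs through an
#'   autoranged ADC of this resolution ([adc_autorange()]).
#' @param modes Detection modes to sweep.
#' @param params Solver settings for [min_tv_reconstruct()].
#' @param seed Base seed; acquisition k uses `seed + k` so the sweep is
#'   reproducible end to end.
#' @return Data frame with columns `ratio`, `mode`, `corr2`, `mse`, `seed`.
#' @export
sweep_fidelity <- function(scn, ratios, basis = build_basis_2d(scn$side),
                           illum = illumination_model(),
                           det_args = list(),
                           acq = acquisition_config(),
                           adc_bits = NULL,
                           modes = c("balanced", "single"),
                           params = tv_params(),
                           seed = 1L) {
  if (length(ratios) == 0) stop("'ratios' must be non-empty")
  stopifnot(all(ratios > 0 & ratios <= 1))
  rows <- list()
  k <- 0L
  for (mode in modes) {
    det <- do.call(detection_config, c(list(mode = mode), det_args))
    acquire <- function(subset, run_seed) {
      adc <- if (is.null(adc_bits)) NULL else
        adc_autorange(scn, basis, subset, illum, det, acq, bits = adc_bits)
      simulate_acquisition(scn, basis, subset, illum, det, adc,
                           acquisition_config(acq$pattern_rate,
                                              acq$samples_per_pattern,
                                              seed = run_seed))
    }
    k <- k + 1L
    ref_rec <- acquire(full_subset(basis), seed + k)
    reference <- inverse_transform(ref_rec, basis)$image
    for (r in ratios) {
      k <- k + 1L
      if (r == 1) {
        rec <- acquire(full_subset(basis), seed + k)
        img <- inverse_transform(rec, basis)$image
      } else {
        subset <- select_low_sequency_subset(basis, r)
        rec <- acquire(subset, seed + k)
        img <- min_tv_reconstruct(rec, sensing_operator(basis, subset),
                                  params)$image
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ratio = r, mode = mode, corr2 = corr2(img, reference),
        mse = image_mse(img, reference), seed = seed)
    }
  }
  do.call(rbind, rows)
}
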