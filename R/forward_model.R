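# Optical/electronic forward model: structured illumination of a scene with
# homogeneous time-varying parasite light, two complementary DMD arms,
# balanced / single / sequential-complementary photodetection, detector
# noise, and ADC quantization.

#' Illumination model
#'
#' Object illumination at power scale `p0` plus a spatially homogeneous
#' ambient ("parasite") term `N(t) = parasite_baseline +
#' ripple_amplitude * sin(2 pi ripple_frequency t + ripple_phase)`, the
#' behaviour of a mains-driven halogen lamp whose intensity ripples at
#' twice the line frequency (100 Hz by default).  The light reaching the
#' DMD plane is `F(t) = p0 * X + N(t) * E` with E the all-ones matrix.
#'
#' @param p0 Object illumination power scale, >= 0.
#' @param parasite_baseline DC ambient level (same radiometric units as the
#'   scene), >= ripple_amplitude so irradiance never goes negative.
#' @param ripple_amplitude Ambient ripple amplitude.
#' @param ripple_frequency Ripple frequency in Hz.
#' @param ripple_phase Ripple phase in radians.
#' @return Object of class `illumination_model`.
#' @export
illumination_model <- function(p0 = 1, parasite_baseline = 0,
                               ripple_amplitude = 0, ripple_frequency = 100,
                               ripple_phase = 0) {
  stopifnot(p0 >= 0, ripple_amplitude >= 0)
  if (parasite_baseline - ripple_amplitude < 0)
    stop("parasite_baseline must be >= ripple_amplitude (irradiance never negative)")
  structure(
    list(p0 = p0, parasite_baseline = parasite_baseline,
         ripple_amplitude = ripple_amplitude,
         ripple_frequency = ripple_frequency, ripple_phase = ripple_phase),
    class = "illumination_model"
  )
}

parasite_level <- function(illum, t) {
  illum$parasite_baseline +
    illum$ripple_amplitude * sin(2 * pi * illum$ripple_frequency * t + illum$ripple_phase)
}

#' Detection configuration
#'
#' @param mode `"balanced"` (both arms subtracted in the analog domain),
#'   `"single"` (one arm, one detector), or `"sequential_complementary"`
#'   (one detector, each pattern and its complement shown one after the
#'   other and subtracted digitally).
#' @param read_noise_sd Additive Gaussian read noise per sample, in volts.
#' @param gain Detector responsivity, volts per irradiance unit.
#' @param shot_noise If `TRUE`, Poisson shot noise is applied to each arm
#'   intensity (treated as a mean photon count per sample) before
#'   subtraction.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(mode = c("balanced", "single", "sequential_complementary"),
                             read_noise_sd = 0, gain = 1, shot_noise = FALSE) {
  mode <- match.arg(mode)
  stopifnot(read_noise_sd >= 0, gain > 0)
  structure(
    list(mode = mode, read_noise_sd = read_noise_sd, gain = gain,
         shot_noise = isTRUE(shot_noise)),
    class = "detection_config"
  )
}

#' ADC configuration
#'
#' A uniform mid-cell quantizer: the span `[v_min, v_max]` is divided into
#' `2^bits` cells of width `(v_max - v_min)/2^bits` and every input maps to
#' the centre of its cell (out-of-range inputs saturate to the extreme
#' cells).  Balanced detection uses a bipolar span centred on zero; a
#' single, always-positive detector signal must use a unipolar span and so
#' effectively spends half of the quantization levels on the DC pedestal.
#'
#' @param bits Number of quantization bits, >= 1.
#' @param v_min,v_max Span bounds in volts, `v_min < v_max`.
#' @return Object of class `adc_config`.
#' @export
adc_config <- function(bits = 16, v_min = -5, v_max = 5) {
  stopifnot(bits >= 1, bits == round(bits), v_min < v_max)
  structure(list(bits = as.integer(bits), v_min = v_min, v_max = v_max),
            class = "adc_config")
}

#' Quantize a signal
#'
#' @param signal Numeric vector of voltages.
#' @param adc An [adc_config()], or `NULL` for an ideal (pass-through)
#'   converter.
#' @return The signal snapped to the ADC's `2^bits` level grid; idempotent,
#'   with out-of-range values clipped to the extreme levels.
#' @export
quantize <- function(signal, adc) {
  if (is.null(adc)) return(signal)
  stopifnot(inherits(adc, "adc_config"))
  delta <- (adc$v_max - adc$v_min) / 2^adc$bits
  k <- floor((signal - adc$v_min) / delta)
  k <- pmin(pmax(k, 0), 2^adc$bits - 1)
  adc$v_min + (k + 0.5) * delta
}

#' Dual-range ADC for balanced acquisition
#'
#' In balanced mode every non-DC pattern produces a small bipolar signal
#' centred on zero, while the all-ones (DC) pattern routes the entire
#' collected flux to one arm and produces a voltage orders of magnitude
#' larger.  Matching one fixed span to both would waste almost all
#' quantization levels on the single DC slot, so the converter is modelled
#' with two ranges, switched per pattern: a fine span for the informative
#' AC measurements and a coarse span for the total-flux (DC) slot.
#'
#' @param ac [adc_config()] applied to non-DC pattern slots.
#' @param dc [adc_config()] applied to the DC (all-ones) pattern slot.
#' @return Object of class `adc_pair`.
#' @export
adc_pair <- function(ac, dc) {
  stopifnot(inherits(ac, "adc_config"), inherits(dc, "adc_config"))
  structure(list(ac = ac, dc = dc), class = "adc_pair")
}

# ADC to apply to a given slot; `dc_slot` marks the all-ones pattern.
slot_adc <- function(adc, dc_slot) {
  if (inherits(adc, "adc_pair")) {
    if (dc_slot) adc$dc else adc$ac
  } else adc
}

#' Acquisition configuration
#'
#' @param pattern_rate DMD pattern display rate in patterns per second.
#' @param samples_per_pattern ADC samples averaged per pattern dwell.
#' @param seed Integer seed for the stochastic stages (read/shot noise);
#'   `NULL` leaves the caller's RNG stream in charge.
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(pattern_rate = 20000, samples_per_pattern = 4,
                               seed = NULL) {
  stopifnot(pattern_rate > 0, samples_per_pattern >= 1)
  structure(
    list(pattern_rate = pattern_rate,
         samples_per_pattern = as.integer(samples_per_pattern), seed = seed),
    class = "acquisition_config"
  )
}

#' Project a scene through a binary mask
#'
#' The single-pixel measurement primitive: elementwise product of scene and
#' mask, summed over all pixels, scaled by the illumination power.
#'
#' @param scn A [scene()] (first frame used) or a plain matrix.
#' @param mask 0/1 matrix of the same shape.
#' @param p0 Illumination power scale.
#' @return Non-negative scalar intensity.
#' @export
project <- function(scn, mask, p0 = 1) {
  X <- if (inherits(scn, "spc_scene")) scn$frames[[1L]] else scn
  if (!identical(dim(X), dim(mask)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match scene shape ", paste(dim(X), collapse = "x"))
  p0 * sum(X * mask)
}

# Ideal per-slot measurement ingredients for pattern index i of `basis`
# against frame X: the signed projection and the frame total.
slot_projection <- function(basis, i, X) {
  H <- basis_function(basis, i)
  c(coef = sum(X * H), total = sum(X))
}

#' Simulate a full single-pixel acquisition
#'
#' Runs the measurement chain for every pattern in `subset`: the scene
#' (advanced per-pattern for videos) is illuminated, both DMD arms collect
#' their complementary shares plus the parasite light at each sample
#' instant, the detector forms a voltage according to `det$mode`, noise is
#' added, each sample is quantized, and samples within a pattern dwell are
#' averaged into one coefficient.
#'
#' In balanced mode the analog subtraction cancels the parasite term for
#' every non-DC pattern exactly (each arm's mask has `size^2 / 2` open
#' mirrors), so with zero noise the coefficients equal `gain * p0 * <X, H_i>`
#' regardless of ambient settings.  Single mode keeps the parasite and the
#' object DC pedestal; sequential complementary mode consumes two pattern
#' slots per coefficient and therefore sees the scene (and the ripple) at
#' two distinct times.
#'
#' @param scn A [scene()].
#' @param basis A [build_basis_2d()] object matching the scene side.
#' @param subset A [select_low_sequency_subset()] / [full_subset()] subset.
#' @param illum An [illumination_model()].
#' @param det A [detection_config()].
#' @param adc An [adc_config()] or `NULL` for an ideal converter.
#' @param acq An [acquisition_config()].
#' @return Object of class `spc_record` with fields `coefficients` (volts,
#'   one per pattern), `arm_plus` / `arm_minus` (ideal mean arm
#'   intensities), `timestamps`, `time_trace` (per-sample `t`, `volts`),
#'   `indices`, `mode`, `gain`, `p0`, `size`, `subset`, `adc`, `acq`.
#' @export
simulate_acquisition <- function(scn, basis, subset = full_subset(basis),
                                 illum = illumination_model(),
                                 det = detection_config(),
                                 adc = NULL,
                                 acq = acquisition_config()) {
  stopifnot(inherits(scn, "spc_scene"), inherits(basis, "wh_basis"),
            inherits(subset, "pattern_subset"))
  if (scn$side != basis$size)
    stop("scene side ", scn$side, " does not match basis size ", basis$size)
  if (subset$size != basis$size || max(subset$indices) > n_functions(basis))
    stop("subset does not belong to this basis")
  run <- function() simulate_acquisition_impl(scn, basis, subset, illum, det, adc, acq)
  if (!is.null(acq$seed)) with_seed(acq$seed, run()) else run()
}

simulate_acquisition_impl <- function(scn, basis, subset, illum, det, adc, acq) {
  s <- basis$size
  idx <- subset$indices
  M <- length(idx)
  spp <- acq$samples_per_pattern
  rate <- acq$pattern_rate
  sequential <- det$mode == "sequential_complementary"
  slots_per_coef <- if (sequential) 2L else 1L
  n_slots <- M * slots_per_coef
  half <- s^2 / 2

  sample_offsets <- (seq_len(spp) - 0.5) / (spp * rate)
  coefficients <- numeric(M)
  arm_plus <- numeric(M)
  arm_minus <- numeric(M)
  timestamps <- numeric(M)
  trace_t <- numeric(n_slots * spp)
  trace_v <- numeric(n_slots * spp)

  # Voltage samples for one slot on one detector; `open` is the number of
  # open mirrors in the displayed mask, `obj` the object-light flux through it.
  arm_samples <- function(obj, open, tt) {
    flux <- obj + parasite_level(illum, tt) * open
    if (det$shot_noise) flux <- stats::rpois(length(flux), pmax(flux, 0))
    flux
  }

  measure_slot <- function(slot, i, signed) {
    # signed = +1 -> plus mask, -1 -> minus mask (sequential one-arm slots)
    t0 <- (slot - 1) / rate
    tt <- t0 + sample_offsets
    t_mid <- t0 + 0.5 / rate
    X <- scene_frame_at(scn, t_mid)
    pr <- slot_projection(basis, i, X)
    h <- if (all(basis$uv[i, ] == 0L)) s^2 else 0  # DC pattern sums to s^2
    obj_plus <- illum$p0 * (pr["total"] + pr["coef"]) / 2
    obj_minus <- illum$p0 * (pr["total"] - pr["coef"]) / 2
    open_plus <- (s^2 + h) / 2
    open_minus <- (s^2 - h) / 2
    list(tt = tt, t_mid = t_mid,
         plus = arm_samples(obj_plus, open_plus, tt),
         minus = arm_samples(obj_minus, open_minus, tt),
         signed = signed)
  }

  read_noise <- function(n) {
    if (det$read_noise_sd > 0) stats::rnorm(n, 0, det$read_noise_sd) else 0
  }

  for (m in seq_len(M)) {
    i <- idx[m]
    adc_m <- slot_adc(adc, all(basis$uv[i, ] == 0L))
    if (!sequential) {
      sl <- measure_slot(m, i, +1)
      v <- switch(det$mode,
        balanced = det$gain * (sl$plus - sl$minus) + read_noise(spp),
        single   = det$gain * sl$plus + read_noise(spp))
      q <- quantize(v, adc_m)
      coefficients[m] <- mean(q)
      arm_plus[m] <- mean(sl$plus)
      arm_minus[m] <- mean(sl$minus)
      timestamps[m] <- sl$t_mid
      span <- ((m - 1L) * spp + 1L):(m * spp)
      trace_t[span] <- sl$tt; trace_v[span] <- q
    } else {
      sl1 <- measure_slot(2L * m - 1L, i, +1)   # plus mask, one detector
      sl2 <- measure_slot(2L * m, i, -1)        # minus mask, same detector, later
      v1 <- det$gain * sl1$plus + read_noise(spp)
      v2 <- det$gain * sl2$minus + read_noise(spp)
      q1 <- quantize(v1, adc_m); q2 <- quantize(v2, adc_m)
      coefficients[m] <- mean(q1) - mean(q2)
      arm_plus[m] <- mean(sl1$plus)
      arm_minus[m] <- mean(sl2$minus)
      timestamps[m] <- (sl1$t_mid + sl2$t_mid) / 2
      span1 <- ((2L * m - 2L) * spp + 1L):((2L * m - 1L) * spp)
      span2 <- ((2L * m - 1L) * spp + 1L):(2L * m * spp)
      trace_t[span1] <- sl1$tt; trace_v[span1] <- q1
      trace_t[span2] <- sl2$tt; trace_v[span2] <- q2
    }
  }

  structure(
    list(coefficients = coefficients, arm_plus = arm_plus,
         arm_minus = arm_minus, timestamps = timestamps,
         time_trace = data.frame(t = trace_t, volts = trace_v),
         indices = idx, mode = det$mode, gain = det$gain, p0 = illum$p0,
         size = s, subset = subset, adc = adc, acq = acq),
    class = "spc_record"
  )
}

#' @export
print.spc_record <- function(x, ...) {
  cat(sprintf("<spc_record> %s mode, %d coefficients, %d x %d basis\n",
              x$mode, length(x$coefficients), x$size, x$size))
  invisible(x)
}

#' Scene-unit signed coefficients from a measurement record
#'
#' Undoes gain and illumination scaling so the vector estimates the basis
#' projections `<X, H_i>`.  Balanced and sequential records carry the
#' signed difference directly; a single-detector record measured the
#' shifted binary mask `(E + H)/2`, so the signed projection is recovered
#' as `2 y_i - y_DC` using the DC (all-ones) measurement, which every
#' subset includes.  Note the DC coefficient itself absorbs whatever
#' parasite light was present in every mode.
#'
#' @param record An [simulate_acquisition()] record.
#' @return Numeric vector of coefficient estimates in scene units.
#' @export
signed_coefficients <- function(record) {
  y <- record$coefficients
  scale <- record$gain * record$p0
  if (record$mode == "single") {
    dc_pos <- match(1L, record$indices)
    if (is.na(dc_pos))
      stop("single-detector recovery needs the DC pattern in the subset")
    y <- 2 * y - y[dc_pos]
    y[dc_pos] <- record$coefficients[dc_pos]
  }
  y / scale
}

#' Oscilloscope-style detector time trace
#'
#' Displays two basis patterns alternately at a low rate (a square wave on
#' the detector) and samples the detector voltage, emulating the scope
#' snapshots used to demonstrate ambient-light immunity: with the ripple
#' on, the single-detector trace carries a clear 100 Hz line that the
#' balanced trace cancels.
#'
#' @param basis A [build_basis_2d()] object.
#' @param scn A [scene()] matching the basis.
#' @param indices Length-2 vector of pattern indices to alternate.
#' @param illum An [illumination_model()].
#' @param det A [detection_config()] (`sequential_complementary` behaves as
#'   `single` here: one arm is observed).
#' @param alternation_rate Pattern alternation rate in Hz.
#' @param sample_rate Detector sampling rate in Hz.
#' @param duration Trace length in seconds; must cover at least two
#'   alternation periods.
#' @param seed Optional seed for the noise draws.
#' @return A data frame with columns `t` and `volts`.
#' @export
detector_time_trace <- function(basis, scn, indices,
                                illum = illumination_model(),
                                det = detection_config(),
                                alternation_rate = 10, sample_rate = 4000,
                                duration = 0.5, seed = NULL) {
  stopifnot(length(indices) == 2L, duration > 0)
  if (duration * alternation_rate < 2)
    stop("duration must cover at least two alternation periods")
  run <- function() {
    t <- seq(0, duration, by = 1 / sample_rate)
    which_pat <- 1L + (floor(t * alternation_rate) %% 2L)
    X <- scn$frames[[1L]]
    s <- basis$size
    v <- numeric(length(t))
    for (k in 1:2) {
      sel <- which_pat == k
      pr <- slot_projection(basis, indices[k], X)
      h <- if (all(basis$uv[indices[k], ] == 0L)) s^2 else 0
      obj_plus <- illum$p0 * (pr["total"] + pr["coef"]) / 2
      obj_minus <- illum$p0 * (pr["total"] - pr["coef"]) / 2
      np <- parasite_level(illum, t[sel])
      plus <- obj_plus + np * (s^2 + h) / 2
      minus <- obj_minus + np * (s^2 - h) / 2
      v[sel] <- if (det$mode == "balanced") det$gain * (plus - minus)
                else det$gain * plus
    }
    if (det$read_noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, det$read_noise_sd)
    data.frame(t = t, volts = v)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Spectral magnitude of a time trace at one frequency
#'
#' Single-bin discrete Fourier magnitude, used to check for the parasite
#' ripple line in detector traces.
#'
#' @param trace A data frame with columns `t` and `volts`.
#' @param freq Frequency in Hz.
#' @return Non-negative magnitude (arbitrary units).
#' @export
trace_spectral_magnitude <- function(trace, freq) {
  Mod(sum(trace$volts * exp(-2i * pi * freq * trace$t)))
}

#' Autorange an ADC to a scenario
#'
#' Runs the noiseless, unquantized chain once and sets the span from the
#' extreme ideal sample voltages with 10% headroom.  Single and sequential
#' signals are always positive and must span the DC pedestal plus the AC
#' oscillations with one unipolar range `[0, max]`.  Balanced mode gets a
#' dual-range [adc_pair()]: a fine bipolar span matched to the non-DC
#' (AC) measurements — the full dynamic range quantizes only the
#' informative fluctuations — and a coarse bipolar span for the total-flux
#' DC slot.
#'
#' @inheritParams simulate_acquisition
#' @param bits ADC resolution for the returned config.
#' @param headroom Span multiplier above the observed extreme (default 1.1).
#' @return An [adc_config()], or an [adc_pair()] for balanced mode.
#' @export
adc_autorange <- function(scn, basis, subset, illum, det, acq =
                            acquisition_config(), bits = 16, headroom = 1.1) {
  det0 <- detection_config(det$mode, read_noise_sd = 0, gain = det$gain,
                           shot_noise = FALSE)
  rec <- simulate_acquisition(scn, basis, subset, illum, det0, adc = NULL,
                              acq = acquisition_config(acq$pattern_rate,
                                                       acq$samples_per_pattern))
  v <- rec$time_trace$volts
  if (det$mode == "balanced") {
    spp <- rec$acq$samples_per_pattern
    slots <- if (det$mode == "sequential_complementary") 2L else 1L
    dc_patterns <- apply(basis$uv[rec$indices, , drop = FALSE] == 0L, 1L, all)
    dc_samples <- rep(dc_patterns, each = spp * slots)
    v_ac <- v[!dc_samples]
    if (length(v_ac) == 0) v_ac <- v
    ac_max <- headroom * max(abs(v_ac), .Machine$double.eps)
    dc_max <- headroom * max(abs(v), .Machine$double.eps)
    adc_pair(adc_config(bits, -ac_max, ac_max),
             adc_config(bits, -dc_max, dc_max))
  } else {
    adc_config(bits, 0, headroom * max(v, .Machine$double.eps))
  }
}

#' Write a measurement record to disk
#'
#' The record goes to `record.csv` (index, timestamp, I_plus, I_minus,
#' coefficient), the per-sample trace to `trace.csv` (t, volts), and the
#' scalar metadata to `record_meta.yaml`.
#'
#' @param record An [simulate_acquisition()] record.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(index = record$indices, timestamp = record$timestamps,
               I_plus = record$arm_plus, I_minus = record$arm_minus,
               coefficient = record$coefficients),
    file.path(dir, "record.csv"), row.names = FALSE)
  utils::write.csv(record$time_trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  meta <- list(mode = record$mode, gain = record$gain, p0 = record$p0,
               size = record$size, ratio = record$subset$ratio,
               pattern_rate = record$acq$pattern_rate,
               samples_per_pattern = record$acq$samples_per_pattern,
               seed = record$acq$seed,
               adc = adc_meta(record$adc))
  yaml::write_yaml(meta, file.path(dir, "record_meta.yaml"))
  invisible(dir)
}

adc_meta <- function(adc) {
  if (is.null(adc)) return("ideal")
  if (inherits(adc, "adc_pair"))
    return(list(ac = adc_meta(adc$ac), dc = adc_meta(adc$dc)))
  list(bits = adc$bits, v_min = adc$v_min, v_max = adc$v_max)
}

adc_from_meta <- function(meta) {
  if (identical(meta, "ideal")) return(NULL)
  if (!is.null(meta$ac))
    return(adc_pair(adc_from_meta(meta$ac), adc_from_meta(meta$dc)))
  adc_config(meta$bits, meta$v_min, meta$v_max)
}

#' Read a measurement record written by [write_record()]
#'
#' @param dir Directory containing `record.csv` and `record_meta.yaml`.
#' @return An `spc_record` (without the original subset's ratio provenance
#'   beyond what the metadata stores).
#' @export
read_record <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "record.csv"))
  meta <- yaml::read_yaml(file.path(dir, "record_meta.yaml"))
  trace <- utils::read.csv(file.path(dir, "trace.csv"))
  adc <- adc_from_meta(meta$adc)
  structure(
    list(coefficients = tab$coefficient, arm_plus = tab$I_plus,
         arm_minus = tab$I_minus, timestamps = tab$timestamp,
         time_trace = trace, indices = tab$index, mode = meta$mode,
         gain = meta$gain, p0 = meta$p0, size = meta$size,
         subset = structure(list(indices = tab$index, ratio = meta$ratio,
                                 size = meta$size), class = "pattern_subset"),
         adc = adc,
         acq = acquisition_config(meta$pattern_rate, meta$samples_per_pattern,
                                  meta$seed)),
    class = "spc_record"
  )
}
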