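# Acquisition bookkeeping: pattern counts, frame times, and frame rates.
# With a DMD displaying `pattern_rate` patterns per second, a frame needs
# one pattern per measured coefficient (two in sequential complementary
# mode), so frame_time = pattern_count / pattern_rate.

#' Patterns needed for one frame
#'
#' Balanced and single modes need `ceiling(ratio * side^2)` patterns
#' (4096 for a lossless 64 x 64 frame, 820 at a 20% measurement ratio);
#' sequential complementary mode displays each pattern and its complement
#' and therefore needs twice as many (8192 lossless at 64 x 64).
#'
#' @param side Image side in pixels (power of two).
#' @param mode `"balanced"`, `"single"`, or `"sequential_complementary"`.
#' @param ratio Measurement ratio in (0, 1].
#' @return Integer pattern count.
#' @export
pattern_count <- function(side, mode = c("balanced", "single",
                                         "sequential_complementary"),
                          ratio = 1) {
  mode <- match.arg(mode)
  if (!is_pow2(side)) stop("'side' must be a power of two, got ", side)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("'ratio' must lie in (0, 1], got ", ratio)
  n <- as.integer(ceiling(ratio * side^2))
  if (mode == "sequential_complementary") 2L * n else n
}

#' Frame time and frame rate
#'
#' `frame_rate()` returns both the raw rate `pattern_rate / pattern_count`
#' and a one-significant-figure report matching how such rates are quoted
#' ("roughly 200 ms", "5 Hz"): 4096 patterns at 20 kHz give a raw
#' 4.8828 Hz, reported as 5 Hz.
#'
#' @inheritParams pattern_count
#' @param pattern_rate DMD pattern rate in patterns per second.
#' @return For `frame_rate()`: list with `raw_hz`, `reported_hz`,
#'   `raw_s`, `reported_ms` (frame time in milliseconds, one significant
#'   figure) and `pattern_count`.  For `frame_time()`: raw seconds.
#' @export
frame_rate <- function(side, mode = "balanced", ratio = 1,
                       pattern_rate = 20000) {
  stopifnot(pattern_rate > 0)
  n <- pattern_count(side, mode, ratio)
  raw_s <- n / pattern_rate
  list(raw_hz = pattern_rate / n,
       reported_hz = signif(pattern_rate / n, 1),
       raw_s = raw_s,
       reported_ms = signif(raw_s * 1000, 1),
       pattern_count = n)
}

#' @rdname frame_rate
#' @export
frame_time <- function(side, mode = "balanced", ratio = 1,
                       pattern_rate = 20000) {
  pattern_count(side, mode, ratio) / pattern_rate
}

#' Acquisition budget table
#'
#' One row per (side, mode, ratio) combination with pattern counts, frame
#' times and raw/reported frame rates.
#'
#' @param sides,modes,ratios Vectors of settings to cross.
#' @param pattern_rate DMD pattern rate in Hz.
#' @return Data frame with columns `side`, `mode`, `ratio`,
#'   `pattern_count`, `frame_time_s`, `frame_rate_hz`, `reported_hz`,
#'   `reported_ms`.
#' @export
acquisition_budget <- function(sides = c(32, 64),
                               modes = c("balanced", "sequential_complementary"),
                               ratios = c(0.2, 1),
                               pattern_rate = 20000) {
  grid <- expand.grid(side = sides, mode = modes, ratio = ratios,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    fr <- frame_rate(g$side, g$mode, g$ratio, pattern_rate)
    data.frame(side = g$side, mode = g$mode, ratio = g$ratio,
               pattern_count = fr$pattern_count, frame_time_s = fr$raw_s,
               frame_rate_hz = fr$raw_hz, reported_hz = fr$reported_hz,
               reported_ms = fr$reported_ms)
  })
  do.call(rbind, rows)
}
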