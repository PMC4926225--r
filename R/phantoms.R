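# Synthetic test scenes: resolution-chart style bar targets and a moving
# cartoon ("Pac-Man eating a pellet") video.  All phantoms are deterministic
# functions of their spec: no hidden randomness.

#' Scene container
#'
#' A scene is a non-negative square irradiance map, or a time sequence of
#' them (a video) with a fixed frame period.
#'
#' @param frames A single matrix, or a list of equally sized matrices.
#' @param frame_period Seconds between consecutive frames (videos only).
#' @return Object of class `spc_scene` with fields `frames` (list of
#'   matrices), `side`, `n_frames`, `frame_period`.
#' @export
scene <- function(frames, frame_period = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  d <- dim(frames[[1L]])
  if (d[1L] != d[2L]) stop("scenes must be square, got ", d[1L], " x ", d[2L])
  for (f in frames) {
    stopifnot(identical(dim(f), d))
    if (any(f < 0)) stop("scene irradiance must be non-negative")
  }
  if (length(frames) > 1L && !is.finite(frame_period))
    stop("a finite 'frame_period' is required for multi-frame scenes")
  structure(
    list(frames = frames, side = d[1L], n_frames = length(frames),
         frame_period = frame_period),
    class = "spc_scene"
  )
}

#' @export
print.spc_scene <- function(x, ...) {
  cat(sprintf("<spc_scene> %d x %d, %d frame(s)\n", x$side, x$side, x$n_frames))
  invisible(x)
}

# Frame active at absolute time t (nearest-frame lookup; frame k covers
# [(k-1)*T, k*T) so we index by the containing interval).
scene_frame_at <- function(scn, t) {
  if (scn$n_frames == 1L) return(scn$frames[[1L]])
  k <- min(scn$n_frames, max(1L, 1L + as.integer(floor(t / scn$frame_period))))
  scn$frames[[k]]
}

#' Bar-target phantom
#'
#' Renders alternating bright/dark bars, the synthetic stand-in for a
#' resolution test chart element.  Bars are axis-aligned with hard binary
#' edges; `n_bars` bright bars of `bar_width` pixels are separated by gaps
#' of the same width and centred in the field.
#'
#' @param side Image side in pixels.
#' @param n_bars Number of bright bars.
#' @param bar_width Bar (and gap) width in pixels, >= 1.
#' @param orientation `"vertical"` (bright columns) or `"horizontal"`.
#' @param foreground,background Radiometric levels in `[0, 1]`.
#' @return A single-frame [scene()].
#' @examples
#' sum(colSums(render_bars(64, 3, 8)$frames[[1]]) > 0)  # 24 bright columns
#' @export
render_bars <- function(side, n_bars = 3, bar_width = side %/% 8,
                        orientation = c("vertical", "horizontal"),
                        foreground = 1, background = 0) {
  orientation <- match.arg(orientation)
  stopifnot(bar_width >= 1, n_bars >= 1, foreground >= background, background >= 0)
  extent <- (2L * n_bars - 1L) * bar_width
  if (extent > side)
    stop("bars exceed the image: need ", extent, " pixels, have ", side)
  img <- matrix(background, side, side)
  start <- (side - extent) %/% 2L
  for (k in seq_len(n_bars)) {
    cols <- start + (2L * (k - 1L)) * bar_width + seq_len(bar_width)
    img[, cols] <- foreground
  }
  if (orientation == "horizontal") img <- t(img)
  scene(img)
}

disc_mask <- function(side, cx, cy, r) {
  x <- matrix(rep(seq_len(side), each = side), side, side)       # column index
  y <- matrix(rep(seq_len(side), times = side), side, side)      # row index
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Moving "Pac-Man eating a pellet" video phantom
#'
#' Each frame shows a bright disc with a wedge-shaped mouth cut out, moving
#' linearly from `start` towards the pellet, which shrinks linearly to
#' nothing over the video.  The mouth opens towards the direction of travel.
#'
#' @param side Image side in pixels.
#' @param n_frames Number of frames, >= 2.
#' @param disc_radius Disc radius in pixels.
#' @param mouth_angle Full mouth opening in radians (0 for a plain disc).
#' @param pellet_radius Initial pellet radius in pixels (0 for no pellet).
#' @param start,end Disc centre (x, y) in the first and last frame.
#' @param pellet_at Pellet centre (x, y); defaults to `end`.
#' @param frame_period Seconds between frames.
#' @param foreground,background Levels in `[0, 1]`.
#' @return A multi-frame [scene()].
#' @export
render_pacman_video <- function(side, n_frames = 8, disc_radius = side / 5,
                                mouth_angle = pi / 3, pellet_radius = side / 12,
                                start = c(side * 0.28, side * 0.5),
                                end = c(side * 0.62, side * 0.5),
                                pellet_at = NULL,
                                frame_period = 0.04,
                                foreground = 1, background = 0) {
  stopifnot(n_frames >= 2, disc_radius >= 1)
  if (is.null(pellet_at)) pellet_at <- end
  path_check <- rbind(start, end)
  if (any(path_check - disc_radius < 1) || any(path_check + disc_radius > side))
    stop("trajectory leaves the frame")
  heading <- atan2(end[2] - start[2], end[1] - start[1])
  if (all(start == end)) heading <- 0
  x <- matrix(rep(seq_len(side), each = side), side, side)
  y <- matrix(rep(seq_len(side), times = side), side, side)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    f <- (k - 1) / (n_frames - 1)
    c_now <- start + f * (end - start)
    img <- matrix(background, side, side)
    in_disc <- disc_mask(side, c_now[1], c_now[2], disc_radius)
    if (mouth_angle > 0) {
      ang <- atan2(y - c_now[2], x - c_now[1])
      d <- atan2(sin(ang - heading), cos(ang - heading))  # wrapped difference
      in_disc <- in_disc & abs(d) > mouth_angle / 2
    }
    img[in_disc] <- foreground
    r_p <- pellet_radius * (1 - f)
    if (r_p >= 0.5) {
      img[disc_mask(side, pellet_at[1], pellet_at[2], r_p)] <- foreground
    }
    frames[[k]] <- img
  }
  scene(frames, frame_period = frame_period)
}

#' Write a scene to image files
#'
#' Single frames go to one PNG/TIFF; videos to a frame directory with a
#' `frames.csv` manifest (frame index, time, file).
#'
#' @param scn A [scene()].
#' @param path Output file (single frame) or directory (video).
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the written path(s).
#' @export
export_scene <- function(scn, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tif"
  writer <- if (format == "png") png::writePNG else tiff::writeTIFF
  clamp01 <- function(m) pmin(pmax(m, 0), 1)
  if (scn$n_frames == 1L) {
    writer(clamp01(scn$frames[[1L]]), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%04d.%s", seq_len(scn$n_frames), ext)
  for (k in seq_len(scn$n_frames))
    writer(clamp01(scn$frames[[k]]), file.path(path, files[k]))
  manifest <- data.frame(frame = seq_len(scn$n_frames),
                         time = (seq_len(scn$n_frames) - 1L) * scn$frame_period,
                         file = files)
  utils::write.csv(manifest, file.path(path, "frames.csv"), row.names = FALSE)
  invisible(file.path(path, files))
}
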