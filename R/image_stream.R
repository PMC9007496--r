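#' Construct an image stream
#'
#' A time-lapse fluorescence stack from a single confocal plane: a 3D array
#' of intensities with acquisition calibrations.  Frames are stored with the
#' time axis last, `frames[row, col, t]`; frame `t` is timestamped
#' `(t - 1) * frame_interval_s` seconds from stream start.
#'
#' @param frames numeric 3D array `(row, col, time)`.
#' @param frame_interval_s frame interval in seconds.
#' @param pixel_size_um pixel size in micrometers.
#' @return An object of class `image_stream`.
#' @export
image_stream <- function(frames, frame_interval_s, pixel_size_um) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_config("frames must be a 3D array (row, col, time)")
  check_scalar(frame_interval_s, "frame_interval_s")
  check_scalar(pixel_size_um, "pixel_size_um")
  structure(list(frames = frames,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um),
            class = "image_stream")
}

#' @export
print.image_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stream> %d frames of %d x %d px, %.3g s/frame, %.3g um/px (%.3g s total)\n",
    d[3], d[1], d[2], x$frame_interval_s, x$pixel_size_um,
    d[3] * x$frame_interval_s))
  invisible(x)
}

#' Number of frames in an image stream
#' @param stream an `image_stream`.
#' @return Integer frame count.
#' @export
n_frames <- function(stream) dim(stream$frames)[3]

# Timestamps of all frames, seconds from stream start.
frame_times <- function(stream) {
  (seq_len(n_frames(stream)) - 1) * stream$frame_interval_s
}
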