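#' Define a neurite path
#'
#' An ordered polyline through the imaged field along which the kymograph is
#' read out.  The first vertex is the end nearest the cell body; positions
#' in micrometers are measured from it, so "anterograde" means increasing
#' position.
#'
#' @param vertices matrix of `(row, col)` points, 1-based pixel coordinates.
#' @param sampling_step_px spacing of sample points along the path, pixels.
#' @param roi_halfwidth_px half-width of the band projected perpendicular to
#'   the path (default 1, a 3-pixel band).
#' @return A `neurite_path` object.
#' @export
neurite_path <- function(vertices, sampling_step_px = 1,
                         roi_halfwidth_px = 1) {
  v <- as_vertices(vertices)
  check_scalar(sampling_step_px, "sampling_step_px")
  if (roi_halfwidth_px < 0) stop_config("roi_halfwidth_px must be >= 0")
  if (path_cumlen(v)[nrow(v)] <= 0) stop_config("path has zero arc length")
  structure(list(vertices = v, sampling_step_px = sampling_step_px,
                 roi_halfwidth_px = roi_halfwidth_px),
            class = "neurite_path")
}

#' Construct a kymograph
#'
#' A 2D position-by-time representation of an image stream along a neurite
#' path.  Rows are frames (time increasing downward), columns are positions
#' along the path (increasing away from the cell body).
#'
#' @param matrix numeric matrix, `time x position`.
#' @param frame_interval_s seconds per row.
#' @param position_step_um micrometers per column.
#' @param t0_s timestamp of the first row, seconds from stream start.
#' @return A `kymograph` object.
#' @export
kymograph <- function(matrix, frame_interval_s, position_step_um, t0_s = 0) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_config("matrix must be a numeric matrix")
  check_scalar(frame_interval_s, "frame_interval_s")
  check_scalar(position_step_um, "position_step_um")
  structure(list(matrix = matrix, frame_interval_s = frame_interval_s,
                 position_step_um = position_step_um, t0_s = t0_s,
                 path_origin = "cell-body end"),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d frames x %d positions; %.3g s/row, %.3g um/col, window starts at %.3g s\n",
    nrow(x$matrix), ncol(x$matrix), x$frame_interval_s, x$position_step_um,
    x$t0_s))
  invisible(x)
}

#' Build a kymograph from an image stream
#'
#' The path is resampled at `sampling_step_px` intervals; for each frame in
#' the time window and each sample point, the kymograph records the maximum
#' intensity over a short band perpendicular to the path
#' (`roi_halfwidth_px` pixels to each side, bilinear interpolation at
#' sub-pixel locations).  Max projection across the neurite width keeps a
#' thin, slightly mis-traced neurite from dimming the readout.
#'
#' @param stream an [image_stream()].
#' @param path a [neurite_path()].
#' @param window `(t_start_s, t_end_s)` half-open time window `[t0, t1)` in
#'   seconds from stream start; `NULL` (default) uses the whole stream.
#' @return A [kymograph()]; rows cover the selected frames, `t0_s` records
#'   the window start.
#' @examples
#' sim <- simulate_transport_stream(transport_sim_config(seed = 1,
#'   duration_s = 5, n_vesicles = 1))
#' k <- build_kymograph(sim$stream,
#'   neurite_path(rbind(c(8, 10), c(8, 120))), window = c(0, 3))
#' k
#' @export
build_kymograph <- function(stream, path, window = NULL) {
  if (!inherits(stream, "image_stream"))
    stop_config("stream must be an image_stream")
  if (!inherits(path, "neurite_path"))
    stop_config("path must be a neurite_path")
  tv <- frame_times(stream)
  total_s <- n_frames(stream) * stream$frame_interval_s
  if (is.null(window)) window <- c(0, total_s)
  if (length(window) != 2L || window[1] >= window[2])
    stop_range("window must be (t_start, t_end) with t_start < t_end")
  if (window[1] < 0 || window[1] > total_s || window[2] > total_s + 1e-9)
    stop_range("window [", window[1], ", ", window[2],
               ") lies outside the stream duration of ", total_s, " s")
  sel <- which(tv >= window[1] & tv < window[2])
  if (length(sel) == 0) stop_range("window selects no frames")

  v <- path$vertices
  L <- path_cumlen(v)[nrow(v)]
  s <- seq(0, L, by = path$sampling_step_px)
  pts <- path_point(v, s)
  tg <- path_tangent(v, s)
  nrm <- cbind(-tg[, 2], tg[, 1])

  h <- path$roi_halfwidth_px
  offs <- seq(-h, h, by = 1)
  nsamp <- length(s); nb <- length(offs)
  rr <- as.vector(outer(nrm[, 1], offs) + pts[, 1])  # nsamp x nb
  cc <- as.vector(outer(nrm[, 2], offs) + pts[, 2])

  d <- dim(stream$frames)
  if (any(rr < 1 | rr > d[1] | cc < 1 | cc > d[2]))
    stop_range("path (with its perpendicular band) leaves the image bounds")

  # bilinear interpolation weights, shared by all frames
  r0 <- pmin(floor(rr), d[1] - 1); c0 <- pmin(floor(cc), d[2] - 1)
  fr <- rr - r0; fc <- cc - c0
  i00 <- (c0 - 1) * d[1] + r0
  i10 <- i00 + 1
  i01 <- i00 + d[1]
  i11 <- i01 + 1
  w00 <- (1 - fr) * (1 - fc); w10 <- fr * (1 - fc)
  w01 <- (1 - fr) * fc;       w11 <- fr * fc

  fl <- matrix(stream$frames, nrow = d[1] * d[2], ncol = d[3])[, sel,
                                                               drop = FALSE]
  vals <- fl[i00, , drop = FALSE] * w00 + fl[i10, , drop = FALSE] * w10 +
    fl[i01, , drop = FALSE] * w01 + fl[i11, , drop = FALSE] * w11
  # vals is (nsamp*nb) x ntime; max over the band
  m <- vals[seq_len(nsamp), , drop = FALSE]
  if (nb > 1) for (b in 2:nb)
    m <- pmax(m, vals[(b - 1) * nsamp + seq_len(nsamp), , drop = FALSE])

  kymograph(t(m), stream$frame_interval_s,
            path$sampling_step_px * stream$pixel_size_um,
            t0_s = window[1])
}

#' Columns of a kymograph covering a bleached segment
#'
#' Maps a half-open interval of positions along the path (micrometers from
#' the cell-body end) to the kymograph columns whose centers fall inside it.
#' Used to restrict event detection to the photobleached, low-background
#' segment.
#'
#' @param kymo a [kymograph()].
#' @param bleach_window_um `(start_um, end_um)`, half-open `[start, end)`.
#' @return Integer vector of column indices (possibly empty).
#' @examples
#' k <- kymograph(matrix(0, 10, 30), 0.1, 0.1)
#' bleach_mask(k, c(1.0, 2.0))  # columns at positions 1.0 ... 1.9 um
#' @export
bleach_mask <- function(kymo, bleach_window_um) {
  if (!inherits(kymo, "kymograph")) stop_config("kymo must be a kymograph")
  if (length(bleach_window_um) != 2L ||
      bleach_window_um[1] > bleach_window_um[2])
    stop_range("bleach window must be (start, end) with start <= end")
  extent <- (ncol(kymo$matrix) - 1) * kymo$position_step_um
  if (bleach_window_um[1] < 0 || bleach_window_um[2] > extent + kymo$position_step_um)
    stop_range("bleach window outside the kymograph position extent")
  pos <- (seq_len(ncol(kymo$matrix)) - 1) * kymo$position_step_um
  which(pos >= bleach_window_um[1] & pos < bleach_window_um[2])
}
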