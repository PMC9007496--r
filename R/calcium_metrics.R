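#' Construct a calcium trace
#'
#' @param time_s per-sample timestamps, seconds, strictly increasing.
#' @param fluorescence per-sample fluorescence, arbitrary units, `>= 0`.
#' @param frame_interval_s sampling interval, seconds.
#' @return A `calcium_trace` object.
#' @export
calcium_trace <- function(time_s, fluorescence, frame_interval_s) {
  if (length(time_s) != length(fluorescence))
    stop_config("time_s and fluorescence must have equal length")
  if (length(time_s) < 1 || is.unsorted(time_s, strictly = TRUE))
    stop_config("time_s must be non-empty and strictly increasing")
  if (any(fluorescence < 0))
    stop_config("fluorescence must be >= 0")
  check_scalar(frame_interval_s, "frame_interval_s")
  structure(list(time_s = as.numeric(time_s),
                 fluorescence = as.numeric(fluorescence),
                 frame_interval_s = frame_interval_s),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d samples at %.3g s (%.3g s total)\n",
              length(x$time_s), x$frame_interval_s,
              length(x$time_s) * x$frame_interval_s))
  invisible(x)
}

#' Analysis parameters for calcium metrics
#'
#' @param baseline_smooth_window_s boxcar window (seconds) applied before
#'   taking the minimum as the baseline; smoothing keeps the baseline from
#'   being a single-sample noise order statistic.
#' @param peak_min_prominence_dff minimum topographic prominence of a peak,
#'   dF/F units.
#' @param peak_min_separation_s minimum spacing between reported peaks,
#'   seconds (the higher peak wins).
#' @return A `calcium_params` list.
#' @export
calcium_params <- function(baseline_smooth_window_s = 1.0,
                           peak_min_prominence_dff = 0.1,
                           peak_min_separation_s = 1.0) {
  check_scalar(baseline_smooth_window_s, "baseline_smooth_window_s")
  check_scalar(peak_min_prominence_dff, "peak_min_prominence_dff")
  check_scalar(peak_min_separation_s, "peak_min_separation_s")
  structure(list(baseline_smooth_window_s = baseline_smooth_window_s,
                 peak_min_prominence_dff = peak_min_prominence_dff,
                 peak_min_separation_s = peak_min_separation_s),
            class = "calcium_params")
}

# Centered boxcar mean with shrinking windows at the edges.
boxcar_smooth <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima with plateau handling; returns first index of each plateau.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- sign(diff(x))
  # carry trend through flat stretches
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  which(diff(d) == -2 | (d[-1] == -1 & d[-length(d)] == 0)) + 1L
}

# Topographic prominence of peaks of x: height above the higher of the two
# key saddles (the minimum between the peak and the nearest higher terrain
# on each side; the trace end acts as higher terrain).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1) {
      higher <- which(x[seq_len(p - 1)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(x[lo:(p - 1L)])
    } else h
    right <- if (p < length(x)) {
      idx <- (p + 1L):length(x)
      higher <- idx[x[idx] > h]
      hi <- if (length(higher)) min(higher) - 1L else length(x)
      min(x[(p + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
}

# Peaks of x with minimum prominence and minimum index separation
# (greedy, highest peak first).
find_peaks <- function(x, min_prominence, min_sep_samples) {
  pk <- local_maxima(x)
  if (length(pk) == 0) return(integer(0))
  prom <- peak_prominence(x, pk)
  pk <- pk[prom >= min_prominence]
  if (length(pk) <= 1) return(pk)
  pk <- pk[order(-x[pk])]
  kept <- integer(0)
  for (p in pk)
    if (all(abs(p - kept) >= min_sep_samples)) kept <- c(kept, p)
  sort(kept)
}

#' Compute calcium trace metrics
#'
#' The baseline `f_min_baseline` is the minimum of the boxcar-smoothed trace.
#' The dF/F series is `(F - f_min) / f_min`; total activity is the sum of
#' supra-baseline fluorescence divided by the baseline,
#' `sum(max(F - f_min, 0)) / f_min` — a dimensionless integrated-activity
#' statistic.  Peaks are local maxima of dF/F with at least
#' `peak_min_prominence_dff` prominence, thinned to
#' `peak_min_separation_s`; `mean_peak_amplitude_dff` is the mean dF/F at
#' those peaks (`NA` when no peak is found).  `mean_dff`, the whole-trace
#' average dF/F, is also reported for users who prefer a peak-free
#' amplitude summary.
#'
#' @param trace a [calcium_trace()].
#' @param params a [calcium_params()].
#' @return A list of class `calcium_metrics`: `f_min_baseline`, `dff`,
#'   `mean_peak_amplitude_dff`, `mean_dff`, `total_activity`, `n_peaks`,
#'   `peak_indices`, `peak_times_s`, and a `params` echo.
#' @examples
#' f <- c(rep(100, 100), rep(150, 10), rep(100, 130))
#' m <- compute_metrics(calcium_trace(seq(0, by = 0.25, length.out = 240),
#'                                    f, 0.25))
#' m$total_activity   # 10 * 50 / 100 = 5
#' m$n_peaks          # 1 peak of amplitude 0.5
#' @export
compute_metrics <- function(trace, params = calcium_params()) {
  if (!inherits(trace, "calcium_trace"))
    stop_config("trace must be a calcium_trace")
  if (!inherits(params, "calcium_params"))
    stop_config("params must be a calcium_params")
  f <- trace$fluorescence
  w <- round(params$baseline_smooth_window_s / trace$frame_interval_s)
  if (w > length(f))
    stop_range("trace shorter than the baseline smoothing window")
  sm <- boxcar_smooth(f, w)
  f_min <- min(sm)
  if (f_min <= 0)
    stop_config("non-positive baseline; trace is not a valid fluorescence record")
  dff <- (f - f_min) / f_min
  total_activity <- sum(pmax(f - f_min, 0)) / f_min
  sep <- max(1L, round(params$peak_min_separation_s / trace$frame_interval_s))
  pk <- find_peaks(dff, params$peak_min_prominence_dff, sep)
  structure(list(
    f_min_baseline = f_min,
    dff = dff,
    mean_peak_amplitude_dff = if (length(pk)) mean(dff[pk]) else NA_real_,
    mean_dff = mean(dff),
    total_activity = total_activity,
    n_peaks = length(pk),
    peak_indices = pk,
    peak_times_s = trace$time_s[pk],
    params = params), class = "calcium_metrics")
}

#' @export
print.calcium_metrics <- function(x, ...) {
  cat(sprintf(
    "<calcium_metrics> baseline %.4g; %d peaks (mean amplitude %.3g dF/F); total activity %.4g\n",
    x$f_min_baseline, x$n_peaks, x$mean_peak_amplitude_dff,
    x$total_activity))
  invisible(x)
}

#' Normalize per-animal metrics to an untreated control group
#'
#' Divides every value in both groups by the mean of the control group, so
#' the control group has mean 1 and treated values are expressed as a
#' fraction of control.
#'
#' @param metric_values per-animal metric values of the treated (or any)
#'   group.
#' @param control_values per-animal metric values of the control group.
#' @return A list with `values` and `control`, both divided by
#'   `mean(control_values)`, input order preserved.
#' @examples
#' normalize_to_control(3, c(2, 4))  # treated value 1.0
#' @export
normalize_to_control <- function(metric_values, control_values) {
  if (length(control_values) == 0)
    stop_config("control_values must be non-empty")
  m <- mean(control_values)
  if (!is.finite(m) || m == 0)
    stop_config("control group mean is zero; cannot normalize")
  list(values = metric_values / m, control = control_values / m)
}

#' Extract a calcium trace from an image stream ROI
#'
#' Averages fluorescence over a region of interest in every frame, giving a
#' per-frame trace (e.g. over a cell body).  The ROI is either a rectangle
#' (`list(rows = c(r0, r1), cols = c(c0, c1))`, 1-based inclusive) or a
#' polygon (`list(polygon = <n x 2 matrix of (row, col) vertices>)`, tested
#' by even-odd crossing at pixel centers).
#'
#' @param stream an [image_stream()].
#' @param roi ROI specification as above (a JSON file with the same keys is
#'   also accepted as a path).
#' @return A [calcium_trace()] of mean ROI fluorescence per frame.
#' @export
extract_roi_trace <- function(stream, roi) {
  if (!inherits(stream, "image_stream"))
    stop_config("stream must be an image_stream")
  if (is.character(roi)) roi <- jsonlite::read_json(roi, simplifyVector = TRUE)
  d <- dim(stream$frames)
  if (!is.null(roi$rows) && !is.null(roi$cols)) {
    rows <- seq(max(1, roi$rows[1]), min(d[1], roi$rows[2]))
    cols <- seq(max(1, roi$cols[1]), min(d[2], roi$cols[2]))
    mask <- matrix(FALSE, d[1], d[2]); mask[rows, cols] <- TRUE
  } else if (!is.null(roi$polygon)) {
    poly <- matrix(unlist(roi$polygon), ncol = 2, byrow = is.list(roi$polygon))
    pr <- rep(seq_len(d[1]), times = d[2])
    pc <- rep(seq_len(d[2]), each = d[1])
    inside <- rep(FALSE, d[1] * d[2])
    n <- nrow(poly)
    jv <- n
    for (iv in seq_len(n)) {  # even-odd ray crossing, ray along +col
      yi <- poly[iv, 1]; xi <- poly[iv, 2]
      yj <- poly[jv, 1]; xj <- poly[jv, 2]
      crosses <- ((yi > pr) != (yj > pr)) &
        (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      jv <- iv
    }
    mask <- matrix(inside, d[1], d[2])
  } else stop_config("roi needs rows+cols or polygon")
  if (!any(mask)) stop_config("ROI covers no pixels")
  flat <- matrix(stream$frames, nrow = d[1] * d[2], ncol = d[3])
  f <- colMeans(flat[as.vector(mask), , drop = FALSE])
  calcium_trace((seq_len(d[3]) - 1) * stream$frame_interval_s,
                pmax(f, 0), stream$frame_interval_s)
}
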