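#' Detection parameters for transport events
#'
#' The thresholds operationalise "a visible directed run" in a kymograph:
#' a punctum must stand out from the local background, persist, and move.
#' All are configurable; defaults suit dim vesicles at signal-to-noise
#' ratios of about 5 and above.
#'
#' @param detection_threshold_sd puncta must exceed the per-column background
#'   median by this many background SDs.
#' @param min_displacement_um minimum net displacement of a run, micrometers.
#' @param min_duration_s minimum run duration, seconds.
#' @param max_gap_frames a punctum may vanish for up to this many consecutive
#'   frames (e.g. while paused or dimmed) and still continue the same event.
#' @param max_link_jump_um maximum position change per frame when linking
#'   candidate puncta across frames, micrometers.
#' @param min_candidate_separation_um candidates closer than this within one
#'   frame are merged, keeping the brightest; suppresses the multiple ragged
#'   maxima a single noisy diffraction-limited spot produces.
#' @param min_points minimum number of linked candidates in an event.
#' @param min_occupancy minimum fraction of frames between an event's first
#'   and last detection that carry a candidate.  A real vesicle is seen in
#'   nearly every frame of its run; chains of isolated noise spikes strung
#'   together through the gap tolerance are not.
#' @return An `event_params` list.
#' @export
event_params <- function(detection_threshold_sd = 3,
                         min_displacement_um = 2.0,
                         min_duration_s = 0.5,
                         max_gap_frames = 3,
                         max_link_jump_um = 0.5,
                         min_candidate_separation_um = 1.0,
                         min_points = 5,
                         min_occupancy = 0.75) {
  check_scalar(detection_threshold_sd, "detection_threshold_sd")
  check_scalar(min_displacement_um, "min_displacement_um")
  check_scalar(min_duration_s, "min_duration_s")
  if (max_gap_frames < 0) stop_config("max_gap_frames must be >= 0")
  check_scalar(max_link_jump_um, "max_link_jump_um")
  check_scalar(min_candidate_separation_um, "min_candidate_separation_um")
  if (min_points < 2) stop_config("min_points must be >= 2")
  if (min_occupancy < 0 || min_occupancy > 1)
    stop_config("min_occupancy must lie in [0, 1]")
  structure(list(detection_threshold_sd = detection_threshold_sd,
                 min_displacement_um = min_displacement_um,
                 min_duration_s = min_duration_s,
                 max_gap_frames = as.integer(max_gap_frames),
                 max_link_jump_um = max_link_jump_um,
                 min_candidate_separation_um = min_candidate_separation_um,
                 min_points = as.integer(min_points),
                 min_occupancy = min_occupancy),
            class = "event_params")
}

# Per-row candidate puncta: local column maxima above the per-column
# background threshold, refined to sub-pixel position by a 3-point parabola.
# Background per column is the temporal median (robust to a punctum passing
# through); its scale is 1.4826 * MAD of the column about that median.
row_candidates <- function(mat, k_sd, min_sep_cols = 0) {
  nc <- ncol(mat)
  bg <- apply(mat, 2, median)
  sig <- 1.4826 * apply(abs(sweep(mat, 2, bg)), 2, median)
  if (all(sig == 0) && all(sweep(mat, 2, bg) == 0)) return(NULL)  # constant
  thr <- bg + k_sd * pmax(sig, 1e-12)
  above <- sweep(mat, 2, thr, ">")
  if (nc < 3) return(list())
  left <- mat[, -c(nc - 1, nc), drop = FALSE]
  mid <- mat[, -c(1, nc), drop = FALSE]
  right <- mat[, -c(1, 2), drop = FALSE]
  ismax <- mid >= left & mid > right & above[, -c(1, nc), drop = FALSE]
  hits <- which(ismax, arr.ind = TRUE)
  if (nrow(hits) == 0) return(list())
  j <- hits[, 2] + 1L  # column in mat
  i <- hits[, 1]
  y0 <- mat[cbind(i, j - 1L)]; y1 <- mat[cbind(i, j)]; y2 <- mat[cbind(i, j + 1L)]
  den <- y0 - 2 * y1 + y2
  delta <- ifelse(den < 0, 0.5 * (y0 - y2) / den, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  # plain numeric vectors (sub-pixel column positions), one per row index
  cols_by_row <- split(j + delta, i)
  vals_by_row <- split(y1, i)
  mapply(function(cl, vl) {
    if (length(cl) < 2 || min_sep_cols <= 0) return(cl)
    o <- order(-vl)
    cl <- cl[o]
    keep <- rep(TRUE, length(cl))
    for (q in seq_along(cl)[-1])
      if (any(abs(cl[q] - cl[seq_len(q - 1)][keep[seq_len(q - 1)]]) <
              min_sep_cols)) keep[q] <- FALSE
    cl[keep]
  }, cols_by_row, vals_by_row, SIMPLIFY = FALSE)
}

#' Detect transport events in a kymograph
#'
#' Per row (frame), candidate puncta are local intensity maxima exceeding the
#' per-column background median by `detection_threshold_sd` robust SDs; the
#' background is estimated from the temporal median of each column, which
#' tolerates residual unbleached stationary puncta.  Candidates are linked
#' across frames by nearest neighbor within `max_link_jump_um` per frame,
#' tolerating up to `max_gap_frames` missed frames (so a briefly pausing or
#' blinking vesicle stays one event).  Linked tracks are kept as events when
#' their net displacement and duration reach the configured minima; velocity
#' is the slope of a least-squares position-versus-time fit and the direction
#' its sign (anterograde = away from the cell body).
#'
#' @param kymo a [kymograph()].
#' @param params an [event_params()].
#' @param restrict_to optional integer vector of kymograph columns (e.g. from
#'   [bleach_mask()]) to which detection is restricted.
#' @return A data frame of class `transport_events`, one row per event,
#'   sorted by start time: `event_id`, `t_start_s`, `t_end_s`,
#'   `pos_start_um`, `pos_end_um`, `direction`, `velocity_um_s`, `n_points`.
#' @export
detect_events <- function(kymo, params = event_params(), restrict_to = NULL) {
  if (!inherits(kymo, "kymograph")) stop_config("kymo must be a kymograph")
  if (!inherits(params, "event_params"))
    stop_config("params must be an event_params")
  mat <- kymo$matrix
  col_offset <- 0L
  if (!is.null(restrict_to)) {
    restrict_to <- sort(unique(as.integer(restrict_to)))
    if (length(restrict_to) > 0 &&
        (min(restrict_to) < 1 || max(restrict_to) > ncol(mat)))
      stop_range("restrict_to columns outside the kymograph")
    mat <- mat[, restrict_to, drop = FALSE]
    col_offset <- if (length(restrict_to)) restrict_to[1] - 1L else 0L
  }
  empty <- empty_events()
  dt <- kymo$frame_interval_s
  if (nrow(mat) * dt < params$min_duration_s) {
    warning("kymograph shorter than min_duration_s; no events detectable")
    return(empty)
  }
  if (nrow(mat) < 10)
    warning("fewer than 10 rows; background statistics are unreliable")
  if (ncol(mat) < 3) return(empty)

  cands <- row_candidates(mat, params$detection_threshold_sd,
                          params$min_candidate_separation_um /
                            kymo$position_step_um)
  if (is.null(cands) || length(cands) == 0) return(empty)

  step_um <- kymo$position_step_um
  max_gap <- params$max_gap_frames

  # active track bookkeeping: last row, last position (um), running direction
  # and an exponentially smoothed velocity (um/frame) used to extrapolate a
  # track across frames, so linking is against the predicted position
  tr_t <- list(); tr_p <- list()        # per-track row indices / positions
  last_row <- integer(0); last_pos <- numeric(0); run_dir <- numeric(0)
  run_vel <- numeric(0)
  done_t <- list(); done_p <- list()

  rows_with <- as.integer(names(cands))
  all_rows <- seq_len(nrow(mat))
  ci <- 1L
  for (t in all_rows) {
    # retire tracks that have been unseen too long
    if (length(last_row)) {
      dead <- which(t - last_row > max_gap + 1L)
      if (length(dead)) {
        done_t <- c(done_t, tr_t[dead]); done_p <- c(done_p, tr_p[dead])
        tr_t <- tr_t[-dead]; tr_p <- tr_p[-dead]
        last_row <- last_row[-dead]; last_pos <- last_pos[-dead]
        run_dir <- run_dir[-dead]; run_vel <- run_vel[-dead]
      }
    }
    if (ci > length(rows_with) || rows_with[ci] != t) next
    pos <- (cands[[ci]] - 1 + col_offset) * step_um
    ci <- ci + 1L
    nA <- length(last_row); nC <- length(pos)
    assigned_tr <- rep(FALSE, nA); assigned_cd <- rep(FALSE, nC)
    if (nA > 0 && nC > 0) {
      gap <- t - last_row
      pred <- last_pos + run_vel * gap
      dist <- abs(outer(pred, pos, "-"))
      allow <- dist <= params$max_link_jump_um * gap
      if (any(allow)) {
        pr <- which(allow, arr.ind = TRUE)
        d <- dist[pr]
        step_sign <- sign(pos[pr[, 2]] - last_pos[pr[, 1]])
        dir_change <- as.numeric(run_dir[pr[, 1]] != 0 &
                                   step_sign != 0 &
                                   step_sign != run_dir[pr[, 1]])
        ord <- order(d, dir_change, pos[pr[, 2]])
        for (o in ord) {
          a <- pr[o, 1]; c <- pr[o, 2]
          if (assigned_tr[a] || assigned_cd[c]) next
          assigned_tr[a] <- TRUE; assigned_cd[c] <- TRUE
          tr_t[[a]] <- c(tr_t[[a]], t); tr_p[[a]] <- c(tr_p[[a]], pos[c])
          step_v <- (pos[c] - last_pos[a]) / gap[a]
          run_vel[a] <- if (length(tr_t[[a]]) == 2L) step_v else
            0.5 * run_vel[a] + 0.5 * step_v
          if (pos[c] != last_pos[a]) run_dir[a] <- sign(pos[c] - last_pos[a])
          last_row[a] <- t; last_pos[a] <- pos[c]
        }
      }
    }
    new <- which(!assigned_cd)
    for (c in new) {
      tr_t[[length(tr_t) + 1L]] <- t
      tr_p[[length(tr_p) + 1L]] <- pos[c]
      last_row <- c(last_row, t); last_pos <- c(last_pos, pos[c])
      run_dir <- c(run_dir, 0); run_vel <- c(run_vel, 0)
    }
  }
  done_t <- c(done_t, tr_t); done_p <- c(done_p, tr_p)

  if (length(done_t) == 0) return(empty)
  ev <- lapply(seq_along(done_t), function(i) {
    ti <- (done_t[[i]] - 1) * dt + kymo$t0_s
    pi <- done_p[[i]]
    n <- length(ti)
    if (n < max(2L, params$min_points)) return(NULL)
    disp <- pi[n] - pi[1]
    dur <- ti[n] - ti[1]
    if (abs(disp) < params$min_displacement_um || dur < params$min_duration_s)
      return(NULL)
    spanned <- (done_t[[i]][n] - done_t[[i]][1]) + 1L
    if (n / spanned < params$min_occupancy) return(NULL)
    slope <- sum((ti - mean(ti)) * (pi - mean(pi))) / sum((ti - mean(ti))^2)
    data.frame(t_start_s = ti[1], t_end_s = ti[n],
               pos_start_um = pi[1], pos_end_um = pi[n],
               direction = if (slope >= 0) "anterograde" else "retrograde",
               velocity_um_s = slope, n_points = n)
  })
  ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(ev) || nrow(ev) == 0) return(empty)
  ev <- ev[order(ev$t_start_s), , drop = FALSE]
  ev <- cbind(event_id = seq_len(nrow(ev)), ev)
  rownames(ev) <- NULL
  class(ev) <- c("transport_events", "data.frame")
  ev
}

empty_events <- function() {
  structure(data.frame(event_id = integer(), t_start_s = numeric(),
                       t_end_s = numeric(), pos_start_um = numeric(),
                       pos_end_um = numeric(), direction = character(),
                       velocity_um_s = numeric(), n_points = integer()),
            class = c("transport_events", "data.frame"))
}

#' Summarize transport events into counts and flux
#'
#' @param events a `transport_events` data frame from [detect_events()]
#'   (an empty frame is allowed).
#' @param window_duration_s duration of the observation window, seconds.
#' @return A list of class `transport_summary`: `n_events`, `n_anterograde`,
#'   `n_retrograde`, `flux_per_min` (`n_events * 60 / window_duration_s`),
#'   `window_duration_s`.
#' @examples
#' cfg <- separated_tracks_config(2, seed = 1)
#' sim <- simulate_transport_stream(cfg)
#' k <- build_kymograph(sim$stream, neurite_path(cfg$path))
#' summarize_events(detect_events(k), window_duration_s = 50)
#' @export
summarize_events <- function(events, window_duration_s) {
  check_scalar(window_duration_s, "window_duration_s")
  n <- nrow(events)
  na <- sum(events$direction == "anterograde")
  structure(list(n_events = n, n_anterograde = na, n_retrograde = n - na,
                 flux_per_min = n * 60 / window_duration_s,
                 window_duration_s = window_duration_s),
            class = "transport_summary")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf(
    "<transport_summary> %d events (%d anterograde, %d retrograde) in %.3g s; flux %.3g /min\n",
    x$n_events, x$n_anterograde, x$n_retrograde, x$window_duration_s,
    x$flux_per_min))
  invisible(x)
}
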