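#' Configuration for the transport-stream simulator
#'
#' Describes a photobleached neurite segment imaged continuously at a single
#' confocal plane, through which dim punctate vesicles move bidirectionally
#' at roughly constant velocity with occasional pauses.  Defaults mirror the
#' acquisition regime the package targets: 50 s streams at 100 ms/frame.
#'
#' Each vesicle is assigned a direction (anterograde with probability
#' `direction_mix`), a speed drawn uniformly from `velocity_range_um_s`, and
#' an entry time drawn uniformly over the stream (unless `entry_times_s` is
#' given).  Anterograde vesicles enter at the cell-body end of the path
#' (position 0) and move toward increasing position; retrograde vesicles
#' enter at the distal end and move back.  In each frame a vesicle pauses
#' with probability `pause_prob_per_frame` and otherwise advances by
#' `v * frame_interval_s`; it leaves the simulation when it exits the path.
#'
#' The photobleach is applied to the pre-existing stationary background only:
#' pixels whose projection onto the path falls inside `bleach_window` (and
#' within `bleach_halfwidth_px` of the path) have their background multiplied
#' by `bleach_factor`.  Moving vesicles are rendered afterwards at full
#' amplitude, as in the real experiment where cargo entering after the bleach
#' is unbleached.
#'
#' @param duration_s stream duration, seconds.
#' @param frame_interval_s frame interval, seconds.
#' @param pixel_size_um pixel size, micrometers per pixel.
#' @param field_shape integer `(rows, cols)` of the imaged field.
#' @param path polyline of `(row, col)` points (1-based pixel coordinates),
#'   ordered from the cell-body end outward.
#' @param n_vesicles number of vesicles launched during the stream.
#' @param velocity_range_um_s `(min, max)` speed, micrometers/second.
#' @param direction_mix fraction of vesicles moving anterograde, in `[0, 1]`.
#' @param pause_prob_per_frame per-frame pause probability.
#' @param vesicle_amplitude peak intensity a vesicle adds above background.
#' @param vesicle_sigma_um Gaussian spot width (sd), micrometers.
#' @param background_level stationary background intensity before bleaching.
#' @param bleach_window `(start_um, end_um)` along the path, half-open.
#' @param bleach_factor multiplicative attenuation in `(0, 1]`.
#' @param bleach_halfwidth_px half-width of the bleached corridor, pixels.
#' @param read_noise_sd additive Gaussian read noise sd (0 disables).
#' @param shot_noise logical; apply Poisson shot noise to the noiseless image.
#' @param reversal_prob_per_frame per-frame probability that a vesicle
#'   reverses direction; 0 by default (directions are fixed per vesicle).
#' @param entry_times_s optional fixed entry times, length `n_vesicles`.
#' @param velocities_um_s optional fixed speeds (unsigned), length `n_vesicles`.
#' @param directions optional fixed directions, `"anterograde"`/`"retrograde"`.
#' @param seed integer seed; mandatory, never taken from global RNG state.
#' @return A `transport_sim_config` list.
#' @seealso [simulate_transport_stream()]
#' @export
transport_sim_config <- function(seed,
                                 duration_s = 50,
                                 frame_interval_s = 0.1,
                                 pixel_size_um = 0.1,
                                 field_shape = c(16L, 130L),
                                 path = rbind(c(8, 10), c(8, 120)),
                                 n_vesicles = 8,
                                 velocity_range_um_s = c(1.0, 3.0),
                                 direction_mix = 0.5,
                                 pause_prob_per_frame = 0.05,
                                 vesicle_amplitude = 50,
                                 vesicle_sigma_um = 0.15,
                                 background_level = 20,
                                 bleach_window = c(0, 11),
                                 bleach_factor = 0.3,
                                 bleach_halfwidth_px = 3,
                                 read_noise_sd = 2,
                                 shot_noise = TRUE,
                                 reversal_prob_per_frame = 0,
                                 entry_times_s = NULL,
                                 velocities_um_s = NULL,
                                 directions = NULL) {
  if (missing(seed)) stop_config("seed is mandatory")
  check_scalar(duration_s, "duration_s")
  check_scalar(frame_interval_s, "frame_interval_s")
  check_scalar(pixel_size_um, "pixel_size_um")
  path <- as_vertices(path)
  if (n_vesicles < 0) stop_config("n_vesicles must be >= 0")
  if (length(velocity_range_um_s) != 2L || any(velocity_range_um_s <= 0) ||
      velocity_range_um_s[1] > velocity_range_um_s[2])
    stop_config("velocity_range_um_s must be positive (min, max) with min <= max")
  if (direction_mix < 0 || direction_mix > 1)
    stop_config("direction_mix must lie in [0, 1]")
  if (bleach_factor <= 0 || bleach_factor > 1)
    stop_config("bleach_factor must lie in (0, 1]")
  path_len_um <- path_cumlen(path)[nrow(path)] * pixel_size_um
  if (length(bleach_window) != 2L || bleach_window[1] > bleach_window[2])
    stop_config("bleach_window must be (start_um, end_um) with start <= end")
  if (bleach_window[1] < 0 || bleach_window[2] > path_len_um + 1e-9)
    stop_config("bleach_window lies outside the path extent (0, ",
                signif(path_len_um, 4), " um)")
  if (!is.null(entry_times_s) && length(entry_times_s) != n_vesicles)
    stop_config("entry_times_s must have length n_vesicles")
  if (!is.null(velocities_um_s) && length(velocities_um_s) != n_vesicles)
    stop_config("velocities_um_s must have length n_vesicles")
  if (!is.null(directions)) {
    if (length(directions) != n_vesicles ||
        !all(directions %in% c("anterograde", "retrograde")))
      stop_config("directions must be n_vesicles values of 'anterograde'/'retrograde'")
  }
  structure(list(
    duration_s = duration_s, frame_interval_s = frame_interval_s,
    pixel_size_um = pixel_size_um, field_shape = as.integer(field_shape),
    path = path, n_vesicles = as.integer(n_vesicles),
    velocity_range_um_s = velocity_range_um_s, direction_mix = direction_mix,
    pause_prob_per_frame = pause_prob_per_frame,
    vesicle_amplitude = vesicle_amplitude, vesicle_sigma_um = vesicle_sigma_um,
    background_level = background_level, bleach_window = bleach_window,
    bleach_factor = bleach_factor, bleach_halfwidth_px = bleach_halfwidth_px,
    read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
    reversal_prob_per_frame = reversal_prob_per_frame,
    entry_times_s = entry_times_s, velocities_um_s = velocities_um_s,
    directions = directions, seed = as.integer(seed)),
    class = "transport_sim_config")
}

#' Simulate a photobleached-neurite transport image stream
#'
#' Renders each vesicle in each frame as an isotropic 2D Gaussian spot
#' evaluated analytically at pixel centers (no stamp shifting, so sub-pixel
#' motion is alias-free), on top of a stationary background attenuated by
#' the photobleach inside the bleach window.  Poisson shot noise and
#' Gaussian read noise are applied last.  Identical config (including seed)
#' gives bit-identical output.
#'
#' @param config a [transport_sim_config()].
#' @return A list with components
#'   \describe{
#'     \item{stream}{an [image_stream()].}
#'     \item{tracks}{data frame of per-vesicle ground truth: `vesicle_id`,
#'       `entry_time_s`, `direction`, `mean_velocity_um_s` (signed underlying
#'       velocity), `paused_frames`, `first_frame`, `last_frame`,
#'       `net_displacement_um` (realised, signed).}
#'     \item{positions_um}{`n_frames x n_vesicles` matrix of ground-truth
#'       positions along the path (um from the cell-body end), `NA` when the
#'       vesicle is not in the imaged window.}
#'   }
#' @examples
#' sim <- simulate_transport_stream(transport_sim_config(seed = 1,
#'   duration_s = 5, n_vesicles = 2))
#' sim$stream
#' sim$tracks
#' @export
simulate_transport_stream <- function(config) {
  if (!inherits(config, "transport_sim_config"))
    stop_config("config must be a transport_sim_config")
  cfg <- config
  nfr <- as.integer(round(cfg$duration_s / cfg$frame_interval_s))
  rows <- cfg$field_shape[1]; cols <- cfg$field_shape[2]
  dt <- cfg$frame_interval_s
  px <- cfg$pixel_size_um
  L_um <- path_cumlen(cfg$path)[nrow(cfg$path)] * px
  nv <- cfg$n_vesicles

  withr::with_seed(cfg$seed, {
    dirs <- if (!is.null(cfg$directions)) cfg$directions else
      ifelse(runif(nv) < cfg$direction_mix, "anterograde", "retrograde")
    speeds <- if (!is.null(cfg$velocities_um_s)) cfg$velocities_um_s else
      runif(nv, cfg$velocity_range_um_s[1], cfg$velocity_range_um_s[2])
    entries <- if (!is.null(cfg$entry_times_s)) cfg$entry_times_s else
      runif(nv, 0, cfg$duration_s)

    tvec <- (seq_len(nfr) - 1) * dt
    pos <- matrix(NA_real_, nfr, max(nv, 1L))
    paused_frames <- integer(nv)
    if (nv > 0) for (v in seq_len(nv)) {
      sgn <- if (dirs[v] == "anterograde") 1 else -1
      s0 <- if (sgn > 0) 0 else L_um
      f0 <- which(tvec >= entries[v])[1]
      if (is.na(f0)) next
      act <- f0:nfr
      paused <- rbinom(length(act), 1L, cfg$pause_prob_per_frame)
      paused[1] <- 0L
      sg <- rep(sgn, length(act))
      if (cfg$reversal_prob_per_frame > 0) {
        flip <- rbinom(length(act), 1L, cfg$reversal_prob_per_frame)
        sg <- sgn * cumprod(ifelse(flip == 1L, -1, 1))
      }
      step <- c(0, (1 - paused[-1]) * speeds[v] * dt * sg[-length(sg)])
      s <- s0 + cumsum(step)
      inside <- s >= 0 & s <= L_um
      first_exit <- which(!inside)[1]
      if (!is.na(first_exit) && first_exit <= length(act))
        inside[first_exit:length(act)] <- FALSE
      pos[act[inside], v] <- s[inside]
      paused_frames[v] <- sum(paused[inside])
    }

    # --- stationary background with photobleached corridor ---
    bg <- matrix(cfg$background_level, rows, cols)
    proj <- path_pixel_projection(cfg$path, c(rows, cols))
    in_corridor <- proj$dist_px <= cfg$bleach_halfwidth_px &
      proj$arc_px * px >= cfg$bleach_window[1] &
      proj$arc_px * px < cfg$bleach_window[2]
    bg[in_corridor] <- bg[in_corridor] * cfg$bleach_factor

    frames <- array(rep(bg, nfr), dim = c(rows, cols, nfr))

    # --- analytic Gaussian rendering of every (vesicle, frame) presence ---
    sigma_px <- cfg$vesicle_sigma_um / px
    R <- ceiling(4 * sigma_px)
    off_dr <- rep(-R:R, times = 2 * R + 1)
    off_dc <- rep(-R:R, each = 2 * R + 1)
    no <- length(off_dr)
    # one vesicle at a time: its patches touch distinct pixels per frame, so
    # plain indexed addition is collision-free (vesicles overlap additively
    # because each loop pass adds onto the running stack)
    if (nv > 0) for (v in seq_len(nv)) {
      fr <- which(!is.na(pos[, v]))
      if (length(fr) == 0) next
      ctr <- path_point(cfg$path, pos[fr, v] / px)
      np <- length(fr)
      rr <- rep(round(ctr[, 1]), each = no) + rep(off_dr, times = np)
      cc <- rep(round(ctr[, 2]), each = no) + rep(off_dc, times = np)
      val <- cfg$vesicle_amplitude *
        exp(-((rr - rep(ctr[, 1], each = no))^2 +
                (cc - rep(ctr[, 2], each = no))^2) / (2 * sigma_px^2))
      keep <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
      lin <- (rep(fr, each = no)[keep] - 1) * (rows * cols) +
        (cc[keep] - 1) * rows + rr[keep]
      frames[lin] <- frames[lin] + val[keep]
    }

    if (cfg$shot_noise)
      frames[] <- rpois(length(frames), lambda = pmax(frames, 0))
    if (cfg$read_noise_sd > 0)
      frames[] <- frames + rnorm(length(frames), 0, cfg$read_noise_sd)
  })

  realised <- function(v) {
    p <- pos[, v]
    ok <- which(!is.na(p))
    if (length(ok) < 2) return(c(NA_real_, NA_integer_, NA_integer_))
    c(p[ok[length(ok)]] - p[ok[1]], ok[1], ok[length(ok)])
  }
  tracks <- if (nv > 0) {
    rl <- t(vapply(seq_len(nv), realised, numeric(3)))
    data.frame(
      vesicle_id = seq_len(nv),
      entry_time_s = entries,
      direction = dirs,
      mean_velocity_um_s = ifelse(dirs == "anterograde", 1, -1) * speeds,
      paused_frames = paused_frames,
      first_frame = as.integer(rl[, 2]),
      last_frame = as.integer(rl[, 3]),
      net_displacement_um = rl[, 1])
  } else {
    data.frame(vesicle_id = integer(), entry_time_s = numeric(),
               direction = character(), mean_velocity_um_s = numeric(),
               paused_frames = integer(), first_frame = integer(),
               last_frame = integer(), net_displacement_um = numeric())
  }

  list(stream = image_stream(frames, dt, px),
       tracks = tracks,
       positions_um = pos[, seq_len(max(nv, 0L)), drop = FALSE])
}
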