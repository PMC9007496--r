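#' Define a two-group in-silico experiment
#'
#' Describes a two-group comparison (e.g. untreated versus drug-treated
#' animals): per-group simulator configurations, group sizes, the metric to
#' compare, and a single master seed from which every per-animal seed is
#' derived (`seed + animal index`, group B offset by the size of group A),
#' so a report is reproducible from its own echoed configuration.
#'
#' @param config_a,config_b per-group simulator configurations
#'   ([transport_sim_config()] or [calcium_sim_config()]); their `seed`
#'   fields are overridden by the derived per-animal seeds.
#' @param n_animals_a,n_animals_b animals per group, each `>= 3`.
#' @param comparison_metric one of `"n_events"`, `"mean_peak_amplitude_dff"`,
#'   `"total_activity"`, `"f_min_baseline"`.
#' @param seed master integer seed.
#' @param label_a,label_b group names.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(config_a, config_b,
                              n_animals_a, n_animals_b,
                              comparison_metric, seed,
                              label_a = "control", label_b = "treated") {
  metrics <- c("n_events", "mean_peak_amplitude_dff", "total_activity",
               "f_min_baseline")
  if (!is.character(comparison_metric) || length(comparison_metric) != 1 ||
      !comparison_metric %in% metrics)
    stop_config("comparison_metric must be one of: ",
                paste(metrics, collapse = ", "))
  if (n_animals_a < 3 || n_animals_b < 3)
    stop_config("each group needs at least 3 animals")
  if (missing(seed)) stop_config("seed is mandatory")
  structure(list(label_a = label_a, label_b = label_b,
                 n_animals_a = as.integer(n_animals_a),
                 n_animals_b = as.integer(n_animals_b),
                 config_a = config_a, config_b = config_b,
                 comparison_metric = comparison_metric,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

animal_seeds <- function(design) {
  list(a = design$seed + seq_len(design$n_animals_a),
       b = design$seed + design$n_animals_a + seq_len(design$n_animals_b))
}

finish_report <- function(design, table, extra = list()) {
  metric <- table$metric
  grp <- table$group
  screen_a <- thompson_tau_screen(metric[grp == design$label_a])
  screen_b <- thompson_tau_screen(metric[grp == design$label_b])
  test <- t_test_two_tailed(screen_a$retained, screen_b$retained,
                            variant = "pooled")
  structure(c(list(metrics = table,
                   outlier_screens = list(a = screen_a, b = screen_b),
                   t_test = test,
                   comparison_metric = design$comparison_metric,
                   design = design,
                   seed = design$seed,
                   package_version = as.character(packageVersion("kymoflux"))),
              extra),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s: %s (n=%d) vs %s (n=%d)\n",
              x$comparison_metric,
              x$design$label_a, x$design$n_animals_a,
              x$design$label_b, x$design$n_animals_b))
  agg <- aggregate(metric ~ group, x$metrics, function(v)
    c(mean = mean(v), sd = sd(v)))
  print(agg)
  print(x$t_test)
  invisible(x)
}

#' Run a two-group transport experiment in silico
#'
#' For every simulated animal: image stream, kymograph over the full stream,
#' event detection restricted to the photobleached segment, and the event
#' count.  Each group is then screened for outliers with
#' [thompson_tau_screen()] and the cleaned groups compared with a pooled
#' two-tailed [t_test_two_tailed()].  Deterministic given the design seed.
#'
#' @param design an [experiment_design()] with `transport_sim_config`
#'   configurations and `comparison_metric = "n_events"`.
#' @param params an [event_params()].
#' @return A `run_report`: per-animal `metrics` table (group, animal, seed,
#'   `n_events`, `n_anterograde`, `n_retrograde`, `flux_per_min`), both
#'   outlier screens, the t-test, the design echo, and the package version.
#' @export
run_transport_experiment <- function(design, params = event_params()) {
  if (!inherits(design, "experiment_design"))
    stop_config("design must be an experiment_design")
  if (design$comparison_metric != "n_events")
    stop_config("transport experiments compare n_events")
  for (cfg in list(design$config_a, design$config_b))
    if (!inherits(cfg, "transport_sim_config"))
      stop_config("both configs must be transport_sim_config objects")
  seeds <- animal_seeds(design)
  one <- function(cfg, seed) {
    cfg$seed <- as.integer(seed)
    sim <- simulate_transport_stream(cfg)
    path <- neurite_path(cfg$path)
    kym <- build_kymograph(sim$stream, path)
    ev <- detect_events(kym, params,
                        restrict_to = bleach_mask(kym, cfg$bleach_window))
    summarize_events(ev, cfg$duration_s)
  }
  rows <- list()
  for (g in c("a", "b")) {
    cfg <- if (g == "a") design$config_a else design$config_b
    lab <- if (g == "a") design$label_a else design$label_b
    for (i in seq_along(seeds[[g]])) {
      sm <- one(cfg, seeds[[g]][i])
      rows[[length(rows) + 1L]] <- data.frame(
        group = lab, animal = i, seed = seeds[[g]][i],
        n_events = sm$n_events, n_anterograde = sm$n_anterograde,
        n_retrograde = sm$n_retrograde, flux_per_min = sm$flux_per_min)
    }
  }
  tab <- do.call(rbind, rows)
  tab$metric <- tab$n_events
  finish_report(design, tab, extra = list(event_params = params))
}

#' Run a two-group calcium-imaging experiment in silico
#'
#' For every simulated animal: calcium trace and [compute_metrics()]; the
#' chosen metric is then normalized to the group-A mean
#' ([normalize_to_control()]), screened per group with
#' [thompson_tau_screen()], and compared with a pooled two-tailed t-test.
#'
#' @param design an [experiment_design()] with `calcium_sim_config`
#'   configurations and a calcium `comparison_metric`.
#' @param params a [calcium_params()].
#' @return A `run_report`; the per-animal table carries the raw and
#'   normalized metric plus `n_samples` per trace, and the report records
#'   `frames_per_trace`.
#' @export
run_calcium_experiment <- function(design, params = calcium_params()) {
  if (!inherits(design, "experiment_design"))
    stop_config("design must be an experiment_design")
  if (design$comparison_metric == "n_events")
    stop_config("calcium experiments compare a calcium metric, not n_events")
  for (cfg in list(design$config_a, design$config_b))
    if (!inherits(cfg, "calcium_sim_config"))
      stop_config("both configs must be calcium_sim_config objects")
  seeds <- animal_seeds(design)
  one <- function(cfg, seed) {
    cfg$seed <- as.integer(seed)
    sim <- simulate_calcium_trace(cfg)
    m <- compute_metrics(sim$trace, params)
    data.frame(raw = m[[design$comparison_metric]],
               n_samples = length(sim$trace$fluorescence))
  }
  rows <- list()
  for (g in c("a", "b")) {
    cfg <- if (g == "a") design$config_a else design$config_b
    lab <- if (g == "a") design$label_a else design$label_b
    for (i in seq_along(seeds[[g]])) {
      r <- one(cfg, seeds[[g]][i])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(group = lab, animal = i, seed = seeds[[g]][i]), r)
    }
  }
  tab <- do.call(rbind, rows)
  if (anyNA(tab$raw))
    stop_config("comparison metric is NA for some animals ",
                "(no peaks found); choose another metric or adjust params")
  norm <- normalize_to_control(tab$raw[tab$group == design$label_b],
                               tab$raw[tab$group == design$label_a])
  tab$metric <- NA_real_
  tab$metric[tab$group == design$label_a] <- norm$control
  tab$metric[tab$group == design$label_b] <- norm$values
  finish_report(design, tab,
                extra = list(calcium_params = params,
                             frames_per_trace = unique(tab$n_samples)))
}

#' Benchmark scene: well-separated constant-velocity tracks
#'
#' A transport-simulator configuration carrying exactly `k` vesicles whose
#' runs occupy disjoint time slots of the stream, so each appears in the
#' kymograph as an isolated straight line.  Used to measure count, direction
#' and velocity recovery against ground truth.
#'
#' @param k number of tracks, `0 <= k <= 6`.
#' @param seed integer seed (velocities and directions are still drawn).
#' @param snr spot amplitude divided by the read-noise SD.
#' @param noise logical; disable for noiseless oracle checks.
#' @return A [transport_sim_config()] for a 50 s stream at 100 ms/frame on a
#'   10 um path.
#' @export
separated_tracks_config <- function(k, seed, snr = 5, noise = TRUE) {
  if (k < 0 || k > 6) stop_config("k must be between 0 and 6")
  amp <- 50
  slots <- if (k > 0) (seq_len(k) - 1) * (50 / k) + 0.5 else numeric(0)
  transport_sim_config(
    seed = seed,
    duration_s = 50, frame_interval_s = 0.1, pixel_size_um = 0.1,
    field_shape = c(12L, 120L),
    path = rbind(c(6, 10), c(6, 110)),
    n_vesicles = k,
    velocity_range_um_s = c(1.5, 3.0),
    pause_prob_per_frame = 0,
    vesicle_amplitude = amp,
    vesicle_sigma_um = 0.15,
    background_level = 20,
    bleach_window = c(0, 10),
    bleach_factor = 0.3,
    read_noise_sd = if (noise) amp / snr else 0,
    shot_noise = FALSE,
    entry_times_s = slots)
}
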