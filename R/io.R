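# Reading and writing the package's on-disk formats: multi-page 16-bit TIFF
# for image streams and kymographs (with a JSON sidecar carrying the
# calibrations), CSV for traces/tracks/events, JSON for configs and reports.

#' Write an image stream as a multi-page 16-bit TIFF
#'
#' One grayscale page per frame; intensities are rounded and clipped to
#' `[0, 65535]`.  Calibrations (frame interval, pixel size) go to a JSON
#' sidecar next to the TIFF (`<file>.json`).
#'
#' @param stream an [image_stream()].
#' @param file output path (`.tif`).
#' @return `file`, invisibly.
#' @export
write_image_stream <- function(stream, file) {
  if (!inherits(stream, "image_stream"))
    stop_config("stream must be an image_stream")
  pages <- lapply(seq_len(n_frames(stream)), function(i)
    pmin(pmax(round(stream$frames[, , i]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  jsonlite::write_json(
    list(frame_interval_s = stream$frame_interval_s,
         pixel_size_um = stream$pixel_size_um,
         n_frames = n_frames(stream)),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read an image stream from a multi-page TIFF
#'
#' @param file TIFF path written by [write_image_stream()]; the JSON sidecar
#'   must be present unless both calibrations are supplied.
#' @param frame_interval_s,pixel_size_um calibrations, overriding the sidecar.
#' @return An [image_stream()] with intensities on the original 0-65535 scale.
#' @export
read_image_stream <- function(file, frame_interval_s = NULL,
                              pixel_size_um = NULL) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(file, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(frame_interval_s)) frame_interval_s <- meta$frame_interval_s
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  }
  if (is.null(frame_interval_s) || is.null(pixel_size_um))
    stop_config("no sidecar metadata; supply frame_interval_s and pixel_size_um")
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_stream(frames * 65535, frame_interval_s, pixel_size_um)
}

#' Write ground-truth tracks
#'
#' Long-format CSV (one row per vesicle per frame it is visible) plus a JSON
#' per-vesicle summary.
#'
#' @param sim result of [simulate_transport_stream()].
#' @param csv_file,json_file output paths.
#' @return `csv_file`, invisibly.
#' @export
write_ground_truth <- function(sim, csv_file, json_file = NULL) {
  pos <- sim$positions_um
  idx <- which(!is.na(pos), arr.ind = TRUE)
  long <- data.frame(vesicle_id = idx[, 2], frame = idx[, 1],
                     position_um = pos[idx])
  long <- long[order(long$vesicle_id, long$frame), ]
  write.csv(long, csv_file, row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(sim$tracks, json_file, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(csv_file)
}

#' Write / read a calcium trace as two-column CSV
#'
#' Columns `time_s`, `fluorescence`.
#'
#' @param trace a [calcium_trace()].
#' @param file CSV path.
#' @return `file` (write) or a [calcium_trace()] (read).
#' @export
write_calcium_trace <- function(trace, file) {
  if (!inherits(trace, "calcium_trace"))
    stop_config("trace must be a calcium_trace")
  write.csv(data.frame(time_s = trace$time_s,
                       fluorescence = trace$fluorescence),
            file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_calcium_trace
#' @export
read_calcium_trace <- function(file) {
  d <- read.csv(file)
  if (!all(c("time_s", "fluorescence") %in% names(d)))
    stop_config("trace CSV needs columns time_s and fluorescence")
  calcium_trace(d$time_s, d$fluorescence,
                frame_interval_s = median(diff(d$time_s)))
}

#' Write a kymograph to disk
#'
#' Writes the raw matrix as CSV, a 16-bit TIFF, and a PNG rendering with
#' time running downward and position rightward (inverted grayscale, so
#' bright vesicles appear as dark traces on a light background, the usual
#' presentation).  Calibrations go to a JSON sidecar of the CSV.
#'
#' @param kymo a [kymograph()].
#' @param basename output path without extension.
#' @return `basename`, invisibly.
#' @export
write_kymograph <- function(kymo, basename) {
  if (!inherits(kymo, "kymograph")) stop_config("kymo must be a kymograph")
  write.table(kymo$matrix, paste0(basename, ".csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(frame_interval_s = kymo$frame_interval_s,
         position_step_um = kymo$position_step_um, t0_s = kymo$t0_s),
    paste0(basename, ".csv.json"), auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF(pmin(pmax(round(kymo$matrix), 0), 65535) / 65535,
                  paste0(basename, ".tif"), bits.per.sample = 16L)
  rng <- range(kymo$matrix)
  scaled <- if (diff(rng) > 0) (kymo$matrix - rng[1]) / diff(rng) else
    kymo$matrix * 0
  png::writePNG(1 - scaled, paste0(basename, ".png"))
  invisible(basename)
}

#' Read a kymograph written by [write_kymograph()]
#' @param csv_file the `.csv` path (its `.json` sidecar must sit next to it).
#' @return A [kymograph()].
#' @export
read_kymograph <- function(csv_file) {
  m <- as.matrix(read.csv(csv_file, header = FALSE))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(csv_file, ".json"),
                              simplifyVector = TRUE)
  kymograph(m, meta$frame_interval_s, meta$position_step_um, meta$t0_s)
}

#' Write detected events and their summary
#'
#' @param events a `transport_events` data frame.
#' @param summary a `transport_summary`.
#' @param csv_file,json_file output paths.
#' @return `csv_file`, invisibly.
#' @export
write_events <- function(events, csv_file, summary = NULL,
                         json_file = NULL) {
  write.csv(as.data.frame(events), csv_file, row.names = FALSE)
  if (!is.null(summary) && !is.null(json_file))
    jsonlite::write_json(unclass(summary), json_file, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_file)
}

#' Load a simulator configuration from JSON
#'
#' Keys mirror the arguments of [transport_sim_config()] /
#' [calcium_sim_config()]; `type` selects which (`"transport"` or
#' `"calcium"`, inferred from the fields when omitted).
#'
#' @param file JSON path.
#' @param type `"transport"`, `"calcium"`, or `NULL` to infer.
#' @return A simulator configuration object.
#' @export
read_sim_config <- function(file, type = NULL) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(type))
    type <- if (!is.null(raw$n_vesicles) || !is.null(raw$path))
      "transport" else "calcium"
  if (!is.null(raw$path)) raw$path <- matrix(unlist(raw$path), ncol = 2,
                                             byrow = is.list(raw$path))
  fun <- if (type == "transport") transport_sim_config else calcium_sim_config
  do.call(fun, raw[names(raw) %in% names(formals(fun))])
}

#' Write a run report as JSON plus a tidy metrics CSV
#'
#' @param report a `run_report`.
#' @param json_file,csv_file output paths (either may be `NULL`).
#' @return `json_file`, invisibly.
#' @export
write_run_report <- function(report, json_file, csv_file = NULL) {
  if (!inherits(report, "run_report"))
    stop_config("report must be a run_report")
  if (!is.null(csv_file))
    write.csv(report$metrics, csv_file, row.names = FALSE)
  design <- report$design
  design$config_a$path <- unclass(design$config_a$path)
  design$config_b$path <- unclass(design$config_b$path)
  out <- list(
    comparison_metric = report$comparison_metric,
    seed = report$seed,
    package_version = report$package_version,
    metrics = report$metrics,
    outlier_screens = lapply(report$outlier_screens, unclass),
    t_test = list(t_statistic = report$t_test$t_statistic,
                  degrees_of_freedom = report$t_test$degrees_of_freedom,
                  p_value = report$t_test$p_value,
                  variant = report$t_test$variant),
    design = lapply(design[c("label_a", "label_b", "n_animals_a",
                             "n_animals_b", "comparison_metric", "seed")],
                    identity),
    config_a = lapply(unclass(design$config_a), identity),
    config_b = lapply(unclass(design$config_b), identity))
  jsonlite::write_json(out, json_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(json_file)
}
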