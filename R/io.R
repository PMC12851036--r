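## Plain-text formats: recording CSV (+ annotations JSON sidecar),
## cohort manifest, Hess chart / diagnosis JSON, pipeline config YAML.
## Signals are small (minutes x 50 Hz x 3 channels), so inspectable
## text formats are preferred over binary containers.

#' Read / write a strain recording
#'
#' Recording CSV has header `t,ch0,ch45,ch90` (seconds and
#' dimensionless relative resistance change) and round-trips at full
#' float precision. The sampling rate is inferred from `t` and
#' validated uniform. Annotations live in a JSON sidecar (same path
#' with extension `.events.json`); a missing sidecar yields an empty
#' annotation list.
#'
#' @param path CSV file path.
#' @param annotationsPath sidecar path; default derives from `path`.
#' @return `readRecording` returns a [StrainRecording-class].
#' @export
readRecording <- function(path, annotationsPath = .sidecarPath(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", channelNames())
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0L, "recording CSV is missing column '%s'",
          if (length(miss)) miss[1L] else "")
  tt <- df$t
  .assert(length(tt) >= 2L, "recording must have at least 2 samples")
  dt <- diff(tt)
  fs <- 1 / stats::median(dt)
  bad <- which(abs(dt - 1 / fs) > 1e-6 / fs)
  .assert(length(bad) == 0L,
          "non-uniform timestamps at index %d (dt = %.9g, expected %.9g)",
          if (length(bad)) bad[1L] + 1L else 0L,
          if (length(bad)) dt[bad[1L]] else 0, 1 / fs)
  ann <- emptyAnnotations()
  meta <- list()
  if (!is.null(annotationsPath) && file.exists(annotationsPath)) {
    side <- jsonlite::read_json(annotationsPath, simplifyVector = TRUE)
    if (length(side$events))
      ann <- gazeEvents(side$events$onset, side$events$direction,
                        angle = side$events$angle_deg,
                        hold_duration = side$events$hold_duration,
                        ramp_time = side$events$ramp_time)
    if (length(side$subject_meta)) meta <- as.list(side$subject_meta)
  }
  ## time vector is regenerated on the exact uniform grid
  strainRecording(tt[1L] + (seq_along(tt) - 1L) / fs,
                  as.matrix(df[, channelNames()]), fs,
                  annotations = ann, subjectMeta = meta)
}

.sidecarPath <- function(path) sub("\\.csv$", ".events.json", path)

#' @param recording a [StrainRecording-class].
#' @rdname readRecording
#' @return `writeRecording` invisibly returns `path`.
#' @export
writeRecording <- function(recording, path,
                           annotationsPath = .sidecarPath(path)) {
  df <- data.frame(t = recording@time, recording@channels,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(annotationsPath)) {
    ann <- recording@annotations
    jsonlite::write_json(
      list(events = ann[, c("onset", "hold_duration", "direction",
                            "angle_deg", "ramp_time", "kind")],
           subject_meta = recording@subjectMeta),
      annotationsPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write / read a cohort manifest
#'
#' The manifest JSON lists, per subject, the recording CSV and
#' annotation sidecar paths plus the subject metadata; it makes a
#' simulated cohort reloadable as a unit.
#'
#' @param recordings list of [StrainRecording-class].
#' @param dir output directory (created if needed).
#' @return `writeCohort` invisibly returns the manifest path;
#'   `readCohort` returns the list of recordings.
#' @export
writeCohort <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(recordings), function(i) {
    id <- recordings[[i]]@subjectMeta$subject_id
    if (is.null(id)) id <- sprintf("S%02d", i)
    f <- file.path(dir, paste0(id, ".csv"))
    writeRecording(recordings[[i]], f)
    list(subject_id = id, recording = basename(f),
         annotations = basename(.sidecarPath(f)),
         subject_meta = recordings[[i]]@subjectMeta)
  })
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(format = "gazeStrain-cohort-1",
                            subjects = entries),
                       mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mf)
}

#' @param manifestPath path to `manifest.json`.
#' @rdname writeCohort
#' @export
readCohort <- function(manifestPath) {
  mf <- jsonlite::read_json(manifestPath, simplifyVector = FALSE)
  .assert(identical(mf$format, "gazeStrain-cohort-1"),
          "not a cohort manifest: %s", manifestPath)
  dir <- dirname(manifestPath)
  lapply(mf$subjects, function(s)
    readRecording(file.path(dir, s$recording),
                  file.path(dir, s$annotations)))
}

#' Write / read a Hess chart as JSON
#'
#' @param chart a [HessChart-class].
#' @param path JSON file path.
#' @return `readHessChart` returns the [HessChart-class];
#'   `writeHessChart` invisibly returns `path`.
#' @export
writeHessChart <- function(chart, path) {
  p <- chart@points
  jsonlite::write_json(list(
    format = "gazeStrain-hess-1",
    eye = chart@eye, fixating_eye = chart@fixatingEye,
    geometry = list(viewing_distance = chart@geometry@viewingDistance,
                    grid_step = chart@geometry@gridStep,
                    inner_field_half_width = chart@geometry@innerFieldHalfWidth),
    points = lapply(seq_len(nrow(p)), function(i) list(
      position_id = p$positionId[i], position = p$position[i],
      target_deg = c(p$targetH[i], p$targetV[i]),
      measured_deg = c(p$measuredH[i], p$measuredV[i]),
      n = p$n[i]))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeHessChart
#' @export
readHessChart <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  .assert(identical(j$format, "gazeStrain-hess-1"),
          "not a Hess chart file: %s", path)
  geom <- hessGeometry(j$geometry$viewing_distance, j$geometry$grid_step,
                       j$geometry$inner_field_half_width)
  m <- do.call(rbind, lapply(j$points, function(pt)
    data.frame(position = pt$position,
               h = pt$measured_deg[[1]], v = pt$measured_deg[[2]],
               stringsAsFactors = FALSE)))
  buildHessChart(m, eye = j$eye, fixatingEye = j$fixating_eye,
                 geometry = geom)
}

#' Write a diagnosis report as JSON
#'
#' @param report a [DiagnosisReport-class].
#' @param path JSON file path.
#' @return invisibly, `path`.
#' @export
writeDiagnosisReport <- function(report, path) {
  ua <- report@metrics$underactions
  jsonlite::write_json(list(
    format = "gazeStrain-diagnosis-1",
    paralytic = report@paralytic,
    paretic_eye = report@pareticEye,
    horizontal_deviation = report@horizontalDeviation,
    vertical_deviation = report@verticalDeviation,
    implicated_muscles = as.list(report@implicatedMuscles),
    metrics = list(
      area_left = report@metrics$areaLeft,
      area_right = report@metrics$areaRight,
      area_ratio = report@metrics$areaRatio,
      mean_shift_left = as.list(report@metrics$meanShiftLeft),
      mean_shift_right = as.list(report@metrics$meanShiftRight),
      underactions = if (is.null(ua)) list() else ua)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Pipeline configuration
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline: sensor and
#' prior parameters, preprocessing recipe, model specs, training
#' settings, Hess geometry and diagnosis thresholds, seeds. The config
#' round-trips losslessly through YAML; unknown keys are rejected on
#' read.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    sensor = list(gauge_factor = 0.169, max_strain = 0.15,
                  sampling_rate = 50, noise_sd = 0.001,
                  drift_amplitude = 0.002, drift_frequency = 0.2),
    simulate = list(n_subjects = 7, gain_jitter = 0.15,
                    events_per_subject = 40, angle_range = c(5, 15),
                    directions = c("up", "down", "right", "left"),
                    artifact_fraction = 0),
    preprocess = list(cutoff_hz = 0.5, window_seconds = 2,
                      long_lag_seconds = 0.2),
    classifier = list(in_channels = 10, n_filters = 32,
                      kernel_sizes = c(17, 7, 3), depth = 2, n_classes = 4),
    regressor = list(input_dim = 10, hidden = c(256, 128, 64),
                     output_dim = 1, dropout = 0.2),
    training = list(learning_rate = 0.001, epochs = 20, batch_size = 32,
                    val_fraction = 0.2, lr_schedule = "cosine",
                    regressor_epochs = 150),
    hess = list(viewing_distance = 0.5, grid_step = 5,
                inner_field_half_width = 15, area_ratio_threshold = 0.85,
                shift_threshold = 2, underaction_threshold = 2),
    seed = 1
  )
}

.checkConfigKeys <- function(cfg, template, prefix = "") {
  unknown <- setdiff(names(cfg), names(template))
  .assert(length(unknown) == 0L, "unknown config field '%s%s'", prefix,
          if (length(unknown)) unknown[1L] else "")
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      .assert(is.list(cfg[[nm]]), "config field '%s%s' must be a section",
              prefix, nm)
      .checkConfigKeys(cfg[[nm]], template[[nm]], paste0(prefix, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Read / write the pipeline configuration
#'
#' @param path YAML file.
#' @param config configuration list (defaults merged in on read;
#'   unknown keys rejected with the offending field named).
#' @return `readPipelineConfig` returns the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  template <- defaultPipelineConfig()
  .checkConfigKeys(cfg, template)
  modifyList(template, cfg)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  .checkConfigKeys(config, defaultPipelineConfig())
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Build simulator objects from a configuration
#'
#' @param config a pipeline configuration list.
#' @return list with `sensor` ([SensorSpec-class]) and `geometry`
#'   ([HessGeometry-class]) plus the diagnosis `thresholds`.
#' @export
configObjects <- function(config) {
  s <- config$sensor
  h <- config$hess
  list(sensor = sensorSpec(s$gauge_factor, s$max_strain, s$sampling_rate,
                           s$noise_sd, s$drift_amplitude, s$drift_frequency),
       geometry = hessGeometry(h$viewing_distance, h$grid_step,
                               h$inner_field_half_width),
       thresholds = hessThresholds(h$area_ratio_threshold,
                                   h$shift_threshold,
                                   h$underaction_threshold))
}
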