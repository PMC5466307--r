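#' Write and read configuration files
#'
#' Subject and acquisition configurations persist as flat JSON key-value
#' files, so a subject's entire raw dataset can be regenerated
#' bit-identically from its config (every random draw flows from the
#' stored seed).
#'
#' @param config A `subject_config` or `acq_config`.
#' @param path Output file path (JSON).
#' @return `path`, invisibly (writer); the restored config (reader).
#' @export
write_config <- function(config, path) {
  cls <- class(config)
  x <- unclass(config)
  x$.class <- cls
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  stopifnot(cls %in% c("subject_config", "acq_config"))
  if (cls == "subject_config") {
    do.call(subject_config, x)
  } else {
    do.call(acq_config, x)
  }
}

#' Persist a subject's derived tables as a plain-text bundle
#'
#' Writes a directory containing `subject_config.json`,
#' `acq_config.json`, `truth.csv` (per-beat R time, RR, end-systole,
#' ectopic flag) and, when a processed result is supplied, `cycles.csv`
#' (per-cycle statuses and measurements) and `model.csv` (the fitted PACM).
#' Raw echo streams and ECG traces are deliberately not stored: they are
#' bit-reproducible from the configs.
#'
#' @param subject A `subject_data`.
#' @param dir Output directory (created if needed).
#' @param result Optional `subject_result` from [process_subject()].
#' @return `dir`, invisibly.
#' @export
write_subject_bundle <- function(subject, dir, result = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(subject$config, file.path(dir, "subject_config.json"))
  write_config(subject$acq, file.path(dir, "acq_config.json"))
  tr <- subject$truth
  truth_df <- data.frame(
    beat = seq_along(tr$rr_durations),
    r_time = tr$r_times[seq_along(tr$rr_durations)],
    rr = tr$rr_durations,
    end_systole_s = tr$end_systole_s,
    is_ectopic = tr$is_ectopic
  )
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(result)) {
    if (!is.null(result$cycles)) {
      utils::write.csv(as.data.frame(result$cycles),
                       file.path(dir, "cycles.csv"), row.names = FALSE)
    }
    if (!is.null(result$pacm)) {
      utils::write.csv(as.data.frame(glance(result$pacm)),
                       file.path(dir, "model.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Regenerate a subject from a persisted bundle
#'
#' Reads the configs back and re-runs the simulator, restoring the raw data
#' bit-identically (the bundle stores no raw arrays).
#'
#' @param dir Bundle directory from [write_subject_bundle()].
#' @param keep_scene Passed to [simulate_subject()].
#' @return A `subject_data`.
#' @export
read_subject_bundle <- function(dir, keep_scene = FALSE) {
  cfg <- read_config(file.path(dir, "subject_config.json"))
  acq <- read_config(file.path(dir, "acq_config.json"))
  simulate_subject(cfg, acq, keep_scene = keep_scene)
}

#' Write cohort report tables to CSV
#'
#' @param report List of tibbles from [cohort_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(as.data.frame(report[[nm]]),
                       file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}
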