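#' Subject-level simulation configuration
#'
#' Describes one synthetic subject of an RTPC acquisition: the heart-rate
#' distribution, the subject's true systole-duration law
#' \eqn{S = intercept + slope \cdot HR + \epsilon}, and nuisance levels
#' (confounding vessels, ectopic beats, R-wave detection jitter,
#' magneto-hydrodynamic ECG artifact, velocity noise).
#'
#' Heart rate (not RR) is drawn from a truncated normal, matching how cohort
#' statistics are reported in bpm. The default population is 67 +/- 9.5 bpm
#' bounded to 44-114 bpm over 128 beats, i.e. the acquisition length of a
#' real RTPC scan. The default systole law is the male Weissler line
#' (slope -0.0018 s/bpm, intercept 0.456 s) with a 5 ms residual SD, a
#' good-quality subject under the 10 ms residual-SD gate.
#'
#' All randomness downstream flows from `seed`: each simulation stage uses a
#' sub-seed `seed + 1009 * k` with a fixed per-stage offset `k`, so any stage
#' can be re-run in isolation and the whole subject is bit-reproducible.
#'
#' @param subject_id Character label.
#' @param sex `"M"` or `"F"`.
#' @param n_beats Number of cardiac cycles acquired (>= 3).
#' @param mean_hr,sd_hr Mean and SD of instantaneous heart rate (bpm).
#' @param hr_bounds Truncation bounds for heart rate (bpm), `c(lo, hi)`.
#' @param true_slope Generating slope of the systole law (s/bpm).
#' @param true_intercept Generating intercept (s).
#' @param residual_sd SD of the Gaussian cycle-to-cycle systole residual (s).
#' @param n_confounders Number of confounding vessels sharing the projection.
#' @param ectopic_rate Per-beat probability of an ectopic (shortened) cycle.
#' @param r_jitter_sd SD of the online R-wave detection error (s).
#' @param mhd_amplitude Amplitude of the magneto-hydrodynamic ECG bump,
#'   relative to the 1 mV R wave.
#' @param noise_sd SD of additive velocity noise (cm/s).
#' @param ecg_noise_sd SD of additive ECG noise (mV).
#' @param seed Integer seed determining every random draw for this subject.
#' @return An object of class `subject_config` (a named list).
#' @export
subject_config <- function(subject_id = "S01",
                           sex = c("M", "F"),
                           n_beats = 128L,
                           mean_hr = 67,
                           sd_hr = 9.5,
                           hr_bounds = c(44, 114),
                           true_slope = -0.0018,
                           true_intercept = 0.456,
                           residual_sd = 0.005,
                           n_confounders = 1L,
                           ectopic_rate = 0.02,
                           r_jitter_sd = 0.010,
                           mhd_amplitude = 0.2,
                           noise_sd = 3,
                           ecg_noise_sd = 0.02,
                           seed = 1L) {
  sex <- match.arg(sex)
  cfg <- list(
    subject_id = as.character(subject_id), sex = sex,
    n_beats = as.integer(n_beats), mean_hr = mean_hr, sd_hr = sd_hr,
    hr_bounds = as.numeric(hr_bounds), true_slope = true_slope,
    true_intercept = true_intercept, residual_sd = residual_sd,
    n_confounders = as.integer(n_confounders), ectopic_rate = ectopic_rate,
    r_jitter_sd = r_jitter_sd, mhd_amplitude = mhd_amplitude,
    noise_sd = noise_sd, ecg_noise_sd = ecg_noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "subject_config"
  validate_subject_config(cfg)
  cfg
}

validate_subject_config <- function(cfg) {
  stopifnot(
    cfg$n_beats >= 3L,
    cfg$sd_hr >= 0,
    cfg$residual_sd >= 0,
    length(cfg$hr_bounds) == 2L,
    cfg$hr_bounds[1] < cfg$hr_bounds[2],
    cfg$hr_bounds[1] > 0,
    cfg$ectopic_rate >= 0, cfg$ectopic_rate <= 1,
    cfg$r_jitter_sd >= 0, cfg$noise_sd >= 0,
    is.finite(cfg$seed)
  )
  invisible(cfg)
}

#' Acquisition configuration of the RTPC sequence
#'
#' Scan parameters of the real-time phase-contrast sequence: a single central
#' k-space line (acquisition matrix 256 x 1) repeated every TR with
#' interleaved through-slice velocity encoding. Defaults are the RTPC
#' protocol values: 350 mm field of view, 256 frequency samples,
#' TR 6.6 ms / TE 3.4 ms, venc 150 cm/s, two coil channels, 8 mm slice.
#'
#' @param fov_mm Field of view along frequency encoding (mm).
#' @param matrix_freq Frequency-encoding matrix size (power of two).
#' @param tr_s Repetition time (s); also the velocity-frame spacing after
#'   shared velocity encoding.
#' @param te_s Echo time (s), metadata only.
#' @param venc_cm_s Velocity-encoding limit (cm/s): the velocity mapped to a
#'   phase difference of pi between the two encodings.
#' @param n_channels Number of receive channels used.
#' @param slice_thickness_mm Slice thickness (mm), metadata only.
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(fov_mm = 350, matrix_freq = 256L, tr_s = 0.0066,
                       te_s = 0.0034, venc_cm_s = 150, n_channels = 2L,
                       slice_thickness_mm = 8) {
  stopifnot(
    matrix_freq >= 2, bitwAnd(as.integer(matrix_freq), as.integer(matrix_freq) - 1L) == 0L,
    tr_s > 0, venc_cm_s > 0, n_channels >= 1
  )
  structure(list(
    fov_mm = fov_mm, matrix_freq = as.integer(matrix_freq), tr_s = tr_s,
    te_s = te_s, venc_cm_s = venc_cm_s, n_channels = as.integer(n_channels),
    slice_thickness_mm = slice_thickness_mm
  ), class = "acq_config")
}

# Deterministic sub-seed for simulation stage `k`; keeps every derived seed a
# valid 32-bit integer so `set.seed()` accepts it.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1009 * k) %% .Machine$integer.max)
}

# Evaluate `expr` under seed `seed`, restoring the caller's RNG state.
with_sub_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.subject_config <- function(x, ...) {
  cat(sprintf(
    "<subject_config> %s (%s): %d beats, HR ~ trunc-N(%g, %g) in [%g, %g] bpm\n",
    x$subject_id, x$sex, x$n_beats, x$mean_hr, x$sd_hr,
    x$hr_bounds[1], x$hr_bounds[2]
  ))
  cat(sprintf(
    "  systole law: S = %.4f %+.5f*HR (s), residual SD %.3f s; seed %d\n",
    x$true_intercept, x$true_slope, x$residual_sd, x$seed
  ))
  invisible(x)
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf(
    "<acq_config> %dx1 matrix, FOV %g mm, TR %.1f ms, venc %g cm/s, %d channels\n",
    x$matrix_freq, x$fov_mm, 1000 * x$tr_s, x$venc_cm_s, x$n_channels
  ))
  invisible(x)
}
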