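#' Draw a sequence of RR intervals for one subject
#'
#' Instantaneous heart rate `HR_i = 60 / RR_i` follows a smooth
#' heart-rate-variability process with the configured mean and SD (bpm),
#' clipped to `hr_bounds`: a respiratory-sinus-arrhythmia oscillation
#' (period 5 beats), a dominant low-frequency oscillation (period 26 beats,
#' random phases per seed) and a small AR(1) residual, with variances
#' calibrated so the stationary SD equals `sd_hr` exactly. Beat-to-beat HR
#' changes therefore stay small (as in real sinus rhythm), so the 20%
#' cycle-screening rule never fires on non-ectopic beats; an i.i.d. draw of
#' HR with SD 9.5 bpm would put ~16% of beats more than 20% away from the
#' median RR, which no screening rule could accept.
#'
#' Ectopic beats, if requested, replace the drawn RR by `0.6 * RR`, which is
#' guaranteed to differ by more than 20% from both the record median and the
#' preceding cycle — the two conditions the downstream screening rule tests.
#'
#' @param config A [subject_config()].
#' @return Numeric vector of `n_beats` RR durations (s), with attributes
#'   `is_ectopic` (logical per beat) and `hr` (the pre-ectopic heart rates).
#' @export
simulate_rr_sequence <- function(config) {
  validate_subject_config(config)
  n <- config$n_beats
  hr <- with_sub_seed(sub_seed(config$seed, 1L), {
    draw_hr_process(n, config$mean_hr, config$sd_hr, config$hr_bounds)
  })
  rr <- 60 / hr
  ect <- with_sub_seed(sub_seed(config$seed, 2L), {
    stats::runif(n) < config$ectopic_rate
  })
  # never make the first or last beat ectopic: the screening rule needs both
  # neighbours to exist for its worked examples to be unambiguous
  ect[c(1L, n)] <- FALSE
  rr[ect] <- 0.6 * rr[ect]
  attr(rr, "is_ectopic") <- ect
  attr(rr, "hr") <- hr
  rr
}

# Smooth HR process: respiratory (period 5 beats, 3.2% of variance) and
# low-frequency (period 26 beats, ~95%) oscillations plus AR(1) noise
# (phi = 0.5), variance shares calibrated so the stationary SD is `sd`.
draw_hr_process <- function(n, mean, sd, bounds, max_tries = 1000L) {
  if (mean < bounds[1] || mean > bounds[2]) {
    stop("degenerate bounds: mean heart rate outside hr_bounds")
  }
  if (sd == 0) return(rep(mean, n))
  var_ar <- 0.011 * sd^2
  a_resp <- sd * sqrt(2 * 0.032)
  a_lf <- sd * sqrt(2 * (1 - 0.032 - 0.011))
  phases <- stats::runif(2, 0, 2 * pi)
  i <- seq_len(n)
  phi <- 0.5
  innov_sd <- sqrt(var_ar * (1 - phi^2))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sqrt(var_ar))
  for (k in seq_len(n)[-1]) e[k] <- phi * e[k - 1] + stats::rnorm(1, 0, innov_sd)
  hr <- mean + a_resp * sin(2 * pi * i / 5 + phases[1]) +
    a_lf * sin(2 * pi * i / 26 + phases[2]) + e
  tries <- 0L
  while (any(hr < bounds[1] | hr > bounds[2])) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("heart-rate sampling failed: bounds too tight for mean/SD")
    }
    bad <- hr < bounds[1] | hr > bounds[2]
    hr[bad] <- pmin(pmax(hr[bad], bounds[1]), bounds[2])
  }
  hr
}

#' Generate true per-cycle end-systole durations
#'
#' Applies the subject's generating law
#' \eqn{S_i = intercept + slope \cdot HR_i + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, residual\_sd)}, with `HR_i = 60 / RR_i`.
#' Draws are clipped to stay strictly inside the cycle `(0, RR_i)`; if the
#' *noise-free* prediction already leaves that interval the configuration is
#' inconsistent and an error is thrown.
#'
#' @param config A [subject_config()].
#' @param rr RR durations (s), e.g. from [simulate_rr_sequence()].
#' @param seed Optional override of the sub-seed used for the residual draws.
#' @return Numeric vector of end-systole durations (s), one per beat.
#' @export
true_end_systole <- function(config, rr, seed = NULL) {
  stopifnot(all(rr > 0))
  hr <- 60 / rr
  mu <- config$true_intercept + config$true_slope * hr
  if (any(mu <= 0 | mu >= rr)) {
    stop("inconsistent config: noise-free systole prediction outside (0, RR)")
  }
  s <- if (config$residual_sd > 0) {
    eps <- with_sub_seed(
      if (is.null(seed)) sub_seed(config$seed, 3L) else seed,
      stats::rnorm(length(rr), 0, config$residual_sd)
    )
    mu + eps
  } else {
    mu
  }
  margin <- 1e-3
  as.numeric(pmin(pmax(s, margin), rr - margin))
}

# Spatial layout of the synthetic slice along the frequency-encoding axis.
# The ascending aorta is a 6-pixel block just right of centre (inside the
# central 50% FOV kept by the reconstruction); confounders alternate between
# a descending-aorta-like vessel (negative flow, similar timing) and a
# smaller delayed positive vessel (pulmonary-artery-like).
scene_layout <- function(acq, n_confounders) {
  n <- acq$matrix_freq
  aorta <- (n %/% 2 + 8L) + 0:5
  conf <- list()
  if (n_confounders >= 1L) {
    for (k in seq_len(n_confounders)) {
      if (k %% 2L == 1L) {
        conf[[k]] <- list(pixels = (n %/% 2 - 20L) + 0:3, sign = -1,
                          peak = 80, delay = 0.030, scale = 1.0)
      } else {
        conf[[k]] <- list(pixels = (n %/% 2 + 26L) + 0:2, sign = +1,
                          peak = 70, delay = 0.150, scale = 0.8)
      }
    }
  }
  body <- seq.int(n %/% 4 + 1L, n - n %/% 4)
  list(aorta = aorta, confounders = conf, body = body)
}

half_sine_wave <- function(t, onset, offset, peak) {
  v <- numeric(length(t))
  inside <- t > onset & t < offset
  v[inside] <- peak * sin(pi * (t[inside] - onset) / (offset - onset))
  v
}

#' Simulate the 1D+t velocity/magnitude scene
#'
#' Builds the ground-truth spatial projection the scanner would see: per
#' beat, the aortic pixel block carries a half-sine forward systolic ejection
#' wave starting 30 ms after the R wave and ending exactly at `R + S_i`
#' (peak 100 cm/s, below venc), a brief dicrotic retrograde undershoot
#' (-15 cm/s, 60 ms) at valve closure, and zero diastolic flow. Optional
#' confounding vessels carry waves of different sign or timing. Magnitude is
#' high inside vessels, intermediate in the body, near zero in air.
#' Gaussian velocity noise of SD `config$noise_sd` is added inside the body.
#'
#' The record starts 0.5 s before the first R wave and ends 0.5 s after the
#' last, so ECG template windows never fall off the record.
#'
#' @param config A [subject_config()].
#' @param acq An [acq_config()].
#' @param rr RR durations (s).
#' @param end_systole True end-systole durations (s), same length as `rr`.
#' @return A `velocity_scene`: list with `velocity` and `magnitude`
#'   (`matrix_freq x n_frames` matrices), frame `times` (s), `truth`
#'   (a `ground_truth` list: `r_times`, `rr_durations`, `end_systole_s`,
#'   `aorta_pixels`, `confounder_pixels`, `is_ectopic`), and the configs.
#' @export
simulate_velocity_scene <- function(config, acq, rr, end_systole) {
  stopifnot(length(rr) == length(end_systole), all(end_systole < rr))
  n_beats <- length(rr)
  lead_in <- 0.5
  tail <- 0.5
  r_times <- lead_in + c(0, cumsum(rr)) # n_beats + 1 R waves
  duration <- lead_in + sum(rr) + tail
  times <- seq(0, duration, by = acq$tr_s)
  n_frames <- length(times)
  lay <- scene_layout(acq, config$n_confounders)

  aorta_course <- numeric(n_frames)
  onset_delay <- 0.030
  for (i in seq_len(n_beats)) {
    # forward ejection lobe ending exactly at R + S_i, followed by a brief
    # dicrotic (valve-closure) retrograde undershoot, then zero diastole
    aorta_course <- aorta_course +
      half_sine_wave(times, r_times[i] + onset_delay,
                     r_times[i] + end_systole[i], peak = 100) +
      half_sine_wave(times, r_times[i] + end_systole[i],
                     r_times[i] + end_systole[i] + 0.060, peak = -15)
  }

  velocity <- matrix(0, nrow = acq$matrix_freq, ncol = n_frames)
  velocity[lay$aorta, ] <- rep(aorta_course, each = length(lay$aorta))
  for (cf in lay$confounders) {
    course <- numeric(n_frames)
    for (i in seq_len(n_beats)) {
      course <- course + half_sine_wave(
        times, r_times[i] + cf$delay,
        r_times[i] + cf$delay + cf$scale * (end_systole[i] - onset_delay),
        peak = cf$sign * cf$peak
      )
    }
    velocity[cf$pixels, ] <- rep(course, each = length(cf$pixels))
  }

  magnitude <- matrix(0.02, nrow = acq$matrix_freq, ncol = n_frames)
  magnitude[lay$body, ] <- 0.3
  magnitude[lay$aorta, ] <- 1
  for (cf in lay$confounders) magnitude[cf$pixels, ] <- 1

  if (config$noise_sd > 0) {
    noise <- with_sub_seed(sub_seed(config$seed, 4L), {
      matrix(stats::rnorm(length(lay$body) * n_frames, 0, config$noise_sd),
             nrow = length(lay$body))
    })
    velocity[lay$body, ] <- velocity[lay$body, ] + noise
  }

  truth <- list(
    r_times = r_times,
    rr_durations = rr,
    end_systole_s = end_systole,
    aorta_pixels = lay$aorta,
    confounder_pixels = lapply(lay$confounders, `[[`, "pixels"),
    is_ectopic = attr(rr, "is_ectopic") %||% rep(FALSE, n_beats)
  )
  class(truth) <- "ground_truth"
  structure(
    list(velocity = velocity, magnitude = magnitude, times = times,
         truth = truth, config = config, acq = acq),
    class = "velocity_scene"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two smooth receive-coil sensitivity profiles, each weighting one half of
# the FOV (anterior top-right / bottom-right elements of the array).
channel_sensitivities <- function(n, n_channels) {
  idx <- seq_len(n)
  centers <- n * (seq_len(n_channels) - 0.5) / n_channels
  vapply(centers, function(c0) 0.25 + exp(-((idx - c0) / (n / 2))^2),
         numeric(n))
}

#' Render central k-space lines from a velocity scene
#'
#' The exact inverse of the reconstruction's 1D Fourier transform: per frame
#' and channel, the complex 1D image
#' \eqn{c_{ch}(x)\,m(x,t)\,\exp(i\,s_t\,\pi v(x,t)/(2\,venc))}
#' is inverse-Fourier transformed (unitary) into one k-space echo. The
#' velocity-encoding toggle \eqn{s_t} alternates +1/-1 between consecutive
#' echoes, so the phase *difference* of adjacent echoes is
#' \eqn{\pi v / venc} — velocities beyond venc alias.
#'
#' @param scene A `velocity_scene`.
#' @param acq An [acq_config()]; defaults to the scene's.
#' @return An `echo_stream`: list with `samples` (list of complex
#'   `matrix_freq x n_echoes` matrices, one per channel), `echo_times`,
#'   `venc_toggle`, `config`.
#' @export
render_kspace_lines <- function(scene, acq = scene$acq) {
  n_frames <- ncol(scene$velocity)
  stopifnot(n_frames >= 2)
  toggle <- rep_len(c(1, -1), n_frames)
  sens <- channel_sensitivities(acq$matrix_freq, acq$n_channels)
  phase <- sweep(scene$velocity * (pi / (2 * acq$venc_cm_s)), 2, toggle, `*`)
  base_img <- scene$magnitude * exp(1i * phase)
  samples <- lapply(seq_len(acq$n_channels), function(ch) {
    img <- base_img * sens[, ch]
    # pixel 1 = FOV edge in image space; ifftshift before the inverse DFT
    stats::mvfft(ifftshift_rows(img), inverse = TRUE) / sqrt(nrow(img))
  })
  structure(
    list(samples = samples, echo_times = scene$times, venc_toggle = toggle,
         config = acq),
    class = "echo_stream"
  )
}

fftshift_rows <- function(x) {
  n <- nrow(x)
  x[c((n %/% 2 + 1L):n, 1:(n %/% 2)), , drop = FALSE]
}

ifftshift_rows <- function(x) {
  n <- nrow(x)
  x[c((n - n %/% 2 + 1L):n, 1:(n - n %/% 2)), , drop = FALSE]
}

# Synthetic QRS complex sampled at offsets `t` (s) from the R wave:
# Q and S troughs flanking a 1 mV R spike, plus P and T waves.
qrs_waveform <- function(t, lead_gain = 1, with_pt = TRUE) {
  g <- function(mu, sd) exp(-((t - mu) / sd)^2 / 2)
  v <- -0.15 * g(-0.025, 0.008) + 1.0 * g(0, 0.006) - 0.25 * g(0.030, 0.009)
  if (with_pt) {
    v <- v + 0.10 * g(-0.160, 0.025) + 0.25 * g(0.280, 0.045)
  }
  lead_gain * v
}

#' Simulate a multi-lead ECG trace with online R-wave detections
#'
#' Each beat is a fixed QRS template (with P and T waves) at the true R time.
#' The magneto-hydrodynamic (MHD) artifact — blood ejected through the static
#' field — appears as a bump synchronous with the systolic ejection window
#' `(R + 30 ms, R + S_i)`, scaled by `config$mhd_amplitude`. Online
#' detections are the true R times plus Gaussian jitter of SD
#' `config$r_jitter_sd`, emulating the scanner's real-time trigger.
#'
#' @param config A [subject_config()].
#' @param rr RR durations (s).
#' @param end_systole True end-systole durations (s).
#' @param fs Sampling rate (Hz), >= 200.
#' @return An `ecg_trace`: list with `samples` (`n_leads x n_samples` mV
#'   matrix), `fs`, `times`, `online_detections` (s), `true_r_times` (s).
#' @export
simulate_ecg <- function(config, rr, end_systole, fs = 500) {
  stopifnot(fs >= 200, length(rr) == length(end_systole))
  n_beats <- length(rr)
  lead_in <- 0.5
  r_times <- lead_in + c(0, cumsum(rr))
  duration <- lead_in + sum(rr) + 0.5
  times <- seq(0, duration, by = 1 / fs)
  gains <- c(1, 0.7)
  mhd_gains <- c(1, 1.4) # MHD is lead-dependent in practice
  samples <- matrix(0, nrow = 2, ncol = length(times))
  for (lead in 1:2) {
    tr <- numeric(length(times))
    for (i in seq_along(r_times)) {
      near <- which(abs(times - r_times[i]) < 0.45)
      tr[near] <- tr[near] + qrs_waveform(times[near] - r_times[i], gains[lead])
    }
    if (config$mhd_amplitude > 0) {
      for (i in seq_len(n_beats)) {
        tr <- tr + half_sine_wave(
          times, r_times[i] + 0.030, r_times[i] + end_systole[i],
          peak = config$mhd_amplitude * mhd_gains[lead]
        )
      }
    }
    samples[lead, ] <- tr
  }
  if (config$ecg_noise_sd > 0) {
    samples <- samples + with_sub_seed(sub_seed(config$seed, 5L), {
      matrix(stats::rnorm(length(samples), 0, config$ecg_noise_sd), nrow = 2)
    })
  }
  det <- if (config$r_jitter_sd > 0) {
    r_times + with_sub_seed(sub_seed(config$seed, 6L), {
      stats::rnorm(length(r_times), 0, config$r_jitter_sd)
    })
  } else {
    r_times
  }
  det <- pmin(pmax(det, 0), duration)
  structure(
    list(samples = samples, fs = fs, times = times,
         online_detections = det, true_r_times = r_times),
    class = "ecg_trace"
  )
}

#' Simulate one complete synthetic RTPC subject
#'
#' Chains [simulate_rr_sequence()], [true_end_systole()],
#' [simulate_velocity_scene()], [render_kspace_lines()] and [simulate_ecg()]
#' into the full raw-data bundle the analysis pipeline consumes. Identical
#' configs (including seed) give bit-identical output.
#'
#' @param config A [subject_config()].
#' @param acq An [acq_config()].
#' @param keep_scene Keep the ground-truth scene matrices (needed by tests
#'   and by scene-level shortcuts; modestly large).
#' @return A `subject_data` list: `config`, `acq`, `kspace` (echo stream),
#'   `ecg` (ECG trace), `truth` (ground truth), and optionally `scene`.
#' @export
simulate_subject <- function(config, acq = acq_config(), keep_scene = FALSE) {
  rr <- simulate_rr_sequence(config)
  s_true <- true_end_systole(config, rr)
  scene <- simulate_velocity_scene(config, acq, rr, s_true)
  kspace <- render_kspace_lines(scene, acq)
  ecg <- simulate_ecg(config, rr, s_true)
  out <- list(config = config, acq = acq, kspace = kspace, ecg = ecg,
              truth = scene$truth)
  if (keep_scene) out$scene <- scene
  class(out) <- "subject_data"
  out
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf(
    "<subject_data> %s: %d beats, %d echoes x %d samples x %d channels, ECG %g Hz\n",
    x$config$subject_id, length(x$truth$rr_durations),
    ncol(x$kspace$samples[[1]]), nrow(x$kspace$samples[[1]]),
    length(x$kspace$samples), x$ecg$fs
  ))
  invisible(x)
}
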