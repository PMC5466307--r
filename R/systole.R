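#' Detect the systolic velocity peak (S wave) of each cycle
#'
#' Within each accepted cardiac cycle `[r_i, r_{i+1})` the S wave is the
#' frame of maximum projected velocity (ties: earliest frame). Cycles whose
#' window contains no velocity frame are marked unmeasured.
#'
#' @param course Aortic ROI velocity time course (cm/s).
#' @param times Frame times (s), same length as `course`.
#' @param cycles A `cycle_table` from [screen_cycles()].
#' @return Tibble per cycle: `cycle`, `peak_frame` (index into `course`,
#'   NA if unmeasurable), `peak_time`, `peak_velocity`.
#' @export
detect_s_waves <- function(course, times, cycles) {
  stopifnot(length(course) == length(times))
  res <- purrr::pmap(
    list(cycles$cycle, cycles$r_time, cycles$rr, cycles$accepted),
    function(cyc, r0, rr, acc) {
      if (!acc) {
        return(tibble::tibble(cycle = cyc, peak_frame = NA_integer_,
                              peak_time = NA_real_, peak_velocity = NA_real_))
      }
      in_cyc <- which(times >= r0 & times < r0 + rr)
      if (!length(in_cyc)) {
        return(tibble::tibble(cycle = cyc, peak_frame = NA_integer_,
                              peak_time = NA_real_, peak_velocity = NA_real_))
      }
      pk <- in_cyc[which.max(course[in_cyc])] # which.max: earliest on ties
      tibble::tibble(cycle = cyc, peak_frame = pk, peak_time = times[pk],
                     peak_velocity = course[pk])
    }
  )
  dplyr::bind_rows(res)
}

#' Iterative baseline of the aortic velocity course
#'
#' Estimates the diastolic zero-flow baseline in 10 iterations: a 0.5 Hz
#' zero-phase low-pass of the course forms the initial baseline; then,
#' using histogram analysis of the original course, extreme values are set
#' to the current baseline value at their frame and the clamped curve is
#' re-low-passed, with the extreme-value threshold lowered by one discrete
#' histogram interval at both sides per iteration.
#'
#' The histogram intervals are anchored on the histogram mode — the
#' diastolic plateau, by far the most populated velocity value of a
#' pulsatile course — with `n_iter + 1` equal intervals between the mode
#' and each data extreme. At iteration `t` every sample further than
#' `n_iter + 1 - t` intervals from the mode (on its side) is clamped to the
#' baseline, so after the last iteration only samples within one interval
#' of the diastolic mode still shape the baseline, which therefore
#' converges onto the diastolic level while systolic lobes and the dicrotic
#' undershoot are progressively erased. (Anchoring the intervals at the raw
#' data extremes instead cannot work: ten intervals of a min/max-spanning
#' histogram never reach past the systolic lobe of a one-sided pulse.)
#'
#' @param course Velocity time course (cm/s).
#' @param dt Frame spacing (s).
#' @param n_iter Number of clamping iterations (10).
#' @param f_lp Low-pass cutoff (Hz), 0.5.
#' @param n_bins Bins of the mode-locating histogram (101).
#' @return A `systole_baseline`: `values` (baseline per frame),
#'   `iterations`, `history` (per-iteration `(lo, hi)` clamp thresholds).
#' @export
compute_baseline <- function(course, dt, n_iter = 10L, f_lp = 0.5,
                             n_bins = 101L) {
  n <- length(course)
  stopifnot(n > 50, dt > 0, n_iter >= 0, n_bins >= 4)
  fs <- 1 / dt
  rng <- range(course)
  baseline <- lowpass_zero_phase(course, f_lp, fs)
  history <- list()
  if (diff(rng) > 0) {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    counts <- tabulate(findInterval(course, edges, rightmost.closed = TRUE),
                       nbins = n_bins)
    mode_bin <- which.max(counts)
    m_lo <- edges[mode_bin]
    m_hi <- edges[mode_bin + 1L]
    d_hi <- (rng[2] - m_hi) / n_iter
    d_lo <- (m_lo - rng[1]) / n_iter
    for (t_it in seq_len(n_iter)) {
      # the kept band shrinks by one interval per side per iteration and
      # ends exactly on the mode bin, so the diastolic plateau is never
      # clamped while systolic extremes are progressively erased
      hi <- m_hi + (n_iter - t_it) * d_hi
      lo <- m_lo - (n_iter - t_it) * d_lo
      clamped <- course
      extreme <- course < lo | course > hi
      clamped[extreme] <- baseline[extreme]
      baseline <- lowpass_zero_phase(clamped, f_lp, fs)
      history[[t_it]] <- c(lo = lo, hi = hi)
    }
  }
  structure(list(values = baseline, iterations = length(history),
                 history = history),
            class = "systole_baseline")
}

#' Per-cycle end of forward systolic flow
#'
#' The end-systole time of a cycle is where the S wave intersects the
#' baseline: scanning forward from the S-wave peak, the first frame with
#' course <= baseline brackets the crossing, which is refined by linear
#' interpolation between the bracketing frames. The systole duration is the
#' crossing time minus the cycle's R time. Durations outside the
#' physiological range 100-500 ms are marked invalid
#' (`systole_out_of_bounds`); cycles with no crossing before the next R
#' wave are `unmeasured`.
#'
#' @param course Aortic velocity course (cm/s).
#' @param times Frame times (s).
#' @param baseline A `systole_baseline` from [compute_baseline()].
#' @param cycles A `cycle_table`.
#' @param s_peaks S-wave tibble from [detect_s_waves()].
#' @param bounds_s Physiological systole bounds (s), default `c(0.1, 0.5)`.
#' @return A `systole_samples` tibble, one row per *accepted* cycle:
#'   `cycle`, `r_time`, `rr`, `hr`, `s_wave_time`, `systole_s`, `valid`,
#'   `reason` (`ok`, `systole_out_of_bounds`, `unmeasured`).
#' @export
end_systole_times <- function(course, times, baseline, cycles, s_peaks,
                              bounds_s = c(0.1, 0.5)) {
  stopifnot(inherits(baseline, "systole_baseline"),
            length(baseline$values) == length(course))
  base <- baseline$values
  acc <- dplyr::left_join(cycles[cycles$accepted, ], s_peaks, by = "cycle")
  res <- purrr::pmap(
    list(acc$cycle, acc$r_time, acc$rr, acc$hr, acc$peak_frame),
    function(cyc, r0, rr, hr, pk) {
      row <- tibble::tibble(cycle = cyc, r_time = r0, rr = rr, hr = hr,
                            s_wave_time = NA_real_, systole_s = NA_real_,
                            valid = FALSE, reason = "unmeasured")
      if (is.na(pk)) return(row)
      row$s_wave_time <- times[pk]
      last <- max(which(times < r0 + rr))
      j <- pk
      while (j <= last && course[j] > base[j]) j <- j + 1L
      if (j > last) return(row) # no crossing before the next R wave
      cross_t <- if (j == pk || course[j] == base[j]) {
        times[j]
      } else {
        d1 <- course[j - 1L] - base[j - 1L] # > 0
        d2 <- course[j] - base[j]           # <= 0
        times[j - 1L] + (times[j] - times[j - 1L]) * d1 / (d1 - d2)
      }
      row$systole_s <- cross_t - r0
      if (row$systole_s >= bounds_s[1] && row$systole_s <= bounds_s[2]) {
        row$valid <- TRUE
        row$reason <- "ok"
      } else {
        row$reason <- "systole_out_of_bounds"
      }
      row
    }
  )
  out <- dplyr::bind_rows(res)
  class(out) <- c("systole_samples", class(out))
  out
}

#' Measure end-systole on every cycle of a segmented subject
#'
#' Chains [detect_s_waves()], [compute_baseline()] and
#' [end_systole_times()], and merges the result back onto the full cycle
#' table so that every cycle of the record carries exactly one terminal
#' status (screening reason, `systole_out_of_bounds`, `unmeasured`, or
#' `ok`).
#'
#' @param seg A `segmentation` (supplies the aortic course and timing).
#' @param cycles A `cycle_table`.
#' @param bounds_s Physiological systole bounds (s).
#' @return A tibble with one row per cycle: screening columns plus
#'   `s_wave_time`, `systole_s`, `valid`, `status`.
#' @export
measure_systole <- function(seg, cycles, bounds_s = c(0.1, 0.5)) {
  times <- seg$t0 + (seq_along(seg$course) - 1L) * seg$dt
  peaks <- detect_s_waves(seg$course, times, cycles)
  baseline <- compute_baseline(seg$course, seg$dt)
  samples <- end_systole_times(seg$course, times, baseline, cycles, peaks,
                               bounds_s = bounds_s)
  out <- dplyr::left_join(
    cycles,
    samples[, c("cycle", "s_wave_time", "systole_s", "valid", "reason")],
    by = "cycle", suffix = c("", ".sys")
  )
  out$valid <- !is.na(out$valid) & out$valid
  out$status <- dplyr::case_when(
    !out$accepted ~ out$reason,
    is.na(out$reason.sys) ~ "unmeasured",
    TRUE ~ out$reason.sys
  )
  out$reason.sys <- NULL
  attr(out, "baseline") <- baseline
  out
}
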