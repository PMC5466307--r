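#' Build the subject's mean QRS pattern
#'
#' Averages windows of the ECG centred on the online R-wave detections, per
#' lead, into one QRS template. Detections whose window would leave the
#' record are skipped (and counted). The template is later slid over the
#' trace to reposition detections, so jitter in the online detections only
#' smears the template slightly without biasing its centre.
#'
#' @param ecg An `ecg_trace`.
#' @param window_s Window length (s), default 0.12 (covers the QRS complex).
#' @return A `qrs_pattern`: `template` (`n_leads x n_window` mV matrix),
#'   `window_s`, `origin_offset` (s from window start to the R wave,
#'   = window_s / 2 for centred windows), `n_used`, `n_skipped`.
#' @export
build_qrs_pattern <- function(ecg, window_s = 0.12) {
  stopifnot(inherits(ecg, "ecg_trace"))
  half <- round(window_s * ecg$fs / 2)
  n <- ncol(ecg$samples)
  centers <- round(ecg$online_detections * ecg$fs) + 1L
  ok <- centers - half >= 1L & centers + half <= n
  if (sum(ok) < 3L) stop("fewer than 3 online detections with full windows")
  idx_rel <- (-half):half
  acc <- matrix(0, nrow = nrow(ecg$samples), ncol = length(idx_rel))
  for (c0 in centers[ok]) acc <- acc + ecg$samples[, c0 + idx_rel, drop = FALSE]
  structure(
    list(template = acc / sum(ok), window_s = 2 * half / ecg$fs,
         origin_offset = half / ecg$fs, n_used = sum(ok),
         n_skipped = sum(!ok)),
    class = "qrs_pattern"
  )
}

#' Reposition R-wave detections by template correlation
#'
#' For each online detection, the QRS template is cross-correlated with the
#' ECG (correlation summed over all leads) within `+/- search_s` of the
#' detection; the refined R time is the lag of maximum correlation (ties:
#' earliest). A flat correlation keeps the online detection. Refinement
#' removes the scanner trigger's jitter down to the ECG sampling grid.
#'
#' @param ecg An `ecg_trace`.
#' @param pattern A `qrs_pattern` from [build_qrs_pattern()].
#' @param search_s Search radius (s), default 0.05.
#' @return Numeric vector of refined R times (s), one per online detection.
#' @export
reposition_detections <- function(ecg, pattern, search_s = 0.05) {
  stopifnot(inherits(pattern, "qrs_pattern"))
  fs <- ecg$fs
  half <- as.integer(round(pattern$origin_offset * fs))
  rad <- as.integer(round(search_s * fs))
  n <- ncol(ecg$samples)
  idx_rel <- (-half):half
  tpl <- pattern$template
  vapply(ecg$online_detections, function(t_det) {
    c0 <- as.integer(round(t_det * fs)) + 1L
    lags <- (c0 - rad):(c0 + rad)
    lags <- lags[lags - half >= 1L & lags + half <= n]
    if (!length(lags)) return(t_det)
    score <- vapply(lags, function(cc) {
      sum(tpl * ecg$samples[, cc + idx_rel, drop = FALSE])
    }, numeric(1))
    if (max(score) - min(score) < .Machine$double.eps * max(1, abs(max(score)))) {
      return(t_det) # flat correlation: keep the online detection
    }
    (lags[which.max(score)] - 1L) / fs
  }, numeric(1))
}

#' Screen cardiac cycles for trigger errors and ectopy
#'
#' Cycle `i` runs from R wave `i` to R wave `i + 1` (the final R wave begins
#' no cycle) with `RR_i = r_{i+1} - r_i` and instantaneous heart rate
#' `60 / RR_i`. Two rules reject cycles:
#' \itemize{
#'   \item obvious QRS detection errors: instantaneous heart rate below 30
#'     or above 120 bpm rejects the cycle itself (`hr_out_of_range`);
#'   \item ectopic beats: an RR differing by more than 20% from *both* the
#'     record median RR and the previous cycle's RR rejects the cycle *and*
#'     its two neighbours (`ectopic`, neighbours `ectopic_neighbor`).
#' }
#' The median RR is computed once over the whole record before any
#' rejection, so re-screening the accepted subset (passing `median_rr`)
#' changes nothing.
#'
#' @param r_times Strictly increasing R-wave times (s), length >= 3.
#' @param median_rr Optional externally fixed median RR (s); defaults to
#'   the median over this record.
#' @param hr_range Acceptable instantaneous heart rate (bpm), default
#'   `c(30, 120)`.
#' @param ectopic_tol Relative RR deviation defining ectopy, default 0.2.
#' @return A `cycle_table` tibble, one row per cycle: `cycle`, `r_time`,
#'   `rr`, `hr`, `accepted`, `reason` (one of `ok`, `hr_out_of_range`,
#'   `ectopic`, `ectopic_neighbor`).
#' @export
screen_cycles <- function(r_times, median_rr = NULL,
                          hr_range = c(30, 120), ectopic_tol = 0.2) {
  stopifnot(length(r_times) >= 3, all(diff(r_times) > 0))
  rr <- diff(r_times)
  n <- length(rr)
  hr <- 60 / rr
  med <- median_rr %||% stats::median(rr)

  ectopic <- rep(FALSE, n)
  for (i in seq_len(n)[-1]) {
    ectopic[i] <- abs(rr[i] - med) > ectopic_tol * med &&
      abs(rr[i] - rr[i - 1]) > ectopic_tol * rr[i - 1]
  }
  neighbor <- rep(FALSE, n)
  for (i in which(ectopic)) {
    if (i > 1L) neighbor[i - 1L] <- TRUE
    if (i < n) neighbor[i + 1L] <- TRUE
  }
  hr_bad <- hr < hr_range[1] | hr > hr_range[2]

  reason <- rep("ok", n)
  reason[neighbor] <- "ectopic_neighbor"
  reason[hr_bad] <- "hr_out_of_range"
  reason[ectopic] <- "ectopic"

  out <- tibble::tibble(
    cycle = seq_len(n),
    r_time = r_times[seq_len(n)],
    rr = rr,
    hr = hr,
    accepted = reason == "ok",
    reason = reason
  )
  attr(out, "median_rr") <- med
  class(out) <- c("cycle_table", class(out))
  out
}

#' Refine R waves and screen cycles in one call
#'
#' Chains [build_qrs_pattern()], [reposition_detections()] and
#' [screen_cycles()] on a raw ECG trace.
#'
#' @param ecg An `ecg_trace`.
#' @param window_s QRS template window (s).
#' @param search_s Repositioning search radius (s).
#' @return A `cycle_table` (see [screen_cycles()]) with attribute
#'   `r_times_refined`.
#' @export
analyze_ecg <- function(ecg, window_s = 0.12, search_s = 0.05) {
  pattern <- build_qrs_pattern(ecg, window_s = window_s)
  r_ref <- reposition_detections(ecg, pattern, search_s = search_s)
  r_ref <- sort(unique(r_ref))
  cycles <- screen_cycles(r_ref)
  attr(cycles, "r_times_refined") <- r_ref
  cycles
}
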