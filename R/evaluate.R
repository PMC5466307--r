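#' Bland-Altman agreement analysis
#'
#' Agreement between predicted and reference end-systole times via the
#' differences `diff = ref - pred`: bias = mean(diff), limits of agreement
#' bias +/- 1.96 * SD(diff), standard error of the bias SD(diff)/sqrt(n)
#' (the "bias +/- SE" reporting convention), and a one-sample t-test of
#' bias != 0.
#'
#' @param pred Predicted values (s).
#' @param ref Reference values (s), same length.
#' @return A `bland_altman` object: `bias`, `sd_diff`, `bias_se`,
#'   `loa_low`, `loa_high`, `n`, `t_stat`, `p_value`, and `data`
#'   (tibble of means and differences for plotting).
#' @export
bland_altman <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 2)
  d <- ref - pred
  bias <- mean(d)
  sd_d <- stats::sd(d)
  n <- length(d)
  se <- sd_d / sqrt(n)
  t_stat <- if (sd_d > 0) bias / se else NA_real_
  p <- if (is.na(t_stat)) NA_real_ else 2 * stats::pt(-abs(t_stat), df = n - 1)
  structure(
    list(bias = bias, sd_diff = sd_d, bias_se = se,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         n = n, t_stat = t_stat, p_value = p,
         data = tibble::tibble(mean = (pred + ref) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d: bias %.2f ms +/- %.2f (SE), LoA [%.2f, %.2f] ms\n",
    x$n, 1000 * x$bias, 1000 * x$bias_se, 1000 * x$loa_low, 1000 * x$loa_high
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, bias_se = x$bias_se, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, n = x$n,
    t_stat = x$t_stat, p_value = x$p_value
  )
}

#' Compare end-systole prediction models on holdout cycles
#'
#' For each fitted or reference model, predicts end-systole from each
#' holdout cycle's heart rate and runs a Bland-Altman analysis against the
#' measured end-systole times; biases of different models are then compared
#' with paired t-tests. Outlying cycles — e.g. abnormally long RR without a
#' matching systole change (non-conducted P wave) or an abnormally long
#' systole (extrasystole) — are excluded by a robust screen before
#' analysis: cycles whose model-vs-measurement difference deviates from the
#' median difference by more than `outlier_mads` MADs under *any* model are
#' dropped, with logged reasons.
#'
#' @param holdout Tibble of holdout cycles with `hr` and `systole_s` (and
#'   optionally `subject_id`).
#' @param models Named list of `cardiac_model`s (or a single model).
#' @param outlier_mads Robust exclusion threshold (default 4).
#' @return A `model_comparison`: `table` (one row per model: tidy
#'   Bland-Altman columns), `pairwise` (paired t-tests between model
#'   absolute errors), `excluded` (tibble of dropped cycles with reasons),
#'   `ba` (named list of `bland_altman` objects).
#' @export
compare_models <- function(holdout, models, outlier_mads = 4) {
  if (inherits(models, "cardiac_model")) models <- list(model = models)
  stopifnot(length(models) >= 1, nrow(holdout) >= 2)
  preds <- lapply(models, predict_end_systole, hr_bpm = holdout$hr)
  diffs <- lapply(preds, function(p) holdout$systole_s - p)

  out_mask <- rep(FALSE, nrow(holdout))
  why <- rep(NA_character_, nrow(holdout))
  for (nm in names(diffs)) {
    d <- diffs[[nm]]
    med <- stats::median(d)
    mad <- stats::mad(d)
    if (mad == 0) next
    bad <- abs(d - med) > outlier_mads * mad
    why[bad & !out_mask] <- sprintf(
      "deviation > %g MAD from median difference under %s", outlier_mads, nm
    )
    out_mask <- out_mask | bad
  }
  keep <- !out_mask
  if (sum(keep) < 2) stop("fewer than 2 holdout cycles survive outlier screening")

  ba <- lapply(names(models), function(nm) {
    bland_altman(preds[[nm]][keep], holdout$systole_s[keep])
  })
  names(ba) <- names(models)
  table <- dplyr::bind_rows(lapply(ba, tidy), .id = "model")

  pairs <- if (length(models) >= 2) {
    utils::combn(names(models), 2, simplify = FALSE)
  } else {
    list()
  }
  pairwise <- dplyr::bind_rows(lapply(pairs, function(pr) {
    e1 <- abs(diffs[[pr[1]]][keep])
    e2 <- abs(diffs[[pr[2]]][keep])
    tt <- stats::t.test(e1, e2, paired = TRUE)
    tibble::tibble(model_a = pr[1], model_b = pr[2],
                   mean_abs_err_a = mean(e1), mean_abs_err_b = mean(e2),
                   t_stat = unname(tt$statistic), p_value = tt$p.value)
  }))
  excluded <- tibble::tibble(
    row = which(out_mask), hr = holdout$hr[out_mask],
    systole_s = holdout$systole_s[out_mask], reason = why[out_mask]
  )
  structure(list(table = table, pairwise = pairwise, excluded = excluded,
                 ba = ba),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(as.data.frame(x$table))
  if (nrow(x$excluded)) {
    cat(sprintf("(%d cycle(s) excluded as outliers)\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' Bi-phasic projection of an intra-cycle time into the mean cycle
#'
#' The cine reconstruction maps each acquired sample's time within its own
#' cardiac cycle into a common mean cycle by two linear stretches: systole
#' `[0, systole_i]` onto `[0, mean_systole]` and diastole
#' `[systole_i, rr_i]` onto `[mean_systole, mean_rr]`. The map is
#' continuous, strictly increasing, and bijective onto `[0, mean_rr]`.
#'
#' @param t Time(s) since the cycle's R wave (s), in `[0, rr_i]`.
#' @param systole_i This cycle's end-systole time (s), in `(0, rr_i)`.
#' @param rr_i This cycle's RR duration (s).
#' @param map A list/`biphasic_map` with `mean_systole` and `mean_rr` (s).
#' @return Projected time(s) in the mean cycle (s).
#' @export
biphasic_project <- function(t, systole_i, rr_i, map) {
  stopifnot(map$mean_systole > 0, map$mean_rr > map$mean_systole,
            systole_i > 0, all(t >= 0), all(t <= rr_i + 1e-12))
  if (rr_i <= systole_i) stop("degenerate diastole: rr_i <= systole_i")
  ifelse(
    t <= systole_i,
    t * map$mean_systole / systole_i,
    map$mean_systole +
      (t - systole_i) * (map$mean_rr - map$mean_systole) / (rr_i - systole_i)
  )
}

#' Mean-cycle description for the bi-phasic projection
#'
#' @param systole_s Per-cycle end-systole durations (s) of accepted cycles.
#' @param rr Per-cycle RR durations (s).
#' @return A `biphasic_map` with `mean_systole` and `mean_rr`.
#' @export
biphasic_map <- function(systole_s, rr) {
  m <- list(mean_systole = mean(systole_s), mean_rr = mean(rr))
  stopifnot(m$mean_systole > 0, m$mean_systole < m$mean_rr)
  class(m) <- "biphasic_map"
  m
}

#' Synthetic multi-beat sample stream for cine reconstruction
#'
#' Emulates a retrospectively gated acquisition of a tissue/flow velocity
#' waveform: one sample per TR over many beats, each beat carrying a
#' systolic S lobe (ending at that beat's true end-systole) and an
#' early-diastolic E lobe whose position scales with the beat's diastole.
#' This stand-in is synthetic: the real counterpart is a free-breathing
#' phase-contrast scan, which the aortic-flow simulator does not produce.
#'
#' @param rr Per-beat RR durations (s).
#' @param end_systole Per-beat true end-systole durations (s).
#' @param dt Sampling interval (s), default 6.6 ms.
#' @param e_amp,s_amp Peak amplitudes of the E and S lobes (cm/s).
#' @param noise_sd Additive Gaussian noise SD (cm/s).
#' @return Tibble of samples: `t_abs`, `beat`, `t_in_cycle`, `rr`,
#'   `systole_s` (true), `value`.
#' @export
simulate_cine_samples <- function(rr, end_systole, dt = 0.0066,
                                  e_amp = 8, s_amp = 10, noise_sd = 0) {
  stopifnot(length(rr) == length(end_systole), all(end_systole < rr))
  r_starts <- c(0, cumsum(rr))
  t_abs <- seq(0, sum(rr) - dt / 2, by = dt)
  beat <- findInterval(t_abs, r_starts, rightmost.closed = FALSE)
  t_in <- t_abs - r_starts[beat]
  s_i <- end_systole[beat]
  rr_i <- rr[beat]
  # S lobe over (0, S_i); E lobe centred at S_i + 0.18 * diastole
  value <- s_amp * sin(pi * pmin(pmax(t_in / s_i, 0), 1)) +
    e_amp * exp(-((t_in - (s_i + 0.18 * (rr_i - s_i))) /
                    (0.08 * (rr_i - s_i)))^2 / 2)
  if (noise_sd > 0) value <- value + stats::rnorm(length(value), 0, noise_sd)
  tibble::tibble(t_abs = t_abs, beat = beat, t_in_cycle = t_in,
                 rr = rr_i, systole_s = s_i, value = value)
}

#' Retrospectively gated cine reconstruction via bi-phasic projection
#'
#' Projects each acquired sample's intra-cycle time into the mean cycle
#' using per-cycle end-systole from either the measured values or a model's
#' prediction, then averages samples into `n_frames` uniform bins of the
#' mean cycle. An inaccurate end-systole source misaligns samples from
#' different beats and smears sharp mid-cycle features, lowering the
#' early-diastolic filling (E-wave) peak.
#'
#' @param samples Sample tibble from [simulate_cine_samples()] (or with the
#'   same columns).
#' @param end_systole_source `"measured"` (use `samples$systole_s`) or a
#'   `cardiac_model` whose prediction at each beat's heart rate is used;
#'   alternatively a numeric vector of per-beat end-systole values (s).
#' @param n_frames Number of cine frames (default 64).
#' @param e_window_frac Early-diastole window for the E peak as a fraction
#'   of diastole after mean systole (default 1/3).
#' @return A `cine_recon`: `course` tibble (`time`, `value`,
#'   `n_samples`, `interpolated`), `e_peak`, `map` (the `biphasic_map`),
#'   `n_interpolated`.
#' @export
reconstruct_cine <- function(samples, end_systole_source = "measured",
                             n_frames = 64L, e_window_frac = 1 / 3) {
  stopifnot(n_frames >= 1)
  per_beat <- samples[!duplicated(samples$beat), c("beat", "rr", "systole_s")]
  src <- if (inherits(end_systole_source, "cardiac_model")) {
    predict_end_systole(end_systole_source, 60 / per_beat$rr)
  } else if (is.numeric(end_systole_source)) {
    stopifnot(length(end_systole_source) == nrow(per_beat))
    end_systole_source
  } else if (identical(end_systole_source, "measured")) {
    per_beat$systole_s
  } else {
    stop("unknown end-systole source")
  }
  src <- pmin(pmax(src, 1e-3), per_beat$rr - 1e-3)
  map <- biphasic_map(per_beat$systole_s, per_beat$rr)

  s_of_beat <- src[match(samples$beat, per_beat$beat)]
  t_proj <- purrr::pmap_dbl(
    list(samples$t_in_cycle, s_of_beat, samples$rr),
    function(t, s, rr) biphasic_project(min(t, rr), s, rr, map)
  )
  edges <- seq(0, map$mean_rr, length.out = n_frames + 1L)
  bin <- pmin(pmax(findInterval(t_proj, edges, rightmost.closed = TRUE), 1L),
              n_frames)
  course <- tibble::tibble(
    frame = seq_len(n_frames),
    time = (edges[-1] + edges[-length(edges)]) / 2,
    value = as.numeric(tapply(samples$value, factor(bin, levels = seq_len(n_frames)),
                              mean)),
    n_samples = as.integer(table(factor(bin, levels = seq_len(n_frames))))
  )
  course$interpolated <- is.na(course$value)
  if (any(course$interpolated)) {
    filled <- stats::approx(course$time[!course$interpolated],
                            course$value[!course$interpolated],
                            xout = course$time, rule = 2)$y
    course$value[course$interpolated] <- filled[course$interpolated]
  }
  e_lo <- map$mean_systole
  e_hi <- map$mean_systole + e_window_frac * (map$mean_rr - map$mean_systole)
  in_e <- course$time >= e_lo & course$time <= e_hi
  e_peak <- if (any(in_e)) max(course$value[in_e]) else NA_real_
  structure(
    list(course = course, e_peak = e_peak, map = map,
         n_interpolated = sum(course$interpolated)),
    class = "cine_recon"
  )
}

#' Paired one-sided Wilcoxon test of E-peak differences
#'
#' Compares E-wave peaks reconstructed with an accurate vs an inaccurate
#' end-systole source (alternative: accurate > inaccurate). For n <= 10
#' pairs the exact permutation distribution of the signed-rank statistic is
#' used, matching the small-sample setting of the cine illustration.
#'
#' @param e_accurate,e_biased Paired E-peak values.
#' @return A list with `statistic` (V) and `p_value`.
#' @export
e_peak_test <- function(e_accurate, e_biased) {
  stopifnot(length(e_accurate) == length(e_biased))
  wt <- stats::wilcox.test(e_accurate, e_biased, paired = TRUE,
                           alternative = "greater",
                           exact = length(e_accurate) <= 10)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
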