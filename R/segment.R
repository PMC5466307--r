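#' Leading singular components of a velocity map
#'
#' Singular value decomposition of the 1D+t velocity image. Pulsatile
#' vessels dominate the first few singular components because their
#' space-time signal is nearly rank one (a spatial footprint times a flow
#' waveform), while noise spreads across all components.
#'
#' @param map A `velocity_map`.
#' @param k Number of leading components (default 3).
#' @return A `svd_components` list: `d` (first `k` singular values), `u`
#'   (`n_pixels x k` spatial vectors), `v` (`n_frames x k` temporal
#'   vectors), and `images` (list of the `k` rank-1 images
#'   \eqn{\sigma_i u_i v_i^T}).
#' @export
svd_components <- function(map, k = 3L) {
  x <- map$velocity
  stopifnot(all(is.finite(x)), k >= 1, k <= min(dim(x)))
  if (all(x == 0)) stop("degenerate velocity map: all zero")
  s <- svd(x, nu = k, nv = k)
  images <- lapply(seq_len(k), function(i) {
    s$d[i] * tcrossprod(s$u[, i], s$v[, i])
  })
  structure(list(d = s$d[seq_len(k)], u = s$u, v = s$v, images = images,
                 n_pixels = nrow(x), pixel_offset = map$pixel_offset),
            class = "svd_components")
}

#' Threshold singular components into a spatial vessel mask
#'
#' A pixel is kept when its largest temporal-energy-weighted spatial
#' loading over the components, \eqn{L(x) = \max_i \sigma_i |u_i(x)|},
#' reaches `tau` times the maximum of `L` over all pixels; this is
#' equivalent to OR-combining the per-component masks thresholded against
#' the common global maximum. Weighting by the singular value means a
#' component that only carries noise (small \eqn{\sigma_i}) cannot inject
#' pixels into the mask, while `tau = 0.25` keeps the full footprint of
#' every genuinely pulsatile vessel.
#'
#' @param components A `svd_components` object.
#' @param tau Relative threshold in (0, 1].
#' @return Logical vector over pixels (the binary spatial mask).
#' @export
threshold_components <- function(components, tau = 0.25) {
  stopifnot(inherits(components, "svd_components"), tau > 0, tau <= 1)
  loadings <- vapply(seq_along(components$d), function(i) {
    components$d[i] * abs(components$u[, i])
  }, numeric(nrow(components$u)))
  l_max <- apply(loadings, 1, max)
  mask <- l_max >= tau * max(l_max) * (1 - 1e-10)
  if (!any(mask)) stop("segmentation failure: empty threshold mask")
  mask
}

#' Group a spatial mask into contiguous regions of interest
#'
#' Maximal runs of consecutive kept pixels become ROIs; each ROI's velocity
#' time course is the unweighted mean of its pixels' series per frame.
#'
#' @param mask Logical vector over pixels.
#' @param map The `velocity_map` the mask refers to.
#' @return A tibble with one row per ROI: `roi` (index), `first_pixel`,
#'   `last_pixel` (1-based on the cropped axis), `n_pixels`,
#'   `mean_velocity`, and `course` (list column of numeric vectors).
#' @export
group_rois <- function(mask, map) {
  stopifnot(any(mask), length(mask) == nrow(map$velocity))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rois <- purrr::map(keep, function(i) {
    px <- seq.int(starts[i], ends[i])
    course <- colMeans(map$velocity[px, , drop = FALSE])
    tibble::tibble(
      first_pixel = px[1], last_pixel = px[length(px)],
      n_pixels = length(px), mean_velocity = mean(course),
      course = list(course)
    )
  })
  out <- dplyr::bind_rows(rois)
  out$roi <- seq_len(nrow(out))
  dplyr::relocate(out, "roi")
}

#' Power of a velocity course in the cardiac spectral band
#'
#' Integrates the plain FFT periodogram of the mean-removed course over the
#' band `mean_hr / 60` +/- `halfwidth_hz`. Pulsatile vessels concentrate
#' their power at the heart frequency; noise and slow drifts do not. If the
#' record is too short to resolve the band, it is widened to one frequency
#' bin and a warning is logged.
#'
#' @param course Numeric velocity time course (cm/s).
#' @param mean_hr_bpm Subject mean heart rate (bpm), taken from screened
#'   R-R intervals.
#' @param dt Frame spacing (s).
#' @param halfwidth_hz Half width of the cardiac band (Hz), default 0.03.
#' @return Band power ((cm/s)^2, periodogram units).
#' @export
cardiac_band_power <- function(course, mean_hr_bpm, dt, halfwidth_hz = 0.03) {
  n <- length(course)
  stopifnot(n >= 4, dt > 0, mean_hr_bpm > 0)
  f0 <- mean_hr_bpm / 60
  x <- course - mean(course)
  spec <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1L) / (n * dt)
  pos <- freqs > 0 & freqs <= 1 / (2 * dt)
  in_band <- pos & freqs >= f0 - halfwidth_hz & freqs <= f0 + halfwidth_hz
  if (!any(in_band)) {
    warning("cardiac band below spectral resolution; widened to nearest bin")
    cand <- which(pos)
    in_band <- cand[which.min(abs(freqs[cand] - f0))]
  }
  2 * sum(spec[in_band])
}

#' Select the ascending-aorta ROI
#'
#' Rule: find the maximum cardiac-band power `P*` over all ROIs; keep ROIs
#' with more than 40% of `P*` *and* a positive mean velocity (the ascending
#' aorta flows head-to-foot through the slice, mapped to positive sign;
#' the descending aorta is antiparallel and excluded); among those, choose
#' the largest ROI in pixels (ties: lowest pixel index, for determinism).
#'
#' @param rois ROI tibble from [group_rois()].
#' @param mean_hr_bpm Subject mean heart rate (bpm).
#' @param dt Frame spacing (s).
#' @param power_frac Fraction of the maximum band power required (0.4).
#' @param halfwidth_hz Cardiac band half width (Hz).
#' @return The ROI tibble with `band_power` and `candidate` columns added
#'   and attribute `chosen` (the selected `roi` index).
#' @export
select_aorta <- function(rois, mean_hr_bpm, dt, power_frac = 0.4,
                         halfwidth_hz = 0.03) {
  stopifnot(nrow(rois) >= 1)
  rois$band_power <- purrr::map_dbl(
    rois$course, cardiac_band_power,
    mean_hr_bpm = mean_hr_bpm, dt = dt, halfwidth_hz = halfwidth_hz
  )
  p_max <- max(rois$band_power)
  rois$candidate <- rois$band_power > power_frac * p_max & rois$mean_velocity > 0
  if (!any(rois$candidate)) {
    stop("segmentation failure: no ROI with positive mean flow in the cardiac band")
  }
  cand <- rois[rois$candidate, ]
  cand <- cand[order(-cand$n_pixels, cand$first_pixel), ]
  attr(rois, "chosen") <- cand$roi[1]
  rois
}

#' Automatic spatial segmentation of the ascending aorta
#'
#' Full segmentation chain on a reconstructed velocity map: SVD of the
#' space-time image, thresholding of the three leading components into a
#' vessel mask, grouping into contiguous ROIs, and selection of the aorta by
#' cardiac-band power, flow sign and size. The procedure is parameter-free
#' per subject: the same defaults apply to every subject.
#'
#' @param map A `velocity_map`.
#' @param mean_hr_bpm Subject mean heart rate (bpm) from screened cycles.
#' @param k Number of singular components (3).
#' @param tau Component threshold (0.25).
#' @param power_frac Band-power fraction (0.4).
#' @param halfwidth_hz Cardiac band half width (0.03 Hz).
#' @return A `segmentation` object: `rois` (tibble with selection columns),
#'   `chosen` (one-row tibble of the selected ROI), `course` (its velocity
#'   time course), `pixels` (cropped-axis pixel indices),
#'   `pixels_original` (uncropped-axis indices), `singular_values`, `mask`.
#' @export
segment_aorta <- function(map, mean_hr_bpm, k = 3L, tau = 0.25,
                          power_frac = 0.4, halfwidth_hz = 0.03) {
  comps <- svd_components(map, k = k)
  mask <- threshold_components(comps, tau = tau)
  rois <- group_rois(mask, map)
  rois <- select_aorta(rois, mean_hr_bpm, map$dt,
                       power_frac = power_frac, halfwidth_hz = halfwidth_hz)
  chosen <- rois[rois$roi == attr(rois, "chosen"), ]
  pixels <- seq.int(chosen$first_pixel, chosen$last_pixel)
  structure(
    list(rois = rois, chosen = chosen, course = chosen$course[[1]],
         pixels = pixels, pixels_original = pixels + map$pixel_offset,
         singular_values = comps$d, mask = mask, dt = map$dt, t0 = map$t0),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation> %d ROI(s); aorta = pixels %d..%d (%d px), band power %.3g\n",
    nrow(x$rois), x$chosen$first_pixel, x$chosen$last_pixel,
    x$chosen$n_pixels, x$chosen$band_power
  ))
  invisible(x)
}

#' Ground-truth velocity map from a simulated scene
#'
#' Bypasses k-space rendering and reconstruction: packages the simulated
#' scene (optionally cropped to the central FOV fraction) directly as a
#' `velocity_map`. Used for fast tests of segmentation and detection, which
#' is legitimate because the render/reconstruct round trip is exact to
#' float tolerance (tested separately).
#'
#' @param scene A `velocity_scene`.
#' @param fraction Central FOV fraction to keep (default 0.5, as in the
#'   reconstruction).
#' @return A `velocity_map`.
#' @export
scene_velocity_map <- function(scene, fraction = 0.5) {
  n <- nrow(scene$velocity)
  keep <- round(fraction * n)
  start <- (n - keep) %/% 2 + 1L
  idx <- seq.int(start, start + keep - 1L)
  velocity_map(scene$velocity[idx, , drop = FALSE],
               scene$magnitude[idx, , drop = FALSE],
               dt = scene$acq$tr_s, t0 = scene$times[1],
               pixel_extent = scene$acq$fov_mm / scene$acq$matrix_freq,
               pixel_offset = start - 1L)
}
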