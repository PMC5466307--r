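#' 1D Fourier reconstruction of central-line echoes
#'
#' Transforms every k-space echo into 1D image space along the frequency
#' encoding direction (unitary FFT, so signal energy is preserved), per
#' receive channel. The spatial axis is shifted so that pixel 1 is the field
#' of view edge and pixel N/2+1 is the magnet isocentre.
#'
#' @param echoes An `echo_stream` (see [render_kspace_lines()]).
#' @return A `channel_images` list: `images` (list of complex
#'   `n_pixels x n_echoes` matrices per channel), `echo_times`,
#'   `venc_toggle`, `config`, `pixel_offset` (0 here; tracks cropping).
#' @export
fourier_1d <- function(echoes) {
  stopifnot(inherits(echoes, "echo_stream"),
            ncol(echoes$samples[[1]]) >= 2)
  dts <- diff(echoes$echo_times)
  if (length(dts) && any(abs(dts - dts[1]) > 1e-9)) {
    stop("malformed echo stream: non-uniform echo spacing")
  }
  images <- lapply(echoes$samples, function(k) {
    fftshift_rows(stats::mvfft(k) / sqrt(nrow(k)))
  })
  structure(
    list(images = images, echo_times = echoes$echo_times,
         venc_toggle = echoes$venc_toggle, config = echoes$config,
         pixel_offset = 0L),
    class = "channel_images"
  )
}

#' Crop the reconstructed image to the central field of view
#'
#' Keeps only the centred `round(fraction * N)` pixels (default: the central
#' 50% FOV, 128 of 256 pixels), discarding noisy air regions and reducing
#' processing cost. Pixel indexing metadata is updated so ground-truth pixel
#' positions remain comparable.
#'
#' @param image A `channel_images` object.
#' @param fraction Fraction of the FOV to keep, in (0, 1].
#' @param truth Optional `ground_truth`; if the crop would exclude any true
#'   aorta pixel a warning is raised (synthetic QC only).
#' @return The cropped `channel_images`, with `pixel_offset` recording how
#'   many leading pixels were removed.
#' @export
crop_fov <- function(image, fraction = 0.5, truth = NULL) {
  stopifnot(inherits(image, "channel_images"), fraction > 0, fraction <= 1)
  n <- nrow(image$images[[1]])
  keep <- round(fraction * n)
  start <- (n - keep) %/% 2 + 1L # 0-based 64..191 for N = 256, fraction 0.5
  idx <- seq.int(start, start + keep - 1L)
  if (!is.null(truth) && !all(truth$aorta_pixels %in% (idx + image$pixel_offset))) {
    warning("crop excludes ground-truth aorta pixels")
  }
  image$images <- lapply(image$images, function(m) m[idx, , drop = FALSE])
  image$pixel_offset <- image$pixel_offset + start - 1L
  image
}

#' Shared velocity encoding: velocity from adjacent interleaved echoes
#'
#' Computes one velocity frame from every *sliding* pair of consecutive
#' echoes (not disjoint pairs), so the velocity frame spacing equals one TR
#' even though two encodings are interleaved. For echoes `j` and `j + 1`
#' with toggles `s_j = -s_{j+1}`:
#' \deqn{v_j = s_{j+1} \frac{venc}{\pi}
#'       \arg\left(I_{j+1} \bar I_j\right)}
#' per pixel, and the frame magnitude is the mean of the two echo
#' magnitudes. Frame `j` is timestamped at the midpoint of its echo pair.
#'
#' @param image A `channel_images` object (possibly cropped).
#' @param acq An [acq_config()]; defaults to the stream's.
#' @return A list of per-channel `velocity_map` objects.
#' @export
shared_velocity_encoding <- function(image, acq = image$config) {
  stopifnot(inherits(image, "channel_images"))
  tog <- image$venc_toggle
  if (any(tog[-1] * tog[-length(tog)] != -1)) {
    stop("velocity-encoding toggle must alternate")
  }
  n_e <- ncol(image$images[[1]])
  if (n_e < 2) stop("need at least two echoes")
  j0 <- seq_len(n_e - 1L)
  lapply(image$images, function(img) {
    prod <- img[, j0 + 1L, drop = FALSE] * Conj(img[, j0, drop = FALSE])
    v <- sweep(Arg(prod), 2, tog[j0 + 1L], `*`) * (acq$venc_cm_s / pi)
    m <- (Mod(img[, j0, drop = FALSE]) + Mod(img[, j0 + 1L, drop = FALSE])) / 2
    velocity_map(v, m,
                 dt = acq$tr_s,
                 t0 = mean(image$echo_times[1:2]),
                 pixel_extent = acq$fov_mm / acq$matrix_freq,
                 pixel_offset = image$pixel_offset)
  })
}

#' Construct a 1D+t velocity map
#'
#' The reconstructed signal: a real-valued space-by-time image of velocity
#' projected along the phase-encoding axis (cm/s), plus its magnitude image,
#' at one-TR temporal spacing.
#'
#' @param velocity,magnitude Congruent `n_pixels x n_frames` matrices.
#' @param dt Frame spacing (s), equal to TR.
#' @param t0 Time of the first frame (s).
#' @param pixel_extent Pixel size along frequency encoding (mm).
#' @param pixel_offset Leading pixels removed by cropping (0-based).
#' @return A `velocity_map` object.
#' @export
velocity_map <- function(velocity, magnitude = NULL, dt, t0 = 0,
                         pixel_extent = NA_real_, pixel_offset = 0L) {
  velocity <- as.matrix(velocity)
  if (is.null(magnitude)) magnitude <- matrix(1, nrow(velocity), ncol(velocity))
  stopifnot(all(dim(velocity) == dim(magnitude)), dt > 0)
  structure(
    list(velocity = velocity, magnitude = magnitude, dt = dt, t0 = t0,
         pixel_extent = pixel_extent, pixel_offset = as.integer(pixel_offset)),
    class = "velocity_map"
  )
}

#' Frame times of a velocity map
#' @param map A `velocity_map`.
#' @return Numeric vector of frame times (s).
#' @export
frame_times <- function(map) {
  map$t0 + (seq_len(ncol(map$velocity)) - 1L) * map$dt
}

#' Magnitude-weighted channel combination
#'
#' Combines per-channel velocity maps into the final map as the
#' magnitude-weighted mean of the channel velocities,
#' \eqn{v = \sum_c m_c v_c / \sum_c m_c}, with combined magnitude
#' \eqn{\sum_c m_c}. Pixels with zero total magnitude get velocity 0.
#'
#' @param maps List of per-channel `velocity_map`s with congruent shapes.
#' @return A single combined `velocity_map`.
#' @export
combine_channels <- function(maps) {
  stopifnot(length(maps) >= 1)
  msum <- Reduce(`+`, lapply(maps, `[[`, "magnitude"))
  vw <- Reduce(`+`, lapply(maps, function(m) m$velocity * m$magnitude))
  v <- ifelse(msum > 0, vw / pmax(msum, .Machine$double.eps), 0)
  out <- maps[[1]]
  out$velocity <- v
  out$magnitude <- msum
  out
}

#' Full RTPC reconstruction: echoes to combined velocity map
#'
#' Convenience chain: [fourier_1d()] then [crop_fov()] then
#' [shared_velocity_encoding()] then [combine_channels()]. No image-based
#' velocity-offset correction is applied, so any constant phase offset in
#' the stream passes through linearly to velocity.
#'
#' @param echoes An `echo_stream`.
#' @param fraction FOV fraction kept (default 0.5).
#' @param truth Optional ground truth for the crop QC warning.
#' @return A combined `velocity_map` with frame count = echo count - 1.
#' @export
reconstruct_velocity_map <- function(echoes, fraction = 0.5, truth = NULL) {
  img <- crop_fov(fourier_1d(echoes), fraction = fraction, truth = truth)
  combine_channels(shared_velocity_encoding(img))
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf(
    "<velocity_map> %d pixels x %d frames, dt %.2f ms, |v| max %.1f cm/s\n",
    nrow(x$velocity), ncol(x$velocity), 1000 * x$dt, max(abs(x$velocity))
  ))
  invisible(x)
}
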