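toy_map <- function(v, dt = 0.0066) velocity_map(v, dt = dt)

test_that("SVD components reproduce low-rank structure and obey Eckart-Young", {
  # rank-1 map: first component reproduces it, remaining singular values 0
  u <- c(0, 1, 2, 0); w <- sin(seq(0, 4 * pi, length.out = 60))
  m1 <- toy_map(tcrossprod(u, w))
  comp <- svd_components(m1, k = 3)
  expect_equal(comp$images[[1]], m1$velocity, tolerance = 1e-10)
  expect_lt(comp$d[2] + comp$d[3], 1e-10)

  # sum of squared singular values never exceeds the Frobenius norm,
  # with equality iff the rank is within k
  set.seed(4)
  mr <- toy_map(matrix(rnorm(8 * 60), 8, 60))
  c_r <- svd_components(mr, k = 3)
  expect_lt(sum(c_r$d^2), sum(mr$velocity^2))
  expect_equal(sum(svd_components(m1, k = 3)$d^2), sum(m1$velocity^2),
               tolerance = 1e-10)

  expect_error(svd_components(toy_map(matrix(0, 4, 10))), "degenerate")
})

test_that("thresholding keeps dominant-loading pixels and drops noise pixels", {
  # one dominant pixel at tau = 0.5 keeps only that pixel
  u <- c(0.05, 1, 0.1, 0.02); w <- rep(1, 50)
  comp <- svd_components(toy_map(tcrossprod(u, w)), k = 1)
  expect_equal(which(threshold_components(comp, tau = 0.5)), 2L)

  # uniform loading: every pixel kept for any tau <= 1
  cu <- svd_components(toy_map(tcrossprod(rep(1, 6), w)), k = 1)
  expect_true(all(threshold_components(cu, tau = 1)))

  # a small-sigma noise component cannot inject pixels into the mask
  sig <- tcrossprod(c(0, 10, 10, 0, 0, 0), sin(seq(0, 6 * pi, length.out = 80)))
  set.seed(7)
  noise <- matrix(rnorm(6 * 80, sd = 0.05), 6, 80)
  comp2 <- svd_components(toy_map(sig + noise), k = 3)
  mask <- threshold_components(comp2, tau = 0.25)
  expect_equal(which(mask), c(2L, 3L))
})

test_that("contiguous ROI grouping and course averaging", {
  v <- matrix(0, 10, 40)
  v[3:5, ] <- 1; v[9, ] <- 2
  mask <- rep(FALSE, 10); mask[c(3, 4, 5, 9)] <- TRUE
  rois <- group_rois(mask, toy_map(v))
  expect_equal(nrow(rois), 2)
  expect_equal(rois$first_pixel, c(3L, 9L))
  expect_equal(rois$last_pixel, c(5L, 9L))
  # single-pixel ROI course equals that pixel's series
  expect_equal(rois$course[[2]], v[9, ])
  # opposite courses average to zero
  v2 <- matrix(0, 4, 40); v2[2, ] <- sin(1:40); v2[3, ] <- -sin(1:40)
  m2 <- rep(FALSE, 4); m2[2:3] <- TRUE
  expect_equal(group_rois(m2, toy_map(v2))$course[[1]], rep(0, 40))
})

test_that("cardiac band power concentrates on the heart frequency", {
  dt <- 0.0066
  n <- 4096
  # heart frequency aligned to a periodogram bin (30 cycles per record)
  # so leakage cannot smear power outside the cardiac band
  f0 <- 30 / (n * dt)
  t <- (0:(n - 1)) * dt
  pure <- sin(2 * pi * f0 * t)
  hr0 <- 60 * f0
  # a pure sinusoid at the heart frequency: band holds >= 99% of AC power
  p_band <- cardiac_band_power(pure, hr0, dt)
  p_tot <- 2 * sum((Mod(fft(pure - mean(pure)))^2 / n)[2:(n / 2)])
  expect_gt(p_band / p_tot, 0.99)
  # constant course: zero power
  expect_equal(cardiac_band_power(rep(3.3, n), hr0, dt), 0)
  # white noise of equal variance always loses to the periodic pulse
  set.seed(11)
  wins <- vapply(1:100, function(i) {
    noise <- rnorm(n, sd = sd(pure))
    cardiac_band_power(pure, hr0, dt) > cardiac_band_power(noise, hr0, dt)
  }, logical(1))
  expect_true(all(wins))
  # too-short record: widened band warns but returns a finite power
  expect_warning(p1 <- cardiac_band_power(sin(2 * pi * f0 * t[1:200]), hr0, dt),
                 "widened")
  expect_true(is.finite(p1))
})

test_that("aorta selection applies the 40% power, sign and size rules", {
  dt <- 0.0066; n <- 4096; t <- (0:(n - 1)) * dt
  pulse <- function(amp) amp * pmax(sin(2 * pi * (67 / 60) * t), 0)
  build_rois <- function(courses, sizes) {
    first <- cumsum(c(1, head(sizes, -1) + 1))
    tibble::tibble(
      roi = seq_along(courses), first_pixel = first,
      last_pixel = first + sizes - 1L, n_pixels = sizes,
      mean_velocity = vapply(courses, mean, numeric(1)), course = courses
    )
  }
  # single positive pulsatile ROI selects itself
  r1 <- select_aorta(build_rois(list(pulse(50)), 1L), 67, dt)
  expect_equal(attr(r1, "chosen"), 1L)

  # descending aorta: similar power but negative mean flow is excluded
  r2 <- select_aorta(
    build_rois(list(pulse(50), -pulse(48)), c(6L, 4L)), 67, dt
  )
  expect_equal(attr(r2, "chosen"), 1L)
  expect_false(r2$candidate[2])

  # the 40% power rule excludes a weak ROI regardless of its size
  r3 <- select_aorta(
    build_rois(list(pulse(50), pulse(25)), c(4L, 9L)), 67, dt
  )
  expect_false(r3$candidate[2]) # power ratio 0.25 < 0.4
  expect_equal(attr(r3, "chosen"), 1L)

  # among candidates, the larger ROI wins even with slightly less power
  r4 <- select_aorta(
    build_rois(list(pulse(50), pulse(45)), c(4L, 7L)), 67, dt
  )
  expect_equal(attr(r4, "chosen"), 2L)

  # all-negative flow is a segmentation failure event
  expect_error(select_aorta(build_rois(list(-pulse(50)), 1L), 67, dt),
               "segmentation failure")
})

test_that("segmentation recovers the true aorta across seeded subjects", {
  # scene-level maps (render/recon round trip is exact; tested separately)
  hits <- vapply(1:12, function(sd) {
    cfg <- noisy_config(n_beats = 24L, seed = 700 + sd)
    rr <- simulate_rr_sequence(cfg)
    s <- true_end_systole(cfg, rr)
    scene <- simulate_velocity_scene(cfg, acq_config(), rr, s)
    map <- scene_velocity_map(scene)
    seg <- segment_aorta(map, mean(60 / rr))
    truth_px <- scene$truth$aorta_pixels
    conf_px <- unlist(scene$truth$confounder_pixels)
    overlap <- length(intersect(seg$pixels_original, truth_px)) /
      length(truth_px)
    overlap >= 0.9 && !any(seg$pixels_original %in% conf_px)
  }, logical(1))
  expect_true(all(hits))
})
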