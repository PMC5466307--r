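test_that("train/holdout split takes the first 80% per subject", {
  mk <- function(n, id) tibble::tibble(
    subject_id = id, hr = 60 + seq_len(n) / 10,
    systole_s = 0.35 + seq_len(n) / 1e4
  )
  sp <- split_train_holdout(mk(10, "a"))
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$holdout), 2)
  # training cycles precede holdout cycles chronologically
  expect_true(max(sp$train$systole_s) < min(sp$holdout$systole_s))

  # the cohort arithmetic: 135 -> 108/27 and 105 -> 84/21 per subject
  sp2 <- split_train_holdout(dplyr::bind_rows(mk(135, "a"), mk(105, "b")))
  expect_equal(as.integer(table(sp2$train$subject_id)), c(108L, 84L))
  expect_equal(as.integer(table(sp2$holdout$subject_id)), c(27L, 21L))

  # frac = 1: empty holdout; n < 5: flagged and excluded from both sets
  expect_equal(nrow(split_train_holdout(mk(10, "a"), frac = 1)$holdout), 0)
  sp3 <- split_train_holdout(mk(4, "tiny"))
  expect_equal(sp3$flagged, "tiny")
  expect_equal(nrow(sp3$train), 0)
})

test_that("PACM fitting recovers a noiseless generating line exactly", {
  hr <- seq(50, 90, by = 0.5)
  train <- tibble::tibble(hr = hr, systole_s = 0.456 - 0.0018 * hr)
  m <- fit_pacm(train)
  expect_equal(m$slope, -0.0018, tolerance = 1e-10)
  expect_equal(m$intercept, 0.456, tolerance = 1e-9)
  expect_equal(m$residual_sd, 0, tolerance = 1e-10)
  expect_true(m$quality_ok)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)

  # robust and ordinary least squares agree on outlier-free data
  m_ols <- fit_pacm(train, method = "ols")
  expect_equal(m$slope, m_ols$slope, tolerance = 1e-10)
  expect_equal(m$intercept, m_ols$intercept, tolerance = 1e-10)
})

test_that("the Huber fit resists a gross outlier that ruins OLS", {
  hr <- seq(50, 90, length.out = 100)
  y <- 0.456 - 0.0018 * hr
  y_out <- y; y_out[50] <- y[50] + 0.5 # half-second outlier
  train <- tibble::tibble(hr = hr, systole_s = y_out)
  m_rob <- fit_pacm(train)
  # oracle: OLS on the data without the outlier
  oracle <- fit_pacm(tibble::tibble(hr = hr[-50], systole_s = y[-50]),
                     method = "ols")
  expect_lt(abs(m_rob$slope - oracle$slope), 1e-4)
  expect_lt(abs(m_rob$intercept - oracle$intercept), 5e-3)
  # OLS on the contaminated data is visibly biased in comparison
  m_ols <- fit_pacm(train, method = "ols")
  expect_gt(abs(m_ols$intercept - oracle$intercept),
            10 * abs(m_rob$intercept - oracle$intercept))
})

test_that("the residual-SD quality gate flags noisy subjects", {
  s <- model_samples(2000, -0.0018, 0.456, 0.023, seed = 31)
  m <- fit_pacm(s)
  expect_gt(m$residual_sd, 0.02)
  expect_false(m$quality_ok)
  s2 <- model_samples(2000, -0.0018, 0.456, 0.005, seed = 32)
  expect_true(fit_pacm(s2)$quality_ok)
})

test_that("zero heart-rate variance yields a usable constant model", {
  train <- tibble::tibble(hr = rep(70, 50),
                          systole_s = 0.33 + rnorm(50, 0, 0.002))
  m <- fit_pacm(train)
  expect_equal(m$slope, 0)
  expect_equal(m$intercept, median(train$systole_s))
  expect_true(is.na(m$r_squared))
  expect_true(m$quality_ok)
  expect_equal(predict_end_systole(m, 120), m$intercept)
})

test_that("published global models expose the printed constants", {
  wm <- weissler_model("M")
  expect_equal(wm$slope, -0.0018)
  expect_equal(wm$intercept, 0.456)
  expect_equal(wm$residual_sd, 0.014)
  wf <- weissler_model("F")
  expect_equal(wf$slope, -0.0016)
  expect_equal(wf$intercept, 0.461)
  # predictions: 0.348 s at 60 bpm and 0.276 s at 100 bpm for males
  expect_equal(predict_end_systole(wm, 60), 0.348)
  expect_equal(predict_end_systole(wm, 100), 0.276)
  # prediction is affine in heart rate
  expect_equal(predict_end_systole(wm, 55) + predict_end_systole(wm, 85),
               2 * predict_end_systole(wm, 70))
  # reference presets used by the simulator
  pf <- reference_model("pacm_averaged", "F")
  expect_equal(pf$intercept, 0.464)
  ec <- reference_model("echo")
  expect_equal(ec$slope, -0.0020)
  expect_error(weissler_model("X"))
})

test_that("population model pools subjects and reports both R-squared views", {
  hr <- seq(55, 85, length.out = 40)
  a <- tibble::tibble(subject_id = "a", hr = hr,
                      systole_s = 0.46 - 0.0018 * hr)
  b <- tibble::tibble(subject_id = "b", hr = hr + 3,
                      systole_s = 0.43 - 0.0018 * (hr + 3))
  # identical lines: pooled fit recovers the common line
  m_same <- fit_population_model(dplyr::bind_rows(
    a, dplyr::mutate(a, subject_id = "b")
  ), sex = "M")
  expect_equal(m_same$slope, -0.0018, tolerance = 1e-9)
  expect_equal(m_same$kind, "pacm_averaged")

  # parallel lines with an intercept offset: pooled fit equals the OLS
  # oracle on the pooled points (checked via lm)
  pool <- dplyr::bind_rows(a, b)
  m_pool <- fit_population_model(pool, sex = "M", method = "ols")
  or <- lm(systole_s ~ hr, data = pool)
  expect_equal(m_pool$slope, unname(coef(or)[2]), tolerance = 1e-10)
  expect_equal(m_pool$intercept, unname(coef(or)[1]), tolerance = 1e-10)
  # per-cycle and subject-mean R-squared both reported and distinct views
  expect_true(is.finite(m_pool$r_squared))
  expect_true(is.finite(m_pool$r_squared_subject))

  # pooled single subject equals that subject's own PACM
  m_single <- fit_population_model(a, sex = "M")
  m_a <- fit_pacm(a)
  expect_equal(m_single$slope, m_a$slope, tolerance = 1e-12)
  expect_equal(m_single$intercept, m_a$intercept, tolerance = 1e-12)
})

test_that("generating constants are recovered from simulated cycles", {
  # scaled-down recovery check (the full 20-seed protocol runs in the
  # acceptance suite): one 3324-cycle draw from the Weissler-M row
  s <- model_samples(3324, -0.0018, 0.456, 0.014, seed = 77)
  m <- fit_pacm(s)
  expect_lt(abs(m$slope - (-0.0018)), 3e-4)
  expect_lt(abs(m$intercept - 0.456), 0.02)
  expect_lt(abs(m$residual_sd - 0.014) / 0.014, 0.05)
})

test_that("tidy and glance methods expose the model as tibbles", {
  s <- model_samples(500, -0.0018, 0.456, 0.005, seed = 9)
  m <- fit_pacm(s)
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "hr"))
  expect_equal(td$estimate, c(m$intercept, m$slope))
  gl <- glance(m)
  expect_equal(gl$residual_sd, m$residual_sd)
  expect_true(gl$quality_ok)
  expect_equal(gl$nobs, 500L)
})
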