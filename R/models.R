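#' Chronological train/holdout split of measured cycles
#'
#' Per subject, the chronologically first `floor(frac * n)` valid cycles
#' form the training set and the remainder the holdout set (default 80/20).
#' Subjects contributing fewer than 5 valid cycles are flagged and excluded
#' from model fitting.
#'
#' @param samples Tibble of valid systole samples, chronologically ordered
#'   within subject; must contain `systole_s` and `hr`, and `subject_id`
#'   when several subjects are pooled.
#' @param frac Training fraction, default 0.8.
#' @return A list of tibbles `train` and `holdout` (each with a `set`
#'   column), plus `flagged` (subject ids with n < 5).
#' @export
split_train_holdout <- function(samples, frac = 0.8) {
  stopifnot(frac > 0, frac <= 1)
  if (!"subject_id" %in% names(samples)) samples$subject_id <- "S"
  flagged <- character(0)
  parts <- samples |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      g$subject_id <- key$subject_id
      if (n < 5L) {
        flagged <<- c(flagged, key$subject_id)
        g$set <- rep("flagged", n)
        return(g)
      }
      n_train <- floor(frac * n)
      g$set <- rep(c("train", "holdout"), c(n_train, n - n_train))
      g
    }) |>
    dplyr::bind_rows()
  list(
    train = parts[parts$set == "train", , drop = FALSE],
    holdout = parts[parts$set == "holdout", , drop = FALSE],
    flagged = flagged
  )
}

new_cardiac_model <- function(slope, intercept, residual_sd, r_squared, n,
                              kind, sex = NA_character_, fit = NULL,
                              slope_se = NA_real_, intercept_se = NA_real_,
                              r_squared_subject = NA_real_) {
  quality_ok <- if (kind == "pacm") !is.na(residual_sd) && residual_sd <= 0.010 else TRUE
  structure(
    list(slope = slope, intercept = intercept, residual_sd = residual_sd,
         r_squared = r_squared, r_squared_subject = r_squared_subject,
         n_train = n, quality_ok = quality_ok, kind = kind, sex = sex,
         slope_se = slope_se, intercept_se = intercept_se, fit = fit),
    class = "cardiac_model"
  )
}

#' Fit the patient-adapted cardiac model (PACM)
#'
#' Robust linear regression (Huber M-estimator, tuning 1.345, via
#' `MASS::rlm`) of measured systole duration (s) on instantaneous heart
#' rate (bpm) over a subject's training cycles. The model quality metric is
#' the standard deviation of the residuals about the fitted line
#' (denominator n - 2); a PACM with residual SD above 10 ms is flagged bad
#' quality (R-squared is deliberately not the gate: a subject with almost
#' constant systole duration has near-zero R-squared under a perfectly good
#' constant model).
#'
#' If heart rate has zero variance the slope is 0, the intercept is the
#' median systole duration, and R-squared is undefined (NA) but the model
#' remains usable.
#'
#' @param train Tibble with `hr` (bpm) and `systole_s` (s).
#' @param method `"huber"` (default) or `"ols"` (the oracle used in tests).
#' @param kind Model kind label, default `"pacm"`.
#' @param sex Optional sex label carried in the model.
#' @return A `cardiac_model` object.
#' @export
fit_pacm <- function(train, method = c("huber", "ols"), kind = "pacm",
                     sex = NA_character_) {
  method <- match.arg(method)
  hr <- train$hr
  y <- train$systole_s
  n <- length(y)
  stopifnot(n >= 2, length(hr) == n)
  if (stats::sd(hr) == 0) {
    res <- y - stats::median(y)
    return(new_cardiac_model(
      slope = 0, intercept = stats::median(y),
      residual_sd = sqrt(sum(res^2) / max(n - 2L, 1L)),
      r_squared = NA_real_, n = n, kind = kind, sex = sex
    ))
  }
  fit <- if (method == "huber") {
    MASS::rlm(y ~ hr, psi = MASS::psi.huber, k = 1.345, maxit = 50)
  } else {
    stats::lm(y ~ hr)
  }
  co <- stats::coef(fit)
  res <- y - (co[1] + co[2] * hr)
  rsd <- sqrt(sum(res^2) / (n - 2L))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  # vcov warns on numerically perfect fits; the SEs are still what we want
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  new_cardiac_model(
    slope = unname(co[2]), intercept = unname(co[1]), residual_sd = rsd,
    r_squared = r2, n = n, kind = kind, sex = sex, fit = fit,
    intercept_se = unname(se[1]), slope_se = unname(se[2])
  )
}

#' Fit the population ("PACM averaged") model
#'
#' Same regression as [fit_pacm()] on the pooled valid cycles of all
#' subjects of one sex. Because the pooled per-cycle R-squared and an
#' R-squared computed on subject-mean points answer different questions,
#' both are reported (`r_squared` and `r_squared_subject`).
#'
#' @param samples Pooled tibble with `hr`, `systole_s` and (optionally)
#'   `subject_id`.
#' @param sex Sex label of the pool.
#' @param method Regression flavour, as in [fit_pacm()].
#' @return A `cardiac_model` with `kind = "pacm_averaged"`.
#' @export
fit_population_model <- function(samples, sex = NA_character_,
                                 method = c("huber", "ols")) {
  m <- fit_pacm(samples, method = method, kind = "pacm_averaged", sex = sex)
  if ("subject_id" %in% names(samples) &&
      length(unique(samples$subject_id)) > 1L) {
    subj <- samples |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(hr = mean(.data$hr),
                       systole_s = mean(.data$systole_s), .groups = "drop")
    pred <- m$intercept + m$slope * subj$hr
    m$r_squared_subject <-
      1 - sum((subj$systole_s - pred)^2) /
        sum((subj$systole_s - mean(subj$systole_s))^2)
  }
  m
}

# Published global model constants (slope s/bpm, intercept s, residual SD s).
global_model_table <- function() {
  tibble::tribble(
    ~kind,            ~sex, ~slope,   ~intercept, ~residual_sd, ~r_squared,
    "weissler",       "M",  -0.0018,  0.456,      0.014,        NA_real_,
    "weissler",       "F",  -0.0016,  0.461,      0.014,        NA_real_,
    "pacm_averaged",  "M",  -0.0016,  0.441,      0.023,        0.96,
    "pacm_averaged",  "F",  -0.0018,  0.464,      0.016,        0.96,
    "echo",           NA,   -0.0020,  0.488,      0.017,        0.54
  )
}

#' Weissler's global systolic-time model
#'
#' The historical phonocardiographic S1-S2 regression of systolic time on
#' heart rate, per sex: males `S = 0.456 - 0.0018 * HR`, females
#' `S = 0.461 - 0.0016 * HR` (seconds, HR in bpm), both with residual SD
#' 0.014 s. This is the global reference model that cine reconstruction
#' conventionally relies on.
#'
#' @param sex `"M"` or `"F"`.
#' @return An immutable `cardiac_model` with `kind = "weissler"`.
#' @export
weissler_model <- function(sex = c("M", "F")) {
  sex <- match.arg(sex)
  reference_model("weissler", sex)
}

#' Published reference model constants as a cardiac model
#'
#' Looks up the constants of a published global model — Weissler by sex,
#' the population-averaged PACM by sex, or the echocardiographic regression
#' — as a `cardiac_model`. The echo row is a simulation preset only (its
#' systole definition is electromechanical, not the end of forward aortic
#' flow), never validation truth.
#'
#' @param kind `"weissler"`, `"pacm_averaged"` or `"echo"`.
#' @param sex `"M"` or `"F"` (ignored for `"echo"`).
#' @return A `cardiac_model`.
#' @export
reference_model <- function(kind = c("weissler", "pacm_averaged", "echo"),
                            sex = c("M", "F")) {
  kind <- match.arg(kind)
  tab <- global_model_table()
  row <- if (kind == "echo") {
    tab[tab$kind == "echo", ]
  } else {
    sex <- match.arg(sex)
    tab[tab$kind == kind & !is.na(tab$sex) & tab$sex == sex, ]
  }
  stopifnot(nrow(row) == 1)
  new_cardiac_model(
    slope = row$slope, intercept = row$intercept,
    residual_sd = row$residual_sd, r_squared = row$r_squared,
    n = NA_integer_, kind = kind, sex = if (kind == "echo") NA_character_ else sex
  )
}

#' Predict end-systole time from heart rate
#'
#' @param model A `cardiac_model`.
#' @param hr_bpm Heart rate(s) in bpm, > 0.
#' @return Predicted end-systole duration(s) in seconds,
#'   `intercept + slope * hr_bpm`.
#' @export
predict_end_systole <- function(model, hr_bpm) {
  stopifnot(inherits(model, "cardiac_model"), all(hr_bpm > 0))
  model$intercept + model$slope * hr_bpm
}

#' @export
predict.cardiac_model <- function(object, newdata, ...) {
  hr <- if (is.data.frame(newdata)) newdata$hr else newdata
  predict_end_systole(object, hr)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_pacm
#' @param x A `cardiac_model`.
#' @param ... Unused.
#' @export
tidy.cardiac_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "hr"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @rdname fit_pacm
#' @export
glance.cardiac_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, sex = x$sex, slope = x$slope, intercept = x$intercept,
    residual_sd = x$residual_sd, r.squared = x$r_squared,
    r.squared.subject = x$r_squared_subject, nobs = x$n_train,
    quality_ok = x$quality_ok
  )
}

#' @export
print.cardiac_model <- function(x, ...) {
  cat(sprintf(
    "<cardiac_model:%s%s> S(HR) = %.4f %+.5f*HR s; residual SD %s s%s\n",
    x$kind, if (is.na(x$sex)) "" else paste0("/", x$sex),
    x$intercept, x$slope,
    ifelse(is.na(x$residual_sd), "NA", sprintf("%.4f", x$residual_sd)),
    if (x$kind == "pacm") {
      sprintf("; quality %s", if (x$quality_ok) "OK" else "BAD (>10 ms)")
    } else ""
  ))
  invisible(x)
}
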