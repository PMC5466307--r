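# Shared fixtures, built once per test run and memoised. All synthetic
# subjects here use a reduced beat count so the suite stays fast; the
# per-cycle properties under test do not depend on record length.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# clean subject: no noise anywhere, no ectopics, no confounders
clean_config <- function(n_beats = 24L, seed = 101L, ...) {
  args <- utils::modifyList(
    list(subject_id = sprintf("clean%d", seed), n_beats = n_beats,
         ectopic_rate = 0, noise_sd = 0, r_jitter_sd = 0, ecg_noise_sd = 0,
         mhd_amplitude = 0, n_confounders = 0L, seed = seed),
    list(...)
  )
  do.call(subject_config, args)
}

# default-noise subject (all nuisance processes on)
noisy_config <- function(n_beats = 12L, seed = 202L, ...) {
  args <- utils::modifyList(
    list(subject_id = sprintf("noisy%d", seed), n_beats = n_beats,
         ectopic_rate = 0, seed = seed),
    list(...)
  )
  do.call(subject_config, args)
}

clean_subject <- function() {
  fixture("clean_subject", function() {
    simulate_subject(clean_config(), keep_scene = TRUE)
  })
}

noisy_subject <- function() {
  fixture("noisy_subject", function() {
    simulate_subject(noisy_config(), keep_scene = TRUE)
  })
}

# regression samples drawn straight from a generating line (no imaging)
model_samples <- function(n, slope, intercept, residual_sd, seed,
                          mean_hr = 67, sd_hr = 9.5, bounds = c(44, 114)) {
  cfg <- subject_config(
    subject_id = "ms", n_beats = n, mean_hr = mean_hr, sd_hr = sd_hr,
    hr_bounds = bounds, true_slope = slope, true_intercept = intercept,
    residual_sd = residual_sd, ectopic_rate = 0, seed = seed
  )
  rr <- simulate_rr_sequence(cfg)
  s <- true_end_systole(cfg, rr)
  tibble::tibble(hr = 60 / rr, systole_s = s, rr = rr)
}
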