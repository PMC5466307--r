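# Zero-phase Butterworth low-pass filtering.
#
# No DSP package is available, so the classical design is implemented
# directly: analog Butterworth poles -> bilinear transform -> second-order
# sections (pole pairing), then forward-backward filtering with odd
# reflection padding. Cascaded biquads keep the very low normalized cutoffs
# used here (0.5 Hz at ~150 Hz frame rate) numerically well conditioned.

butter_lowpass_sos <- function(order, fc, fs) {
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs) # prewarped analog cutoff (rad/s)
  k <- seq_len(order)
  p_analog <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p <- (2 * fs + p_analog) / (2 * fs - p_analog) # bilinear transform
  # pair complex-conjugate poles into biquads (order assumed even here)
  stopifnot(order %% 2 == 0)
  used <- rep(FALSE, order)
  sos <- list()
  for (i in seq_len(order)) {
    if (used[i]) next
    j <- which(!used & abs(p - Conj(p[i])) < 1e-9 & seq_len(order) != i)[1]
    used[c(i, j)] <- TRUE
    a <- c(1, -2 * Re(p[i]), Mod(p[i])^2)
    b <- c(1, 2, 1) # two zeros at z = -1
    # normalize DC gain of the section to 1
    b <- b * (sum(a) / sum(b))
    sos[[length(sos) + 1L]] <- list(b = b, a = a)
  }
  sos
}

# Direct-form IIR via stats::filter (C loops): moving-average part then the
# recursive part.
iir_filter <- function(x, b, a) {
  u <- stats::filter(c(rep(0, length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  u <- as.numeric(u)[-seq_len(length(b) - 1)]
  as.numeric(stats::filter(u, -a[-1], method = "recursive"))
}

sos_filter <- function(x, sos) {
  for (sec in sos) x <- iir_filter(x, sec$b, sec$a)
  x
}

# Forward-backward (zero-phase) filtering with odd-reflection edge padding.
# The pad must cover the filter's transient, which for very low normalized
# cutoffs is ~3 time constants = 3 fs / fc samples.
filtfilt_sos <- function(x, sos, pad) {
  n <- length(x)
  pad <- min(n - 1L, pad)
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- c(pre, x, post)
  y <- sos_filter(y, sos)
  y <- rev(sos_filter(rev(y), sos))
  y[seq(pad + 1, pad + n)]
}

# Zero-phase 4th-order Butterworth low-pass, the smoother used by the
# iterative baseline estimator.
lowpass_zero_phase <- function(x, fc, fs, order = 4L) {
  if (fc >= fs / 2) stop("low-pass cutoff at or above Nyquist")
  # filter the mean-removed signal: numerically exact for constants and
  # much better conditioned at very low normalized cutoffs
  mu <- mean(x)
  mu + filtfilt_sos(x - mu, butter_lowpass_sos(order, fc, fs),
                    pad = as.integer(ceiling(3 * fs / fc)))
}
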