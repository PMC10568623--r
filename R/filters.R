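# Zero-phase frequency-domain filtering.
#
# Filters are applied by multiplying the FFT of each channel with a real,
# non-negative magnitude response: strictly zero-phase by construction.
# The band-pass response is a 4th-order Butterworth magnitude (high-pass at
# `lo` times low-pass at `hi`); the notch is a narrow Gaussian band-stop.

butterworth_bandpass_response <- function(freqs, lo, hi, order = 4) {
  f <- abs(freqs)
  hp <- ifelse(f == 0, 0, 1 / sqrt(1 + (lo / pmax(f, .Machine$double.eps))^(2 * order)))
  lp <- 1 / sqrt(1 + (f / hi)^(2 * order))
  hp * lp
}

gaussian_notch_response <- function(freqs, notch, width = 0.5) {
  1 - exp(-((abs(freqs) - notch)^2) / (2 * width^2))
}

fft_freqs <- function(n, sfreq) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  k * sfreq / n
}

# Apply a magnitude response H(f) to each row of a channels x samples matrix.
apply_fft_filter <- function(x, sfreq, response_fn) {
  n <- ncol(x)
  H <- response_fn(fft_freqs(n, sfreq))
  xf <- t(stats::mvfft(t(x)))
  Re(t(stats::mvfft(t(xf * rep(H, each = nrow(x))), inverse = TRUE))) / n
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  xf <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(xf * h, inverse = TRUE) / n
}

# Band-limited unit-RMS noise: white Gaussian noise through the band-pass
# magnitude response. Callers manage the RNG state.
band_limited_noise <- function(n, sfreq, lo, hi, order = 8) {
  x <- matrix(stats::rnorm(n), nrow = 1)
  y <- apply_fft_filter(x, sfreq, function(f) butterworth_bandpass_response(f, lo, hi, order))
  y <- drop(y)
  r <- sqrt(mean(y^2))
  if (r < .Machine$double.eps) y else y / r
}

# Copy of a narrowband signal lagging `x` by `lag` radians at its carrier.
phase_lagged_copy <- function(x, lag) {
  Re(analytic_signal(x) * exp(-1i * lag))
}
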