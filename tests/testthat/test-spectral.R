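test_that("welch_psd locates peaks, satisfies Parseval, averages epochs", {
  rec <- make_sine_recording(10, duration = 10, n_channels = 1)
  ps <- welch_psd(rec$data, seg_length = 500, sfreq = 250)
  expect_equal(ps$freqs[which.max(ps$psd[1, ])], 10)

  set.seed(1)
  noise <- matrix(rnorm(2 * 10000, sd = 4), 2, 10000)
  ps <- welch_psd(noise, seg_length = 500, sfreq = 250)
  for (ch in 1:2)
    expect_equal(sum(ps$psd[ch, ]) * ps$df, var(noise[ch, ]), tolerance = 0.1)

  # identical epochs average to the single-epoch PSD
  ep1 <- structure(list(epochs = list(noise), sfreq = 250,
                        channel_labels = c("a", "b")), class = "epoched_eeg")
  ep2 <- structure(list(epochs = list(noise, noise), sfreq = 250,
                        channel_labels = c("a", "b")), class = "epoched_eeg")
  expect_equal(welch_psd(ep1, seg_length = 500)$psd,
               welch_psd(ep2, seg_length = 500)$psd, tolerance = 1e-12)

  expect_error(welch_psd(noise[, 1:100, drop = FALSE], seg_length = 500,
                         sfreq = 250), class = "invalid_parameter")
})

test_that("band powers integrate the PSD per half-open band", {
  freqs <- seq(1, 44.5, by = 0.5)
  # concentrated at 6 Hz -> all theta
  conc <- matrix(0, 1, length(freqs))
  conc[1, freqs == 6] <- 10
  bp <- band_powers(power_spectrum(freqs, conc))
  expect_equal(unname(bp$rel[1, "theta"]), 1.0)
  expect_equal(sum(bp$rel[1, names(bp$rel[1, ]) != "theta"]), 0)

  # flat PSD: relative powers equal bandwidth fractions of 44 Hz
  flat <- band_powers(power_spectrum(freqs, matrix(1, 1, length(freqs))))
  expect_equal(unname(flat$rel[1, "delta"]), 3 / 44, tolerance = 1e-12)
  expect_equal(unname(flat$rel[1, "gamma"]), 15 / 44, tolerance = 1e-12)

  # doubling scales absolute, leaves relative unchanged
  dbl <- band_powers(power_spectrum(freqs, matrix(2, 1, length(freqs))))
  expect_equal(dbl$abs, 2 * flat$abs)
  expect_equal(dbl$rel, flat$rel)

  # grid not covering the scheme
  expect_error(band_powers(power_spectrum(seq(1, 20, 0.5), matrix(1, 1, 39))),
               class = "coverage_error")
})

test_that("relative powers sum to one and bands are additive", {
  set.seed(3)
  noise <- matrix(rnorm(4 * 5000), 4, 5000)
  ps <- welch_psd(noise, seg_length = 500, sfreq = 250)
  bp <- band_powers(ps)
  expect_equal(unname(rowSums(bp$rel)), rep(1, 4), tolerance = 1e-9)
  # additivity over disjoint sub-bands: delta + theta = direct 1-8 Hz integral
  sel <- ps$freqs >= 1 & ps$freqs < 8
  direct <- rowSums(ps$psd[, sel]) * ps$df
  expect_equal(unname(bp$abs[, "delta"] + bp$abs[, "theta"]), unname(direct),
               tolerance = 1e-12)
})

test_that("power ratios follow their composite-band definitions", {
  mk <- function(vals) {
    m <- matrix(vals, 1, 8,
                dimnames = list("ch1", band_scheme()$name))
    structure(list(abs = m, rel = m / sum(m), scheme = band_scheme()),
              class = "band_power_table")
  }
  # theta=2, alpha1=alpha2=1 -> TAR = 1
  r <- power_ratios(mk(c(1, 2, 1, 1, 1, 1, 1, 1)))
  expect_equal(r$TAR, 1.0)
  # theta=3, beta2=1 -> TBR2 = 3
  r <- power_ratios(mk(c(1, 3, 1, 1, 1, 1, 1, 1)))
  expect_equal(r$TBR2, 3.0)
  # all equal -> TBR = 1/3
  r <- power_ratios(mk(rep(2, 8)))
  expect_equal(r$TBR, 1 / 3)
  # zero denominator -> NA, flagged
  r <- power_ratios(mk(c(1, 1, 0, 0, 1, 1, 1, 1)))
  expect_true(is.na(r$TAR) && is.na(r$DAR))
  expect_gte(nrow(attr(r, "flags")), 2)
})

test_that("ratios are invariant to global rescaling of the recording", {
  set.seed(5)
  x <- matrix(rnorm(2 * 5000), 2, 5000)
  r1 <- power_ratios(band_powers(welch_psd(x, 500, sfreq = 250)))
  r2 <- power_ratios(band_powers(welch_psd(3.7 * x, 500, sfreq = 250)))
  expect_equal(as.matrix(r1), as.matrix(r2), tolerance = 1e-9)
})

test_that("spectral feature rows are completely and uniquely named", {
  set.seed(6)
  x <- matrix(rnorm(3 * 2500), 3, 2500, dimnames = list(c("F3", "Cz", "P4"), NULL))
  row <- spectral_feature_row(band_powers(welch_psd(x, 500, sfreq = 250)))
  expect_equal(length(row), 3 * 8 * 2 + 3 * 4)
  expect_false(anyDuplicated(names(row)) > 0)
  expect_true(all(c("F3_theta_abs", "Cz_gamma_rel", "P4_TBR2") %in% names(row)))
})
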