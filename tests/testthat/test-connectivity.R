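test_that("cross-spectrum is Hermitian with real non-negative diagonal", {
  set.seed(1)
  x <- matrix(rnorm(3 * 5000), 3, 5000)
  x[3, ] <- x[1, ]                       # identical pair
  cs <- cross_spectral_density(x, seg_length = 500, sfreq = 250)
  for (b in c(1, 10, 100)) {
    S <- cs$S[, , b]
    expect_equal(S, Conj(t(S)), tolerance = 1e-12)
    expect_true(all(Re(diag(S)) >= 0))
    expect_lt(max(abs(Im(diag(S)))), 1e-12)
  }
  # identical signals: imaginary part of the cross term vanishes at every bin
  expect_lt(max(abs(Im(cs$S[1, 3, ]))), 1e-10)
  # diagonal equals the Welch PSD with the same parameters
  ps <- welch_psd(x, seg_length = 500, sfreq = 250)
  expect_equal(Re(cs$S[2, 2, ]), unname(ps$psd[2, ]), tolerance = 1e-10)
})

test_that("independent noise cross-spectra shrink with averaging", {
  set.seed(2)
  x <- matrix(rnorm(2 * 250 * 120), 2, 250 * 120)   # >= 60 segments
  cs <- cross_spectral_density(x, seg_length = 500, sfreq = 250)
  ratio <- sapply(seq_along(cs$freqs)[-1], function(b)
    Mod(cs$S[1, 2, b]) / sqrt(Re(cs$S[1, 1, b]) * Re(cs$S[2, 2, b])))
  expect_lt(mean(ratio), 0.1)
})

test_that("quadrature pair puts the cross power in the imaginary part", {
  src <- quadrature_sources(duration = 60, noise_sd = 1e-4, seed = 5)
  cs <- cross_spectral_density(src, seg_length = 500)
  b0 <- which.min(abs(cs$freqs - 6))
  expect_equal(abs(Im(cs$S[1, 2, b0])),
               sqrt(Re(cs$S[1, 1, b0]) * Re(cs$S[2, 2, b0])),
               tolerance = 0.02)
  expect_warning(cross_spectral_density(src$signals[[1]][, 1:500],
                                        seg_length = 500, sfreq = 250),
                 "fewer than 2 segments")
})

test_that("icoh_matrix honours its contract on arbitrary input", {
  set.seed(3)
  x <- matrix(rnorm(5 * 4000), 5, 4000)
  cs <- cross_spectral_density(x, seg_length = 500, sfreq = 250)
  for (b in c("delta", "alpha2", "gamma")) {
    cm <- icoh_matrix(cs, b)
    expect_equal(cm$values, t(cm$values))
    expect_true(all(diag(cm$values) == 0))
    expect_lte(max(cm$values), 1)
    expect_gte(min(cm$values), 0)
  }
  expect_error(icoh_matrix(cs, "ripple"), class = "coverage_error")
})

test_that("proportional thresholding retains the exact edge count", {
  set.seed(4)
  M <- matrix(0, 68, 68)
  M[upper.tri(M)] <- runif(68 * 67 / 2)
  M <- M + t(M)
  tn <- proportional_threshold(M, 0.25)
  expect_equal(tn$n_edges, 569)          # floor(0.25 * 2278)
  expect_equal(sum(tn$adjacency[upper.tri(tn$adjacency)] > 0), 569)

  # density 1 returns the off-diagonal input unchanged
  full <- proportional_threshold(M, 1)
  expect_equal(full$adjacency, M - diag(diag(M)))

  # 4-node brute-force anchor: keep the 3 largest of {6,5,4,3,2,1}
  A <- matrix(0, 4, 4)
  A[upper.tri(A)] <- c(6, 5, 4, 3, 2, 1)
  A <- A + t(A)
  th <- proportional_threshold(A, 0.5)
  expect_equal(sort(th$adjacency[upper.tri(th$adjacency)][th$adjacency[upper.tri(th$adjacency)] > 0]),
               c(4, 5, 6))
  expect_error(proportional_threshold(A, 0), class = "invalid_parameter")
  expect_warning(proportional_threshold(matrix(0, 4, 4), 0.5), "empty network")
})

test_that("thresholding composes idempotently", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- runif(n * (n - 1) / 2)
    M <- M + t(M)
    once <- proportional_threshold(M, 0.2)$adjacency
    twice <- proportional_threshold(proportional_threshold(M, 0.5)$adjacency, 0.2)$adjacency
    expect_identical(once, twice)
  }
})

test_that("zero-lag mixtures of shared sources have negligible iCOH", {
  # instantaneous mixing of common sources across 4 channels (volume conduction)
  set.seed(6)
  n <- 250 * 120
  s1 <- band_limited <- drop(strokenet:::apply_fft_filter(
    matrix(rnorm(n), 1), 250, function(f)
      strokenet:::butterworth_bandpass_response(f, 8, 12, 8)))
  s2 <- drop(strokenet:::apply_fft_filter(
    matrix(rnorm(n), 1), 250, function(f)
      strokenet:::butterworth_bandpass_response(f, 4, 8, 8)))
  mix <- matrix(runif(8, 0.2, 1), 4, 2)
  x <- mix %*% rbind(s1, s2) + 0.05 * matrix(rnorm(4 * n), 4, n)
  cm <- icoh_matrix(cross_spectral_density(x, seg_length = 500, sfreq = 250),
                    "alpha1")
  expect_lt(max(cm$values), 0.05)
})
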