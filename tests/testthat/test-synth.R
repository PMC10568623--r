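test_that("uncoupled sources show no imaginary coherence anywhere", {
  src <- gen_coupled_sources(4, 250, 120, specs = list(), noise_sd = 1, seed = 42)
  cs <- cross_spectral_density(src, seg_length = 250)
  for (b in band_scheme()$name) {
    cm <- icoh_matrix(cs, b)
    expect_lt(max(cm$values), 0.1)
  }
})

test_that("quadrature coupling gives near-unit iCOH; zero lag gives none", {
  src <- quadrature_sources(duration = 60, noise_sd = 1e-3, seed = 3)
  cm <- icoh_matrix(cross_spectral_density(src, seg_length = 500), "theta")
  expect_gte(cm$values[1, 2], 0.95)

  sp0 <- coupling_spec("theta", cbind(1, 2, 0, 1), carrier_freq = 6)
  src0 <- gen_coupled_sources(2, 250, 60, list(sp0), noise_sd = 1e-3, seed = 4)
  cs0 <- cross_spectral_density(src0, seg_length = 500)
  cm0 <- icoh_matrix(cs0, "theta")
  expect_lt(cm0$values[1, 2], 0.05)
  # ... despite strong real coherence at the carrier
  sel <- which(cs0$freqs >= 5 & cs0$freqs < 7)
  coh <- sapply(sel, function(b)
    Mod(cs0$S[1, 2, b]) / sqrt(Re(cs0$S[1, 1, b]) * Re(cs0$S[2, 2, b])))
  expect_gt(mean(coh), 0.9)
})

test_that("coupling strength monotonically increases band iCOH", {
  vals <- sapply(c(0.2, 0.5, 0.9), function(s) {
    src <- quadrature_sources(duration = 60, noise_sd = 1, seed = 7, strength = s)
    icoh_matrix(cross_spectral_density(src, seg_length = 500), "theta")$values[1, 2]
  })
  expect_true(all(diff(vals) > 0))
})

test_that("gen_coupled_sources validates specs and is deterministic", {
  sp <- coupling_spec("alpha1", cbind(1, 9, pi / 4, 0.5))
  expect_error(gen_coupled_sources(4, 250, 10, list(sp)), class = "invalid_spec")
  expect_error(coupling_spec("theta", cbind(1, 2, 0, 1.5)), class = "invalid_spec")
  expect_error(coupling_spec("theta", cbind(1, 2, 3 * pi, 0.5)), class = "invalid_spec")
  a <- gen_coupled_sources(3, 250, 5, seed = 9)
  b <- gen_coupled_sources(3, 250, 5, seed = 9)
  expect_identical(a$signals, b$signals)
})

test_that("gen_leadfield: shape, rank, determinism, smoothness", {
  lf <- gen_leadfield(19, 68, smoothness = 0, seed = 1)
  expect_equal(dim(lf$gain), c(19, 68))
  expect_equal(qr(lf$gain)$rank, 19)
  expect_identical(gen_leadfield(19, 68, smoothness = 0, seed = 1)$gain, lf$gain)
  expect_error(gen_leadfield(0, 10), class = "invalid_spec")
  expect_error(gen_leadfield(19, -1), class = "invalid_spec")

  sm <- gen_leadfield(19, 68, smoothness = 0.9, seed = 1)$gain
  adj_cor <- mean(sapply(1:67, function(j) abs(cor(sm[, j], sm[, j + 1]))))
  set.seed(2)
  pairs <- replicate(200, sample(68, 2))
  rnd_cor <- mean(apply(pairs, 2, function(p) abs(cor(sm[, p[1]], sm[, p[2]]))))
  expect_gt(adj_cor, rnd_cor)
})

test_that("gen_feature_table plants recoverable effects", {
  tb <- gen_feature_table(50, 10, planted = list(c(1, 1.0)), noise_sd = 0, seed = 2)
  expect_equal(cor(tb$feature_001, tb$moca_std), 1.0, tolerance = 1e-12)

  # null: max |r| over 100 features at n=50 rarely exceeds 0.5
  hits <- sum(sapply(1:20, function(s) {
    tb0 <- gen_feature_table(50, 100, planted = list(), noise_sd = 1, seed = s)
    mx <- max(abs(cor(as.matrix(tb0[, feature_cols(tb0)]), tb0$moca_std)))
    mx < 0.5
  }))
  expect_gte(hits, 19)

  tb3 <- gen_feature_table(200, 10, planted = list(c(3, 2.0)), noise_sd = 1, seed = 5)
  r <- abs(cor(as.matrix(tb3[, feature_cols(tb3)]), tb3$moca_std))
  expect_equal(which.max(r), 3L)

  expect_error(gen_feature_table(10, 2, planted = list(c(5, 1))),
               class = "invalid_spec")
})

test_that("cohort generator is reproducible and encodes laterality", {
  a <- gen_cohort(10, seed = 3, mode = "features")
  b <- gen_cohort(10, seed = 3, mode = "features")
  expect_identical(a$clinical$moca_std, b$clinical$moca_std)
  expect_identical(as.data.frame(a$features), as.data.frame(b$features))

  # all-left cohort: lesioned-hemisphere slow-wave sensor power dominates
  co <- gen_cohort(8, cohort_profile(duration = 10,
                                     side_probs = c(left = 1, right = 0, bilateral = 0)),
                   seed = 5, mode = "eeg")
  hemi <- strokenet:::channel_hemisphere(co$recordings[[1]]$channel_labels)
  for (r in co$recordings) {
    bp <- band_powers(welch_psd(r$data, seg_length = 500, sfreq = r$sfreq))
    slow <- bp$abs[, "delta"] + bp$abs[, "theta"]
    expect_gt(sum(slow[hemi == "left"]), sum(slow[hemi == "right"]))
  }
})

test_that("noiseless planted outcome is perfectly recoverable", {
  co <- gen_cohort(40, cohort_profile(moca_noise_sd = 0), seed = 8, mode = "features")
  planted <- names(co$truth$planted)
  ev <- fit_regressors_loo(as.data.frame(co$features)[, planted],
                           co$features$moca_std, models = "ridge", seed = 1,
                           hyper = list(ridge = list(lambda = 1e-4)))
  expect_equal(ev$ridge$r2, 1.0, tolerance = 0.01)
})

test_that("degenerate profile warns and errors are classed", {
  expect_warning(gen_cohort(5, cohort_profile(planted = numeric(0),
                                              moca_noise_sd = 0),
                            seed = 1, mode = "features"),
                 "degenerate")
  expect_error(gen_cohort(1, mode = "features"), class = "invalid_spec")
  expect_error(cohort_profile(asymmetry = 0.5), class = "invalid_spec")
})
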