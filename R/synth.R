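# Synthetic-cohort generator: band-limited stochastic oscillators with
# phase-lagged coupling, a hemisphere-structured random leadfield,
# lesion-side slow-wave asymmetry, and outcomes driven by planted theta-band
# network effects. All randomness flows from one seed via derive_seeds().

#' Coupling specification for synthetic sources
#'
#' Describes phase-lagged narrowband coupling between ROI pairs. Carriers are
#' band-pass-filtered Gaussian noise (not deterministic sinusoids) so Welch
#' estimators see realistic, stochastic spectra.
#'
#' @param band band name (see [band_scheme()]).
#' @param pairs matrix/data.frame with columns `roi_i`, `roi_j` (1-based ROI
#'   numbers), `lag` (radians in `(-pi, pi]`; the j signal lags i) and
#'   `strength` in `[0, 1]`.
#' @param carrier_freq carrier frequency in Hz; default: band midpoint.
#' @param carrier_bw carrier half-bandwidth in Hz (default 1).
#' @param scheme a [band_scheme()].
#' @return a `coupling_spec` object.
#' @export
coupling_spec <- function(band, pairs, carrier_freq = NULL, carrier_bw = 1,
                          scheme = band_scheme()) {
  lim <- band_limits(scheme, band)
  pairs <- as.data.frame(pairs)
  names(pairs) <- c("roi_i", "roi_j", "lag", "strength")[seq_len(ncol(pairs))]
  sn_assert(all(c("roi_i", "roi_j", "lag", "strength") %in% names(pairs)),
            "pairs needs columns roi_i, roi_j, lag, strength", "invalid_spec")
  sn_assert(all(pairs$roi_i >= 1 & pairs$roi_j >= 1 & pairs$roi_i != pairs$roi_j),
            "ROI indices must be >= 1 and distinct within a pair", "invalid_spec")
  sn_assert(all(pairs$strength >= 0 & pairs$strength <= 1),
            "strength must be in [0, 1]", "invalid_spec")
  sn_assert(all(pairs$lag > -pi & pairs$lag <= pi + 1e-12),
            "lag must be in (-pi, pi]", "invalid_spec")
  carrier_freq <- carrier_freq %||% mean(lim)
  sn_assert(carrier_freq >= lim[1] && carrier_freq <= lim[2],
            "carrier_freq must lie within the band", "invalid_spec")
  structure(list(band = band, pairs = pairs, carrier_freq = carrier_freq,
                 carrier_bw = carrier_bw, lo = lim[1], hi = lim[2]),
            class = "coupling_spec")
}

#' Generate coupled ROI source time courses
#'
#' Each ROI carries independent Gaussian noise; each coupled pair additionally
#' shares a narrowband stochastic carrier, with the second ROI receiving a
#' copy phase-lagged by the stated amount. A zero-lag pair therefore has high
#' real coherence but (up to estimation noise) zero imaginary coherence --
#' the volume-conduction null the connectivity stage is built to respect.
#'
#' @param n_rois number of ROI signals (>= 2).
#' @param sfreq sampling rate in Hz.
#' @param duration record length in seconds.
#' @param specs list of [coupling_spec()] objects.
#' @param noise_sd independent-noise standard deviation per ROI.
#' @param seed RNG seed (bit-reproducible output).
#' @return an `roi_timecourses` object (single epoch).
#' @export
gen_coupled_sources <- function(n_rois, sfreq, duration, specs = list(),
                                noise_sd = 1, seed = 1) {
  sn_assert(is_count(n_rois) && n_rois >= 2, "n_rois must be >= 2", "invalid_spec")
  n <- round(duration * sfreq)
  sn_assert(n >= 2, "duration * sfreq must be >= 2", "invalid_spec")
  if (inherits(specs, "coupling_spec")) specs <- list(specs)
  for (sp in specs) {
    sn_assert(all(c(sp$pairs$roi_i, sp$pairs$roi_j) <= n_rois),
              "coupling spec references an ROI beyond n_rois", "invalid_spec")
  }
  X <- with_seed(seed, {
    X <- matrix(stats::rnorm(n_rois * n, sd = noise_sd), n_rois, n)
    for (sp in specs) {
      lo <- max(sp$lo, sp$carrier_freq - sp$carrier_bw)
      hi <- min(sp$hi, sp$carrier_freq + sp$carrier_bw)
      for (p in seq_len(nrow(sp$pairs))) {
        pr <- sp$pairs[p, ]
        carrier <- band_limited_noise(n, sfreq, lo, hi)
        X[pr$roi_i, ] <- X[pr$roi_i, ] + pr$strength * carrier
        X[pr$roi_j, ] <- X[pr$roi_j, ] +
          pr$strength * phase_lagged_copy(carrier, pr$lag)
      }
    }
    X
  })
  structure(list(signals = list(X), sfreq = sfreq,
                 roi_labels = if (n_rois == 68) dk_roi_table()$name
                              else paste0("roi", seq_len(n_rois))),
            class = "roi_timecourses")
}

#' Generate a random spatially smooth leadfield
#'
#' Gaussian random gain matrix whose columns are optionally smoothed over
#' source index (nearby sources get correlated topographies), column-normalized
#' and guaranteed full row rank. Deterministic in the seed.
#'
#' @param n_channels number of sensors (>= 2).
#' @param n_sources number of sources (under-determined n_sources > n_channels
#'   is allowed).
#' @param smoothness in `[0, 1)`: 0 = independent columns; larger values mix
#'   neighbouring source topographies with a Gaussian kernel of SD
#'   `5 * smoothness` source indices.
#' @param seed RNG seed.
#' @return a [leadfield()] (no ROI map attached).
#' @export
gen_leadfield <- function(n_channels, n_sources, smoothness = 0, seed = 1) {
  sn_assert(is_count(n_channels) && n_channels >= 2,
            "n_channels must be a count >= 2", "invalid_spec")
  sn_assert(is_count(n_sources) && n_sources >= 1,
            "n_sources must be a positive count", "invalid_spec")
  sn_assert(smoothness >= 0 && smoothness < 1, "smoothness must be in [0, 1)",
            "invalid_spec")
  G <- with_seed(seed, matrix(stats::rnorm(n_channels * n_sources),
                              n_channels, n_sources))
  if (smoothness > 0) {
    sig <- 5 * smoothness
    idx <- seq_len(n_sources)
    Kmat <- exp(-outer(idx, idx, "-")^2 / (2 * sig^2))
    G <- G %*% Kmat
  }
  G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
  leadfield(G)
}

default_band_amplitudes <- function() {
  c(delta = 1.0, theta = 0.8, alpha1 = 0.7, alpha2 = 0.6,
    beta1 = 0.4, beta2 = 0.3, beta3 = 0.25, gamma = 0.15)
}

# Composite spectral-shaping response: summed band-pass responses weighted by
# the band amplitude profile, with an extra multiplier on delta+theta.
composite_response <- function(f, amps, scheme, slow_mult = 1) {
  H <- 0
  for (i in seq_len(nrow(scheme))) {
    b <- scheme$name[i]
    m <- if (b %in% c("delta", "theta")) slow_mult else 1
    H <- H + amps[[b]] * m *
      butterworth_bandpass_response(f, scheme$lo[i], scheme$hi[i], 4)
  }
  H
}

# One ROI's broadband signal (scalar path, kept for clarity/tests).
gen_roi_signal <- function(n, sfreq, amps, scheme, slow_mult = 1) {
  drop(apply_fft_filter(matrix(stats::rnorm(n), 1), sfreq,
                        function(f) composite_response(f, amps, scheme, slow_mult)))
}

# All 68 ROI signals at once: one forward and one inverse FFT for the whole
# matrix, with the lesioned-hemisphere rows shaped by the slow-wave-boosted
# response. Identical model to gen_roi_signal, vectorized.
gen_roi_signals_matrix <- function(n_rois, n, sfreq, amps, scheme,
                                   lesioned_rows, slow_mult) {
  f <- fft_freqs(n, sfreq)
  H1 <- composite_response(f, amps, scheme, 1)
  H2 <- if (slow_mult == 1) H1 else composite_response(f, amps, scheme, slow_mult)
  W <- matrix(stats::rnorm(n_rois * n), n_rois, n)
  WF <- t(stats::mvfft(t(W)))
  Hm <- matrix(rep(H1, each = n_rois), n_rois, n)
  if (length(lesioned_rows))
    Hm[lesioned_rows, ] <- matrix(rep(H2, each = length(lesioned_rows)),
                                  length(lesioned_rows), n)
  Re(t(stats::mvfft(t(WF * Hm), inverse = TRUE))) / n
}

#' Default synthetic-cohort profile
#'
#' The stated world of the generator: lesion-side proportions matching a
#' typical acute-stroke cohort (about a quarter bilateral), a slow-wave
#' asymmetry multiplier of 2 on the lesioned hemisphere, three planted
#' theta-band network effects driving the outcome at signal fraction 0.8, and
#' a generic continuous standardized cognitive score scale (mean 50, SD 10).
#'
#' @param side_probs named probabilities for left/right/bilateral lesions.
#' @param asymmetry delta+theta source-amplitude multiplier (>= 1) on the
#'   lesioned hemisphere.
#' @param planted named weight vector on network feature columns (features
#'   mode) defining the outcome signal.
#' @param signal_fraction fraction of outcome variance explained by the
#'   planted signal (0 < f <= 1); ignored if `moca_noise_sd` is given.
#' @param moca_noise_sd outcome noise SD on the latent (unit-signal) scale,
#'   overriding `signal_fraction`.
#' @param moca_mean,moca_sd location/scale of the emitted standardized score.
#' @param duration,sfreq,n_channels EEG-mode recording parameters.
#' @param coupling_pairs EEG mode: matrix of theta coupling pairs
#'   (roi_i, roi_j, lag); per-subject strengths drive the outcome.
#' @param sensor_noise_sd EEG-mode sensor noise (microvolts).
#' @return a `cohort_profile` list.
#' @export
cohort_profile <- function(side_probs = c(left = 0.40, right = 0.36, bilateral = 0.24),
                           asymmetry = 2.0,
                           planted = c(theta_global_efficiency = 1.0,
                                       theta_clustering_ROI2 = 1.0,
                                       theta_efficiency_ROI6 = 1.0),
                           signal_fraction = 0.8,
                           moca_noise_sd = NULL,
                           moca_mean = 50, moca_sd = 10,
                           duration = 60, sfreq = 250, n_channels = 19,
                           coupling_pairs = cbind(roi_i = c(1, 2, 5),
                                                  roi_j = c(3, 4, 7),
                                                  lag = pi / 2),
                           sensor_noise_sd = 2) {
  sn_assert(asymmetry >= 1, "asymmetry multiplier must be >= 1", "invalid_spec")
  sn_assert(is.null(moca_noise_sd) || moca_noise_sd >= 0,
            "moca_noise_sd must be >= 0", "invalid_spec")
  sn_assert(signal_fraction > 0 && signal_fraction <= 1,
            "signal_fraction must be in (0, 1]", "invalid_spec")
  side_probs <- side_probs / sum(side_probs)
  structure(list(side_probs = side_probs, asymmetry = asymmetry,
                 planted = planted, signal_fraction = signal_fraction,
                 moca_noise_sd = moca_noise_sd, moca_mean = moca_mean,
                 moca_sd = moca_sd, duration = duration, sfreq = sfreq,
                 n_channels = n_channels, coupling_pairs = coupling_pairs,
                 sensor_noise_sd = sensor_noise_sd),
            class = "cohort_profile")
}

#' Generate a synthetic feature table with planted outcome effects
#'
#' Fast test path for the prediction stage: standardized Gaussian features,
#' an outcome that is a noisy linear combination of the planted columns, and
#' the ground truth recorded as an attribute.
#'
#' @param n_subjects number of rows (>= 2).
#' @param n_features number of feature columns.
#' @param planted list of `c(index, weight)` pairs (or a 2-column matrix);
#'   indices must be `<= n_features`.
#' @param noise_sd outcome noise SD (outcome signal has SD
#'   `sqrt(sum(weights^2))`).
#' @param seed RNG seed.
#' @param feature_names optional column names (default `feature_001`, ...).
#' @return a `feature_table` data.frame with columns `subject_id`,
#'   `lesion_side` (NA), `moca_std` and the features; attributes `planted`
#'   (named weights) and `outcome_col`.
#' @export
gen_feature_table <- function(n_subjects, n_features, planted = list(),
                              noise_sd = 1, seed = 1, feature_names = NULL) {
  sn_assert(is_count(n_subjects) && n_subjects >= 2, "n_subjects must be >= 2",
            "invalid_spec")
  if (is.matrix(planted)) planted <- split(planted, row(planted))
  idx <- vapply(planted, `[`, numeric(1), 1)
  wts <- vapply(planted, `[`, numeric(1), 2)
  sn_assert(all(idx >= 1 & idx <= n_features),
            "planted indices must be in 1..n_features", "invalid_spec")
  feature_names <- feature_names %||% sprintf("feature_%03d", seq_len(n_features))
  sn_assert(length(feature_names) == n_features, "feature_names length mismatch",
            "invalid_spec")
  drawn <- with_seed(seed, {
    X <- matrix(stats::rnorm(n_subjects * n_features), n_subjects, n_features)
    y <- if (length(idx)) drop(X[, idx, drop = FALSE] %*% wts) else numeric(n_subjects)
    list(X = X, y = y + stats::rnorm(n_subjects, sd = noise_sd))
  })
  X <- drawn$X
  out <- drawn$y
  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                    lesion_side = NA_character_, moca_std = out,
                    stringsAsFactors = FALSE)
  feat <- as.data.frame(X)
  names(feat) <- feature_names
  tab <- cbind(tab, feat)
  pw <- stats::setNames(wts, feature_names[idx])
  as_feature_table(tab, planted = pw)
}

as_feature_table <- function(df, planted = NULL) {
  structure(df, class = c("feature_table", "data.frame"),
            outcome_col = "moca_std", group_col = "lesion_side",
            planted = planted)
}

#' Feature columns of a feature table
#' @param table a `feature_table` (or compatible data.frame).
#' @return character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), c("subject_id", "lesion_side", "moca_std"))
}

#' Generate a synthetic cohort
#'
#' In `"features"` mode, emits a subjects x network-features table (all 1120
#' columns of the 8-band layout) whose outcome is a noisy linear function of
#' the planted theta-band columns. In `"eeg"` mode, emits one 19-channel
#' recording per subject: 68 broadband ROI sources with a delta+theta
#' amplitude excess on the lesioned hemisphere, per-subject theta coupling
#' strengths (the latent drivers of the theta network attributes) that
#' generate the outcome, projected through a hemisphere-structured smooth
#' random leadfield with additive sensor noise.
#'
#' @param n_subjects cohort size (>= 2).
#' @param profile a [cohort_profile()].
#' @param seed master seed; the same seed reproduces the cohort bit for bit.
#' @param mode "features" or "eeg".
#' @return a `synthetic_cohort` list: `clinical` (subject_id, lesion_side,
#'   moca_std), `features` (features mode) or `recordings` + `leadfield` +
#'   `source_roi_map` (eeg mode), and `truth` (planted ground truth).
#' @export
gen_cohort <- function(n_subjects, profile = cohort_profile(), seed = 1,
                       mode = c("features", "eeg")) {
  mode <- match.arg(mode)
  sn_assert(is_count(n_subjects) && n_subjects >= 2, "n_subjects must be >= 2",
            "invalid_spec")
  stopifnot(inherits(profile, "cohort_profile"))
  seeds <- derive_seeds(seed, 4 + n_subjects)
  sides <- with_seed(seeds[1], sample(names(profile$side_probs), n_subjects,
                                      replace = TRUE, prob = profile$side_probs))
  if (mode == "features") {
    scheme <- band_scheme()
    nets <- lapply(stats::setNames(scheme$name, scheme$name), function(b)
      structure(list(global_efficiency = 0, char_path_length = 0,
                     clustering = numeric(68), clustering_mean = 0,
                     modularity = 0, nodal_efficiency = numeric(68)),
                class = "network_feature_set"))
    feat_names <- names(assemble_network_features(nets, scheme))
    w <- profile$planted
    sn_assert(all(names(w) %in% feat_names),
              "planted names must be network feature columns", "invalid_spec")
    p <- length(feat_names)
    X <- with_seed(seeds[2], matrix(stats::rnorm(n_subjects * p), n_subjects, p))
    colnames(X) <- feat_names
    sig <- if (length(w)) drop(X[, names(w), drop = FALSE] %*% w) else
      numeric(n_subjects)
    s_sd <- sqrt(sum(w^2))
    noise_sd <- profile$moca_noise_sd %||%
      (s_sd * sqrt((1 - profile$signal_fraction) / profile$signal_fraction))
    if (s_sd == 0 && noise_sd == 0)
      warning("degenerate profile: zero weights and zero noise give a constant outcome")
    z <- sig + with_seed(seeds[3], stats::rnorm(n_subjects, sd = noise_sd))
    tot_sd <- sqrt(s_sd^2 + noise_sd^2)
    moca <- profile$moca_mean +
      profile$moca_sd * (if (tot_sd > 0) z / tot_sd else z)
    tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                      lesion_side = sides, moca_std = moca,
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(X))
    return(structure(list(clinical = tab[, 1:3],
                          features = as_feature_table(tab, planted = w),
                          truth = list(planted = w, noise_sd = noise_sd),
                          seed = seed, mode = mode),
                     class = "synthetic_cohort"))
  }

  # ---- EEG mode ----
  scheme <- band_scheme()
  roi_tab <- dk_roi_table()
  lf0 <- gen_leadfield(profile$n_channels, 68, smoothness = 0.5, seed = seeds[2])
  labels <- montage_1020()[seq_len(profile$n_channels)]
  ch_hemi <- channel_hemisphere(labels)
  wmat <- outer(ch_hemi, roi_tab$hemisphere, function(ch, rh)
    ifelse(ch == "midline", 0.6, ifelse(ch == rh, 1.0, 0.25)))
  G <- lf0$gain * wmat
  G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
  lf <- leadfield(G, source_roi_map = seq_len(68))

  cp <- as.data.frame(profile$coupling_pairs)
  strengths <- with_seed(seeds[3], matrix(stats::runif(n_subjects * nrow(cp), 0.2, 1),
                                          n_subjects, nrow(cp)))
  w <- rep(1, nrow(cp))
  sig <- drop(scale(strengths) %*% w)
  s_sd <- sqrt(sum(w^2))
  noise_sd <- profile$moca_noise_sd %||%
    (s_sd * sqrt((1 - profile$signal_fraction) / profile$signal_fraction))
  z <- sig + with_seed(seeds[4], stats::rnorm(n_subjects, sd = noise_sd))
  moca <- profile$moca_mean + profile$moca_sd * z / sqrt(s_sd^2 + noise_sd^2)

  n <- round(profile$duration * profile$sfreq)
  amps <- default_band_amplitudes()
  recordings <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    recordings[[s]] <- with_seed(seeds[4 + s], {
      lesioned <- switch(sides[s], left = "left", right = "right",
                         bilateral = c("left", "right"))
      S <- gen_roi_signals_matrix(68, n, profile$sfreq, amps, scheme,
                                  which(roi_tab$hemisphere %in% lesioned),
                                  profile$asymmetry)
      for (p in seq_len(nrow(cp))) {
        carrier <- band_limited_noise(n, profile$sfreq, 5, 7)
        amp <- 1.5 * strengths[s, p]
        S[cp$roi_i[p], ] <- S[cp$roi_i[p], ] + amp * carrier
        S[cp$roi_j[p], ] <- S[cp$roi_j[p], ] +
          amp * phase_lagged_copy(carrier, cp$lag[p])
      }
      X <- 10 * (G %*% S) +
        matrix(stats::rnorm(profile$n_channels * n, sd = profile$sensor_noise_sd),
               profile$n_channels, n)
      eeg_recording(X, labels, profile$sfreq,
                    subject_id = sprintf("S%03d", s))
    })
  }
  structure(list(clinical = data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                                       lesion_side = sides, moca_std = moca,
                                       stringsAsFactors = FALSE),
                 recordings = recordings, leadfield = lf,
                 truth = list(coupling_pairs = cp, strengths = strengths,
                              asymmetry = profile$asymmetry, noise_sd = noise_sd),
                 seed = seed, mode = mode),
            class = "synthetic_cohort")
}
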