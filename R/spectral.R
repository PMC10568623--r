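#' Power spectrum container
#'
#' Thin constructor, mainly useful for building fixtures; [welch_psd()] is the
#' estimator used in the pipeline.
#'
#' @param freqs frequency grid in Hz (equally spaced, ascending).
#' @param values channels x frequency-bins matrix of power spectral density
#'   (microvolt^2 per Hz), non-negative.
#' @param channel_labels optional channel names.
#' @return a `power_spectrum` object.
#' @export
power_spectrum <- function(freqs, values, channel_labels = rownames(values)) {
  values <- as.matrix(values)
  sn_assert(length(freqs) == ncol(values), "freqs must match columns of values")
  sn_assert(all(values >= 0), "PSD must be non-negative")
  df <- if (length(freqs) > 1) diff(freqs)[1] else NA_real_
  structure(list(freqs = as.numeric(freqs), psd = values, df = df,
                 channel_labels = channel_labels %||% paste0("ch", seq_len(nrow(values)))),
            class = "power_spectrum")
}

window_fn <- function(name, n) {
  switch(name,
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))),
         rectangular = ,
         boxcar = rep(1, n),
         sn_stop(sprintf("unknown window '%s'", name), "invalid_parameter"))
}

segment_starts <- function(total, seg, step) seq(1L, total - seg + 1L, by = step)

#' Welch power spectral density
#'
#' One-sided Welch PSD averaged over windowed, demeaned segments within each
#' epoch and over epochs. With the defaults (Hann window, 2 s segments, 50%
#' overlap at 250 Hz) the grid resolution is 0.5 Hz, which places a bin on
#' every band edge exactly.
#'
#' @param epochs an `epoched_eeg` (or a channels x samples matrix plus `sfreq`).
#' @param seg_length segment length in samples (default: 2 s worth).
#' @param seg_overlap fraction of overlap between segments (default 0.5).
#' @param window window name, `"hann"` (default) or `"rectangular"`.
#' @param sfreq sampling rate, only needed for matrix input.
#' @return a [power_spectrum()] (density units: microvolt^2/Hz), satisfying
#'   Parseval: band-integrated power approximates signal variance.
#' @export
welch_psd <- function(epochs, seg_length = NULL, seg_overlap = 0.5,
                      window = "hann", sfreq = NULL) {
  if (inherits(epochs, "epoched_eeg")) {
    sfreq <- epochs$sfreq
    labels <- epochs$channel_labels
    eps <- epochs$epochs
  } else {
    sn_assert(!is.null(sfreq), "sfreq required for matrix input")
    labels <- rownames(epochs) %||% paste0("ch", seq_len(nrow(epochs)))
    eps <- list(as.matrix(epochs))
  }
  seg_length <- as.integer(seg_length %||% round(2 * sfreq))
  sn_assert(seg_length >= 2, "seg_length must be >= 2")
  sn_assert(all(vapply(eps, ncol, 1L) >= seg_length),
            "fewer samples than one segment", "invalid_parameter")
  step <- max(1L, round(seg_length * (1 - seg_overlap)))
  w <- window_fn(window, seg_length)
  U <- sum(w^2)
  nb <- seg_length %/% 2 + 1L
  acc <- matrix(0, nrow(eps[[1]]), nb)
  nseg <- 0L
  for (e in eps) {
    for (s in segment_starts(ncol(e), seg_length, step)) {
      seg <- e[, s:(s + seg_length - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)
      X <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))[seq_len(nb), , drop = FALSE]
      acc <- acc + t(Mod(X)^2)
      nseg <- nseg + 1L
    }
  }
  scale <- rep(2, nb)
  scale[1] <- 1
  if (seg_length %% 2 == 0) scale[nb] <- 1
  psd <- acc / (nseg * sfreq * U) * rep(scale, each = nrow(acc))
  freqs <- (seq_len(nb) - 1) * sfreq / seg_length
  power_spectrum(freqs, psd, labels)
}

#' Absolute and relative band powers
#'
#' Integrates the PSD over each half-open band interval `[lo, hi)`; relative
#' power is each band's share of the total over all bands in the scheme.
#'
#' @param psd a [power_spectrum()].
#' @param scheme a [band_scheme()].
#' @return a `band_power_table`: list with `abs` and `rel`
#'   (channels x bands matrices) and the scheme.
#' @export
band_powers <- function(psd, scheme = band_scheme()) {
  stopifnot(inherits(psd, "power_spectrum"))
  sn_assert(min(psd$freqs) <= min(scheme$lo) + psd$df &&
              max(psd$freqs) >= max(scheme$hi) - psd$df,
            "PSD frequency grid does not cover the band scheme", "coverage_error")
  absb <- sapply(seq_len(nrow(scheme)), function(i) {
    sel <- psd$freqs >= scheme$lo[i] & psd$freqs < scheme$hi[i]
    if (!any(sel))
      sn_stop(sprintf("no frequency bins inside band %s", scheme$name[i]),
              "coverage_error")
    rowSums(psd$psd[, sel, drop = FALSE]) * psd$df
  })
  absb <- matrix(absb, nrow = nrow(psd$psd),
                 dimnames = list(psd$channel_labels, scheme$name))
  total <- rowSums(absb)
  rel <- absb / ifelse(total > 0, total, NA_real_)
  structure(list(abs = absb, rel = rel, scheme = scheme),
            class = "band_power_table")
}

#' Spectral power ratios
#'
#' The four classical slow/fast ratios per channel: TAR = theta/alpha,
#' TBR = theta/beta, TBR2 = theta/beta2, DAR = delta/alpha, where alpha is the
#' composite alpha1+alpha2 (8-12 Hz) and beta the composite
#' beta1+beta2+beta3 (12-30 Hz).
#'
#' @param bp a `band_power_table` from [band_powers()].
#' @return data.frame with columns TAR, TBR, TBR2, DAR (one row per channel);
#'   zero-denominator entries are `NA` and listed in the `"flags"` attribute.
#' @export
power_ratios <- function(bp) {
  stopifnot(inherits(bp, "band_power_table"))
  a <- bp$abs
  need <- c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "beta3")
  sn_assert(all(need %in% colnames(a)),
            "ratio computation needs the default 8-band scheme", "coverage_error")
  alpha <- a[, "alpha1"] + a[, "alpha2"]
  beta <- a[, "beta1"] + a[, "beta2"] + a[, "beta3"]
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(TAR = safe_div(a[, "theta"], alpha),
                    TBR = safe_div(a[, "theta"], beta),
                    TBR2 = safe_div(a[, "theta"], a[, "beta2"]),
                    DAR = safe_div(a[, "delta"], alpha),
                    row.names = rownames(a))
  flags <- which(is.na(as.matrix(out)), arr.ind = TRUE)
  attr(out, "flags") <- flags
  out
}

#' One subject's sensor-level spectral feature row
#'
#' Flattens band powers and ratios into a single named numeric vector with
#' columns `<channel>_<band>_abs`, `<channel>_<band>_rel`, `<channel>_<ratio>`.
#'
#' @param bp a `band_power_table`.
#' @param ratios output of [power_ratios()] (computed if missing).
#' @return named numeric vector.
#' @export
spectral_feature_row <- function(bp, ratios = power_ratios(bp)) {
  ch <- rownames(bp$abs)
  bands <- colnames(bp$abs)
  v <- c(as.vector(t(bp$abs)), as.vector(t(bp$rel)),
         as.vector(t(as.matrix(ratios))))
  names(v) <- c(paste0(rep(ch, each = length(bands)), "_", bands, "_abs"),
                paste0(rep(ch, each = length(bands)), "_", bands, "_rel"),
                paste0(rep(ch, each = ncol(ratios)), "_", colnames(ratios)))
  v
}
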