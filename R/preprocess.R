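#' EEG recording container
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_labels unique channel names (10-20 convention for the
#'   standard montage); defaults to the matrix rownames.
#' @param sfreq sampling frequency in Hz.
#' @param subject_id optional subject identifier.
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(data, channel_labels = rownames(data), sfreq,
                          subject_id = "") {
  data <- as.matrix(data)
  sn_assert(is.numeric(data) && all(is.finite(data)),
            "data must be finite numeric", "invalid_input")
  sn_assert(is.numeric(sfreq) && length(sfreq) == 1 && sfreq > 0,
            "sfreq must be a positive scalar", "invalid_input")
  sn_assert(!is.null(channel_labels) && length(channel_labels) == nrow(data) &&
              !anyDuplicated(channel_labels),
            "channel_labels must be unique and match the number of rows",
            "invalid_input")
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = as.character(channel_labels),
                 sfreq = sfreq, subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}

#' Zero-phase band-pass and notch filtering
#'
#' Band-pass with a squared-magnitude 4th-order Butterworth response applied
#' in the frequency domain (strictly zero-phase), optionally followed by a
#' narrow notch at the mains frequency.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz; defaults 1 and 45.5 Hz.
#' @param notch mains frequency in Hz (default 60; use 50 where applicable),
#'   or `NULL` to skip.
#' @param order Butterworth order (default 4).
#' @return the filtered `eeg_recording`, same length.
#' @export
bandpass_notch <- function(rec, lo = 1, hi = 45.5, notch = 60, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  sn_assert(lo > 0 && hi > lo, "need 0 < lo < hi", "invalid_parameter")
  sn_assert(hi < rec$sfreq / 2, "hi must be below the Nyquist frequency",
            "invalid_parameter")
  resp <- function(f) {
    H <- butterworth_bandpass_response(f, lo, hi, order)
    if (!is.null(notch) && notch < rec$sfreq / 2)
      H <- H * gaussian_notch_response(f, notch)
    H
  }
  rec$data <- apply_fft_filter(rec$data, rec$sfreq, resp)
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean is zero at every sample.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  sn_assert(nrow(rec$data) >= 2, "CAR needs at least 2 channels", "invalid_input")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Epoching with amplitude/variance artifact rejection
#'
#' Cuts the recording into (possibly overlapping) fixed-length epochs and
#' drops epochs whose peak absolute amplitude exceeds `amp_thresh`, or whose
#' variance on any channel exceeds `var_ratio_thresh` times that channel's
#' median epoch variance. This documented deterministic rule stands in for
#' platform-internal artifact subspace reconstruction; an externally computed
#' ICA cleanup can be applied to the recording before calling this.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_length epoch length in seconds (default 4).
#' @param overlap fraction of overlap between consecutive epochs in `[0, 1)`
#'   (default 0.5).
#' @param amp_thresh peak-amplitude rejection threshold in microvolts
#'   (default 100).
#' @param var_ratio_thresh variance-ratio rejection threshold (default 5).
#' @return an `epoched_eeg` object with fields `epochs` (list of channels x
#'   samples matrices), `rejection_log` (one row per pre-rejection epoch) and
#'   the epoching parameters.
#' @export
epoch_and_reject <- function(rec, epoch_length = 4, overlap = 0.5,
                             amp_thresh = 100, var_ratio_thresh = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  nsamp <- round(epoch_length * rec$sfreq)
  sn_assert(nsamp >= 2, "epoch_length * sfreq must be >= 2", "invalid_parameter")
  sn_assert(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)",
            "invalid_parameter")
  step <- max(1L, round(nsamp * (1 - overlap)))
  total <- ncol(rec$data)
  sn_assert(total >= nsamp, "recording shorter than one epoch", "invalid_parameter")
  starts <- seq(1L, total - nsamp + 1L, by = step)

  epochs <- lapply(starts, function(s) rec$data[, s:(s + nsamp - 1L), drop = FALSE])
  peak <- vapply(epochs, function(e) max(abs(e)), numeric(1))
  v <- vapply(epochs, function(e) apply(e, 1, stats::var),
              numeric(nrow(rec$data)))           # channels x epochs
  med_v <- apply(v, 1, stats::median)
  amp_bad <- peak > amp_thresh
  var_bad <- colSums(v > var_ratio_thresh * pmax(med_v, .Machine$double.eps)) > 0

  reason <- rep("", length(epochs))
  reason[var_bad] <- "variance"
  reason[amp_bad] <- "amplitude"                  # amplitude rule takes precedence
  keep <- !(amp_bad | var_bad)
  log <- data.frame(epoch = seq_along(epochs), start_sample = starts,
                    keep = keep, reason = reason, stringsAsFactors = FALSE)
  if (!any(keep))
    sn_stop("no analyzable data: all epochs rejected", "no_analyzable_data")

  structure(list(epochs = epochs[keep], sfreq = rec$sfreq,
                 channel_labels = rec$channel_labels,
                 epoch_length = epoch_length, overlap = overlap,
                 rejection_log = log, subject_id = rec$subject_id),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf("<epoched_eeg> %d epochs of %.3g s kept (%d rejected), %d channels @ %g Hz\n",
              length(x$epochs), x$epoch_length,
              sum(!x$rejection_log$keep), length(x$channel_labels), x$sfreq))
  invisible(x)
}
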