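#' Welch cross-spectral density between ROI time courses
#'
#' Hermitian cross-spectrum averaged over windowed, demeaned segments within
#' and across epochs; the diagonal equals each ROI's Welch PSD computed with
#' the same parameters.
#'
#' @param roi an `roi_timecourses` (or channels x samples matrix with `sfreq`).
#' @param seg_length segment length in samples (default 2 s worth).
#' @param seg_overlap segment overlap fraction (default 0.5).
#' @param window window name (default "hann").
#' @param sfreq sampling rate for matrix input.
#' @return a `cross_spectrum`: complex array m x m x bins plus frequency grid.
#' @export
cross_spectral_density <- function(roi, seg_length = NULL, seg_overlap = 0.5,
                                   window = "hann", sfreq = NULL) {
  if (inherits(roi, "roi_timecourses")) {
    sfreq <- roi$sfreq
    sigs <- roi$signals
    labels <- roi$roi_labels
  } else {
    sn_assert(!is.null(sfreq), "sfreq required for matrix input")
    sigs <- list(as.matrix(roi))
    labels <- rownames(roi) %||% paste0("roi", seq_len(nrow(roi)))
  }
  m <- nrow(sigs[[1]])
  seg_length <- as.integer(seg_length %||% round(2 * sfreq))
  sn_assert(all(vapply(sigs, ncol, 1L) >= seg_length),
            "fewer samples than one segment", "invalid_parameter")
  step <- max(1L, round(seg_length * (1 - seg_overlap)))
  w <- window_fn(window, seg_length)
  U <- sum(w^2)
  nb <- seg_length %/% 2 + 1L

  # FFT of every segment of every epoch, stacked: (segments) x bins x channels
  seg_ffts <- list()
  for (e in sigs) {
    for (s in segment_starts(ncol(e), seg_length, step)) {
      seg <- e[, s:(s + seg_length - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)
      X <- stats::mvfft(t(seg * rep(w, each = m)))[seq_len(nb), , drop = FALSE]
      seg_ffts[[length(seg_ffts) + 1L]] <- X
    }
  }
  nseg <- length(seg_ffts)
  if (nseg < 2)
    warning("fewer than 2 segments: imaginary parts of a single segment are estimation-degenerate")
  S <- array(0 + 0i, dim = c(m, m, nb))
  scale <- rep(2, nb); scale[1] <- 1
  if (seg_length %% 2 == 0) scale[nb] <- 1
  for (b in seq_len(nb)) {
    Mb <- t(vapply(seg_ffts, function(X) X[b, ], complex(m)))  # segments x channels
    if (m == 1) Mb <- matrix(Mb, ncol = 1)
    S[, , b] <- (t(Mb) %*% Conj(Mb)) / (nseg * sfreq * U) * scale[b]
  }
  structure(list(S = S, freqs = (seq_len(nb) - 1) * sfreq / seg_length,
                 labels = labels, n_segments = nseg),
            class = "cross_spectrum")
}

#' Imaginary-coherence connectivity matrix
#'
#' The edge weight between ROIs x and y in a band is the magnitude of the mean
#' over the band's frequency bins of `Im(S_xy / sqrt(S_xx S_yy))` -- the
#' imaginary part of the complex coherency. Zero-lag (volume-conducted) mixing
#' contributes nothing to the imaginary part, so nonzero values indicate
#' genuinely lagged interaction; the magnitude is taken because proportional
#' thresholding needs a one-sided ordering (the sign only encodes lead/lag).
#' Averaging the signed per-bin values before taking the magnitude lets
#' estimation noise cancel across bins, so the null (uncoupled or
#' volume-conducted) level stays near zero; a consistent lag contributes with
#' constant sign and is unaffected.
#'
#' @param cs a [cross_spectral_density()] result.
#' @param band band name within `scheme`.
#' @param scheme a [band_scheme()].
#' @return a `connectivity_matrix`: symmetric values in `[0, 1]`, zero
#'   diagonal; entries whose PSD vanishes at any band bin are `NA` (flagged).
#' @export
icoh_matrix <- function(cs, band, scheme = band_scheme()) {
  stopifnot(inherits(cs, "cross_spectrum"))
  lim <- band_limits(scheme, band)
  sel <- which(cs$freqs >= lim[1] & cs$freqs < lim[2])
  sn_assert(length(sel) > 0, sprintf("no frequency bins in band %s", band),
            "coverage_error")
  m <- dim(cs$S)[1]
  acc <- matrix(0, m, m)
  bad <- matrix(FALSE, m, m)
  for (b in sel) {
    Sb <- cs$S[, , b]
    p <- Re(diag(Sb))
    denom <- sqrt(outer(p, p))
    zero <- denom <= 0
    denom[zero] <- 1
    acc <- acc + Im(Sb) / denom
    bad <- bad | zero
  }
  vals <- abs(acc) / length(sel)
  vals <- (vals + t(vals)) / 2
  vals <- pmin(vals, 1)
  diag(vals) <- 0
  vals[bad] <- NA_real_
  diag(vals) <- 0
  dimnames(vals) <- list(cs$labels, cs$labels)
  structure(list(values = vals, band = band), class = "connectivity_matrix")
}

#' Proportional edge thresholding
#'
#' Retains the `floor(density * P)` largest upper-triangle entries (P = number
#' of node pairs) and zeroes the rest, fixing network density across subjects.
#' Ties are broken deterministically by lower (row, column) index first.
#'
#' @param cm a `connectivity_matrix` (or plain symmetric matrix).
#' @param density fraction of edges to retain, in `(0, 1]` (default 0.25).
#' @return a `thresholded_network` with the weighted adjacency, the density
#'   and the retained-edge count.
#' @export
proportional_threshold <- function(cm, density = 0.25) {
  vals <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  band <- if (inherits(cm, "connectivity_matrix")) cm$band else NA_character_
  sn_assert(density > 0 && density <= 1, "density must be in (0, 1]",
            "invalid_parameter")
  n <- nrow(vals)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  v <- vals[ut]
  v[is.na(v)] <- 0
  keep_n <- floor(density * nrow(ut))
  ord <- order(-v, ut[, 1], ut[, 2])
  kept <- ord[seq_len(keep_n)]
  kept <- kept[v[kept] > 0]
  if (length(kept) == 0)
    warning("all connectivity values are zero: empty network")
  adj <- matrix(0, n, n, dimnames = dimnames(vals))
  adj[ut[kept, , drop = FALSE]] <- v[kept]
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = density, band = band,
                 n_edges = length(kept)),
            class = "thresholded_network")
}
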