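#' Leadfield container
#'
#' @param gain channels x sources gain matrix (sensor microvolts per unit
#'   source amplitude). Must have full row rank.
#' @param source_roi_map optional integer vector mapping each source (column)
#'   to an ROI number in 1..68; every ROI referenced downstream must have at
#'   least one source.
#' @return a `leadfield` object.
#' @export
leadfield <- function(gain, source_roi_map = NULL) {
  gain <- as.matrix(gain)
  sn_assert(all(is.finite(gain)), "gain must be finite", "invalid_input")
  sn_assert(nrow(gain) >= 2, "need at least 2 channels", "invalid_input")
  if (qr(gain)$rank < nrow(gain))
    sn_stop("gain matrix is row-rank deficient", "invalid_input")
  if (!is.null(source_roi_map)) {
    sn_assert(length(source_roi_map) == ncol(gain),
              "source_roi_map must have one entry per source", "invalid_input")
  }
  structure(list(gain = gain, source_roi_map = source_roi_map),
            class = "leadfield")
}

#' Read a leadfield from delimited files
#'
#' @param gain_file delimited numeric matrix, channels as rows.
#' @param map_file optional two-column delimited file (source index,
#'   ROI number 1..68), no header.
#' @param sep field separator (default whitespace/tab via [utils::read.table()]).
#' @return a [leadfield()].
#' @export
read_leadfield <- function(gain_file, map_file = NULL, sep = "") {
  gain <- as.matrix(utils::read.table(gain_file, sep = sep))
  map <- NULL
  if (!is.null(map_file)) {
    m <- utils::read.table(map_file, sep = sep)
    map <- integer(ncol(gain))
    map[m[[1]]] <- m[[2]]
  }
  leadfield(gain, map)
}

#' sLORETA inverse operator
#'
#' Minimum-norm inverse kernel `K = G' (G G' + alpha I)^-1` standardized per
#' source by the square root of the corresponding diagonal entry of the
#' resolution matrix `K G`. Standardized estimates have the zero
#' localization error property for single sources in the noiseless case.
#'
#' @param lf a [leadfield()].
#' @param alpha Tikhonov regularization (>= 0). Default: 0.05 times the mean
#'   eigenvalue of the sensor-space Gram matrix `G G'`, a scale-free choice.
#' @return an `inverse_operator` with fields `kernel` (sources x channels),
#'   `standardization` (positive per-source scale) and `alpha`.
#' @export
sloreta_operator <- function(lf, alpha = NULL) {
  stopifnot(inherits(lf, "leadfield"))
  G <- lf$gain
  gram <- G %*% t(G)
  if (is.null(alpha)) alpha <- 0.05 * mean(diag(gram))
  sn_assert(alpha >= 0, "alpha must be >= 0")
  A <- gram + diag(alpha, nrow(gram))
  Ainv <- tryCatch(solve(A), error = function(e)
    sn_stop("sensor Gram matrix is singular; use alpha > 0", "singularity_error"))
  K <- t(G) %*% Ainv
  R <- K %*% G
  std <- sqrt(pmax(diag(R), 0))
  if (any(std <= 0))
    sn_stop("resolution matrix has non-positive diagonal entries (silent source); use alpha > 0 and a non-degenerate leadfield",
            "singularity_error")
  structure(list(kernel = K, standardization = std, alpha = alpha,
                 source_roi_map = lf$source_roi_map),
            class = "inverse_operator")
}

#' Apply an inverse operator to sensor data
#'
#' Linear per-sample mapping of sensor epochs to standardized source
#' amplitudes (raw minimum-norm estimate divided by the per-source
#' standardization).
#'
#' @param epochs an `epoched_eeg`, or a channels x samples matrix.
#' @param op an [sloreta_operator()].
#' @param standardize divide by the sLORETA standardization (default TRUE).
#' @return a `source_signals` object: list of sources x samples matrices (one
#'   per epoch) plus metadata.
#' @export
apply_inverse <- function(epochs, op, standardize = TRUE) {
  stopifnot(inherits(op, "inverse_operator"))
  eps <- if (inherits(epochs, "epoched_eeg")) epochs$epochs else list(as.matrix(epochs))
  sfreq <- if (inherits(epochs, "epoched_eeg")) epochs$sfreq else NA_real_
  sn_assert(nrow(eps[[1]]) == ncol(op$kernel),
            sprintf("channel count (%d) does not match kernel (%d)",
                    nrow(eps[[1]]), ncol(op$kernel)), "dimension_error")
  scale <- if (standardize) op$standardization else rep(1, nrow(op$kernel))
  out <- lapply(eps, function(e) (op$kernel %*% e) / scale)
  structure(list(signals = out, sfreq = sfreq,
                 source_roi_map = op$source_roi_map),
            class = "source_signals")
}

#' Aggregate source signals into ROI time courses
#'
#' ROI signal = arithmetic mean of member source signals at each sample
#' (a first-principal-component aggregation is available via `method`).
#'
#' @param src a `source_signals` object (or list of sources x samples matrices).
#' @param map integer vector: ROI number per source. Defaults to the map
#'   carried by `src`.
#' @param n_rois number of ROIs (default: max of `map`).
#' @param method "mean" (default) or "pc1".
#' @param sfreq sampling rate override.
#' @return an `roi_timecourses` object: list of n_rois x samples matrices.
#' @export
roi_timecourses <- function(src, map = NULL, n_rois = NULL, method = "mean",
                            sfreq = NULL) {
  sigs <- if (inherits(src, "source_signals")) src$signals else src
  map <- map %||% (if (inherits(src, "source_signals")) src$source_roi_map else NULL)
  sn_assert(!is.null(map), "a source->ROI map is required", "mapping_error")
  n_rois <- n_rois %||% max(map)
  members <- split(seq_along(map), factor(map, levels = seq_len(n_rois)))
  empty <- vapply(members, length, 1L) == 0
  if (any(empty))
    sn_stop(sprintf("ROI(s) with no sources: %s",
                    paste(which(empty), collapse = ", ")), "mapping_error")
  agg <- function(S) {
    out <- matrix(0, n_rois, ncol(S))
    for (r in seq_len(n_rois)) {
      block <- S[members[[r]], , drop = FALSE]
      out[r, ] <- if (method == "pc1" && nrow(block) > 1) {
        p <- stats::prcomp(t(block), center = FALSE)
        sc <- p$x[, 1]
        # sign convention: positive correlation with the mean signal
        if (stats::cor(sc, colMeans(block)) < 0) -sc else sc
      } else colMeans(block)
    }
    out
  }
  structure(list(signals = lapply(sigs, agg),
                 sfreq = sfreq %||% (if (inherits(src, "source_signals")) src$sfreq else NA_real_),
                 roi_labels = if (n_rois == 68) dk_roi_table()$name else paste0("roi", seq_len(n_rois))),
            class = "roi_timecourses")
}

#' @export
print.roi_timecourses <- function(x, ...) {
  cat(sprintf("<roi_timecourses> %d ROIs, %d epoch(s) of %d samples @ %s Hz\n",
              nrow(x$signals[[1]]), length(x$signals), ncol(x$signals[[1]]),
              format(x$sfreq)))
  invisible(x)
}
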