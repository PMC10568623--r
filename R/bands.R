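#' Frequency band scheme
#'
#' The eight canonical resting-EEG bands used throughout the pipeline:
#' delta (1-4), theta (4-8), alpha1 (8-10), alpha2 (10-12), beta1 (12-15),
#' beta2 (15-20), beta3 (20-30) and gamma (30-45 Hz). Band intervals are
#' half-open `[lo, hi)` so shared edges are counted exactly once.
#'
#' @param bands named list of `c(lo, hi)` pairs in Hz, ordered by frequency.
#'   Defaults to the eight-band scheme above. Bands must be contiguous and
#'   non-overlapping.
#' @return a `band_scheme` object (data.frame with columns name, lo, hi).
#' @examples
#' sch <- band_scheme()
#' sch[sch$name == "theta", ]
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(
      delta = c(1, 4), theta = c(4, 8), alpha1 = c(8, 10), alpha2 = c(10, 12),
      beta1 = c(12, 15), beta2 = c(15, 20), beta3 = c(20, 30), gamma = c(30, 45)
    )
  }
  sn_assert(length(names(bands)) == length(bands) && !anyDuplicated(names(bands)),
            "bands must be uniquely named")
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  sn_assert(all(lo < hi), "each band needs lo < hi")
  if (length(lo) > 1) {
    sn_assert(all(abs(hi[-length(hi)] - lo[-1]) < 1e-9),
              "bands must be contiguous and non-overlapping")
  }
  structure(data.frame(name = names(bands), lo = lo, hi = hi,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("band_scheme", "data.frame"))
}

band_limits <- function(scheme, band) {
  i <- match(band, scheme$name)
  sn_assert(!is.na(i), sprintf("unknown band '%s'", band), "coverage_error")
  c(scheme$lo[i], scheme$hi[i])
}
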