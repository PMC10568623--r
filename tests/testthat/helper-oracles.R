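# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, direct formulas) so they share no code
# path with the implementation they check.

# All-pairs shortest paths by Floyd-Warshall on an edge-length matrix.
oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(adj, binary = TRUE) {
  len <- adj
  len[adj > 0] <- if (binary) 1 else 1 / adj[adj > 0]
  d <- oracle_floyd_warshall(len)
  vals <- 1 / d[row(d) != col(d)]
  mean(vals)
}

oracle_char_path_length <- function(adj, binary = TRUE) {
  len <- adj
  len[adj > 0] <- if (binary) 1 else 1 / adj[adj > 0]
  d <- oracle_floyd_warshall(len)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_nodal_efficiency <- function(adj, binary = TRUE) {
  len <- adj
  len[adj > 0] <- if (binary) 1 else 1 / adj[adj > 0]
  d <- oracle_floyd_warshall(len)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) mean(1 / d[i, -i]), numeric(1))
}

# Binary clustering by direct triangle enumeration.
oracle_clustering_binary <- function(adj) {
  B <- (adj > 0) * 1
  n <- nrow(B)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a != b && B[nb[a], nb[b]] > 0) tri <- tri + 1
    out[i] <- tri / (k * (k - 1))
  }
  out
}

# Onnela weighted clustering by triple loops.
oracle_clustering_weighted <- function(adj) {
  n <- nrow(adj)
  W <- adj / max(adj)
  B <- (adj > 0) * 1
  k <- rowSums(B)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        s <- s + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    out[i] <- s / (k[i] * (k[i] - 1))
  }
  out
}

# Direct modularity evaluation (weighted).
oracle_modularity <- function(adj, membership) {
  m2 <- sum(adj)
  if (m2 == 0) return(0)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] / m2 - sum(adj[i, ]) * sum(adj[j, ]) / m2^2
  q
}

# Direct rectangular-window, non-overlapping-segment cross-spectrum and band
# iCOH: an independent estimation route (no Hann window, no overlap, scalar
# accumulation) for comparing against the pipeline with matching parameters.
oracle_band_icoh <- function(x, y, sfreq, seg, lo, hi) {
  nseg <- floor(length(x) / seg)
  nb <- seg %/% 2 + 1
  sxx <- syy <- numeric(nb)
  sxy <- complex(nb)
  for (s in seq_len(nseg)) {
    idx <- ((s - 1) * seg + 1):(s * seg)
    X <- stats::fft(x[idx] - mean(x[idx]))[1:nb]
    Y <- stats::fft(y[idx] - mean(y[idx]))[1:nb]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  freqs <- (0:(nb - 1)) * sfreq / seg
  sel <- freqs >= lo & freqs < hi
  abs(mean(Im(sxy[sel] / sqrt(sxx[sel] * syy[sel]))))
}

# Random symmetric test graph (possibly weighted) with given edge probability.
random_graph <- function(n, p = 0.4, weighted = FALSE) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on_ <- stats::runif(length(ut)) < p
  A[ut[on_]] <- if (weighted) stats::runif(sum(on_), 0.1, 1) else 1
  A + t(A)
}

make_sine_recording <- function(freq, sfreq = 250, duration = 10, amp = 1,
                                n_channels = 3) {
  t <- seq(0, duration - 1 / sfreq, by = 1 / sfreq)
  data <- matrix(rep(amp * sin(2 * pi * freq * t), n_channels),
                 nrow = n_channels, byrow = TRUE)
  eeg_recording(data, paste0("ch", seq_len(n_channels)), sfreq)
}

quadrature_sources <- function(duration = 120, sfreq = 250, band = "theta",
                               carrier = 6, noise_sd = 1e-3, seed = 3,
                               strength = 1) {
  sp <- coupling_spec(band, cbind(1, 2, pi / 2, strength), carrier_freq = carrier)
  gen_coupled_sources(2, sfreq, duration, list(sp), noise_sd = noise_sd,
                      seed = seed)
}

# Laterality helper: sensor spectral feature table for a cohort.
cohort_spectral_table <- function(cohort) {
  rows <- lapply(cohort$recordings, function(r) {
    r <- common_average_reference(bandpass_notch(r))
    ep <- epoch_and_reject(r)
    spectral_feature_row(band_powers(welch_psd(ep, seg_length = round(2 * r$sfreq))))
  })
  strokenet:::as_feature_table(cbind(cohort$clinical,
                                     as.data.frame(do.call(rbind, rows))))
}
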