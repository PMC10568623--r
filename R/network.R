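#' Graph-theoretic network attributes
#'
#' Computes the four network attributes used by the pipeline, globally and per
#' node, from a thresholded connectivity network:
#' \itemize{
#'   \item global efficiency: mean over ordered node pairs of `1/d(i,j)`
#'     (with `1/Inf = 0`), an integration measure;
#'   \item characteristic path length: mean shortest-path distance over
#'     connected pairs (a disconnection flag is set if the graph fragments);
#'   \item clustering coefficient: per-node triangle closure (binary:
#'     triangles over possible; weighted: the Onnela geometric-mean variant on
#'     weights rescaled by their maximum), plus the node mean;
#'   \item modularity: best quality over seeded restarts of Louvain community
#'     optimization (vertex order permuted per restart);
#'   \item nodal efficiency: per node, mean of `1/d(i,j)` over `j != i`.
#' }
#' In weighted mode the shortest-path edge length is `1/weight`.
#'
#' @param net a [proportional_threshold()] result, or a symmetric non-negative
#'   adjacency matrix.
#' @param mode "weighted" (default) or "binary".
#' @param community_restarts Louvain restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @return a `network_feature_set` list: `global_efficiency`,
#'   `char_path_length`, `clustering` (per node), `clustering_mean`,
#'   `modularity`, `membership`, `nodal_efficiency`, `disconnected`, `mode`,
#'   `band`.
#' @export
network_metrics <- function(net, mode = c("weighted", "binary"),
                            community_restarts = 10, seed = 1) {
  mode <- match.arg(mode)
  A <- if (inherits(net, "thresholded_network")) net$adjacency else as.matrix(net)
  band <- if (inherits(net, "thresholded_network")) net$band else NA_character_
  n <- nrow(A)
  sn_assert(n >= 2, "need at least 2 nodes", "invalid_input")
  sn_assert(all(A >= 0) && max(abs(A - t(A))) < 1e-12,
            "adjacency must be symmetric and non-negative", "invalid_input")
  diag(A) <- 0
  B <- (A > 0) * 1

  W <- if (mode == "binary") B else A
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  ew <- igraph::E(g)$weight
  if (length(ew)) {
    d <- igraph::distances(g, weights = 1 / ew)
  } else {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
  }
  off <- d[row(d) != col(d)]
  inv_d <- 1 / d
  diag(inv_d) <- 0
  geff <- mean(inv_d[row(d) != col(d)])
  connected <- is.finite(off)
  disconnected <- !all(connected)
  cpl <- if (any(connected)) mean(off[connected]) else NA_real_
  nodal_eff <- rowSums(inv_d) / (n - 1)

  k <- rowSums(B)
  denom <- k * (k - 1)
  if (mode == "binary") {
    tri <- diag(B %*% B %*% B)
  } else {
    mx <- max(A)
    Wh <- if (mx > 0) (A / mx)^(1 / 3) else A
    tri <- diag(Wh %*% Wh %*% Wh)
  }
  clustering <- ifelse(denom > 0, tri / denom, 0)

  if (length(ew) == 0) {
    Q <- 0
    membership <- seq_len(n)
    warning("empty network: modularity set to 0 with singleton communities")
  } else {
    Q <- -Inf
    membership <- NULL
    seeds <- derive_seeds(seed, community_restarts)
    for (r in seq_len(community_restarts)) {
      perm <- with_seed(seeds[r], sample.int(n))
      gp <- igraph::graph_from_adjacency_matrix(W[perm, perm],
                                                mode = "undirected", weighted = TRUE)
      cl <- with_seed(seeds[r], igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight))
      q <- igraph::modularity(gp, igraph::membership(cl), weights = igraph::E(gp)$weight)
      if (q > Q) {
        Q <- q
        membership <- integer(n)
        membership[perm] <- igraph::membership(cl)
      }
    }
  }

  structure(list(global_efficiency = geff, char_path_length = cpl,
                 clustering = clustering, clustering_mean = mean(clustering),
                 modularity = Q, membership = membership,
                 nodal_efficiency = nodal_eff,
                 disconnected = disconnected, mode = mode, band = band),
            class = "network_feature_set")
}

#' Direct modularity evaluation for a given partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` with `e_c` the within-community edge
#' weight, `d_c` the community degree sum and `m` the total edge weight.
#' Exposed for oracle checks and reporting.
#'
#' @param A symmetric adjacency matrix.
#' @param membership integer community labels per node.
#' @return modularity Q.
#' @export
modularity_q <- function(A, membership) {
  A <- as.matrix(A)
  diag(A) <- 0
  m2 <- sum(A)                       # 2m
  if (m2 == 0) return(0)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(A[idx, ])
    q <- q + e_c / (m2 / 2) - (d_c / m2)^2
  }
  q
}

#' Assemble one subject's network feature row across bands
#'
#' One named numeric vector with, per band, the three global attributes
#' (`<band>_global_efficiency`, `<band>_char_path_length`,
#' `<band>_clustering`), `<band>_modularity`, and the nodal attributes
#' `<band>_clustering_ROI<k>` and `<band>_efficiency_ROI<k>` for k = 1..68
#' (140 columns per band, 1120 for the 8-band scheme).
#'
#' @param nets named list of `network_feature_set`, one per band in `scheme`.
#' @param scheme a [band_scheme()]; all its bands must be present.
#' @return named numeric vector.
#' @export
assemble_network_features <- function(nets, scheme = band_scheme()) {
  missing <- setdiff(scheme$name, names(nets))
  sn_assert(length(missing) == 0,
            sprintf("missing band(s): %s", paste(missing, collapse = ", ")),
            "coverage_error")
  rows <- lapply(scheme$name, function(b) {
    f <- nets[[b]]
    n <- length(f$clustering)
    v <- c(f$global_efficiency, f$char_path_length, f$clustering_mean,
           f$modularity, f$clustering, f$nodal_efficiency)
    names(v) <- c(paste0(b, "_global_efficiency"), paste0(b, "_char_path_length"),
                  paste0(b, "_clustering"), paste0(b, "_modularity"),
                  paste0(b, "_clustering_ROI", seq_len(n)),
                  paste0(b, "_efficiency_ROI", seq_len(n)))
    v
  })
  unlist(rows)
}

#' Parse a network feature name
#'
#' Inverts the [assemble_network_features()] naming scheme:
#' band, metric, ROI number (NA for global attributes), hemisphere (even ROI
#' numbers are left, odd right) and lobe from the packaged ROI table.
#'
#' @param names character vector of feature names.
#' @param roi_table ROI table (default [dk_roi_table()]).
#' @return data.frame with columns feature, band, metric, roi, hemisphere, lobe.
#' @export
parse_feature_name <- function(names, roi_table = dk_roi_table()) {
  band <- sub("^([a-z0-9]+)_.*$", "\\1", names)
  rest <- sub("^[a-z0-9]+_", "", names)
  roi <- suppressWarnings(
    ifelse(grepl("_ROI[0-9]+$", rest),
           as.integer(sub(".*_ROI([0-9]+)$", "\\1", rest)), NA_integer_))
  metric <- sub("_ROI[0-9]+$", "", rest)
  hemisphere <- ifelse(is.na(roi), NA_character_, roi_hemisphere(roi))
  lobe <- ifelse(is.na(roi), NA_character_, roi_lobe(roi, roi_table))
  data.frame(feature = names, band = band, metric = metric, roi = roi,
             hemisphere = hemisphere, lobe = lobe, stringsAsFactors = FALSE)
}
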