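# Minimal seeded CART + bagged ensemble.
#
# Variance-reduction (least-squares) splits on numeric features; two-class
# classification is handled by regressing on a 0/1 coding (equivalent to Gini
# up to a constant factor). Split-gain importance is accumulated per feature,
# which is the "how much each feature is used in each node" notion the
# selection stage normalizes. Everything is deterministic given the seed.

find_best_split <- function(x, y, minbucket) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(ys)
  if (n < 2 * minbucket) return(NULL)
  cs <- cumsum(ys)
  css <- cumsum(ys^2)
  i <- seq_len(n - 1)
  ok <- xs[i] < xs[i + 1] & i >= minbucket & (n - i) >= minbucket
  if (!any(ok)) return(NULL)
  sse_l <- css[i] - cs[i]^2 / i
  sse_r <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  tot <- css[n] - cs[n]^2 / n
  gain <- tot - (sse_l + sse_r)
  gain[!ok] <- -Inf
  best <- which.max(gain)
  if (!is.finite(gain[best]) || gain[best] <= 1e-12) return(NULL)
  list(threshold = (xs[best] + xs[best + 1]) / 2, gain = gain[best])
}

grow_tree <- function(X, y, maxdepth = 4, minsplit = 5, mtry = ncol(X),
                      importance_env = NULL) {
  p <- ncol(X)
  build <- function(idx, depth) {
    node <- list(value = mean(y[idx]), n = length(idx))
    if (depth >= maxdepth || length(idx) < minsplit ||
        stats::var(y[idx]) < 1e-14) return(node)
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    best <- NULL
    minbucket <- max(1L, minsplit %/% 3L)
    for (j in feats) {
      sp <- find_best_split(X[idx, j], y[idx], minbucket)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp
        best$feature <- j
      }
    }
    if (is.null(best)) return(node)
    if (!is.null(importance_env))
      importance_env$gain[best$feature] <- importance_env$gain[best$feature] + best$gain
    left <- idx[X[idx, best$feature] <= best$threshold]
    right <- setdiff(idx, left)
    node$feature <- best$feature
    node$threshold <- best$threshold
    node$left <- build(left, depth + 1)
    node$right <- build(right, depth + 1)
    node
  }
  build(seq_len(nrow(X)), 0)
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  descend <- function(node, idx) {
    if (is.null(node$feature)) {
      out[idx] <<- node$value
      return(invisible(NULL))
    }
    go_left <- X[idx, node$feature] <= node$threshold
    if (any(go_left)) descend(node$left, idx[go_left])
    if (any(!go_left)) descend(node$right, idx[!go_left])
  }
  if (nrow(X)) descend(tree, seq_len(nrow(X)))
  out
}

#' Seeded bagged tree ensemble
#'
#' Bootstrap-aggregated CART trees with per-node feature subsampling and
#' split-gain importance; used for the laterality classifier and the
#' importance-ranking stage, and as the AdaBoost base learner.
#'
#' @param X numeric matrix (rows = subjects).
#' @param y numeric response, or a two-level factor/character for
#'   classification.
#' @param ntree number of trees (default 100).
#' @param mtry features tried per node (default: sqrt(p) for classification,
#'   p/3 for regression).
#' @param maxdepth,minsplit tree size controls.
#' @param seed RNG seed (deterministic fit).
#' @return a `bagged_trees` model with `$importance` (named split-gain sums).
#' @export
bagged_trees <- function(X, y, ntree = 100, mtry = NULL, maxdepth = 4,
                         minsplit = 5, seed = 1) {
  X <- as.matrix(X)
  classification <- !is.numeric(y)
  levels <- NULL
  if (classification) {
    y <- as.factor(y)
    sn_assert(nlevels(y) == 2, "classification requires exactly 2 classes",
              "invalid_input")
    levels <- levels(y)
    y <- as.numeric(y) - 1
  }
  p <- ncol(X)
  mtry <- mtry %||% max(1L, if (classification) floor(sqrt(p)) else floor(p / 3))
  imp <- new.env(parent = emptyenv())
  imp$gain <- numeric(p)
  trees <- with_seed(seed, lapply(seq_len(ntree), function(t) {
    rows <- sample.int(nrow(X), replace = TRUE)
    grow_tree(X[rows, , drop = FALSE], y[rows], maxdepth, minsplit, mtry, imp)
  }))
  importance <- stats::setNames(imp$gain, colnames(X) %||% paste0("V", seq_len(p)))
  structure(list(trees = trees, levels = levels, mtry = mtry,
                 importance = importance,
                 feature_names = colnames(X)),
            class = "bagged_trees")
}

#' @param object a `bagged_trees` model.
#' @param newdata matrix of new rows.
#' @param type "response" (numeric / class label) or "prob" (classification
#'   probability of the second level).
#' @param ... unused.
#' @rdname bagged_trees
#' @export
predict.bagged_trees <- function(object, newdata, type = "response", ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  m <- vapply(object$trees, function(tr) predict_tree(tr, newdata),
              numeric(nrow(newdata)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(newdata))
  preds <- rowMeans(m)
  if (is.null(object$levels) || type == "prob") return(preds)
  object$levels[(preds > 0.5) + 1]
}
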