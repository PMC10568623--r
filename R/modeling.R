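#' Coefficient of determination from pooled predictions
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_res = sum (y_i - yhat_i)^2` and
#' `SS_tot = sum (y_i - mean(y))^2`. With leave-one-out predictions this is
#' computed once over the pooled predictions, not averaged per fold (a
#' per-fold R^2 is undefined for a single held-out observation). LOO R^2 can
#' be negative; it is always <= 1.
#'
#' @param y actual values.
#' @param yhat predicted values.
#' @return list with `ss_res`, `ss_tot`, `r2`.
#' @export
r_squared <- function(y, yhat) {
  sn_assert(length(y) == length(yhat) && length(y) >= 2,
            "y and yhat must have equal length >= 2", "invalid_input")
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(ss_res = ss_res, ss_tot = ss_tot, r2 = 1 - ss_res / ss_tot)
}

outcome_vector <- function(table, outcome = NULL) {
  outcome %||% table[["moca_std"]]
}

#' Lesion-laterality classification with LOO validation
#'
#' Trains a seeded bagged-tree classifier on the unilateral (left/right)
#' subjects only and reports leave-one-out accuracy, sensitivity and
#' specificity (left lesions taken as the positive class). Bilateral subjects
#' are excluded from training and can be assigned afterwards with
#' [assign_bilateral()].
#'
#' @param table a `feature_table` with a `lesion_side` column containing
#'   "left"/"right" (and possibly "bilateral") labels.
#' @param features feature columns to use (default: all).
#' @param seed RNG seed.
#' @param ntree trees in the ensemble (default 100).
#' @param maxdepth tree depth (default 3).
#' @return a `laterality_model`: fitted ensemble, LOO `predictions`,
#'   `accuracy`, `sensitivity`, `specificity`, `confusion`.
#' @export
classify_laterality <- function(table, features = feature_cols(table), seed = 1,
                                ntree = 100, maxdepth = 3) {
  side <- table[["lesion_side"]]
  uni <- which(side %in% c("left", "right"))
  sn_assert(length(unique(side[uni])) == 2,
            "need both left and right unilateral subjects", "invalid_input")
  sn_assert(min(table(side[uni])) >= 2, "need >= 2 subjects per class",
            "invalid_input")
  X <- as.matrix(table[uni, features, drop = FALSE])
  yl <- side[uni]
  seeds <- derive_seeds(seed, length(uni) + 1)
  preds <- character(length(uni))
  for (i in seq_along(uni)) {
    fit <- bagged_trees(X[-i, , drop = FALSE], yl[-i], ntree = ntree,
                        maxdepth = maxdepth, seed = seeds[i])
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  tp <- sum(preds == "left" & yl == "left")
  tn <- sum(preds == "right" & yl == "right")
  acc <- mean(preds == yl)
  model <- bagged_trees(X, yl, ntree = ntree, maxdepth = maxdepth,
                        seed = seeds[length(uni) + 1])
  structure(list(model = model, features = features,
                 predictions = data.frame(subject = table$subject_id[uni],
                                          actual = yl, predicted = preds,
                                          stringsAsFactors = FALSE),
                 accuracy = acc,
                 sensitivity = tp / sum(yl == "left"),
                 specificity = tn / sum(yl == "right"),
                 confusion = table(actual = yl, predicted = factor(preds, c("left", "right")))),
            class = "laterality_model")
}

#' Assign bilateral subjects to a lesion-side group
#'
#' Unilateral subjects keep their true label; subjects labelled "bilateral"
#' (or NA) are assigned by the trained laterality model, so the result
#' partitions the cohort into exactly two groups.
#'
#' @param model a [classify_laterality()] result.
#' @param table the full `feature_table`.
#' @return character vector ("left"/"right") per subject.
#' @export
assign_bilateral <- function(model, table) {
  stopifnot(inherits(model, "laterality_model"))
  side <- table[["lesion_side"]]
  out <- side
  todo <- which(!(side %in% c("left", "right")))
  if (length(todo)) {
    X <- as.matrix(table[todo, model$features, drop = FALSE])
    out[todo] <- predict(model$model, X)
  }
  out
}

#' Correlation filter on features
#'
#' Retains features whose absolute Pearson correlation with the outcome
#' exceeds `r_min`; zero-variance features are excluded (undefined r) and
#' logged.
#'
#' @param table a `feature_table`.
#' @param outcome outcome vector (default: the table's `moca_std` column).
#' @param r_min correlation threshold (default 0.3, strict inequality).
#' @return the filtered table; attributes `correlations` (named r for every
#'   feature) and `excluded_zero_variance`.
#' @export
correlation_filter <- function(table, outcome = NULL, r_min = 0.3) {
  y <- outcome_vector(table, outcome)
  sn_assert(length(y) >= 3, "need at least 3 subjects", "invalid_input")
  feats <- feature_cols(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  zero_var <- feats[sds == 0]
  r <- rep(NA_real_, length(feats))
  names(r) <- feats
  ok <- sds > 0
  r[ok] <- drop(stats::cor(X[, ok, drop = FALSE], y))
  keep <- feats[!is.na(r) & abs(r) > r_min]
  out <- table[, c(intersect(c("subject_id", "lesion_side", "moca_std"),
                             names(table)), keep), drop = FALSE]
  out <- as_feature_table(out, planted = attr(table, "planted"))
  attr(out, "correlations") <- r
  attr(out, "excluded_zero_variance") <- zero_var
  out
}

#' Importance-based feature ranking
#'
#' Fits a seeded bagged-tree regression of the outcome on all remaining
#' features and ranks them by split-gain importance normalized to sum to one
#' (each feature's share of the total importance). Ties are broken by feature
#' name.
#'
#' @param table a (typically correlation-filtered) `feature_table`.
#' @param outcome outcome vector (default `moca_std`).
#' @param seed RNG seed.
#' @param ntree,maxdepth ensemble size controls.
#' @return a `feature_ranking`: data.frame (feature, importance,
#'   norm_importance) sorted by normalized importance, descending.
#' @export
rank_importance <- function(table, outcome = NULL, seed = 1, ntree = 200,
                            maxdepth = 4) {
  y <- outcome_vector(table, outcome)
  feats <- feature_cols(table)
  sn_assert(length(feats) >= 1, "no features to rank", "invalid_input")
  X <- as.matrix(table[, feats, drop = FALSE])
  fit <- bagged_trees(X, y, ntree = ntree, maxdepth = maxdepth, seed = seed)
  imp <- fit$importance
  total <- sum(imp)
  norm <- if (total > 0) imp / total else {
    warning("all split gains are zero; importance set uniform")
    rep(1 / length(imp), length(imp))
  }
  ord <- order(-norm, names(imp))
  structure(list(ranking = data.frame(feature = names(imp)[ord],
                                      importance = unname(imp[ord]),
                                      norm_importance = unname(norm[ord]),
                                      stringsAsFactors = FALSE),
                 r_threshold = attr(table, "r_threshold"),
                 seed = seed),
            class = "feature_ranking")
}

#' Select the top-k features of a ranking
#'
#' @param ranking a [rank_importance()] result.
#' @param k number of features (default 20); if fewer are available, all are
#'   returned with a warning.
#' @return data.frame subset of the ranking, in ranking order.
#' @export
select_top_k <- function(ranking, k = 20) {
  stopifnot(inherits(ranking, "feature_ranking"))
  sn_assert(is_count(k) && k >= 1, "k must be a positive count")
  avail <- nrow(ranking$ranking)
  if (avail < k)
    warning(sprintf("only %d features available (requested %d)", avail, k))
  ranking$ranking[seq_len(min(k, avail)), , drop = FALSE]
}

#' Selection summary over frequency bands and lobes
#'
#' Mirrors the two-panel summary of selected features: per frequency band and
#' per lobe (frontal, temporal, parietal, occipital, isthmus, others), the
#' feature count with its percentage of k and the summed normalized importance
#' with its percentage of the selected total. Global (non-nodal) attributes
#' and unmapped ROIs fall in the "others" bucket (with a warning for unmapped
#' ROIs).
#'
#' @param selected a [select_top_k()] result (feature + norm_importance).
#' @param roi_table ROI lookup table (default [dk_roi_table()]).
#' @return a `selection_summary`: list of `band` and `lobe` data.frames.
#' @export
summarize_selection <- function(selected, roi_table = dk_roi_table()) {
  info <- parse_feature_name(selected$feature, roi_table)
  k <- nrow(selected)
  tot_imp <- sum(selected$norm_importance)
  lobe <- info$lobe
  unmapped <- !is.na(info$roi) & is.na(lobe)
  if (any(unmapped))
    warning(sprintf("%d feature(s) with unmapped ROI placed in 'others'",
                    sum(unmapped)))
  lobe[is.na(lobe)] <- "others"
  lobe[lobe == "other"] <- "others"
  panel <- function(fac, levels) {
    f <- factor(fac, levels = levels)
    cnt <- as.integer(table(f))
    imp <- vapply(levels, function(l)
      sum(selected$norm_importance[which(f == l)]), numeric(1))
    data.frame(category = levels, n = cnt,
               pct_n = 100 * cnt / k,
               importance = unname(imp),
               pct_importance = if (tot_imp > 0) 100 * unname(imp) / tot_imp else 0,
               stringsAsFactors = FALSE)
  }
  structure(list(
    band = panel(info$band, band_scheme()$name),
    lobe = panel(lobe, c("frontal", "temporal", "parietal", "occipital",
                         "isthmus", "others")),
    k = k),
    class = "selection_summary")
}

#' Leave-one-out regression over the model families
#'
#' For each requested model, fits n leave-one-out folds (subject i predicted
#' by the fit that excludes subject i; any hyperparameter tuning happens
#' inside the training fold only) and evaluates one pooled
#' `R^2 = 1 - SS_res/SS_tot` over the LOO predictions.
#'
#' @param table a `feature_table` restricted to the selected features (or a
#'   plain numeric matrix/data.frame of features).
#' @param outcome outcome vector (default the table's `moca_std`).
#' @param models subset of `c("ridge", "lasso", "elasticnet", "svr",
#'   "adaboost")`.
#' @param seed RNG seed.
#' @param hyper optional named list of per-model hyperparameter lists, e.g.
#'   `list(ridge = list(lambda = 0.01))`.
#' @return named list of `model_evaluation` objects (fields: `model`, `y`,
#'   `yhat`, `ss_res`, `ss_tot`, `r2`, `n`).
#' @export
fit_regressors_loo <- function(table, outcome = NULL, models = "ridge",
                               seed = 1, hyper = list()) {
  y <- outcome_vector(table, outcome)
  sn_assert(length(y) >= 3, "need n >= 3 subjects", "invalid_input")
  bad <- setdiff(models, sn_model_names)
  sn_assert(length(bad) == 0,
            sprintf("unknown model(s): %s", paste(bad, collapse = ", ")),
            "invalid_parameter")
  feats <- if (inherits(table, "feature_table")) feature_cols(table) else
    colnames(as.data.frame(table))
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  n <- length(y)
  out <- list()
  for (m in models) {
    seeds <- derive_seeds(seed + match(m, sn_model_names), n)
    yhat <- numeric(n)
    for (i in seq_len(n)) {
      fit <- fit_regressor(m, X[-i, , drop = FALSE], y[-i], seed = seeds[i],
                           hyper = hyper[[m]] %||% list())
      yhat[i] <- predict(fit, X[i, , drop = FALSE])
    }
    ev <- r_squared(y, yhat)
    out[[m]] <- structure(list(model = m, y = y, yhat = yhat,
                               ss_res = ev$ss_res, ss_tot = ev$ss_tot,
                               r2 = ev$r2, n = n),
                          class = "model_evaluation")
  }
  out
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %s: LOO R^2 = %.4f (n = %d)\n",
              x$model, x$r2, x$n))
  invisible(x)
}

#' Count the composite-model search space
#'
#' Number of feature subsets taking `t` features from the top pool (t ranging
#' over `top_take`) plus features from the bottom pool, either any number up
#' to `max_total - t` or exactly `max_total - t` (`bottom_exact`).
#'
#' @param top_pool,bottom_pool pool sizes.
#' @param top_take integer range of top-features taken.
#' @param max_total maximum subset size.
#' @param bottom_exact take exactly `max_total - t` bottom features instead of
#'   0..(max_total - t).
#' @return total subset count (numeric).
#' @export
count_composite_models <- function(top_pool = 5, bottom_pool = 15,
                                   top_take = 3:5, max_total = 10,
                                   bottom_exact = FALSE) {
  total <- 0
  for (t in top_take) {
    bsizes <- if (bottom_exact) max_total - t else 0:(max_total - t)
    bsizes <- bsizes[bsizes >= 0 & bsizes <= bottom_pool]
    total <- total + choose(top_pool, t) * sum(choose(bottom_pool, bsizes))
  }
  total
}

#' Composite-model sensitivity search
#'
#' Enumerates feature subsets combining 3-5 of the top-5 ranked features with
#' features from the next 15 ("bottom pool"), total size capped (default 10),
#' fits each subset by leave-one-out regression and returns the evaluations
#' sorted by LOO R^2. If the constraint set admits more than `max_models`
#' subsets, a seeded random subsample of distinct subsets is evaluated.
#'
#' @param ranking a [rank_importance()] result with at least
#'   `top_pool + bottom_pool` features.
#' @param table feature table holding the ranked features.
#' @param outcome outcome vector (default `moca_std`).
#' @param top_pool,bottom_pool,top_take,max_total search constraints.
#' @param max_models evaluation budget (default 9000).
#' @param model model family fitted on every subset (default "ridge").
#' @param seed RNG seed (drives the subsampling and the fits).
#' @param hyper hyperparameters forwarded to [fit_regressors_loo()].
#' @param bottom_exact see [count_composite_models()].
#' @return a `composite_search`: data.frame of subsets with R^2 (descending)
#'   and the list of evaluations.
#' @export
composite_search <- function(ranking, table, outcome = NULL, top_pool = 5,
                             bottom_pool = 15, top_take = 3:5, max_total = 10,
                             max_models = 9000, model = "ridge", seed = 1,
                             hyper = list(), bottom_exact = FALSE) {
  stopifnot(inherits(ranking, "feature_ranking"))
  feats <- ranking$ranking$feature
  sn_assert(length(feats) >= top_pool + bottom_pool,
            sprintf("ranking has %d features; need >= %d", length(feats),
                    top_pool + bottom_pool), "invalid_input")
  top <- feats[seq_len(top_pool)]
  bottom <- feats[top_pool + seq_len(bottom_pool)]
  total <- count_composite_models(top_pool, bottom_pool, top_take, max_total,
                                  bottom_exact)
  sn_assert(total > 0, "constraints admit no feature subsets", "empty_search")

  subset_key <- function(s) paste(sort(s), collapse = "|")
  subsets <- list()
  if (total <= max_models) {
    for (t in top_take) {
      tcombs <- utils::combn(top, t, simplify = FALSE)
      bsizes <- if (bottom_exact) max_total - t else 0:(max_total - t)
      bsizes <- bsizes[bsizes >= 0 & bsizes <= bottom_pool]
      for (b in bsizes) {
        bcombs <- if (b == 0) list(character(0)) else
          utils::combn(bottom, b, simplify = FALSE)
        for (tc in tcombs) for (bc in bcombs)
          subsets[[length(subsets) + 1]] <- c(tc, bc)
      }
    }
  } else {
    # seeded subsample of distinct subsets, cell-weighted by exact counts
    cells <- do.call(rbind, lapply(top_take, function(t) {
      bsizes <- if (bottom_exact) max_total - t else 0:(max_total - t)
      bsizes <- bsizes[bsizes >= 0 & bsizes <= bottom_pool]
      data.frame(t = t, b = bsizes,
                 count = choose(top_pool, t) * choose(bottom_pool, bsizes))
    }))
    subsets <- with_seed(seed, {
      seen <- new.env(parent = emptyenv())
      acc <- list()
      guard <- 0
      while (length(acc) < max_models && guard < 50 * max_models) {
        guard <- guard + 1
        cell <- cells[sample.int(nrow(cells), 1, prob = cells$count), ]
        s <- c(sample(top, cell$t),
               if (cell$b > 0) sample(bottom, cell$b) else character(0))
        key <- subset_key(s)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          acc[[length(acc) + 1]] <- s
        }
      }
      acc
    })
  }

  seeds <- derive_seeds(seed, length(subsets))
  evals <- vector("list", length(subsets))
  r2 <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    sub_tab <- as.data.frame(table)[, subsets[[i]], drop = FALSE]
    ev <- fit_regressors_loo(sub_tab, outcome = outcome_vector(table, outcome),
                             models = model, seed = seeds[i], hyper = hyper)[[model]]
    evals[[i]] <- ev
    r2[i] <- ev$r2
  }
  ord <- order(-r2)
  structure(list(results = data.frame(
    subset = vapply(subsets[ord], paste, character(1), collapse = ","),
    size = vapply(subsets[ord], length, integer(1)),
    r2 = r2[ord], stringsAsFactors = FALSE),
    evaluations = evals[ord], n_enumerated = total,
    n_evaluated = length(subsets), model = model),
    class = "composite_search")
}

#' Group-specific feature selection and LOO regression
#'
#' The second stage of the procedure for one laterality group: correlation
#' filter (|r| > `r_min`), importance ranking, top-k selection and LOO
#' regression. In `"paper"` mode selection runs once on the whole group before
#' LOO (as the published flow implies); `"strict"` mode re-runs the entire
#' selection inside every LOO training fold, which is slower but leakage-free
#' by construction, and is reported alongside as a robustness check.
#'
#' @param table the group's `feature_table` (network features).
#' @param outcome outcome vector (default `moca_std`).
#' @param r_min correlation threshold (default 0.3).
#' @param top_k number of selected features (default 20).
#' @param models model families to fit.
#' @param seed RNG seed.
#' @param selection_mode "paper" or "strict".
#' @param hyper forwarded to [fit_regressors_loo()].
#' @return list with `selected`, `ranking`, `summary`, `evaluations`
#'   (paper mode) or `evaluations` only (strict mode: per-fold selection).
#' @export
predict_outcome_group <- function(table, outcome = NULL, r_min = 0.3,
                                  top_k = 20, models = "ridge", seed = 1,
                                  selection_mode = c("paper", "strict"),
                                  hyper = list()) {
  selection_mode <- match.arg(selection_mode)
  y <- outcome_vector(table, outcome)
  if (selection_mode == "paper") {
    filt <- correlation_filter(table, y, r_min = r_min)
    if (length(feature_cols(filt)) == 0) {
      # nothing survives the filter: report the uninformative mean predictor
      warning("no features pass the correlation filter; fitting the mean predictor")
      n <- length(y)
      yhat <- vapply(seq_len(n), function(i) mean(y[-i]), numeric(1))
      ev <- r_squared(y, yhat)
      evals <- stats::setNames(lapply(models, function(m)
        structure(list(model = m, y = y, yhat = yhat, ss_res = ev$ss_res,
                       ss_tot = ev$ss_tot, r2 = ev$r2, n = n),
                  class = "model_evaluation")), models)
      return(list(selected = NULL, ranking = NULL, summary = NULL,
                  evaluations = evals, selection_mode = selection_mode))
    }
    ranking <- rank_importance(filt, y, seed = seed)
    selected <- select_top_k(ranking, k = top_k)
    evals <- fit_regressors_loo(
      as.data.frame(table)[, selected$feature, drop = FALSE], y,
      models = models, seed = seed, hyper = hyper)
    list(selected = selected, ranking = ranking,
         summary = summarize_selection(selected), evaluations = evals,
         selection_mode = selection_mode)
  } else {
    n <- length(y)
    seeds <- derive_seeds(seed, n)
    evals <- list()
    for (m in models) {
      yhat <- numeric(n)
      for (i in seq_len(n)) {
        tr <- as_feature_table(as.data.frame(table)[-i, , drop = FALSE])
        filt <- correlation_filter(tr, y[-i], r_min = r_min)
        if (length(feature_cols(filt)) == 0) {
          yhat[i] <- mean(y[-i])
          next
        }
        rk <- rank_importance(filt, y[-i], seed = seeds[i])
        sel <- suppressWarnings(select_top_k(rk, k = top_k))
        fit <- fit_regressor(m, as.matrix(as.data.frame(table)[-i, sel$feature,
                                                               drop = FALSE]),
                             y[-i], seed = seeds[i], hyper = hyper[[m]] %||% list())
        yhat[i] <- predict(fit, as.matrix(as.data.frame(table)[i, sel$feature,
                                                               drop = FALSE]))
      }
      ev <- r_squared(y, yhat)
      evals[[m]] <- structure(list(model = m, y = y, yhat = yhat,
                                   ss_res = ev$ss_res, ss_tot = ev$ss_tot,
                                   r2 = ev$r2, n = n),
                              class = "model_evaluation")
    }
    list(evaluations = evals, selection_mode = selection_mode)
  }
}
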