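test_that("R-squared follows its defining identity", {
  y <- c(1, 2, 3)
  yhat <- c(1.1, 1.9, 3.2)
  ev <- r_squared(y, yhat)
  # independent evaluation of the printed formula
  expect_equal(ev$ss_res, sum((y - yhat)^2))
  expect_equal(ev$ss_res, 0.06, tolerance = 1e-12)
  expect_equal(ev$ss_tot, 2)
  expect_equal(ev$r2, 0.97, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    yy <- rnorm(10); hh <- rnorm(10)
    e <- r_squared(yy, hh)
    expect_equal(e$r2, 1 - e$ss_res / e$ss_tot, tolerance = 1e-12)
    expect_lte(e$r2, 1)
  }
})

test_that("correlation filter keeps signal, drops constants and noise", {
  tb <- gen_feature_table(200, 30, planted = lapply(1:7, function(i) c(i, 2)),
                          noise_sd = 1e-9, seed = 3)
  tb$feature_030 <- 1.0    # constant column
  filt <- correlation_filter(tb, r_min = 0.3)
  kept <- feature_cols(filt)
  expect_true(all(sprintf("feature_%03d", 1:7) %in% kept))
  expect_lte(length(setdiff(kept, sprintf("feature_%03d", 1:7))), 2)
  expect_equal(attr(filt, "excluded_zero_variance"), "feature_030")
  # feature identical to the outcome is retained with r = 1
  tb2 <- gen_feature_table(50, 3, planted = list(c(1, 1)), noise_sd = 0, seed = 4)
  f2 <- correlation_filter(tb2)
  expect_equal(unname(attr(f2, "correlations")["feature_001"]), 1, tolerance = 1e-12)
  expect_error(correlation_filter(tb2[1:2, ]), class = "invalid_input")
})

test_that("importance ranking finds dominant features and normalizes", {
  # single feature -> importance 1
  tb1 <- gen_feature_table(30, 1, planted = list(c(1, 1)), noise_sd = 0.5, seed = 1)
  rk1 <- rank_importance(tb1, seed = 1, ntree = 50)
  expect_equal(rk1$ranking$norm_importance, 1.0)

  # dominant planted feature (10x weight, noiseless) ranks first in >= 18/20 seeds
  wins <- 0
  for (s in 1:20) {
    tb <- gen_feature_table(80, 6, planted = list(c(2, 10), c(5, 1)),
                            noise_sd = 0, seed = 100 + s)
    rk <- rank_importance(tb, seed = s, ntree = 60)
    wins <- wins + (rk$ranking$feature[1] == "feature_002")
    expect_equal(sum(rk$ranking$norm_importance), 1, tolerance = 1e-9)
  }
  expect_gte(wins, 18)
})

test_that("top-k selection respects order, shortfall and ties", {
  tb <- gen_feature_table(100, 30, planted = lapply(1:5, function(i) c(i, 1)),
                          noise_sd = 0.5, seed = 2)
  rk <- rank_importance(tb, seed = 3)
  sel <- select_top_k(rk, 20)
  expect_equal(nrow(sel), 20)
  expect_equal(sel$feature, rk$ranking$feature[1:20])
  expect_true(all(diff(sel$norm_importance) <= 1e-12))
  expect_warning(s5 <- select_top_k(rank_importance(tb1 <- gen_feature_table(
    20, 5, planted = list(c(1, 1)), seed = 1), seed = 1, ntree = 30), 20),
    "only 5")
  expect_equal(nrow(s5), 5)
  expect_equal(nrow(select_top_k(rk, 1)), 1)
})

test_that("selection summaries mirror the two-panel layout", {
  sel <- data.frame(
    feature = c(paste0("theta_clustering_ROI", 1:13),          # frontal ROIs 1-13
                paste0("theta_clustering_ROI", c(21, 23, 25, 27)),  # temporal
                "theta_clustering_ROI39",                       # parietal
                "theta_clustering_ROI49",                       # occipital
                "theta_global_efficiency"),                     # global -> others
    norm_importance = rep(0.05, 20), stringsAsFactors = FALSE)
  sm <- summarize_selection(sel)
  expect_equal(sm$band$n[sm$band$category == "theta"], 20)
  expect_equal(sm$band$pct_n[sm$band$category == "theta"], 100)
  expect_equal(sum(sm$band$n), 20)
  expect_equal(sum(sm$lobe$n), 20)
  expect_equal(sum(sm$lobe$pct_n), 100, tolerance = 0.1)
  expect_equal(sum(sm$lobe$pct_importance), 100, tolerance = 0.1)
  expect_equal(sm$lobe$n[sm$lobe$category == "frontal"], 13)
  expect_equal(sm$lobe$pct_n[sm$lobe$category == "frontal"], 65)
})

test_that("LOO regression recovers a noiseless linear map and rejects bad models", {
  tb <- gen_feature_table(40, 4, planted = list(c(1, 2), c(2, -1)),
                          noise_sd = 0, seed = 5)
  ev <- fit_regressors_loo(tb, models = "ridge", seed = 1,
                           hyper = list(ridge = list(lambda = 1e-4)))
  expect_gte(ev$ridge$r2, 0.99)
  expect_equal(ev$ridge$r2, 1 - ev$ridge$ss_res / ev$ridge$ss_tot,
               tolerance = 1e-12)
  expect_error(fit_regressors_loo(tb, models = "forest"),
               class = "invalid_parameter")
})

test_that("all five model families run and stay within the R2 contract", {
  tb <- gen_feature_table(35, 3, planted = list(c(1, 2), c(2, 1)),
                          noise_sd = 0.3, seed = 6)
  evs <- fit_regressors_loo(tb, models = c("ridge", "lasso", "elasticnet",
                                           "svr", "adaboost"), seed = 2)
  expect_setequal(names(evs), c("ridge", "lasso", "elasticnet", "svr", "adaboost"))
  for (ev in evs) {
    expect_lte(ev$r2, 1)
    expect_equal(length(ev$yhat), 35)
  }
  expect_gte(evs$ridge$r2, 0.8)
  expect_gte(evs$svr$r2, 0.5)
})

test_that("pure-noise outcomes give no spurious LOO skill", {
  r2s <- sapply(1:10, function(s) {
    tb <- gen_feature_table(40, 5, planted = list(), noise_sd = 1, seed = 200 + s)
    fit_regressors_loo(tb, models = "ridge", seed = s)$ridge$r2
  })
  expect_lte(mean(r2s), 0.1)
})

test_that("subject i's LOO prediction ignores subject i's outcome", {
  tb <- gen_feature_table(25, 4, planted = list(c(1, 1)), noise_sd = 0.5, seed = 7)
  base <- fit_regressors_loo(tb, models = "ridge", seed = 3)$ridge
  set.seed(8)
  for (k in 1:5) {
    i <- sample(25, 1)
    y2 <- tb$moca_std
    y2[i] <- y2[i] + rnorm(1, sd = 5)
    pert <- fit_regressors_loo(tb, outcome = y2, models = "ridge", seed = 3)$ridge
    expect_equal(pert$yhat[i], base$yhat[i], tolerance = 1e-12)
  }
})

test_that("laterality classification separates planted asymmetry", {
  # perfectly separable one-feature toy
  toy <- strokenet:::as_feature_table(data.frame(
    subject_id = sprintf("T%02d", 1:20),
    lesion_side = rep(c("left", "right"), each = 10),
    moca_std = rnorm(20),
    sep = rep(c(-1, 1), each = 10) + rnorm(20, sd = 0.05)))
  lat <- classify_laterality(toy, seed = 1, ntree = 30)
  expect_equal(lat$accuracy, 1.0)
  expect_equal(lat$sensitivity, 1.0)
  expect_equal(lat$specificity, 1.0)
  # no bilateral subjects: assignments equal labels
  expect_equal(assign_bilateral(lat, toy), toy$lesion_side)
  # bilateral subjects get assigned to exactly one group
  toy2 <- toy
  toy2$lesion_side[c(3, 14)] <- "bilateral"
  lat2 <- classify_laterality(toy2, seed = 1, ntree = 30)
  g <- assign_bilateral(lat2, toy2)
  expect_true(all(g %in% c("left", "right")))
  expect_equal(length(g), 20)
  # a bilateral subject sitting on the left centroid is assigned left
  toy3 <- toy2
  toy3$sep[3] <- mean(toy$sep[toy$lesion_side == "left"])
  expect_equal(assign_bilateral(classify_laterality(toy3, seed = 1, ntree = 30),
                                toy3)[3], "left")
  # single-class input errors
  bad <- toy; bad$lesion_side <- "left"
  expect_error(classify_laterality(bad, seed = 1), class = "invalid_input")
})

test_that("composite search counts, ordering and degenerate constraints", {
  expect_equal(count_composite_models(top_take = 5:5, bottom_pool = 15,
                                      max_total = 5), 1)
  expect_equal(count_composite_models(top_take = 3:5, bottom_pool = 15,
                                      max_total = 10, bottom_exact = TRUE),
               choose(5, 3) * choose(15, 7) + choose(5, 4) * choose(15, 6) +
                 choose(5, 5) * choose(15, 5))

  tb <- gen_feature_table(30, 12, planted = list(c(1, 2), c(2, 1), c(3, 1)),
                          noise_sd = 0.5, seed = 9)
  rk <- rank_importance(tb, seed = 1, ntree = 80)
  cs <- composite_search(rk, tb, top_pool = 3, bottom_pool = 4, top_take = 2:3,
                         max_total = 4, max_models = 50, model = "ridge",
                         seed = 2, hyper = list(ridge = list(lambda = 0.01)))
  expect_equal(cs$n_enumerated,
               count_composite_models(3, 4, 2:3, 4))
  expect_equal(cs$results$r2, sort(cs$results$r2, decreasing = TRUE))
  expect_true(all(cs$results$size <= 4))
  # the full top-3 subset is in the search space, so the best composite beats
  # (or equals) the plain top-3 model under identical folds
  # (fixed-lambda ridge LOO is deterministic, so the seed is irrelevant here)
  top3 <- fit_regressors_loo(as.data.frame(tb)[, rk$ranking$feature[1:3]],
                             tb$moca_std, models = "ridge", seed = 99,
                             hyper = list(ridge = list(lambda = 0.01)))$ridge
  expect_gte(cs$results$r2[1] + 1e-9, top3$r2)
  expect_error(composite_search(rk, tb, top_pool = 5, bottom_pool = 15),
               class = "invalid_input")
  expect_error(composite_search(rk, tb, top_pool = 3, bottom_pool = 4,
                                top_take = 4:4, max_total = 4),
               class = "empty_search")
})

test_that("subsampled composite search respects the budget and dedupes", {
  tb <- gen_feature_table(25, 25, planted = list(c(1, 2)), noise_sd = 0.5, seed = 10)
  rk <- rank_importance(tb, seed = 1, ntree = 50)
  cs <- composite_search(rk, tb, top_pool = 5, bottom_pool = 15, top_take = 3:5,
                         max_total = 10, max_models = 40, model = "ridge",
                         seed = 3, hyper = list(ridge = list(lambda = 0.05)))
  expect_equal(cs$n_evaluated, 40)
  expect_gt(cs$n_enumerated, 40)
  expect_false(anyDuplicated(cs$results$subset) > 0)
})

test_that("strict selection mode produces leakage-free evaluations", {
  co <- gen_cohort(30, cohort_profile(signal_fraction = 0.9), seed = 12,
                   mode = "features")
  tab <- co$features
  # restrict to a manageable feature subset for runtime
  keep <- c(names(co$truth$planted),
            setdiff(feature_cols(tab), names(co$truth$planted))[1:30])
  small <- strokenet:::as_feature_table(
    as.data.frame(tab)[, c("subject_id", "lesion_side", "moca_std", keep)])
  res <- suppressWarnings(
    predict_outcome_group(small, models = "ridge", seed = 4, top_k = 10,
                          selection_mode = "strict",
                          hyper = list(ridge = list(lambda = 0.05))))
  expect_equal(res$selection_mode, "strict")
  expect_lte(res$evaluations$ridge$r2, 1)
  expect_gte(res$evaluations$ridge$r2, 0.3)
})
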