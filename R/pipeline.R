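sn_config_defaults <- function() {
  list(
    # acquisition / preprocessing
    sfreq = 250, filter_lo = 1, filter_hi = 45.5, notch = 60,
    epoch_length = 4, overlap = 0.5, amp_thresh = 100, var_ratio_thresh = 5,
    # spectra / connectivity / networks
    seg_length_s = 2, density = 0.25, community_restarts = 10,
    network_mode = "weighted", source_alpha = NA,
    # modeling
    r_min = 0.3, top_k = 20,
    models = c("ridge", "lasso", "elasticnet", "svr", "adaboost"),
    selection_mode = "paper", run_sensitivity = FALSE, max_models = 9000,
    # simulation
    n_subjects = 10, asymmetry = 2.0, signal_fraction = 0.8, duration = 60,
    simulate_mode = "eeg",
    # bookkeeping
    seed = 1, input_dir = NA, out_dir = NA
  )
}

#' Pipeline run configuration
#'
#' All numeric defaults mirror the published acquisition and modeling
#' settings: 250 Hz sampling, 1-45.5 Hz band-pass, the 8-band scheme, 25%
#' network density, correlation threshold 0.3 and top-20 feature selection.
#' Unknown keys are rejected.
#'
#' @param ... overrides of the default keys (see [print_config()]).
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- sn_config_defaults()
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  sn_assert(length(unknown) == 0,
            sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            "invalid_parameter")
  cfg[names(over)] <- over
  sn_assert(cfg$density > 0 && cfg$density <= 1, "density must be in (0, 1]",
            "invalid_parameter")
  sn_assert(cfg$r_min >= 0 && cfg$r_min < 1, "r_min must be in [0, 1)",
            "invalid_parameter")
  sn_assert(cfg$filter_lo > 0 && cfg$filter_hi > cfg$filter_lo &&
              cfg$filter_hi < cfg$sfreq / 2,
            "need 0 < filter_lo < filter_hi < sfreq/2", "invalid_parameter")
  sn_assert(is_count(cfg$top_k) && cfg$top_k >= 1, "top_k must be >= 1",
            "invalid_parameter")
  sn_assert(is_count(cfg$n_subjects) && cfg$n_subjects >= 1,
            "n_subjects must be >= 1", "invalid_parameter")
  sn_assert(all(cfg$models %in% sn_model_names),
            sprintf("models must be a subset of {%s}",
                    paste(sn_model_names, collapse = ", ")), "invalid_parameter")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file of key/value overrides.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Print the default configuration as JSON
#' @param cfg a `run_config` (default: all defaults).
#' @return the JSON string, invisibly; prints it.
#' @export
print_config <- function(cfg = run_config()) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null")
  cat(js, "\n")
  invisible(js)
}

#' Simulate a synthetic cohort to disk
#'
#' EEG mode writes one EDF file per subject plus `clinical.csv` and a
#' ground-truth sidecar `truth.json`; feature mode writes a single
#' `features.csv` with `subject_id, lesion_side, moca_std` and the feature
#' columns.
#'
#' @param config a [run_config()]; uses `n_subjects`, `seed`, `asymmetry`,
#'   `signal_fraction`, `duration`, `simulate_mode` and `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the `synthetic_cohort`, invisibly.
#' @export
simulate_cohort <- function(config = run_config(), out_dir = NULL) {
  out_dir <- out_dir %||% config$out_dir
  profile <- cohort_profile(asymmetry = config$asymmetry,
                            signal_fraction = config$signal_fraction,
                            duration = config$duration, sfreq = config$sfreq)
  cohort <- gen_cohort(config$n_subjects, profile, seed = config$seed,
                       mode = config$simulate_mode)
  if (!is.null(out_dir) && !is.na(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
                     row.names = FALSE)
    if (cohort$mode == "eeg") {
      for (i in seq_along(cohort$recordings))
        write_edf(cohort$recordings[[i]],
                  file.path(out_dir, sprintf("%s.edf", cohort$clinical$subject_id[i])))
      utils::write.table(cohort$leadfield$gain,
                         file.path(out_dir, "leadfield.tsv"),
                         row.names = FALSE, col.names = FALSE, sep = "\t")
      utils::write.table(cbind(seq_along(cohort$leadfield$source_roi_map),
                               cohort$leadfield$source_roi_map),
                         file.path(out_dir, "source_roi_map.tsv"),
                         row.names = FALSE, col.names = FALSE, sep = "\t")
    } else {
      utils::write.csv(as.data.frame(cohort$features),
                       file.path(out_dir, "features.csv"), row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = config$seed, mode = cohort$mode,
           truth = lapply(cohort$truth, function(x)
             if (is.matrix(x)) as.data.frame(x) else x)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(cohort)
}

#' Compute one subject's full feature row
#'
#' The sensor-to-feature chain for a single recording: band-pass + notch,
#' common average reference, epoching with artifact rejection, Welch spectral
#' features, sLORETA source estimation onto ROIs, per-band imaginary-coherence
#' networks at the configured density, and the assembled network attributes.
#'
#' @param rec an [eeg_recording()].
#' @param inv_op an [sloreta_operator()] carrying a source->ROI map.
#' @param config a [run_config()].
#' @param seed RNG seed (community detection restarts).
#' @return list with `spectral` and `network` named feature vectors and
#'   `n_epochs`.
#' @export
subject_features <- function(rec, inv_op, config = run_config(), seed = 1) {
  rec <- bandpass_notch(rec, config$filter_lo, config$filter_hi, config$notch)
  rec <- common_average_reference(rec)
  ep <- epoch_and_reject(rec, config$epoch_length, config$overlap,
                         config$amp_thresh, config$var_ratio_thresh)
  seg <- round(config$seg_length_s * rec$sfreq)
  psd <- welch_psd(ep, seg_length = seg)
  bp <- band_powers(psd)
  spectral <- spectral_feature_row(bp)
  src <- apply_inverse(ep, inv_op)
  roi <- roi_timecourses(src, sfreq = ep$sfreq)
  cs <- cross_spectral_density(roi, seg_length = seg)
  scheme <- band_scheme()
  seeds <- derive_seeds(seed, nrow(scheme))
  nets <- lapply(seq_len(nrow(scheme)), function(i) {
    cm <- icoh_matrix(cs, scheme$name[i], scheme)
    tn <- proportional_threshold(cm, config$density)
    network_metrics(tn, mode = config$network_mode,
                    community_restarts = config$community_restarts,
                    seed = seeds[i])
  })
  names(nets) <- scheme$name
  list(spectral = spectral, network = assemble_network_features(nets, scheme),
       n_epochs = length(ep$epochs))
}

read_cohort_dir <- function(input_dir) {
  clinical <- utils::read.csv(file.path(input_dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  recs <- lapply(clinical$subject_id, function(id)
    read_edf(file.path(input_dir, sprintf("%s.edf", id))))
  lf <- read_leadfield(file.path(input_dir, "leadfield.tsv"),
                       file.path(input_dir, "source_roi_map.tsv"), sep = "\t")
  list(clinical = clinical, recordings = recs, leadfield = lf, mode = "eeg")
}

#' Run the full pipeline
#'
#' Executes the stages in order: preprocess, spectral features, source
#' estimation, connectivity, network attributes, laterality classification,
#' bilateral assignment, group-specific selection + LOO regression and the
#' optional composite sensitivity search. Writes feature tables, model
#' reports and a provenance manifest when `out_dir` is set.
#'
#' @param config a [run_config()].
#' @param cohort an in-memory `synthetic_cohort` (default: simulated from the
#'   config, or read from `config$input_dir` when set).
#' @param out_dir report directory (overrides `config$out_dir`; optional).
#' @return a `pipeline_result` list: `features` (feature_table), `laterality`,
#'   `groups`, per-group `models`, `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$input_dir) && !is.na(config$input_dir))
      read_cohort_dir(config$input_dir)
    else simulate_cohort(config)
  }

  if (!is.null(cohort$features)) {
    features <- cohort$features
  } else {
    lf <- cohort$leadfield
    if (is.null(lf$source_roi_map)) lf$source_roi_map <- seq_len(ncol(lf$gain))
    alpha <- if (is.na(config$source_alpha)) NULL else config$source_alpha
    inv_op <- sloreta_operator(lf, alpha = alpha)
    seeds <- derive_seeds(config$seed, length(cohort$recordings))
    rows <- vector("list", length(cohort$recordings))
    for (i in seq_along(cohort$recordings)) {
      f <- tryCatch(
        subject_features(cohort$recordings[[i]], inv_op, config, seed = seeds[i]),
        error = function(e) sn_stop(
          sprintf("stage features failed for subject %s: %s",
                  cohort$clinical$subject_id[i], conditionMessage(e)),
          "stage_error"))
      rows[[i]] <- c(f$spectral, f$network)
    }
    feat_mat <- do.call(rbind, rows)
    features <- as_feature_table(cbind(cohort$clinical,
                                       as.data.frame(feat_mat)))
  }

  # stage: laterality (spectral + ratio + network features)
  lat <- NULL
  groups <- features$lesion_side
  if (any(features$lesion_side %in% c("left", "right"))) {
    lat <- tryCatch(
      classify_laterality(features, seed = config$seed),
      error = function(e) NULL)
    if (!is.null(lat)) groups <- assign_bilateral(lat, features)
  }
  groups[!(groups %in% c("left", "right"))] <- "left"

  # stage: group-specific selection + regression on network features only
  net_cols <- grep("_(global_efficiency|char_path_length|clustering|modularity|clustering_ROI[0-9]+|efficiency_ROI[0-9]+)$",
                   names(features), value = TRUE)
  models_by_group <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 5) next
    gtab <- as_feature_table(
      as.data.frame(features)[idx, c("subject_id", "lesion_side", "moca_std",
                                     net_cols), drop = FALSE])
    res <- tryCatch(
      predict_outcome_group(gtab, r_min = config$r_min, top_k = config$top_k,
                            models = config$models, seed = config$seed,
                            selection_mode = config$selection_mode),
      error = function(e) list(error = conditionMessage(e)))
    if (config$run_sensitivity && !is.null(res$ranking) &&
        nrow(res$ranking$ranking) >= 20) {
      res$sensitivity <- composite_search(res$ranking, gtab,
                                          max_models = min(config$max_models, 200),
                                          model = "ridge", seed = config$seed)
    }
    models_by_group[[g]] <- res
  }

  result <- structure(list(features = features, laterality = lat,
                           groups = groups, models = models_by_group,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir) && !is.na(out_dir)) write_report(result, out_dir)
  result
}

#' Write pipeline reports and the provenance manifest
#'
#' @param result a `pipeline_result`.
#' @param out_dir directory to create/write into.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result$features),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  if (!is.null(result$laterality)) {
    jsonlite::write_json(list(
      accuracy = result$laterality$accuracy,
      sensitivity = result$laterality$sensitivity,
      specificity = result$laterality$specificity,
      confusion = as.data.frame(result$laterality$confusion),
      groups = data.frame(subject_id = result$features$subject_id,
                          group = result$groups)),
      file.path(out_dir, "laterality.json"), auto_unbox = TRUE, digits = NA)
  }
  for (g in names(result$models)) {
    res <- result$models[[g]]
    if (!is.null(res$evaluations)) {
      report <- lapply(res$evaluations, function(ev)
        list(model = ev$model, r2 = ev$r2, ss_res = ev$ss_res,
             ss_tot = ev$ss_tot, n = ev$n))
      jsonlite::write_json(report,
                           file.path(out_dir, sprintf("models_%s.json", g)),
                           auto_unbox = TRUE, digits = NA)
      preds <- do.call(rbind, lapply(res$evaluations, function(ev)
        data.frame(model = ev$model, y = ev$y, yhat = ev$yhat)))
      utils::write.csv(preds,
                       file.path(out_dir, sprintf("loo_predictions_%s.csv", g)),
                       row.names = FALSE)
    }
    if (!is.null(res$summary)) {
      utils::write.csv(rbind(cbind(panel = "band", res$summary$band),
                             cbind(panel = "lobe",
                                   stats::setNames(res$summary$lobe,
                                                   names(res$summary$band)))),
                       file.path(out_dir, sprintf("selection_summary_%s.csv", g)),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    package = "strokenet",
    version = as.character(utils::packageVersion("strokenet")),
    r_version = as.character(getRversion()),
    seed = result$config$seed,
    config = unclass(result$config),
    config_hash = sum(utf8ToInt(paste(
      names(result$config), vapply(result$config, function(x)
        paste(format(x), collapse = ","), character(1)),
      collapse = ";"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
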