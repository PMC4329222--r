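# End-to-end orchestration: ROI -> wavelet -> GLCM features -> attribute
# selection -> pair search -> SVM grid -> scan-level evaluation.
#
# The report has one row per (family, level, angle) configuration, carrying
# the winning sub-band and feature pair with its test metrics -- the shape
# of a per-configuration nodule-classification results table.

#' Pipeline configuration
#'
#' Defaults reproduce the full study grid: db1/db2/db4 families, depths 1
#' and 2, GLCM angles 0/45/90/135 at distance 1 with 8 gray levels, C in
#' {1, 1e1, 1e2, 1e3, 1e4} and sigma in {4, 32}, 11 selected attributes.
#'
#' @param families Daubechies families to analyze.
#' @param levels Decomposition depths to analyze (subset of 1:2 tested).
#' @param angles GLCM angles (degrees).
#' @param n_gray GLCM gray levels.
#' @param distance GLCM displacement length (px).
#' @param n_attributes Attribute-selection target count.
#' @param svm An [svm_config] for final model training.
#' @param pair_cost,pair_sigma,pair_folds SVM hyperparameters and folds used
#'   while scoring candidate feature pairs.
#' @param roi_radius_range Hough radius search range (fractions of half the
#'   minimum dimension).
#' @param seed Master seed; every stochastic step derives its seed from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(families = c("db1", "db2", "db4"),
                            levels = c(1L, 2L), angles = c(0, 45, 90, 135),
                            n_gray = 8L, distance = 1L, n_attributes = 11L,
                            svm = svm_config(),
                            pair_cost = 100, pair_sigma = 4, pair_folds = 5L,
                            roi_radius_range = c(0.6, 1.0), seed = 1L) {
  bad <- setdiff(families, c("db1", "db2", "db4"))
  if (length(bad) > 0L) {
    stopf("unknown wavelet family: %s", paste(bad, collapse = ", "))
  }
  levels <- as.integer(levels)
  if (any(levels < 1L)) stopf("`levels` must be >= 1")
  bad_ang <- setdiff(angles, c(0, 45, 90, 135))
  if (length(bad_ang) > 0L) {
    stopf("unsupported GLCM angle(s): %s", paste(bad_ang, collapse = ", "))
  }
  stopifnot(inherits(svm, "svm_config"))
  structure(list(families = families, levels = levels, angles = angles,
                 n_gray = as.integer(n_gray), distance = as.integer(distance),
                 n_attributes = as.integer(n_attributes), svm = svm,
                 pair_cost = pair_cost, pair_sigma = pair_sigma,
                 pair_folds = as.integer(pair_folds),
                 roi_radius_range = roi_radius_range,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Accept a phantom_set or a bare list(slices, labels, scan_ids).
.as_slice_set <- function(data) {
  if (inherits(data, "phantom_set")) {
    return(list(slices = data$slices, labels = data$labels,
                scan_ids = data$scan_ids))
  }
  if (inherits(data, "ct_scan")) {
    if (is.null(data$labels)) stopf("scan '%s' has no labels", data$scan_id)
    return(list(slices = data$slices, labels = data$labels,
                scan_ids = rep(data$scan_id, length(data$slices))))
  }
  if (is.list(data) && !is.null(data$slices) && !is.null(data$labels)) {
    ids <- data$scan_ids %||% sprintf("s%03d", seq_along(data$slices))
    return(list(slices = data$slices, labels = as.integer(data$labels),
                scan_ids = ids))
  }
  stopf("expected a phantom_set, labelled ct_scan, or list(slices, labels)")
}

#' Extract the descriptor matrix of a labelled slice set
#'
#' Runs ROI detection + masking and the wavelet-GLCM descriptor on every
#' slice, for every configured depth, and stacks the descriptors into a
#' feature matrix.
#'
#' @param data A `phantom_set`, labelled [ct_scan], or
#'   `list(slices, labels, scan_ids)`.
#' @param config A [pipeline_config].
#' @return List with `features` (matrix, one row per slice), `labels`,
#'   `scan_ids`, `rois` (list of detected [circle_roi]).
#' @export
extract_features <- function(data, config = pipeline_config()) {
  ds <- .as_slice_set(data)
  rois <- vector("list", length(ds$slices))
  rows <- vector("list", length(ds$slices))
  for (i in seq_along(ds$slices)) {
    slice <- ds$slices[[i]]
    roi <- detect_body_circle(slice, radius_range = config$roi_radius_range)
    masked <- apply_roi(slice, roi)
    desc <- unlist(lapply(config$levels, function(k) {
      extract_descriptor(masked, families = config$families, levels = k,
                         angles = config$angles, n_gray = config$n_gray,
                         roi = roi, distance = config$distance)
    }))
    rois[[i]] <- roi
    rows[[i]] <- desc
  }
  features <- do.call(rbind, rows)
  rownames(features) <- ds$scan_ids
  list(features = features, labels = ds$labels, scan_ids = ds$scan_ids,
       rois = rois)
}

# Column names of one (family, level, band, angle) feature block.
.block_cols <- function(family, level, band, angle) {
  sprintf("%s.%d.%s.%s.%s", family, level, band, angle, glcm_feature_names())
}

#' Run the CADx pipeline end to end
#'
#' Trains on `train`, evaluates on `test`. For every (family, depth, angle)
#' configuration the attribute selection and exhaustive pair search are run
#' on each sub-band; the sub-band whose best pair cross-validates highest is
#' selected, a final SVM is grid-trained on that pair, test slices are
#' classified, and slice decisions are OR-aggregated per scan before the
#' contingency metrics and scan-level AUC (from the maximum slice score per
#' scan) are computed.
#'
#' @param train,test Labelled slice sets (see [extract_features()]).
#' @param config A [pipeline_config].
#' @return Object of class `cadx_report`: a data frame with one row per
#'   configuration (`family`, `level`, `angle`, `subband`, `feature_1`,
#'   `feature_2`, `pair_cv_accuracy`, `model_cv_accuracy`, `cost`, `sigma`,
#'   `specificity`, `sensitivity`, `preciseness`, `auc`), with the trained
#'   models and per-scan predictions in `attr(, "details")` and the config
#'   in `attr(, "config")`.
#' @export
run_pipeline <- function(train, test, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  tr <- extract_features(train, config)
  te <- extract_features(test, config)

  # scan-level truth: a scan is positive iff any of its slices is
  scan_ids <- unique(te$scan_ids)
  scan_truth <- vapply(scan_ids, function(s) {
    as.integer(any(te$labels[te$scan_ids == s] == 1L))
  }, integer(1))

  rows <- list()
  details <- list()
  row_i <- 0L
  for (fam in config$families) {
    for (k in config$levels) {
      for (ang in config$angles) {
        row_i <- row_i + 1L
        band_results <- list()
        for (band in subband_labels(k)) {
          cols <- .block_cols(fam, k, band, ang)
          fm <- feature_matrix(tr$features[, cols, drop = FALSE], tr$labels)
          sel <- select_attributes(fm, config$n_attributes)
          pr <- select_pair(fm, candidates = sel$selected,
                            folds = config$pair_folds,
                            seed = derive_seed(config$seed, row_i),
                            cost = config$pair_cost,
                            sigma = config$pair_sigma)
          band_results[[band]] <- list(band = band, selection = sel,
                                       pair = pr)
        }
        accs <- vapply(band_results, function(b) b$pair$accuracy, numeric(1))
        best_band <- band_results[[which.max(accs)]]
        pair_cols <- best_band$pair$pair

        svm_cfg <- config$svm
        svm_cfg$seed <- derive_seed(config$seed, 10000L + row_i)
        model <- svm_train(
          feature_matrix(tr$features[, pair_cols, drop = FALSE], tr$labels),
          svm_cfg)

        slice_scores <- .model_scores(model,
                                      te$features[, pair_cols, drop = FALSE])
        slice_pred <- as.integer(slice_scores > 0)
        scan_pred <- vapply(scan_ids, function(s) {
          as.integer(any(slice_pred[te$scan_ids == s] == 1L))
        }, integer(1))
        scan_score <- vapply(scan_ids, function(s) {
          max(slice_scores[te$scan_ids == s])
        }, numeric(1))
        tab <- contingency(scan_pred, scan_truth)
        met <- cadx_metrics(tab)
        auc <- if (length(unique(scan_truth)) == 2L) {
          roc_auc(scan_score, scan_truth)$auc
        } else NA_real_

        rows[[row_i]] <- data.frame(
          family = fam, level = k, angle = ang, subband = best_band$band,
          feature_1 = sub("^.*\\.", "", pair_cols[1]),
          feature_2 = sub("^.*\\.", "", pair_cols[2]),
          pair_cv_accuracy = best_band$pair$accuracy,
          model_cv_accuracy = model$cv_accuracy,
          cost = model$cost, sigma = model$sigma,
          specificity = met$specificity, sensitivity = met$sensitivity,
          preciseness = met$preciseness, auc = auc,
          stringsAsFactors = FALSE)
        details[[row_i]] <- list(
          family = fam, level = k, angle = ang,
          band_results = band_results, model = model,
          contingency = tab,
          scan = data.frame(scan_id = scan_ids, truth = scan_truth,
                            predicted = scan_pred, score = scan_score,
                            stringsAsFactors = FALSE))
      }
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "details") <- details
  attr(report, "config") <- config
  class(report) <- c("cadx_report", "data.frame")
  report
}

#' Pick the best configuration of a pipeline report
#'
#' Selected by the final model's training cross-validated accuracy (a
#' train-side criterion; test metrics are never used), ties going to the
#' earlier row.
#'
#' @param report A `cadx_report`.
#' @return The winning report row (single-row data frame); its index is in
#'   `attr(, "row")`.
#' @export
best_configuration <- function(report) {
  stopifnot(inherits(report, "cadx_report"))
  i <- which.max(report$model_cv_accuracy)
  out <- report[i, , drop = FALSE]
  attr(out, "row") <- i
  out
}

#' @export
print.cadx_report <- function(x, ...) {
  df <- as.data.frame(x)
  for (col in c("specificity", "sensitivity", "preciseness")) {
    df[[col]] <- sprintf("%.2f%%", df[[col]])
  }
  df$pair_cv_accuracy <- sprintf("%.3f", df$pair_cv_accuracy)
  df$model_cv_accuracy <- sprintf("%.3f", df$model_cv_accuracy)
  df$auc <- sprintf("%.3f", df$auc)
  cat("CADx nodule classification report (one row per configuration)\n")
  print(df, row.names = FALSE)
  invisible(x)
}
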