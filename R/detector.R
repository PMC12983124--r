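# Boosted-tree contamination classifier. Trained on the simulated
# (50% linear-dilution) training set; shallow trees with row/column
# subsampling guard against overfitting the simulation. Cross-validation is
# grouped by patient so a patient's overlapping trios never straddle a fold
# boundary.

xgb_defaults <- function() {
  list(max_depth = 3, eta = 0.1, nrounds = 300,
       subsample = 0.8, colsample_bytree = 0.8, nthread = 1)
}

fit_xgb <- function(X, y, objective, params, seed) {
  p <- modifyList(xgb_defaults(), params)
  nrounds <- p$nrounds
  p$nrounds <- NULL
  p$objective <- objective
  p$seed <- as.integer(seed)
  xgboost::xgb.train(params = p,
                     data = xgboost::xgb.DMatrix(X, label = y),
                     nrounds = nrounds, verbose = 0)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive scores above a random negative,
#' with tied scores receiving half credit — computed from midranks, which
#' is algebraically identical to brute-force pairwise concordance.
#'
#' @param prob Predicted scores.
#' @param labels 0/1 labels.
#' @return auROC in \[0, 1\]; `NA` with a warning when only one class is
#'   present.
#' @export
auroc <- function(prob, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warn("auROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(prob, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Stepwise integration of precision over recall, descending the score
#' ordering; tied scores enter as one block so the curve does not depend on
#' an arbitrary permutation within ties.
#'
#' @inheritParams auroc
#' @return auPR in \[0, 1\]; `NA` with a warning for single-class labels.
#' @export
aupr <- function(prob, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) {
    warn("auPR undefined: only one class present")
    return(NA_real_)
  }
  o <- order(prob, decreasing = TRUE)
  ys <- y[o]; ps <- prob[o]
  grp_end <- cumsum(rle(ps)$lengths)
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(1 - ys)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics at a threshold
#'
#' Scores at or above the threshold are called positive. auROC is computed
#' by pairwise concordance and auPR by stepwise precision-recall
#' integration; confusion counts and the derived rates are reported at the
#' supplied threshold.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold; `prob >= threshold` is positive.
#' @return A list of class `metrics_report`: `auroc`, `aupr`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`, `threshold`,
#'   `n`.
#' @export
evaluate_classifier <- function(prob, labels, threshold = 0.75) {
  if (length(prob) != length(labels)) stop_usage("prob and labels differ in length")
  y <- as.integer(labels)
  pred <- prob >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
  structure(list(
    auroc = auroc(prob, y), aupr = aupr(prob, y),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn) tn / (tn + fn) else NA_real_,
    threshold = threshold, n = length(y)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n=%d  auROC=%.3f  auPR=%.3f  @thr=%.3f\n",
              x$n, x$auroc, x$aupr, x$threshold))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sens=%.3f spec=%.3f ppv=%.3f npv=%.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Calibrate the decision threshold to a target PPV
#'
#' Scans a fixed grid of thresholds (step `step`, ascending) and returns
#' the smallest whose empirical PPV exceeds `target_ppv`; being the
#' smallest valid threshold, it maximizes sensitivity subject to the PPV
#' constraint even when the PPV is non-monotone across the grid.
#'
#' @inheritParams auroc
#' @param target_ppv Required PPV (exclusive bound), default 0.80.
#' @param step Grid step, default 0.005.
#' @return The threshold, with attributes `ppv` and `sensitivity`; errors
#'   with class `cbccontam_calibration_error` when no grid point attains
#'   the target (the message reports the best achievable PPV).
#' @export
calibrate_threshold <- function(prob, labels, target_ppv = 0.80, step = 0.005) {
  y <- as.integer(labels)
  if (sum(y == 1) == 0) {
    abort("threshold calibration needs at least one positive label",
          class = "cbccontam_calibration_error")
  }
  grid <- seq(step, 1, by = step)
  best_ppv <- -Inf
  for (thr in grid) {
    pred <- prob >= thr
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    if (tp + fp == 0) next
    ppv <- tp / (tp + fp)
    best_ppv <- max(best_ppv, ppv)
    if (ppv > target_ppv) {
      return(structure(thr, ppv = ppv,
                       sensitivity = tp / sum(y == 1)))
    }
  }
  abort(sprintf("target PPV %.3f unattainable; best achievable PPV: %.3f",
                target_ppv, if (is.finite(best_ppv)) best_ppv else NA_real_),
        class = "cbccontam_calibration_error")
}

patient_folds <- function(patient_id, nfolds, seed) {
  pats <- unique(patient_id)
  with_seed(seed, {
    shuffled <- sample(pats)
    fold_of <- setNames(rep(seq_len(nfolds), length.out = length(shuffled)),
                        shuffled)
    unname(fold_of[patient_id])
  })
}

#' Train the contamination detector
#'
#' Fits a gradient-boosted tree classifier to a simulated labeled trio
#' table. Cross-validation metrics are computed with patient-grouped folds
#' (all of a patient's trios share a fold, preventing leakage across
#' overlapping trios), with the PCA transform refit inside each training
#' fold. The returned bundle's transform and model are then fit on the
#' full training set.
#'
#' @param labeled Trio table from [simulate_training_set()] (columns
#'   `contaminated`, `rho` present).
#' @param mode Feature set: `"combined"` (default), `"raw"`, or `"pca"`.
#' @param k Principal components kept (ignored for `mode = "raw"`).
#' @param params Named list overriding the boosted-tree defaults
#'   (`max_depth` 3, `eta` 0.1, `nrounds` 300, `subsample` 0.8,
#'   `colsample_bytree` 0.8, single-threaded for determinism).
#' @param nfolds Cross-validation folds (default 5); `0` skips CV.
#' @param threshold Operating threshold stored in the bundle, default 0.75.
#' @param seed Integer seed controlling fold assignment and tree fitting.
#' @return A `detector_bundle`: fitted booster, PCA transform, feature
#'   schema, threshold, per-fold `cv_metrics` tibble, and training
#'   metadata.
#' @export
train_detector <- function(labeled, mode = c("combined", "raw", "pca"),
                           k = 5, params = list(), nfolds = 5,
                           threshold = 0.75, seed = 1L) {
  mode <- match.arg(mode)
  if (!all(c("contaminated", "rho") %in% names(labeled)))
    stop_usage("labeled trios must carry 'contaminated' and 'rho' columns")
  y <- as.integer(labeled$contaminated)
  if (length(unique(y)) < 2) stop_data("training data contain a single class")
  analytes <- attr(labeled, "analytes") %||% CBC_ANALYTES

  cv_metrics <- NULL
  if (nfolds > 0) {
    fold <- patient_folds(labeled$patient_id, nfolds, seed)
    rows <- lapply(seq_len(nfolds), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      pca_f <- if (mode == "raw") NULL else
        fit_pca(labeled[tr, ], k = k, label = y[tr], analytes = analytes)
      Xtr <- make_features(labeled[tr, ], mode, pca_f, analytes)
      Xte <- make_features(labeled[te, ], mode, pca_f, analytes)
      m <- fit_xgb(Xtr, y[tr], "binary:logistic", params, seed + f)
      p <- predict(m, Xte)
      rep <- evaluate_classifier(p, y[te], threshold)
      tibble(fold = f, auroc = rep$auroc, aupr = rep$aupr,
             sensitivity = rep$sensitivity, specificity = rep$specificity,
             ppv = rep$ppv, npv = rep$npv)
    })
    cv_metrics <- bind_rows(rows)
  }

  pca <- if (mode == "raw") NULL else
    fit_pca(labeled, k = k, label = y, analytes = analytes)
  X <- make_features(labeled, mode, pca, analytes)
  model <- fit_xgb(X, y, "binary:logistic", params, seed)
  structure(list(model = model, pca = pca, mode = mode, k = k,
                 analytes = analytes, feature_names = colnames(X),
                 threshold = threshold, params = modifyList(xgb_defaults(), params),
                 seed = as.integer(seed), n_train = nrow(labeled),
                 cv_metrics = cv_metrics, type = "detector"),
            class = "detector_bundle")
}

#' @export
print.detector_bundle <- function(x, ...) {
  cat(sprintf("<detector_bundle> %s features (%d cols), threshold %.3f, n_train %d\n",
              x$mode, length(x$feature_names), x$threshold, x$n_train))
  if (!is.null(x$cv_metrics))
    cat(sprintf("  CV (%d folds): mean auROC %.4f, mean auPR %.4f\n",
                nrow(x$cv_metrics), mean(x$cv_metrics$auroc),
                mean(x$cv_metrics$aupr)))
  invisible(x)
}

bundle_features <- function(bundle, trios) {
  X <- if (is.matrix(trios)) trios
       else make_features(trios, bundle$mode, bundle$pca, bundle$analytes)
  if (!identical(colnames(X), bundle$feature_names))
    stop_usage("feature schema does not match the trained bundle")
  X
}

#' Predict contamination probabilities
#'
#' @param bundle A [train_detector()] bundle.
#' @param trios Trio table (or a prebuilt feature matrix with matching
#'   schema).
#' @return Tibble `trio_id`, `probability`, `predicted_contaminated`
#'   (probability at or above the bundle threshold).
#' @export
predict_proba <- function(bundle, trios) {
  stopifnot(inherits(bundle, "detector_bundle"))
  X <- bundle_features(bundle, trios)
  p <- predict(bundle$model, X)
  tibble(trio_id = if (is.matrix(trios)) as.character(seq_len(nrow(X)))
                   else trios$trio_id,
         probability = as.numeric(p),
         predicted_contaminated = as.numeric(p) >= bundle$threshold)
}

#' Persist and restore model bundles
#'
#' A bundle directory holds the booster (`model.ubj`) and a JSON metadata
#' file carrying the PCA transform, feature schema, threshold, and training
#' parameters. Works for both detector and mixture-ratio bundles.
#'
#' @param bundle A `detector_bundle` or `ratio_model`.
#' @param dir Directory to create/read.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(bundle$model, file.path(dir, "model.ubj"))
  meta <- bundle[setdiff(names(bundle), "model")]
  if (!is.null(meta$pca)) {
    meta$pca <- lapply(unclass(meta$pca), function(v)
      if (is.matrix(v)) list(data = as.numeric(v), dim = dim(v),
                             dimnames = dimnames(v)) else v)
  }
  meta$class <- class(bundle)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cls <- meta$class
  meta$class <- NULL
  if (!is.null(meta$pca) && length(meta$pca)) {
    rot <- matrix(meta$pca$rotation$data, nrow = meta$pca$rotation$dim[1])
    dimnames(rot) <- meta$pca$rotation$dimnames
    pca <- list(center = unlist(meta$pca$center), scale = unlist(meta$pca$scale),
                rotation = rot, sdev = meta$pca$sdev, k = meta$pca$k,
                feature_names = meta$pca$feature_names,
                analytes = meta$pca$analytes)
    class(pca) <- "cbc_pca"
    meta$pca <- pca
  }
  if (!is.null(meta$cv_metrics)) meta$cv_metrics <- as_tibble(meta$cv_metrics)
  meta$model <- xgboost::xgb.load(file.path(dir, "model.ubj"))
  structure(meta, class = cls)
}
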