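# Contamination severity: a gradient-boosted regressor trained on simulated
# dilutions estimates the mixture ratio rho for panels the detector calls
# contaminated. Supervised regression is preferred over the closed-form
# inversion rho = 1 - current/baseline because the patient baseline is never
# observed noise-free.

#' Train the mixture-ratio regressor
#'
#' Regresses the known simulated mixture ratio on the same feature vector
#' the detector uses. By default only the simulated positives are used;
#' clean rows (rho = 0) can be included with `include_negatives`.
#'
#' @inheritParams train_detector
#' @param include_negatives Include clean rows with `rho = 0` in training.
#' @param pca Optional pre-fitted [fit_pca()] transform (e.g. the
#'   detector's); fitted on the full labeled table when `NULL`.
#' @return A `ratio_model` bundle (same persistence format as the
#'   detector's).
#' @export
train_ratio_regressor <- function(labeled, mode = c("combined", "raw", "pca"),
                                  k = 5, pca = NULL, include_negatives = FALSE,
                                  params = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (!all(c("contaminated", "rho") %in% names(labeled)))
    stop_usage("labeled trios must carry 'contaminated' and 'rho' columns")
  if (sum(labeled$contaminated == 1) == 0)
    stop_data("no positive (contaminated) rows to train on")
  analytes <- attr(labeled, "analytes") %||% CBC_ANALYTES
  if (mode != "raw" && is.null(pca))
    pca <- fit_pca(labeled, k = k, label = labeled$contaminated,
                   analytes = analytes)
  rows <- if (include_negatives) seq_len(nrow(labeled)) else
    which(labeled$contaminated == 1)
  X <- make_features(labeled[rows, ], mode, pca, analytes)
  defaults <- list(max_depth = 4, nrounds = 400)
  model <- fit_xgb(X, labeled$rho[rows], "reg:squarederror",
                   modifyList(defaults, params), seed)
  structure(list(model = model, pca = pca, mode = mode, k = k,
                 analytes = analytes, feature_names = colnames(X),
                 threshold = NA_real_,
                 params = modifyList(modifyList(xgb_defaults(), defaults), params),
                 seed = as.integer(seed), n_train = length(rows),
                 cv_metrics = NULL, type = "ratio"),
            class = c("ratio_model", "detector_bundle"))
}

#' Estimate mixture ratios for trios
#'
#' Typically applied to detector-positive panels; estimates are clipped to
#' \[0, 0.99\].
#'
#' @param model A [train_ratio_regressor()] bundle.
#' @param trios Trio table (or matching feature matrix).
#' @return Tibble `trio_id`, `rho_hat`.
#' @export
estimate_mixture_ratio <- function(model, trios) {
  stopifnot(inherits(model, "ratio_model"))
  X <- bundle_features(model, trios)
  p <- pmin(pmax(as.numeric(predict(model$model, X)), 0), 0.99)
  tibble(trio_id = if (is.matrix(trios)) as.character(seq_len(nrow(X)))
                   else trios$trio_id,
         rho_hat = p)
}

#' @export
print.ratio_model <- function(x, ...) {
  cat(sprintf("<ratio_model> %s features (%d cols), n_train %d\n",
              x$mode, length(x$feature_names), x$n_train))
  invisible(x)
}
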