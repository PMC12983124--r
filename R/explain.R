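# Shapley additive attributions for individual predictions. Computed on
# the margin (log-odds) scale with the exact tree-path algorithm, where
# additivity is exact for tree ensembles: the base value plus the sum of
# per-feature contributions reproduces the model's margin output.

#' Shapley attributions for trio predictions
#'
#' @param bundle A tree-ensemble bundle ([train_detector()] or
#'   [train_ratio_regressor()]).
#' @param trios Trio table (or matching feature matrix).
#' @return Object of class `shap_attribution`: `contributions` (matrix,
#'   one row per trio, one column per feature, margin scale), `base`
#'   (expected model output), `margin` (per-trio margin prediction), and
#'   `features` (the input feature matrix).
#' @export
attribute <- function(bundle, trios) {
  if (!inherits(bundle, "detector_bundle"))
    stop_usage("attribution requires a tree-ensemble bundle")
  X <- bundle_features(bundle, trios)
  contrib <- predict(bundle$model, X, predcontrib = TRUE)
  bias_col <- which(colnames(contrib) %in% c("BIAS", "(Intercept)"))
  if (length(bias_col) == 0) bias_col <- ncol(contrib)
  base <- contrib[1, bias_col]
  contributions <- contrib[, -bias_col, drop = FALSE]
  structure(list(contributions = contributions,
                 base = unname(base),
                 margin = unname(base + rowSums(contributions)),
                 features = X),
            class = "shap_attribution")
}

#' Global feature importance from attributions
#'
#' Aggregates per-prediction attributions into a global ranking: features
#' ordered by decreasing median absolute contribution, ties broken
#' alphabetically.
#'
#' @param attributions A [attribute()] result.
#' @return Tibble `feature`, `median_abs_contribution`, `rank`.
#' @export
global_importance <- function(attributions) {
  stopifnot(inherits(attributions, "shap_attribution"))
  med <- apply(abs(attributions$contributions), 2, median)
  ord <- order(-med, names(med), method = "radix")
  tibble(feature = names(med)[ord],
         median_abs_contribution = unname(med[ord]),
         rank = seq_along(med))
}

#' Importance bar plot
#'
#' @param attributions A [attribute()] result.
#' @param top_n Number of features to show.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_importance <- function(attributions, top_n = 15) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_usage("the ggplot2 package is required for plotting")
  imp <- head(global_importance(attributions), top_n)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$median_abs_contribution,
                                    y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "median |SHAP| (margin scale)", y = NULL) +
    ggplot2::theme_minimal()
}
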