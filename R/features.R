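# Candidate feature sets for the detector: raw per-analyte values and
# deltas, principal-component scores of those raw features, or both. The
# dilutional error process is linear and proportional across analytes, so
# the leading principal component of a 50%-contaminated training set
# captures the anomaly-with-resolution pattern; raw features are kept
# alongside it because residual biological and analytic variation remains
# informative.

#' Raw feature names for an analyte set
#'
#' Fixed, documented order: for each analyte, `current`, `delta_prior`,
#' `delta_post`. The CBC set yields nine features.
#'
#' @param analytes Analyte codes, default the CBC analytes.
#' @return Character vector of feature (column) names.
#' @export
feature_names <- function(analytes = CBC_ANALYTES) {
  unlist(lapply(tolower(analytes), function(a)
    paste0(a, c("_current", "_delta_prior", "_delta_post"))))
}

raw_feature_matrix <- function(trios, analytes) {
  cols <- feature_names(analytes)
  missing <- setdiff(cols, names(trios))
  if (length(missing))
    stop_usage(paste0("trios lack feature columns: ",
                      paste(missing, collapse = ", ")))
  as.matrix(trios[cols])
}

#' Fit the PCA transform on a (simulated) training feature table
#'
#' Standardizes each raw feature (centre/scale) and extracts the leading
#' `k` principal components. Loadings are sign-fixed deterministically:
#' each component is flipped so its largest-magnitude loading is positive,
#' and, when training labels are supplied, flipped again so its score
#' correlates non-negatively with the contamination label (which makes PC1
#' point "toward contamination" in downstream explanation plots).
#'
#' @param trios Training trio table — the *simulated* training set
#'   (contaminated and clean rows together), matching how the final model
#'   is fit.
#' @param k Number of components to keep (default 5; must not exceed the
#'   raw feature count).
#' @param label Optional 0/1 contamination labels for the sign convention.
#' @param analytes Analyte set.
#' @return Object of class `cbc_pca`: centring/scaling constants, the
#'   orthonormal loading matrix (features x k), and component standard
#'   deviations.
#' @export
fit_pca <- function(trios, k = 5, label = NULL, analytes = NULL) {
  analytes <- analytes %||% attr(trios, "analytes") %||% CBC_ANALYTES
  X <- raw_feature_matrix(trios, analytes)
  if (k > ncol(X)) stop_config("k must not exceed the number of raw features")
  if (k < 1) stop_config("k must be >= 1")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  if (!is.null(label)) {
    scores <- scale(X, pc$center, pc$scale) %*% rot
    for (j in seq_len(k)) {
      r <- suppressWarnings(cor(scores[, j], label))
      if (!is.na(r) && r < 0) rot[, j] <- -rot[, j]
    }
  }
  colnames(rot) <- paste0("PC", seq_len(k))
  structure(list(center = pc$center, scale = pc$scale, rotation = rot,
                 sdev = pc$sdev[seq_len(k)], k = k,
                 feature_names = colnames(X), analytes = analytes),
            class = "cbc_pca")
}

#' @export
predict.cbc_pca <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else raw_feature_matrix(newdata, object$analytes)
  if (!identical(colnames(X), object$feature_names))
    stop_usage("feature columns do not match the fitted PCA transform")
  scale(X, object$center, object$scale) %*% object$rotation
}

#' @export
print.cbc_pca <- function(x, ...) {
  cat("PCA transform:", length(x$feature_names), "features ->", x$k,
      "components\n")
  cat("explained variance:",
      paste0(round(100 * x$sdev^2 / length(x$feature_names), 1), "%",
             collapse = " "), "\n")
  invisible(x)
}

#' Build the model feature matrix for a trio table
#'
#' @param trios Trio table with complete deltas.
#' @param mode `"raw"` (per-analyte current values and deltas), `"pca"`
#'   (principal-component scores only), or `"combined"` (raw then scores).
#' @param pca A fitted [fit_pca()] transform; required unless
#'   `mode = "raw"`.
#' @param analytes Analyte set (defaults to the table's attribute).
#' @return Numeric matrix, one row per trio, columns in the fixed
#'   documented order.
#' @export
make_features <- function(trios, mode = c("combined", "raw", "pca"),
                          pca = NULL, analytes = NULL) {
  mode <- match.arg(mode)
  analytes <- analytes %||% attr(trios, "analytes") %||% CBC_ANALYTES
  raw <- raw_feature_matrix(trios, analytes)
  if (mode == "raw") return(raw)
  if (is.null(pca)) stop_usage("a fitted PCA transform is required for mode != 'raw'")
  scores <- predict(pca, raw)
  if (mode == "pca") scores else cbind(raw, scores)
}
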