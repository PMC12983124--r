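# Orthogonal evidence from paired chemistry panels: when a CBC is called
# contaminated, a BMP collected moments earlier on the same stick should
# show the same dilution, typically slightly more pronounced (the BMP tube
# is drawn first). Agreement between the two independent severity
# estimates supports the CBC predictions.

#' Pair predicted-contaminated CBCs with nearby BMPs
#'
#' Only CBC trios that are predicted contaminated *and* carry an estimated
#' mixture ratio above `min_rho` (default 0.10) are eligible. Each eligible
#' CBC keeps the nearest BMP trio collected within `window_min` minutes
#' (inclusive) of its current draw.
#'
#' @param cbc_preds Tibble with `trio_id`, `patient_id`, `t_current`,
#'   `predicted_contaminated`, `rho_hat` for CBC trios (join of the trio
#'   table, [predict_proba()] and [estimate_mixture_ratio()] output).
#' @param bmp_trios BMP trio table from [build_trios()] with the BMP
#'   analyte set.
#' @param window_min Pairing window in minutes, boundary inclusive.
#' @param min_rho Eligibility cutoff on the CBC mixture-ratio estimate
#'   (strict).
#' @return Tibble of `panel_pair`s: `trio_id`, `bmp_trio_id`, `offset_min`
#'   (positive when the BMP precedes the CBC), `cbc_rho_hat`.
#' @export
pair_cbc_bmp <- function(cbc_preds, bmp_trios, window_min = 5, min_rho = 0.10) {
  need <- c("trio_id", "patient_id", "t_current", "predicted_contaminated",
            "rho_hat")
  missing <- setdiff(need, names(cbc_preds))
  if (length(missing))
    stop_usage(paste0("cbc_preds lack columns: ", paste(missing, collapse = ", ")))
  elig <- cbc_preds %>%
    filter(.data$predicted_contaminated, .data$rho_hat > min_rho)
  if (nrow(elig) == 0 || nrow(bmp_trios) == 0)
    return(tibble(trio_id = character(), bmp_trio_id = character(),
                  offset_min = double(), cbc_rho_hat = double()))
  bmp <- bmp_trios %>%
    select(bmp_trio_id = "trio_id", "patient_id", bmp_t = "t_current")
  elig %>%
    left_join(bmp, by = "patient_id", relationship = "many-to-many") %>%
    mutate(offset_min = as.numeric(difftime(.data$t_current, .data$bmp_t,
                                            units = "mins"))) %>%
    filter(!is.na(.data$offset_min), abs(.data$offset_min) <= window_min) %>%
    group_by(.data$trio_id) %>%
    slice_min(abs(.data$offset_min), n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("trio_id", "bmp_trio_id", "offset_min", cbc_rho_hat = "rho_hat")
}

#' Cross-check CBC contamination against paired BMPs
#'
#' Estimates BMP mixture ratios for the paired panels with a BMP-feature
#' ratio model (the mixture-ratio machinery retrained on simulated BMP
#' dilutions with a configured fluid), reports the fraction of pairs with
#' BMP evidence of contamination (`rho_hat >= evidence_threshold`,
#' symmetric with the CBC filter), and, among co-contaminated pairs, the
#' ordinary-least-squares slope, intercept, and coefficient of
#' determination of the BMP estimate on the CBC estimate.
#'
#' @param pairs Output of [pair_cbc_bmp()]. When the table already carries
#'   a `bmp_rho_hat` column, `bmp_model`/`bmp_trios` may be `NULL` and the
#'   stored estimates are used as-is.
#' @param bmp_model A `ratio_model` trained on BMP features.
#' @param bmp_trios The BMP trio table the pairs refer to.
#' @param evidence_threshold BMP mixture-ratio cutoff for "evidence of
#'   contamination" (default 0.10, inclusive).
#' @return List of class `crosscheck_report`: `n_pairs`,
#'   `n_bmp_contaminated`, `frac_bmp_contaminated`, `slope`, `intercept`,
#'   `r2`, and the per-pair table with `bmp_rho_hat` appended. Errors when
#'   fewer than 3 co-contaminated pairs exist (the correlation is
#'   undefined).
#' @export
crosscheck <- function(pairs, bmp_model = NULL, bmp_trios = NULL,
                       evidence_threshold = 0.10) {
  if (nrow(pairs) == 0) stop_data("no CBC-BMP pairs to cross-check")
  if (!"bmp_rho_hat" %in% names(pairs)) {
    if (is.null(bmp_model) || is.null(bmp_trios))
      stop_usage("bmp_model and bmp_trios are required unless pairs carry bmp_rho_hat")
    bmp_sub <- bmp_trios[match(pairs$bmp_trio_id, bmp_trios$trio_id), ]
    est <- estimate_mixture_ratio(bmp_model, bmp_sub)
    pairs$bmp_rho_hat <- est$rho_hat
  }
  co <- pairs %>% filter(.data$bmp_rho_hat >= evidence_threshold)
  if (nrow(co) < 3)
    stop_data("fewer than 3 co-contaminated pairs: correlation undefined")
  fit <- lm(bmp_rho_hat ~ cbc_rho_hat, data = co)
  structure(list(
    n_pairs = nrow(pairs),
    n_bmp_contaminated = nrow(co),
    frac_bmp_contaminated = nrow(co) / nrow(pairs),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    pairs = pairs),
    class = "crosscheck_report")
}

#' @export
print.crosscheck_report <- function(x, ...) {
  cat(sprintf(
    "<crosscheck> %d pairs; %d (%.0f%%) with BMP evidence; slope %.2f, R^2 %.2f\n",
    x$n_pairs, x$n_bmp_contaminated, 100 * x$frac_bmp_contaminated,
    x$slope, x$r2))
  invisible(x)
}
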