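# End-to-end retrospective audit: train the detector and severity models
# on simulated contamination, apply them to a (synthetic or user) cohort,
# and report contamination prevalence, severity, transfusion impact, and
# the BMP cross-check — the shape of a full-year institutional run.

#' Configuration for the end-to-end audit
#'
#' @param train_patients,eval_patients Cohort sizes for the simulated
#'   training set and the audited (evaluation) cohort.
#' @param contamination_rate Fraction of complete CBC draws in the audited
#'   cohort that receive injected contamination (0 for a clean negative
#'   control).
#' @param train_fraction Fraction of training trios diluted (default 0.5).
#' @param dist Mixture-ratio distribution used for both training and
#'   injection.
#' @param fluid_name Fluid used for BMP dilutions (see
#'   [fluid_compositions()]).
#' @param mode,k,threshold,detector_params,ratio_params,nfolds Passed to
#'   [train_detector()] / [train_ratio_regressor()]; `nfolds = 0` skips CV
#'   during the audit (CV is a training-time diagnostic).
#' @param with_bmp Generate BMPs and run the cross-check.
#' @param p_joint Probability a paired BMP shares an injected
#'   contamination.
#' @param cohort_overrides Named list of [cohort_config()] overrides
#'   applied to both cohorts.
#' @param seed Master seed; all stage seeds derive from it and are recorded
#'   in the report.
#' @return List of class `audit_config`.
#' @export
audit_config <- function(train_patients = 1200, eval_patients = 1500,
                         contamination_rate = 0.02, train_fraction = 0.5,
                         dist = mixture_ratio_dist(),
                         fluid_name = "normal_saline",
                         mode = "combined", k = 5, threshold = 0.75,
                         detector_params = list(), ratio_params = list(),
                         nfolds = 0, with_bmp = TRUE, p_joint = 0.8,
                         cohort_overrides = list(), seed = 1L) {
  structure(as.list(environment()), class = "audit_config")
}

count_complete_cbc_draws <- function(results) {
  vals <- coerce_numeric(results$value_raw)
  results %>%
    mutate(.v = vals) %>%
    filter(.data$analyte %in% CBC_ANALYTES, !is.na(.data$.v)) %>%
    distinct(.data$patient_id, .data$drawn_at, .data$analyte) %>%
    count(.data$patient_id, .data$drawn_at) %>%
    filter(.data$n == length(CBC_ANALYTES)) %>%
    nrow()
}

#' Run the end-to-end contamination audit
#'
#' Generates a training cohort, trains the detector and mixture-ratio
#' models on simulated dilutions, generates an independent audited cohort
#' with contamination injected at the configured rate, and reports
#' prevalence, severity, transfusion flags, and (when enabled) the BMP
#' cross-check. Deterministic given the config seed.
#'
#' @param config An [audit_config()].
#' @return List of class `audit_result`: `report` (the summary described
#'   above, JSON-serialisable), `tables` (every intermediate table),
#'   `models` (the fitted bundles), and `log` (per-stage row counts).
#' @export
run_audit <- function(config = audit_config()) {
  stopifnot(inherits(config, "audit_config"))
  seed <- as.integer(config$seed)
  fluid <- fluid_compositions()[[config$fluid_name]]
  if (is.null(fluid)) stop_config(paste0("unknown fluid: ", config$fluid_name))
  log <- list()
  note <- function(stage, rows_in, rows_out)
    log[[length(log) + 1]] <<- tibble(stage = stage, rows_in = rows_in,
                                      rows_out = rows_out)

  # --- training side -------------------------------------------------
  cfg_tr <- do.call(cohort_config, modifyList(
    list(n_patients = config$train_patients, seed = seed),
    config$cohort_overrides))
  tr_cohort <- generate_cohort(cfg_tr)
  tr <- generate_transfusions(tr_cohort, cfg_tr)
  tr_trios <- build_trios(tr$cohort)
  note("train_trios", count_complete_cbc_draws(tr$cohort), nrow(tr_trios))
  labeled <- simulate_training_set(tr_trios, config$train_fraction,
                                   config$dist, seed = seed + 11L)
  detector <- train_detector(labeled, mode = config$mode, k = config$k,
                             params = config$detector_params,
                             nfolds = config$nfolds,
                             threshold = config$threshold, seed = seed)
  ratio_model <- train_ratio_regressor(labeled, mode = config$mode,
                                       k = config$k, pca = detector$pca,
                                       params = config$ratio_params,
                                       seed = seed)
  bmp_ratio_model <- NULL
  if (config$with_bmp) {
    tr_bmp <- generate_paired_bmps(tr$cohort, cfg_tr)
    tr_bmp_trios <- build_trios(tr_bmp, analytes = BMP_ANALYTES)
    bmp_labeled <- simulate_training_set(tr_bmp_trios, config$train_fraction,
                                         config$dist, fluid = fluid,
                                         seed = seed + 13L)
    bmp_ratio_model <- train_ratio_regressor(bmp_labeled, mode = config$mode,
                                             k = config$k, seed = seed)
  }

  # --- audited cohort ------------------------------------------------
  cfg_ev <- do.call(cohort_config, modifyList(
    list(n_patients = config$eval_patients, seed = seed + 101L),
    config$cohort_overrides))
  ev_cohort <- generate_cohort(cfg_ev)
  ev <- generate_transfusions(ev_cohort, cfg_ev)
  ev_bmp <- if (config$with_bmp) generate_paired_bmps(ev$cohort, cfg_ev) else NULL
  inj <- inject_contamination(ev$cohort, config$contamination_rate,
                              dist = config$dist, bmp = ev_bmp,
                              fluid = fluid, p_joint = config$p_joint,
                              seed = seed + 7L)
  n_cbcs <- count_complete_cbc_draws(inj$results)
  trios <- build_trios(inj$results)
  note("eval_trios", n_cbcs, nrow(trios))

  preds <- predict_proba(detector, trios)
  note("predictions", nrow(trios), nrow(preds))
  pos <- preds %>% filter(.data$predicted_contaminated)
  ratios <- if (nrow(pos)) {
    estimate_mixture_ratio(ratio_model,
                           trios[match(pos$trio_id, trios$trio_id), ])
  } else tibble(trio_id = character(), rho_hat = double())

  matches <- match_transfusions_to_trios(trios, ev$transfusions)
  assessments <- assess_transfusions(matches, trios, preds)
  tx_summary <- summarize_assessments(assessments)
  note("transfusions", nrow(ev$transfusions), sum(assessments$matched))

  xcheck <- NULL
  if (config$with_bmp && nrow(pos)) {
    bmp_trios <- build_trios(inj$bmp, analytes = BMP_ANALYTES)
    cbc_preds <- trios %>%
      select("trio_id", "patient_id", "t_current") %>%
      dplyr::inner_join(pos, by = "trio_id") %>%
      dplyr::inner_join(ratios, by = "trio_id")
    pairs <- pair_cbc_bmp(cbc_preds, bmp_trios)
    xcheck <- tryCatch(crosscheck(pairs, bmp_ratio_model, bmp_trios),
                       cbccontam_data_error = function(e) NULL)
  }

  severity <- if (nrow(ratios)) list(
    median_rho_hat = median(ratios$rho_hat),
    frac_above_0.10 = mean(ratios$rho_hat > 0.10),
    frac_above_0.20 = mean(ratios$rho_hat > 0.20),
    max_rho_hat = max(ratios$rho_hat)
  ) else list(median_rho_hat = NA_real_, frac_above_0.10 = NA_real_,
              frac_above_0.20 = NA_real_, max_rho_hat = NA_real_)

  report <- list(
    seed = seed,
    contamination_rate = config$contamination_rate,
    n_cbcs = n_cbcs,
    n_trios = nrow(trios),
    frac_cbcs_with_trio = nrow(trios) / max(n_cbcs, 1),
    n_predicted_contaminated = nrow(pos),
    frac_predicted_contaminated = nrow(pos) / max(nrow(trios), 1),
    severity = severity,
    n_transfusions = tx_summary$n_transfusions,
    n_matched = tx_summary$n_matched,
    frac_matched = tx_summary$n_matched / max(tx_summary$n_transfusions, 1),
    n_flagged_unnecessary = tx_summary$n_flagged,
    frac_flagged_of_matched = tx_summary$flagged_fraction,
    crosscheck = if (!is.null(xcheck)) xcheck[c(
      "n_pairs", "n_bmp_contaminated", "frac_bmp_contaminated",
      "slope", "intercept", "r2")] else NULL)

  structure(list(report = report,
                 tables = list(trios = trios, predictions = preds,
                               ratios = ratios, assessments = assessments,
                               truth = inj$truth),
                 models = list(detector = detector, ratio = ratio_model,
                               bmp_ratio = bmp_ratio_model),
                 log = bind_rows(log)),
            class = "audit_result")
}

#' @export
print.audit_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<audit> %d CBCs, %d trios (%.0f%%)\n", r$n_cbcs, r$n_trios,
              100 * r$frac_cbcs_with_trio))
  cat(sprintf("  predicted contaminated: %d (%.2f%% of trios)\n",
              r$n_predicted_contaminated,
              100 * r$frac_predicted_contaminated))
  if (!is.na(r$severity$median_rho_hat))
    cat(sprintf("  severity: median rho_hat %.2f, %.0f%% > 0.10, %.0f%% > 0.20\n",
                r$severity$median_rho_hat, 100 * r$severity$frac_above_0.10,
                100 * r$severity$frac_above_0.20))
  cat(sprintf("  transfusions: %d, matched %d (%.0f%%), flagged %d (%.1f%% of matched)\n",
              r$n_transfusions, r$n_matched, 100 * r$frac_matched,
              r$n_flagged_unnecessary, 100 * (r$frac_flagged_of_matched %||% NA)))
  if (!is.null(r$crosscheck))
    cat(sprintf("  BMP cross-check: %d pairs, %.0f%% co-contaminated, slope %.2f, R^2 %.2f\n",
                r$crosscheck$n_pairs, 100 * r$crosscheck$frac_bmp_contaminated,
                r$crosscheck$slope, r$crosscheck$r2))
  invisible(x)
}

#' Write an audit report as JSON
#'
#' @param audit An [run_audit()] result.
#' @param path Output JSON path.
#' @export
write_audit_report <- function(audit, path) {
  jsonlite::write_json(audit$report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", POSIXt = "ISO8601")
  invisible(path)
}
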