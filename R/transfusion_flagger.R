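# Retrospective transfusion audit: match RBC transfusions to CBC trios and
# apply the three-criterion rule for a "potentially unnecessary"
# transfusion — (1) the current CBC was predicted contaminated, (2) the
# post-transfusion Hgb exceeded 8 g/dL (above the empiric-transfusion
# cutoff), and (3) the post Hgb exceeded both the prior and the current Hgb
# (excluding true ongoing blood loss). All three must hold.

#' Match transfusions to CBC trios
#'
#' A transfusion matches a trio when the patient matches and the
#' administration time falls strictly between the current and post draws.
#' When several overlapping trios qualify, the one whose current draw is
#' latest before the administration is kept — the most proximal
#' decision-relevant CBC. Unmatched transfusions are retained with a
#' missing `trio_id` so the matched fraction can be reported.
#'
#' @param trios Trio table from [build_trios()].
#' @param transfusions Tibble `patient_id`, `administered_at`, `units`
#'   (a `tx_id` is added when absent).
#' @return Tibble: one row per transfusion with `trio_id` (`NA` when
#'   unmatched) and `matched`.
#' @export
match_transfusions_to_trios <- function(trios, transfusions) {
  tx <- as_tibble(transfusions)
  if (!"tx_id" %in% names(tx)) tx$tx_id <- sprintf("TX%05d", seq_len(nrow(tx)))
  if (!"units" %in% names(tx)) tx$units <- 1L
  if (any(tx$units < 1)) stop_data("transfusion units must be >= 1")
  if (nrow(tx) == 0 || nrow(trios) == 0) {
    tx$trio_id <- rep(NA_character_, nrow(tx))
    tx$matched <- rep(FALSE, nrow(tx))
    return(tx)
  }
  cand <- tx %>%
    left_join(trios %>% select("trio_id", "patient_id", "t_current", "t_post"),
              by = "patient_id", relationship = "many-to-many") %>%
    filter(.data$administered_at > .data$t_current,
           .data$administered_at < .data$t_post) %>%
    group_by(.data$tx_id) %>%
    slice_max(.data$t_current, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("tx_id", "trio_id")
  out <- tx %>% left_join(cand, by = "tx_id")
  out$matched <- !is.na(out$trio_id)
  out
}

#' Apply the three-criterion transfusion rule
#'
#' @param matches Output of [match_transfusions_to_trios()].
#' @param trios The trio table (for the hemoglobin values).
#' @param predictions Detector output ([predict_proba()]), carrying
#'   `predicted_contaminated` per `trio_id`.
#' @return Tibble, one row per transfusion: the three criterion booleans
#'   and `flagged_unnecessary` (their conjunction); unmatched transfusions
#'   carry `NA` criteria and are excluded from flagged fractions.
#' @export
assess_transfusions <- function(matches, trios, predictions) {
  need <- c("hgb_prior", "hgb_current", "hgb_post")
  if (!all(need %in% names(trios)))
    stop_data("trios lack hemoglobin columns required for assessment")
  hb <- trios %>% select("trio_id", dplyr::all_of(need))
  pred <- predictions %>% select("trio_id", "predicted_contaminated")
  out <- matches %>%
    left_join(hb, by = "trio_id") %>%
    left_join(pred, by = "trio_id")
  if (any(out$matched & (is.na(out$hgb_prior) | is.na(out$hgb_current) |
                         is.na(out$hgb_post))))
    stop_data("matched trio is missing a hemoglobin value")
  out %>%
    mutate(
      criterion_contaminated = ifelse(.data$matched,
                                      .data$predicted_contaminated, NA),
      criterion_post_gt8 = ifelse(.data$matched, .data$hgb_post > 8.0, NA),
      criterion_post_above_both = ifelse(
        .data$matched,
        .data$hgb_post > .data$hgb_prior & .data$hgb_post > .data$hgb_current,
        NA),
      flagged_unnecessary = .data$criterion_contaminated &
        .data$criterion_post_gt8 & .data$criterion_post_above_both) %>%
    select("tx_id", "patient_id", "administered_at", "units", "trio_id",
           "matched", "criterion_contaminated", "criterion_post_gt8",
           "criterion_post_above_both", "flagged_unnecessary")
}

haldane_or <- function(a, b, c, d, conf = 0.95) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  c(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

#' Summarise transfusion assessments
#'
#' Reports matched/flagged counts and fractions, plus, for each supplied
#' context column (care setting, stated indication, ...), the odds ratio of
#' being flagged for every level against a reference level (the most
#' frequent level unless named in `reference`), with a Haldane-Anscombe 0.5
#' correction when a 2x2 cell is zero and 95% CIs from the log-odds normal
#' approximation.
#'
#' @param assessments Output of [assess_transfusions()], optionally with
#'   extra context columns.
#' @param context Character vector of context column names.
#' @param reference Optional named character vector mapping context column
#'   to its reference level.
#' @return List: `n_transfusions`, `n_matched`, `n_flagged`,
#'   `flagged_fraction` (of matched), and `odds_ratios` tibble (or `NULL`).
#' @export
summarize_assessments <- function(assessments, context = NULL, reference = NULL) {
  m <- assessments %>% filter(.data$matched)
  out <- list(
    n_transfusions = nrow(assessments),
    n_matched = nrow(m),
    n_flagged = sum(m$flagged_unnecessary, na.rm = TRUE),
    flagged_fraction = if (nrow(m)) mean(m$flagged_unnecessary, na.rm = TRUE)
                       else NA_real_,
    odds_ratios = NULL)
  if (!is.null(context) && nrow(m)) {
    rows <- list()
    for (col in context) {
      lv <- table(m[[col]])
      ref <- reference[[col]] %||% names(lv)[which.max(lv)]
      flagged <- m$flagged_unnecessary %in% TRUE
      a_ref <- sum(flagged & m[[col]] == ref)
      b_ref <- sum(!flagged & m[[col]] == ref)
      for (level in setdiff(names(lv), ref)) {
        a <- sum(flagged & m[[col]] == level)
        b <- sum(!flagged & m[[col]] == level)
        or <- haldane_or(a, b, a_ref, b_ref)
        rows[[length(rows) + 1]] <- tibble(
          context = col, level = level, reference = ref,
          n = a + b, n_flagged = a,
          odds_ratio = or[["or"]], ci_lo = or[["lo"]], ci_hi = or[["hi"]])
      }
    }
    out$odds_ratios <- bind_rows(rows)
  }
  out
}
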