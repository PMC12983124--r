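tx_at <- function(patient, t, units = 1L) {
  tibble::tibble(patient_id = patient,
                 administered_at = as.POSIXct(t, tz = "UTC"),
                 units = units)
}

test_that("transfusions match trios strictly between current and post draws", {
  trios <- make_trios(hgb = cbind(9, 6.8, 8.5), plt = cbind(200, 150, 190),
                      wbc = cbind(7, 5, 6.5), patient_id = "A")
  # t_current = 20:00, t_post = 08:00 next day (12-h spacing)
  inside <- tx_at("A", trios$t_current + 3600)
  before <- tx_at("A", trios$t_current - 3600)
  at_post <- tx_at("A", trios$t_post)
  other <- tx_at("B", trios$t_current + 3600)
  m <- match_transfusions_to_trios(trios,
                                   dplyr::bind_rows(inside, before, at_post,
                                                    other))
  expect_equal(m$matched, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(m$trio_id[1], trios$trio_id[1])
})

test_that("overlapping trios resolve to the most proximal current draw and the fixture matches brute force", {
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  trios <- dplyr::bind_rows(
    make_trios(hgb = cbind(10, 9, 9.5), plt = cbind(200, 190, 195),
               wbc = cbind(7, 6, 6.5), patient_id = "A"),
    make_trios(hgb = cbind(9, 8, 9), plt = cbind(190, 180, 185),
               wbc = cbind(6, 5, 5.5), patient_id = "A"),
    make_trios(hgb = cbind(8, 7, 8.5), plt = cbind(180, 170, 175),
               wbc = cbind(5, 4, 4.5), patient_id = "B"))
  trios$trio_id <- paste0("T", 1:3)
  # overlap: stretch trio 1's post window over trio 2's current
  trios$t_prior <- t0 + c(0, 6, 0) * 3600
  trios$t_current <- t0 + c(12, 18, 12) * 3600
  trios$t_post <- t0 + c(30, 36, 30) * 3600
  txs <- dplyr::bind_rows(
    tx_at("A", t0 + 13 * 3600),   # inside trio 1 only
    tx_at("A", t0 + 20 * 3600),   # inside both -> trio 2 (latest current)
    tx_at("A", t0 + 40 * 3600),   # after both
    tx_at("B", t0 + 15 * 3600),   # inside trio 3
    tx_at("C", t0 + 15 * 3600))   # unknown patient
  m <- match_transfusions_to_trios(trios, txs)
  expect_equal(m$trio_id, c("T1", "T2", NA, "T3", NA))

  # brute-force oracle over every (transfusion, trio) combination
  for (i in seq_len(nrow(txs))) {
    ok <- which(trios$patient_id == txs$patient_id[i] &
                  trios$t_current < txs$administered_at[i] &
                  trios$t_post > txs$administered_at[i])
    want <- if (length(ok)) trios$trio_id[ok[which.max(
      as.numeric(trios$t_current[ok]))]] else NA_character_
    expect_equal(m$trio_id[i], want)
  }
})

test_that("the three-criterion rule matches its literal conjunction on an exhaustive grid", {
  hgbs <- c(6.5, 7.9, 8.0, 8.1, 9.0)
  grid <- expand.grid(pred = c(TRUE, FALSE), prior = hgbs, current = hgbs,
                      post = hgbs)
  n <- nrow(grid)
  trios <- make_trios(hgb = cbind(grid$prior, grid$current, grid$post),
                      plt = matrix(200, n, 3), wbc = matrix(7, n, 3))
  txs <- tibble::tibble(patient_id = trios$patient_id,
                        administered_at = trios$t_current + 3600,
                        units = 1L)
  preds <- tibble::tibble(trio_id = trios$trio_id,
                          probability = ifelse(grid$pred, 0.9, 0.1),
                          predicted_contaminated = grid$pred)
  m <- match_transfusions_to_trios(trios, txs)
  a <- assess_transfusions(m, trios, preds)
  want <- grid$pred & grid$post > 8.0 &
    (grid$post > grid$prior & grid$post > grid$current)
  expect_equal(a$flagged_unnecessary, want)
  # boundary: post exactly 8.0 is never flagged
  expect_false(any(a$flagged_unnecessary[grid$post == 8.0]))
  # spot checks from the rule set
  pick <- function(pred, pr, cu, po)
    a$flagged_unnecessary[grid$pred == pred & grid$prior == pr &
                            grid$current == cu & grid$post == po]
  expect_true(pick(TRUE, 7.9, 6.5, 9.0))    # all criteria met
  expect_false(pick(TRUE, 7.9, 6.5, 7.9))   # post not > 8
  expect_false(pick(TRUE, 9.0, 6.5, 8.1))   # post not above prior
  expect_false(pick(FALSE, 7.9, 6.5, 9.0))  # not predicted contaminated
})

test_that("summaries report flagged fractions and Haldane-corrected odds ratios", {
  # 2x2 a=10 flagged / b=90 in ward; c=5 / d=95 in ICU (reference)
  assessments <- tibble::tibble(
    tx_id = sprintf("TX%03d", 1:200),
    patient_id = "X", administered_at = Sys.time(), units = 1L,
    trio_id = "T", matched = TRUE,
    criterion_contaminated = TRUE, criterion_post_gt8 = TRUE,
    criterion_post_above_both = TRUE,
    flagged_unnecessary = c(rep(TRUE, 10), rep(FALSE, 90),
                            rep(TRUE, 5), rep(FALSE, 95)),
    setting = c(rep("ward", 100), rep("icu", 100)))
  s <- summarize_assessments(assessments, context = "setting",
                             reference = c(setting = "icu"))
  expect_equal(s$n_matched, 200)
  expect_equal(s$n_flagged, 15)
  expect_equal(s$flagged_fraction, 15 / 200)
  or <- s$odds_ratios
  expect_equal(or$level, "ward")
  expect_equal(round(or$odds_ratio, 2), 2.11)
  expect_true(or$ci_lo < or$odds_ratio & or$odds_ratio < or$ci_hi)

  # identical rates across levels: OR = 1
  assessments$flagged_unnecessary <- rep(c(TRUE, FALSE), 100)
  s2 <- summarize_assessments(assessments, context = "setting",
                              reference = c(setting = "icu"))
  expect_equal(s2$odds_ratios$odds_ratio, 1)

  # zero cell stays finite via the 0.5 correction
  assessments$flagged_unnecessary <- c(rep(TRUE, 10), rep(FALSE, 190))
  s3 <- summarize_assessments(assessments, context = "setting",
                              reference = c(setting = "icu"))
  expect_true(is.finite(s3$odds_ratios$odds_ratio))
  expect_gt(s3$odds_ratios$odds_ratio, 1)
})

test_that("flagging rises with the injected contamination rate", {
  b <- small_detector()
  set.seed(42)
  fractions <- sapply(c(0, 0.25, 0.7), function(rate) {
    trios <- small_clean_trios()
    lab <- simulate_training_set(trios, rate, seed = 31)
    # transfuse after every low current Hgb
    low <- lab[lab$hgb_current < 8, ]
    if (nrow(low) == 0) return(0)
    txs <- tibble::tibble(patient_id = low$patient_id,
                          administered_at = low$t_current + 3600, units = 1L)
    # the transfusion lifts the post Hgb it causes
    lift <- lab
    lift$hgb_post[match(low$trio_id, lift$trio_id)] <-
      lift$hgb_post[match(low$trio_id, lift$trio_id)] + 1.2
    preds <- predict_proba(b, lift)
    m <- match_transfusions_to_trios(lift, txs)
    a <- assess_transfusions(m, lift, preds)
    summarize_assessments(a)$flagged_fraction
  })
  expect_true(all(diff(fractions) > 0))
})
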