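test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- cohort_config(n_patients = 40, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ta <- generate_transfusions(a, cfg)
  tb <- generate_transfusions(b, cfg)
  expect_identical(ta, tb)
  expect_identical(generate_paired_bmps(ta$cohort, cfg),
                   generate_paired_bmps(tb$cohort, cfg))
})

test_that("degenerate noise collapses serial Hgb onto the patient baseline", {
  cfg <- cohort_config(n_patients = 25, ar1 = 0,
                       hgb_within_sd = 1e-9, plt_within_sd = 1e-9,
                       wbc_within_sd = 1e-9,
                       cv = c(HGB = 1e-9, PLT = 1e-9, WBC = 1e-9,
                              "NA" = 1e-9, K = 1e-9, CL = 1e-9, CO2 = 1e-9,
                              BUN = 1e-9, CREAT = 1e-9, GLU = 1e-9,
                              CA = 1e-9),
                       censor_frac = 0, nonnumeric_frac = 0, bleed_prob = 0,
                       seed = 3)
  co <- generate_cohort(cfg)
  base <- attr(co, "patients")
  hgb <- co[co$analyte == "HGB", ]
  expect_equal(hgb$.value,
               base$hgb_baseline[match(hgb$patient_id, base$patient_id)],
               tolerance = 1e-6)
})

test_that("within-patient lag-1 autocorrelation of Hgb tracks the configured coefficient", {
  cfg <- cohort_config(n_patients = 2000, draws_min = 4, draws_mean = 6,
                       bleed_prob = 0, tx_prob = 0, censor_frac = 0,
                       nonnumeric_frac = 0, seed = 31)
  co <- generate_cohort(cfg)
  base <- attr(co, "patients")
  hgb <- co[co$analyte == "HGB", ]
  hgb <- hgb[order(hgb$patient_id, hgb$drawn_at), ]
  dev <- coerce_numeric(hgb$value_raw) -
    base$hgb_baseline[match(hgb$patient_id, base$patient_id)]
  same <- hgb$patient_id[-1] == hgb$patient_id[-nrow(hgb)]
  x <- dev[-nrow(hgb)][same]
  y <- dev[-1][same]
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_lt(abs(r - cfg$ar1), 0.1)
})

test_that("marginal medians land near the configured targets", {
  cfg <- cohort_config(n_patients = 2500, seed = 12)
  co <- generate_cohort(cfg)
  v <- coerce_numeric(co$value_raw)
  med <- tapply(v, co$analyte, median, na.rm = TRUE)
  expect_lt(abs(med[["HGB"]] / cfg$hgb_mean - 1), 0.05)
  expect_lt(abs(med[["PLT"]] / cfg$plt_median - 1), 0.05)
  expect_lt(abs(med[["WBC"]] / cfg$wbc_median - 1), 0.05)
})

test_that("censored and non-numeric strings are emitted at the configured rates", {
  cfg <- cohort_config(n_patients = 400, censor_frac = 0.05,
                       nonnumeric_frac = 0.02, seed = 9)
  co <- generate_cohort(cfg)
  frac_cens <- mean(grepl("^[<>]", co$value_raw))
  frac_drop <- mean(co$value_raw == "See Comment")
  expect_lt(abs(frac_cens - 0.05), 0.02)
  expect_lt(abs(frac_drop - 0.02), 0.01)
  # censored strings coerce back to their numeric value
  cens <- grepl("^[<>]", co$value_raw)
  expect_equal(coerce_numeric(co$value_raw[cens]),
               signif(co$.value[cens], 6))
})

test_that("transfusion generation honours probability, increment, and trio context", {
  cfg0 <- cohort_config(n_patients = 60, tx_prob = 0, seed = 5)
  out0 <- generate_transfusions(generate_cohort(cfg0), cfg0)
  expect_equal(nrow(out0$transfusions), 0)

  # noise off, AR off: every draw sits at baseline, so the draw after a
  # 1-unit transfusion must read exactly baseline + increment
  cfg1 <- cohort_config(n_patients = 200, ar1 = 0, hgb_within_sd = 1e-12,
                        plt_within_sd = 1e-12, wbc_within_sd = 1e-12,
                        cv = c(HGB = 1e-12, PLT = 1e-12, WBC = 1e-12,
                               "NA" = 1e-12, K = 1e-12, CL = 1e-12,
                               CO2 = 1e-12, BUN = 1e-12, CREAT = 1e-12,
                               GLU = 1e-12, CA = 1e-12),
                        censor_frac = 0, nonnumeric_frac = 0, bleed_prob = 0,
                        tx_prob = 1, tx_increment = 1.0, tx_two_unit_prob = 0,
                        hgb_mean = 7.5, hgb_sd = 1.5, seed = 8)
  out1 <- generate_transfusions(generate_cohort(cfg1), cfg1)
  expect_gt(nrow(out1$transfusions), 0)
  hgb <- out1$cohort[out1$cohort$analyte == "HGB", ]
  hgb <- hgb[order(hgb$patient_id, hgb$drawn_at), ]
  tx1 <- out1$transfusions[out1$transfusions$units == 1, ]
  for (r in seq_len(min(nrow(tx1), 20))) {
    ph <- hgb[hgb$patient_id == tx1$patient_id[r], ]
    before <- max(which(ph$drawn_at < tx1$administered_at[r]))
    expect_equal(ph$.value[before + 1], ph$.value[before] + 1.0,
                 tolerance = 1e-9)
  }

  # transfusions always fall strictly between two draws of their patient,
  # so the surrounding-trio accounting is well defined
  cfg2 <- cohort_config(n_patients = 300, hgb_mean = 9, seed = 21)
  out2 <- generate_transfusions(generate_cohort(cfg2), cfg2)
  trios <- build_trios(out2$cohort)
  m <- match_transfusions_to_trios(trios, out2$transfusions)
  expect_gt(nrow(out2$transfusions), 10)
  expect_gt(mean(m$matched), 0.3)
})

test_that("BMP pairing respects probability and offset bounds", {
  cfg <- cohort_config(n_patients = 40, bmp_pair_prob = 1,
                       bmp_offset_min = 1, bmp_offset_max = 1, seed = 2)
  co <- generate_cohort(cfg)
  bmp <- generate_paired_bmps(co, cfg)
  cbc_times <- unique(paste(co$patient_id, co$drawn_at))
  bmp_na <- bmp[bmp$analyte == "NA", ]
  expect_equal(nrow(bmp_na), length(cbc_times))
  expect_setequal(paste(bmp_na$patient_id, bmp_na$drawn_at + 60), cbc_times)

  cfg0 <- cohort_config(n_patients = 40, bmp_pair_prob = 0, seed = 2)
  expect_equal(nrow(generate_paired_bmps(co, cfg0)), 0)

  cfg5 <- cohort_config(n_patients = 60, bmp_pair_prob = 1,
                        bmp_offset_min = 1, bmp_offset_max = 5, seed = 4)
  bmp5 <- generate_paired_bmps(co, cfg5)
  events <- unique(co[co$analyte == "HGB", c("patient_id", "drawn_at")])
  offs <- sapply(seq_len(nrow(bmp5)), function(i) {
    cand <- events$drawn_at[events$patient_id == bmp5$patient_id[i]]
    min(as.numeric(difftime(cand[cand >= bmp5$drawn_at[i]], bmp5$drawn_at[i],
                            units = "mins")))
  })
  expect_true(all(offs >= 1 & offs <= 5))
})

test_that("lab results and transfusions survive a CSV round trip", {
  cfg <- cohort_config(n_patients = 15, seed = 77)
  co <- generate_cohort(cfg)
  tx <- generate_transfusions(co, cfg)
  bmp <- generate_paired_bmps(tx$cohort, cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_lab_results(rbind(tx$cohort, bmp), f1)
  back <- read_lab_results(f1)
  orig <- rbind(tx$cohort, bmp)
  expect_equal(back$value_raw, orig$value_raw)
  expect_equal(back$drawn_at, orig$drawn_at)
  expect_true("NA" %in% back$analyte)  # sodium code must not become missing
  write_transfusions(tx$transfusions, f2)
  tback <- read_transfusions(f2)
  expect_equal(tback$administered_at, tx$transfusions$administered_at)
  expect_equal(tback$units, tx$transfusions$units)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(ar1 = 1), class = "cbccontam_config_error")
  expect_error(cohort_config(tx_prob = 1.2), class = "cbccontam_config_error")
  expect_error(cohort_config(cv = c(HGB = 0, PLT = 0.1, WBC = 0.1)),
               class = "cbccontam_config_error")
  expect_error(cohort_config(interval_mean_h = -1),
               class = "cbccontam_config_error")
})
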