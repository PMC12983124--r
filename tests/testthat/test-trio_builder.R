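lab_row <- function(patient, t, analyte, raw, seq) {
  tibble::tibble(patient_id = patient,
                 drawn_at = as.POSIXct(t, tz = "UTC"),
                 analyte = analyte, value_raw = raw, seq = seq)
}

cbc_draw <- function(patient, t, hgb, plt, wbc, seq0 = 1) {
  dplyr::bind_rows(
    lab_row(patient, t, "HGB", as.character(hgb), seq0),
    lab_row(patient, t, "PLT", as.character(plt), seq0 + 1),
    lab_row(patient, t, "WBC", as.character(wbc), seq0 + 2))
}

test_that("censored strings coerce to their bound and junk is dropped", {
  expect_equal(coerce_numeric(">1500"), 1500)
  expect_equal(coerce_numeric("<0.1"), 0.1)
  expect_true(is.na(coerce_numeric("See Comment")))
  expect_equal(coerce_numeric(c("12.3", ">1500", "<0.1", "TNP", "")),
               c(12.3, 1500, 0.1, NA, NA))
})

test_that("three complete draws yield exactly the middle trio", {
  res <- dplyr::bind_rows(
    cbc_draw("A", "2024-01-01 00:00:00", 10, 200, 7, 1),
    cbc_draw("A", "2024-01-01 12:00:00", 8, 160, 5.5, 4),
    cbc_draw("A", "2024-01-02 00:00:00", 10, 205, 7.2, 7))
  trios <- build_trios(res)
  expect_equal(nrow(trios), 1)
  expect_equal(trios$t_current, as.POSIXct("2024-01-01 12:00:00", tz = "UTC"))
  expect_equal(trios$hgb_prior, 10)
  expect_equal(trios$hgb_current, 8)
  expect_equal(trios$hgb_delta_prior, -2)
  expect_equal(trios$hgb_delta_post, 2)
})

test_that("the 48-hour window boundary is inclusive", {
  base <- dplyr::bind_rows(
    cbc_draw("A", "2024-01-01 00:00:00", 10, 200, 7, 1),
    cbc_draw("A", "2024-01-02 23:00:00", 9, 190, 6, 4),
    cbc_draw("A", "2024-01-04 22:00:00", 10, 210, 7, 7))
  # prior at -47 h and post at +47 h: inside
  expect_equal(nrow(build_trios(base)), 1)
  # two draws 49 h apart: no trio
  res2 <- dplyr::bind_rows(
    cbc_draw("B", "2024-01-01 00:00:00", 10, 200, 7, 1),
    cbc_draw("B", "2024-01-03 01:00:00", 9, 190, 6, 4))
  expect_equal(nrow(build_trios(res2)), 0)
  # exactly 48 h is still a neighbour
  res3 <- dplyr::bind_rows(
    cbc_draw("C", "2024-01-01 00:00:00", 10, 200, 7, 1),
    cbc_draw("C", "2024-01-03 00:00:00", 9, 190, 6, 4),
    cbc_draw("C", "2024-01-05 00:00:00", 10, 210, 7, 7))
  expect_equal(nrow(build_trios(res3)), 1)
})

test_that("incomplete draws and non-numeric values never anchor a trio", {
  res <- dplyr::bind_rows(
    cbc_draw("A", "2024-01-01 00:00:00", 10, 200, 7, 1),
    lab_row("A", "2024-01-01 12:00:00", "HGB", "8", 4),   # no PLT/WBC
    cbc_draw("A", "2024-01-02 00:00:00", 10, 205, 7.2, 7))
  expect_equal(nrow(build_trios(res)), 0)
  res2 <- dplyr::bind_rows(
    cbc_draw("A", "2024-01-01 00:00:00", 10, 200, 7, 1),
    cbc_draw("A", "2024-01-01 12:00:00", "See Comment", 160, 5.5, 4),
    cbc_draw("A", "2024-01-02 00:00:00", 10, 205, 7.2, 7))
  expect_equal(nrow(build_trios(res2)), 0)
  expect_equal(nrow(build_trios(res[0, ])), 0)
})

test_that("relative deltas divide by the reference result", {
  trios <- make_trios(hgb = cbind(10, 8, 10), plt = cbind(200, 160, 200),
                      wbc = cbind(5, 4, 5))
  rel <- compute_deltas(trios, "relative")
  expect_equal(rel$hgb_delta_prior, -0.2)
  expect_equal(rel$hgb_delta_post, 0.25)
  expect_equal(rel$plt_delta_prior, -0.2)
  flat <- make_trios(hgb = cbind(12, 12, 12), plt = cbind(250, 250, 250),
                     wbc = cbind(8, 8, 8))
  expect_equal(compute_deltas(flat, "relative")$hgb_delta_prior, 0)
  expect_equal(compute_deltas(flat, "absolute")$hgb_delta_post, 0)
  zero <- make_trios(hgb = cbind(0, 8, 10), plt = cbind(200, 160, 200),
                     wbc = cbind(5, 4, 5))
  expect_error(compute_deltas(zero, "relative"),
               class = "cbccontam_data_error")
})

test_that("duplicate timestamps keep the latest reported result", {
  res <- dplyr::bind_rows(
    cbc_draw("A", "2024-01-01 00:00:00", 10, 200, 7, 1),
    cbc_draw("A", "2024-01-01 12:00:00", 8, 160, 5.5, 4),
    lab_row("A", "2024-01-01 12:00:00", "HGB", "8.4", 10),  # corrected report
    cbc_draw("A", "2024-01-02 00:00:00", 10, 205, 7.2, 7))
  trios <- build_trios(res)
  expect_equal(trios$hgb_current, 8.4)
})

test_that("build_trios matches the exhaustive neighbour-search oracle", {
  set.seed(404)
  for (rep in 1:25) {
    n_draws <- sample(2:6, 1)
    pats <- sample(c("A", "B"), n_draws, replace = TRUE)
    times <- as.POSIXct("2024-01-01", tz = "UTC") +
      3600 * sample(0:120, n_draws)
    res <- dplyr::bind_rows(lapply(seq_len(n_draws), function(i) {
      cbc_draw(pats[i], times[i], round(runif(1, 5, 15), 1),
               round(runif(1, 50, 400)), round(runif(1, 1, 20), 1),
               seq0 = (i - 1) * 3 + 1)
    }))
    # occasionally drop one analyte row to create incomplete draws
    if (runif(1) < 0.4) res <- res[-sample(nrow(res), 1), ]
    got <- build_trios(res)
    want <- oracle_build_trios(res)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$patient_id, got$t_current), ]
      expect_equal(nrow(got), nrow(want))
      for (col in c("t_prior", "t_current", "t_post", "hgb_prior",
                    "hgb_current", "hgb_post", "plt_current", "wbc_post")) {
        expect_equal(unname(got[[col]]), unname(want[[col]]),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("shrinking the window never increases the trio count", {
  cfg <- cohort_config(n_patients = 60, seed = 15)
  co <- generate_cohort(cfg)
  counts <- sapply(c(72, 48, 24, 12, 6), function(w)
    nrow(build_trios(co, window_h = w)))
  expect_true(all(diff(counts) <= 0))
})

test_that("the latest-within-window post rule picks the latest subsequent draw", {
  res <- dplyr::bind_rows(
    cbc_draw("A", "2024-01-01 00:00:00", 10, 200, 7, 1),
    cbc_draw("A", "2024-01-01 12:00:00", 8, 160, 5.5, 4),
    cbc_draw("A", "2024-01-02 00:00:00", 9, 180, 6, 7),
    cbc_draw("A", "2024-01-03 06:00:00", 10, 210, 7, 10))
  early <- build_trios(res)
  late <- build_trios(res, post_rule = "latest")
  mid_e <- early[early$t_current == as.POSIXct("2024-01-01 12:00:00", tz = "UTC"), ]
  mid_l <- late[late$t_current == as.POSIXct("2024-01-01 12:00:00", tz = "UTC"), ]
  expect_equal(mid_e$t_post, as.POSIXct("2024-01-02 00:00:00", tz = "UTC"))
  expect_equal(mid_l$t_post, as.POSIXct("2024-01-03 06:00:00", tz = "UTC"))
  expect_equal(mid_l$hgb_post, 10)
})

test_that("trio tables survive a CSV round trip exactly", {
  trios <- small_clean_trios()
  f <- tempfile(fileext = ".csv")
  write_trios(trios, f)
  back <- read_trios(f)
  expect_equal(back$hgb_current, trios$hgb_current)
  expect_equal(back$t_post, trios$t_post)
  expect_equal(attr(back, "analytes"), attr(trios, "analytes"))
  expect_equal(attr(back, "delta_mode"), attr(trios, "delta_mode"))
  expect_equal(back$wbc_delta_post, trios$wbc_delta_post)
})
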