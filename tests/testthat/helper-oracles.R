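# Independent oracles used across the suite: brute-force implementations
# kept deliberately separate from the package's own algorithms.

# auROC by explicit enumeration of all positive/negative pairs,
# half credit for ties.
oracle_auroc <- function(prob, y) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exhaustive trio construction: for every complete draw, scan every other
# complete draw of the same patient for the neighbour roles.
oracle_build_trios <- function(results, window_h = 48,
                               analytes = c("HGB", "PLT", "WBC")) {
  v <- coerce_numeric(results$value_raw)
  df <- results[!is.na(v) & results$analyte %in% analytes, ]
  df$value <- v[!is.na(v) & results$analyte %in% analytes]
  if (!"seq" %in% names(df)) df$seq <- seq_len(nrow(df))
  # complete draws, duplicates resolved by highest seq
  draws <- list()
  for (key in unique(paste(df$patient_id, df$drawn_at))) {
    sub <- df[paste(df$patient_id, df$drawn_at) == key, ]
    vals <- sapply(analytes, function(a) {
      rows <- sub[sub$analyte == a, ]
      if (nrow(rows) == 0) return(NA_real_)
      rows$value[which.max(rows$seq)]
    })
    if (!anyNA(vals))
      draws[[length(draws) + 1]] <- list(patient = sub$patient_id[1],
                                         t = sub$drawn_at[1], vals = vals)
  }
  win <- window_h * 3600
  out <- list()
  for (i in seq_along(draws)) {
    d <- draws[[i]]
    others <- Filter(function(o) o$patient == d$patient, draws)
    before <- Filter(function(o) o$t < d$t &
                       as.numeric(d$t) - as.numeric(o$t) <= win, others)
    after <- Filter(function(o) o$t > d$t &
                      as.numeric(o$t) - as.numeric(d$t) <= win, others)
    if (length(before) == 0 || length(after) == 0) next
    prior <- before[[which.max(sapply(before, function(o) as.numeric(o$t)))]]
    post <- after[[which.min(sapply(after, function(o) as.numeric(o$t)))]]
    out[[length(out) + 1]] <- data.frame(
      patient_id = d$patient, t_prior = prior$t, t_current = d$t,
      t_post = post$t,
      t(setNames(c(prior$vals, d$vals, post$vals),
                 c(paste0(tolower(analytes), "_prior"),
                   paste0(tolower(analytes), "_current"),
                   paste0(tolower(analytes), "_post")))))
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$patient_id, res$t_current), ]
}

# Closed-form simple least squares.
oracle_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  fitted <- ic + sl * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = sl, intercept = ic, r2 = r2)
}

# Exhaustive grid search for the PPV-calibrated threshold.
oracle_calibrate <- function(prob, y, target = 0.80, step = 0.005) {
  for (thr in seq(step, 1, by = step)) {
    pred <- prob >= thr
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    if (tp + fp == 0) next
    if (tp / (tp + fp) > target) return(thr)
  }
  NA_real_
}

# Directly constructed trio tables (bypassing build_trios) for model tests.
make_trios <- function(hgb, plt, wbc, patient_id = NULL, spacing_h = 12) {
  n <- nrow(hgb)
  t0 <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC")
  out <- tibble::tibble(
    trio_id = sprintf("T%05d", seq_len(n)),
    patient_id = patient_id %||% sprintf("P%05d", seq_len(n)),
    t_prior = t0 + (seq_len(n) - 1) * 86400,
    t_current = t0 + (seq_len(n) - 1) * 86400 + spacing_h * 3600,
    t_post = t0 + (seq_len(n) - 1) * 86400 + 2 * spacing_h * 3600,
    hgb_prior = hgb[, 1], hgb_current = hgb[, 2], hgb_post = hgb[, 3],
    plt_prior = plt[, 1], plt_current = plt[, 2], plt_post = plt[, 3],
    wbc_prior = wbc[, 1], wbc_current = wbc[, 2], wbc_post = wbc[, 3])
  attr(out, "analytes") <- c("HGB", "PLT", "WBC")
  compute_deltas(out, "absolute")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared small fixtures, built once per test session.
.fixtures <- new.env(parent = emptyenv())

small_labeled <- function() {
  if (is.null(.fixtures$labeled)) {
    cfg <- cohort_config(n_patients = 400, seed = 2024)
    co <- generate_cohort(cfg)
    tx <- generate_transfusions(co, cfg)
    trios <- build_trios(tx$cohort)
    .fixtures$labeled <- simulate_training_set(trios, 0.5, seed = 11)
  }
  .fixtures$labeled
}

small_detector <- function() {
  if (is.null(.fixtures$detector)) {
    .fixtures$detector <- train_detector(small_labeled(), nfolds = 0,
                                         params = list(nrounds = 150),
                                         seed = 5)
  }
  .fixtures$detector
}

small_clean_trios <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- cohort_config(n_patients = 250, seed = 4048)
    tx <- generate_transfusions(generate_cohort(cfg), cfg)
    .fixtures$clean <- build_trios(tx$cohort)
  }
  .fixtures$clean
}
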