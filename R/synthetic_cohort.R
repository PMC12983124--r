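# Seeded synthetic longitudinal cohort: serial CBC results with
# within-patient AR(1) correlation, multiplicative analytic noise,
# transfusion-induced Hgb increments, acute-bleed mimickers, and optional
# paired BMPs. Stands in for institutional LIS extracts so the whole
# pipeline can be exercised without patient data.

# Physiologic marginals for BMP analytes. Location/scale are population
# parameters; `within` is the within-patient stationary SD of the AR(1)
# process (absolute units for normal marginals, log units for lognormal).
BMP_MARGINALS <- list(
  "NA"  = list(dist = "normal",    location = 140, scale = 3,    within = 1.5),
  K     = list(dist = "normal",    location = 4.1, scale = 0.45, within = 0.25),
  CL    = list(dist = "normal",    location = 103, scale = 3.5,  within = 1.2),
  CO2   = list(dist = "normal",    location = 25,  scale = 2.8,  within = 1.2),
  BUN   = list(dist = "lognormal", location = 16,  scale = 1.7,  within = 0.12),
  CREAT = list(dist = "lognormal", location = 0.9, scale = 1.6,  within = 0.08),
  GLU   = list(dist = "lognormal", location = 115, scale = 1.35, within = 0.15),
  CA    = list(dist = "normal",    location = 9.3, scale = 0.5,  within = 0.2)
)

#' Configuration for the synthetic cohort generator
#'
#' Returns a validated configuration controlling every stochastic element of
#' the generator: cohort size and draw cadence, per-analyte marginal
#' distributions and within-patient serial correlation, analytic
#' (measurement) noise, censored-string emission, acute-bleed mimickers,
#' transfusion behaviour, and BMP pairing.
#'
#' Patient baselines are drawn from the configured marginals (Hgb truncated
#' normal in g/dL; Plt and WBC lognormal in 10^3/uL). Serial values follow a
#' stationary AR(1) process around the baseline (on the log scale for Plt and
#' WBC) and are reported with multiplicative lognormal analytic noise of the
#' given coefficient of variation (CV).
#'
#' @param n_patients Number of patients.
#' @param draws_min,draws_mean Draws per patient: `draws_min` plus a Poisson
#'   count with mean `draws_mean - draws_min`.
#' @param interval_mean_h,interval_shape Gamma-distributed inter-draw
#'   interval in hours (mean and shape); intervals are floored at 30 min.
#' @param hgb_mean,hgb_sd,hgb_range Hgb baseline marginal (g/dL), truncated
#'   to `hgb_range`.
#' @param hgb_within_sd Within-patient stationary SD of serial Hgb (g/dL).
#' @param plt_median,plt_gsd,plt_within_sd Platelet baseline median
#'   (10^3/uL), geometric SD, and within-patient log-scale SD.
#' @param wbc_median,wbc_gsd,wbc_within_sd Same for WBC.
#' @param ar1 Within-patient lag-1 autocorrelation coefficient, in \[0, 1).
#' @param cv Named vector of analytic CVs per analyte (all > 0).
#' @param censor_frac Fraction of results emitted as censored strings
#'   ("<x" / ">x") to exercise coercion.
#' @param nonnumeric_frac Fraction emitted as a non-numeric string
#'   ("See Comment"), dropped downstream.
#' @param bleed_prob Per-patient probability of an acute-bleed mimicker: a
#'   persistent Hgb drop of `bleed_drop` g/dL with no rebound.
#' @param bleed_drop Magnitude of the bleed drop (g/dL).
#' @param tx_prob Probability that a draw with effective Hgb below
#'   `tx_threshold` is followed by an RBC transfusion before the next draw.
#' @param tx_threshold Hgb decision threshold for transfusion (g/dL).
#' @param tx_increment Hgb increment per transfused unit (g/dL), applied to
#'   all subsequent latent values before analytic noise.
#' @param tx_two_unit_prob Probability a transfusion is a two-unit order.
#' @param bmp_pair_prob Fraction of CBC draws with a paired BMP.
#' @param bmp_offset_min,bmp_offset_max BMP collection offset before the CBC,
#'   whole minutes, sampled uniformly in the range.
#' @param bmp_marginals Named list of BMP marginal specs (see
#'   `cbccontam:::BMP_MARGINALS` for the format and defaults).
#' @param seed Integer seed; identical configurations produce byte-identical
#'   output tables.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500,
                          draws_min = 3,
                          draws_mean = 6.5,
                          interval_mean_h = 12,
                          interval_shape = 2,
                          hgb_mean = 11.5, hgb_sd = 2.2, hgb_range = c(3, 20),
                          hgb_within_sd = 0.35,
                          plt_median = 220, plt_gsd = 1.6, plt_within_sd = 0.09,
                          wbc_median = 8, wbc_gsd = 1.7, wbc_within_sd = 0.11,
                          ar1 = 0.85,
                          cv = c(HGB = 0.01, PLT = 0.04, WBC = 0.03,
                                 "NA" = 0.005, K = 0.02, CL = 0.01, CO2 = 0.02,
                                 BUN = 0.03, CREAT = 0.03, GLU = 0.02,
                                 CA = 0.015),
                          censor_frac = 0.002,
                          nonnumeric_frac = 0.001,
                          bleed_prob = 0.02, bleed_drop = 3,
                          tx_prob = 0.6, tx_threshold = 7, tx_increment = 1.0,
                          tx_two_unit_prob = 0.15,
                          bmp_pair_prob = 0.5,
                          bmp_offset_min = 1, bmp_offset_max = 1,
                          bmp_marginals = NULL,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), draws_min = as.integer(draws_min),
    draws_mean = draws_mean, interval_mean_h = interval_mean_h,
    interval_shape = interval_shape,
    hgb_mean = hgb_mean, hgb_sd = hgb_sd, hgb_range = hgb_range,
    hgb_within_sd = hgb_within_sd,
    plt_median = plt_median, plt_gsd = plt_gsd, plt_within_sd = plt_within_sd,
    wbc_median = wbc_median, wbc_gsd = wbc_gsd, wbc_within_sd = wbc_within_sd,
    ar1 = ar1, cv = cv,
    censor_frac = censor_frac, nonnumeric_frac = nonnumeric_frac,
    bleed_prob = bleed_prob, bleed_drop = bleed_drop,
    tx_prob = tx_prob, tx_threshold = tx_threshold,
    tx_increment = tx_increment, tx_two_unit_prob = tx_two_unit_prob,
    bmp_pair_prob = bmp_pair_prob,
    bmp_offset_min = as.integer(bmp_offset_min),
    bmp_offset_max = as.integer(bmp_offset_max),
    bmp_marginals = modifyList(BMP_MARGINALS, bmp_marginals %||% list()),
    seed = as.integer(seed)
  )
  probs <- c(cfg$censor_frac, cfg$nonnumeric_frac, cfg$bleed_prob,
             cfg$tx_prob, cfg$tx_two_unit_prob, cfg$bmp_pair_prob)
  if (any(probs < 0 | probs > 1)) stop_config("all probabilities must be in [0, 1]")
  if (any(cfg$cv <= 0)) stop_config("analytic CVs must be > 0")
  if (cfg$ar1 < 0 || cfg$ar1 >= 1) stop_config("ar1 must be in [0, 1)")
  if (cfg$n_patients < 1) stop_config("n_patients must be >= 1")
  if (cfg$draws_mean < cfg$draws_min) stop_config("draws_mean must be >= draws_min")
  if (cfg$interval_mean_h <= 0 || cfg$interval_shape <= 0)
    stop_config("inter-draw interval parameters must be > 0")
  if (cfg$bmp_offset_min < 0 || cfg$bmp_offset_max < cfg$bmp_offset_min)
    stop_config("bmp offsets must satisfy 0 <= min <= max")
  if (cfg$hgb_sd <= 0 || cfg$plt_gsd <= 1 || cfg$wbc_gsd <= 1)
    stop_config("marginal scale parameters out of range")
  structure(cfg, class = "cohort_config")
}

# Stationary AR(1) deviations for runs of lengths `lens`; each run restarts.
ar1_deviations <- function(lens, phi, sd) {
  n <- sum(lens)
  z <- rnorm(n)
  first <- rep(FALSE, n)
  first[cumsum(c(1, lens[-length(lens)]))] <- TRUE
  e <- numeric(n)
  innov <- sqrt(1 - phi^2) * sd
  for (i in seq_len(n)) {
    e[i] <- if (first[i]) sd * z[i] else phi * e[i - 1] + innov * z[i]
  }
  e
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

format_value <- function(x) as.character(signif(x, 6))

# value_raw with optional censoring/non-numeric emission; censored strings
# carry the full value after the relational prefix so coercion is lossless.
emit_raw <- function(value, censor, nonnum, prefix) {
  out <- format_value(value)
  out[censor] <- paste0(prefix[censor], out[censor])
  out[nonnum] <- "See Comment"
  out
}

#' Generate a synthetic longitudinal CBC cohort
#'
#' Simulates serial Hgb/Plt/WBC results for `config$n_patients` patients.
#' Each patient has a baseline drawn from the configured marginals; serial
#' values follow a stationary AR(1) process around that baseline (log scale
#' for Plt/WBC), a configurable fraction of patients suffer a persistent
#' acute-bleed Hgb drop, and reported values carry multiplicative lognormal
#' analytic noise. A small fraction of results are emitted as censored
#' strings (e.g. `">1500"`) or as `"See Comment"` to exercise coercion.
#'
#' @param config A [cohort_config()].
#' @return A tibble of lab results with columns `patient_id`, `drawn_at`
#'   (POSIXct, minute resolution, UTC), `analyte`, `value_raw` (string as
#'   reported), and `seq` (insertion sequence number used for tie-breaking).
#'   Internal dot-columns (`.latent`, `.noise`, `.value`) carry the noise-free
#'   latent value, the analytic noise multiplier, and the numeric reported
#'   value; [write_lab_results()] drops them. Patient baselines are attached
#'   as the `"patients"` attribute.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("P%05d", seq_len(n))
    d <- config$draws_min + stats::rpois(n, config$draws_mean - config$draws_min)
    N <- sum(d)
    p_idx <- rep(seq_len(n), d)
    within_idx <- sequence(d)

    # draw times: staggered admission, gamma inter-draw intervals >= 30 min
    start_min <- round(runif(n, 0, 300 * 24 * 60))
    ivl_h <- pmax(stats::rgamma(N, shape = config$interval_shape,
                                rate = config$interval_shape / config$interval_mean_h),
                  0.5)
    ivl_min <- ifelse(within_idx == 1, 0, round(ivl_h * 60))
    t_min <- start_min[p_idx] +
      stats::ave(ivl_min, p_idx, FUN = cumsum) + (within_idx - 1)
    drawn_at <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") + 60 * t_min

    # baselines and AR(1) latent series
    hgb_b <- rtruncnorm(n, config$hgb_mean, config$hgb_sd,
                        config$hgb_range[1], config$hgb_range[2])
    plt_b <- rlnorm(n, log(config$plt_median), log(config$plt_gsd))
    wbc_b <- rlnorm(n, log(config$wbc_median), log(config$wbc_gsd))
    hgb_lat <- pmin(pmax(hgb_b[p_idx] + ar1_deviations(d, config$ar1, config$hgb_within_sd),
                         config$hgb_range[1]), config$hgb_range[2])
    plt_lat <- exp(log(plt_b[p_idx]) + ar1_deviations(d, config$ar1, config$plt_within_sd))
    wbc_lat <- exp(log(wbc_b[p_idx]) + ar1_deviations(d, config$ar1, config$wbc_within_sd))

    # acute-bleed mimicker: persistent drop, no rebound
    bleeders <- which(runif(n) < config$bleed_prob & d >= 3)
    if (length(bleeders)) {
      bleed_at <- vapply(d[bleeders], function(k) sample(2:k, 1L), integer(1))
      hit <- p_idx %in% bleeders
      bleed_idx <- setNames(bleed_at, bleeders)
      after <- hit & within_idx >= bleed_idx[as.character(p_idx)]
      after[is.na(after)] <- FALSE
      hgb_lat[after] <- pmax(hgb_lat[after] - config$bleed_drop, config$hgb_range[1])
    }

    res <- tibble(
      patient_id = rep(pid[p_idx], times = 3),
      drawn_at = rep(drawn_at, times = 3),
      analyte = rep(CBC_ANALYTES, each = N),
      .latent = c(hgb_lat, plt_lat, wbc_lat)
    )
    res$.noise <- exp(rnorm(3 * N, 0, rep(config$cv[CBC_ANALYTES], each = N)))
    res$.value <- res$.latent * res$.noise
    res <- res %>% arrange(.data$patient_id, .data$drawn_at, match(.data$analyte, CBC_ANALYTES))
    res$seq <- seq_len(nrow(res))

    censor <- runif(nrow(res)) < config$censor_frac
    nonnum <- runif(nrow(res)) < config$nonnumeric_frac
    prefix <- ifelse(runif(nrow(res)) < 0.5, "<", ">")
    res$value_raw <- emit_raw(res$.value, censor, nonnum, prefix)
    res <- res %>% select("patient_id", "drawn_at", "analyte", "value_raw",
                          "seq", ".latent", ".noise", ".value")
    attr(res, "patients") <- tibble(patient_id = pid, hgb_baseline = hgb_b,
                                    plt_baseline = plt_b, wbc_baseline = wbc_b)
    attr(res, "config") <- config
    res
  })
}

#' Generate transfusion records and apply their Hgb increments
#'
#' Walks each patient's serial Hgb results in time order. A draw whose
#' effective Hgb (latent plus any increments from earlier transfusions,
#' before analytic noise) falls below `config$tx_threshold` triggers a
#' transfusion with probability `config$tx_prob`, administered at a random
#' time before the next draw. Every subsequent latent Hgb for that patient
#' is incremented by `units * config$tx_increment` g/dL before noise, and the
#' reported values/strings are regenerated (censoring style preserved).
#'
#' @param cohort Result table from [generate_cohort()].
#' @param config The same [cohort_config()] used to generate it.
#' @return A list with `transfusions` (tibble `tx_id`, `patient_id`,
#'   `administered_at`, `units`) and `cohort` (the updated result table).
#' @export
generate_transfusions <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 1L, {
    hgb <- cohort %>% filter(.data$analyte == "HGB") %>%
      arrange(.data$patient_id, .data$drawn_at, .data$seq)
    add_lat <- numeric(nrow(cohort))       # increment per cohort row (HGB only)
    tx <- list()
    k <- 0L
    for (p in split(seq_len(nrow(hgb)), hgb$patient_id)) {
      cum <- 0
      for (j in seq_along(p)) {
        i <- p[j]
        v_eff <- (hgb$.latent[i] + cum) * hgb$.noise[i]
        if (j < length(p) && v_eff < config$tx_threshold &&
            runif(1) < config$tx_prob) {
          gap_min <- as.numeric(difftime(hgb$drawn_at[p[j + 1]], hgb$drawn_at[i],
                                         units = "mins"))
          if (gap_min > 2) {
            units <- 1L + rbinom(1, 1, config$tx_two_unit_prob)
            delay <- min(round(runif(1, 30, 240)), gap_min - 1)
            k <- k + 1L
            tx[[k]] <- tibble(
              tx_id = NA_character_, patient_id = hgb$patient_id[i],
              administered_at = hgb$drawn_at[i] + 60 * delay,
              units = units)
            cum <- cum + units * config$tx_increment
          }
        }
      }
    }
    transfusions <- if (k) bind_rows(tx) else
      tibble(tx_id = character(), patient_id = character(),
             administered_at = as.POSIXct(character(), tz = "UTC"),
             units = integer())
    if (nrow(transfusions)) {
      transfusions$tx_id <- sprintf("TX%05d", seq_len(nrow(transfusions)))
      # persistent latent increment for every HGB row after each transfusion
      is_hgb <- cohort$analyte == "HGB"
      for (r in seq_len(nrow(transfusions))) {
        hit <- is_hgb & cohort$patient_id == transfusions$patient_id[r] &
          cohort$drawn_at > transfusions$administered_at[r]
        add_lat[hit] <- add_lat[hit] +
          transfusions$units[r] * config$tx_increment
      }
      changed <- add_lat > 0
      if (any(changed)) {
        cohort$.latent[changed] <- cohort$.latent[changed] + add_lat[changed]
        cohort$.value[changed] <- cohort$.latent[changed] * cohort$.noise[changed]
        old <- cohort$value_raw[changed]
        pre <- ifelse(grepl("^[<>]", old), substr(old, 1, 1), "")
        new_raw <- paste0(pre, format_value(cohort$.value[changed]))
        new_raw[old == "See Comment"] <- "See Comment"
        cohort$value_raw[changed] <- new_raw
      }
    }
    list(transfusions = transfusions, cohort = cohort)
  })
}

#' Generate BMPs paired to CBC draws
#'
#' For a configurable fraction of CBC draw events, emits a basic metabolic
#' panel collected shortly *before* the CBC (BMP tubes are drawn first on a
#' typical collection), at an offset of `bmp_offset_min`..`bmp_offset_max`
#' whole minutes. BMP analytes follow per-patient AR(1) series around
#' physiologic baselines with analytic noise, mirroring the CBC generator.
#'
#' @inheritParams generate_transfusions
#' @return A tibble of BMP lab results in the same schema as
#'   [generate_cohort()].
#' @export
generate_paired_bmps <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 2L, {
    events <- cohort %>% filter(.data$analyte == "HGB") %>%
      distinct(.data$patient_id, .data$drawn_at) %>%
      arrange(.data$patient_id, .data$drawn_at)
    if (nrow(events) == 0 || config$bmp_pair_prob == 0) {
      return(tibble(patient_id = character(),
                    drawn_at = as.POSIXct(character(), tz = "UTC"),
                    analyte = character(), value_raw = character(),
                    seq = integer(), .latent = double(), .noise = double(),
                    .value = double()))
    }
    d <- as.integer(table(factor(events$patient_id, unique(events$patient_id))))
    n <- length(d)
    N <- nrow(events)
    paired <- runif(N) < config$bmp_pair_prob
    offs <- if (config$bmp_offset_min == config$bmp_offset_max)
      rep(config$bmp_offset_min, N) else
      sample(seq(config$bmp_offset_min, config$bmp_offset_max), N, replace = TRUE)

    out <- lapply(names(config$bmp_marginals), function(a) {
      m <- config$bmp_marginals[[a]]
      if (m$dist == "normal") {
        b <- rnorm(n, m$location, m$scale)
        lat <- pmax(rep(b, d) + ar1_deviations(d, config$ar1, m$within), 1e-3)
      } else {
        b <- rlnorm(n, log(m$location), log(m$scale))
        lat <- exp(log(rep(b, d)) + ar1_deviations(d, config$ar1, m$within))
      }
      noise <- exp(rnorm(N, 0, config$cv[[a]]))
      tibble(patient_id = events$patient_id,
             drawn_at = events$drawn_at - 60 * offs,
             analyte = a, .latent = lat, .noise = noise,
             .value = lat * noise)
    })
    bmp <- bind_rows(out)[rep(paired, length(config$bmp_marginals)), ]
    bmp <- bmp %>% arrange(.data$patient_id, .data$drawn_at,
                           match(.data$analyte, BMP_ANALYTES))
    bmp$seq <- max(cohort$seq) + seq_len(nrow(bmp))
    bmp$value_raw <- format_value(bmp$.value)
    bmp %>% select("patient_id", "drawn_at", "analyte", "value_raw", "seq",
                   ".latent", ".noise", ".value")
  })
}

#' Write and read tidy lab result / transfusion tables
#'
#' Results are written in long format with columns `patient_id`, `drawn_at`
#' (ISO-8601 UTC), `analyte`, `value_raw`; internal dot-columns and `seq` are
#' dropped on write and `seq` is re-derived from row order on read. CSV is
#' used for a `.csv` path and Parquet (via the arrow package) for
#' `.parquet`. Empty strings, not the token "NA", encode missing values so
#' the sodium analyte code survives a round trip.
#'
#' @param results,transfusions Tables as produced by the generator.
#' @param path Output/input file path (`.csv` or `.parquet`).
#' @return `write_*` return `path` invisibly; `read_*` return tibbles.
#' @export
write_lab_results <- function(results, path) {
  out <- results %>%
    mutate(drawn_at = format(.data$drawn_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) %>%
    select("patient_id", "drawn_at", "analyte", "value_raw")
  write_table(out, path)
}

#' @rdname write_lab_results
#' @export
read_lab_results <- function(path) {
  out <- read_table_file(path, c("patient_id", "drawn_at", "analyte", "value_raw"))
  out$drawn_at <- as.POSIXct(out$drawn_at, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$seq <- seq_len(nrow(out))
  out
}

#' @rdname write_lab_results
#' @export
write_transfusions <- function(transfusions, path) {
  out <- transfusions %>%
    mutate(administered_at = format(.data$administered_at,
                                    "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) %>%
    select("patient_id", "administered_at", "units")
  write_table(out, path)
}

#' @rdname write_lab_results
#' @export
read_transfusions <- function(path) {
  out <- read_table_file(path, c("patient_id", "administered_at", "units"))
  out$administered_at <- as.POSIXct(out$administered_at,
                                    format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$units <- as.integer(out$units)
  out$tx_id <- sprintf("TX%05d", seq_len(nrow(out)))
  out
}

is_parquet <- function(path) grepl("\\.parquet$", path, ignore.case = TRUE)

write_table <- function(df, path) {
  if (is_parquet(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_usage("the arrow package is required for parquet output")
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

read_table_file <- function(path, expected_cols) {
  if (!file.exists(path)) stop_data(paste0("input file not found: ", path))
  df <- if (is_parquet(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_usage("the arrow package is required for parquet input")
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, colClasses = "character", na.strings = NULL)
  }
  missing <- setdiff(expected_cols, names(df))
  if (length(missing))
    stop_data(paste0("missing columns in ", path, ": ",
                     paste(missing, collapse = ", ")))
  as_tibble(df)
}
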