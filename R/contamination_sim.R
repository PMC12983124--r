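# Simulated IV-fluid contamination: linear dilution of a panel at a sampled
# mixture ratio rho (the volume fraction of contaminating fluid in the
# specimen). For an analyte with patient value v and fluid concentration f,
# the contaminated measurement is (1 - rho) * v + rho * f. All IV fluids
# carry zero cells and hemoglobin, so CBC analytes scale uniformly by
# (1 - rho); fluid composition matters only for chemistry panels.

#' IV fluid composition library
#'
#' Reads the bundled YAML table of common IV fluids (normal saline,
#' half-normal saline, D5W, D5 half-normal saline, lactated Ringer's).
#' Concentrations are expressed in each analyte's reporting units; analytes
#' absent from an entry are zero, so every fluid has zero concentration for
#' the cellular CBC analytes.
#'
#' @param path Optional path to an alternative YAML fluid table.
#' @return Named list of fluids; each fluid is a full named numeric vector
#'   over [analyte_codes()].
#' @export
fluid_compositions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fluids.yaml", package = "cbccontam")
  raw <- yaml::read_yaml(path)
  lapply(raw, function(fl) {
    out <- setNames(numeric(length(analyte_codes())), analyte_codes())
    fl <- unlist(fl)
    if (any(fl < 0)) stop_config("fluid concentrations must be >= 0")
    out[names(fl)] <- fl
    out
  })
}

#' Mixture-ratio distribution for simulated contamination severities
#'
#' Contamination severities are drawn from a distribution of mixture ratios
#' meant to mimic real-world events: mostly mild dilutions with a heavy
#' enough tail of severe ones. The default is a Beta(1.5, 8) truncated to
#' \[0.02, 0.95\].
#'
#' @param family `"beta"` (truncated Beta) or `"uniform"`.
#' @param shape1,shape2 Beta shape parameters (ignored for uniform).
#' @param lo,hi Support bounds, `0 < lo < hi < 1`; samples never fall
#'   outside them.
#' @return An object of class `mixture_ratio_dist`.
#' @export
mixture_ratio_dist <- function(family = c("beta", "uniform"),
                               shape1 = 1.5, shape2 = 8,
                               lo = 0.02, hi = 0.95) {
  family <- match.arg(family)
  if (!(lo > 0 && hi < 1 && lo < hi))
    stop_config("support bounds must satisfy 0 < lo < hi < 1")
  if (family == "beta" && (shape1 <= 0 || shape2 <= 0))
    stop_config("beta shape parameters must be > 0")
  structure(list(family = family, shape1 = shape1, shape2 = shape2,
                 lo = lo, hi = hi),
            class = "mixture_ratio_dist")
}

#' Sample mixture ratios
#'
#' Samples by inverse-CDF so truncation is exact: every draw lies in
#' `[lo, hi]` and identical seeds give identical samples.
#'
#' @param dist A [mixture_ratio_dist()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector of `n` mixture ratios.
#' @export
sample_mixture_ratio <- function(dist, n, seed = 1L) {
  stopifnot(inherits(dist, "mixture_ratio_dist"))
  with_seed(seed, {
    if (dist$family == "beta") {
      u <- runif(n, pbeta(dist$lo, dist$shape1, dist$shape2),
                 pbeta(dist$hi, dist$shape1, dist$shape2))
      qbeta(u, dist$shape1, dist$shape2)
    } else {
      runif(n, dist$lo, dist$hi)
    }
  })
}

#' Apply a linear dilution to a panel of analyte values
#'
#' @param values Named numeric vector of analyte values (names from
#'   [analyte_codes()]), or an unnamed vector of CBC values in HGB/PLT/WBC
#'   order.
#' @param rho Mixture ratio in `[0, 1)`.
#' @param fluid A fluid from [fluid_compositions()]; defaults to an
#'   all-zero fluid, which is exact for CBC analytes regardless of fluid.
#' @return The diluted values, `(1 - rho) * value + rho * fluid`.
#' @export
apply_dilution <- function(values, rho, fluid = NULL) {
  if (any(rho < 0 | rho >= 1)) stop_usage("rho must be in [0, 1)")
  if (is.null(names(values)) && length(values) == 3)
    names(values) <- CBC_ANALYTES
  f <- if (is.null(fluid)) setNames(numeric(length(values)), names(values))
       else fluid[names(values)]
  (1 - rho) * values + rho * f
}

#' Simulate a contaminated training set from clean trios
#'
#' Dilutes the *current* values of a random `fraction` of trios (the prior
#' and post results stay clean — contamination of a single draw resolves on
#' the next properly collected specimen), recomputes deltas, and labels
#' every trio: `contaminated` 1 with the sampled `rho` for diluted rows,
#' 0 with `rho = 0` otherwise.
#'
#' @param trios Clean trio table from [build_trios()].
#' @param fraction Fraction of trios to contaminate (default 0.5).
#' @param dist Mixture-ratio distribution, default [mixture_ratio_dist()].
#' @param fluid Fluid composition for non-CBC analyte sets (ignored for CBC
#'   trios, where every fluid contributes zero).
#' @param seed Integer seed.
#' @return The trio table with current values (and deltas) updated and
#'   columns `contaminated` (integer 0/1) and `rho` appended.
#' @export
simulate_training_set <- function(trios, fraction = 0.5,
                                  dist = mixture_ratio_dist(),
                                  fluid = NULL, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop_config("fraction must be in [0, 1]")
  analytes <- attr(trios, "analytes") %||% CBC_ANALYTES
  mode <- attr(trios, "delta_mode") %||% "absolute"
  n <- nrow(trios)
  n_pos <- round(fraction * n)
  with_seed(seed, {
    pos <- sample.int(n, n_pos)
    rho <- numeric(n)
    if (n_pos > 0)
      rho[pos] <- sample_mixture_ratio(dist, n_pos,
                                       seed = sample.int(.Machine$integer.max, 1))
    for (a in analytes) {
      col <- paste0(tolower(a), "_current")
      f_a <- if (is.null(fluid)) 0 else fluid[[a]]
      trios[[col]][pos] <- (1 - rho[pos]) * trios[[col]][pos] + rho[pos] * f_a
    }
    trios <- compute_deltas(trios, mode = mode)
    trios$contaminated <- as.integer(seq_len(n) %in% pos)
    trios$rho <- rho
    trios
  })
}

#' Inject contamination events into a longitudinal cohort
#'
#' End-to-end counterpart of [simulate_training_set()] that operates on the
#' raw result table rather than built trios: a random `rate` fraction of
#' complete CBC draws is diluted at a sampled mixture ratio. When a BMP was
#' collected within `bmp_window_min` minutes before a contaminated CBC, the
#' BMP is co-contaminated with probability `p_joint` at
#' `rho * Uniform(uplift)` (BMP tubes are drawn first by the same
#' collector, so their mixture ratio tends to run slightly higher).
#'
#' @param results CBC result table (long format, from [generate_cohort()]
#'   or user data).
#' @param rate Fraction of complete CBC draws to contaminate.
#' @param dist Mixture-ratio distribution.
#' @param bmp Optional BMP result table to co-contaminate.
#' @param fluid Fluid composition used for the BMP analytes.
#' @param p_joint Probability a paired BMP shares the contamination.
#' @param uplift Length-2 range of the BMP/CBC mixture-ratio multiplier.
#' @param bmp_window_min Pairing window in minutes.
#' @param seed Integer seed.
#' @return List with `results`, `bmp` (updated tables) and `truth`, a tibble
#'   of injected events (`patient_id`, `drawn_at`, `rho`, `bmp_drawn_at`,
#'   `rho_bmp`; `NA` where no BMP was co-contaminated).
#' @export
inject_contamination <- function(results, rate,
                                 dist = mixture_ratio_dist(),
                                 bmp = NULL,
                                 fluid = fluid_compositions()[["normal_saline"]],
                                 p_joint = 0.8, uplift = c(1, 1.3),
                                 bmp_window_min = 5, seed = 1L) {
  if (rate < 0 || rate > 1) stop_config("rate must be in [0, 1]")
  with_seed(seed, {
    vals <- coerce_numeric(results$value_raw)
    complete_events <- results %>%
      mutate(.v = vals) %>%
      filter(.data$analyte %in% CBC_ANALYTES, !is.na(.data$.v)) %>%
      distinct(.data$patient_id, .data$drawn_at, .data$analyte) %>%
      count(.data$patient_id, .data$drawn_at) %>%
      filter(.data$n == length(CBC_ANALYTES))
    n_ev <- nrow(complete_events)
    n_hit <- stats::rbinom(1, n_ev, rate)
    truth <- tibble(patient_id = character(), drawn_at = as.POSIXct(character(), tz = "UTC"),
                    rho = double(),
                    bmp_drawn_at = as.POSIXct(character(), tz = "UTC"),
                    rho_bmp = double())
    if (n_hit == 0) return(list(results = results, bmp = bmp, truth = truth))
    hit <- complete_events[sample.int(n_ev, n_hit), c("patient_id", "drawn_at")]
    hit$rho <- sample_mixture_ratio(dist, n_hit,
                                    seed = sample.int(.Machine$integer.max, 1))
    hit$bmp_drawn_at <- as.POSIXct(NA, tz = "UTC")
    hit$rho_bmp <- NA_real_

    key <- paste(results$patient_id, results$drawn_at)
    hkey <- paste(hit$patient_id, hit$drawn_at)
    idx <- match(key, hkey)
    sel <- !is.na(idx) & results$analyte %in% CBC_ANALYTES & !is.na(vals)
    results$value_raw[sel] <- format_value((1 - hit$rho[idx[sel]]) * vals[sel])
    if (".value" %in% names(results))
      results$.value[sel] <- (1 - hit$rho[idx[sel]]) * results$.value[sel]

    if (!is.null(bmp) && nrow(bmp)) {
      bvals <- coerce_numeric(bmp$value_raw)
      bmp_events <- bmp %>% distinct(.data$patient_id, .data$drawn_at)
      for (r in seq_len(n_hit)) {
        cand <- bmp_events$patient_id == hit$patient_id[r] &
          bmp_events$drawn_at <= hit$drawn_at[r] &
          as.numeric(difftime(hit$drawn_at[r], bmp_events$drawn_at,
                              units = "mins")) <= bmp_window_min
        if (any(cand) && runif(1) < p_joint) {
          bt <- max(bmp_events$drawn_at[cand])
          rho_b <- min(hit$rho[r] * runif(1, uplift[1], uplift[2]), 0.95)
          rows <- which(bmp$patient_id == hit$patient_id[r] & bmp$drawn_at == bt)
          f <- fluid[bmp$analyte[rows]]
          newv <- (1 - rho_b) * bvals[rows] + rho_b * f
          bmp$value_raw[rows] <- format_value(newv)
          if (".value" %in% names(bmp)) bmp$.value[rows] <- newv
          hit$bmp_drawn_at[r] <- bt
          hit$rho_bmp[r] <- rho_b
        }
      }
    }
    list(results = results, bmp = bmp, truth = hit)
  })
}
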