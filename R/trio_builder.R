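# CBC trio construction: censored-value coercion, neighbor attachment
# within a 48-h window, and delta computation.

#' Coerce reported result strings to numeric values
#'
#' Strips a single leading `<` or `>` (censored results are replaced by
#' their stated bound, e.g. `">1500"` becomes 1500) and parses the
#' remainder. Strings that cannot be parsed (e.g. `"See Comment"`) return
#' `NA`, the "dropped" state; dropping is a return value, never an error.
#'
#' @param value_raw Character vector of reported values.
#' @return Numeric vector, `NA` where the input is non-numeric.
#' @export
coerce_numeric <- function(value_raw) {
  x <- trimws(as.character(value_raw))
  x <- sub("^[<>]", "", x)
  x <- gsub(",", "", x)
  suppressWarnings(as.numeric(x))
}

trio_value_cols <- function(analytes) {
  slots <- c("prior", "current", "post", "delta_prior", "delta_post")
  unlist(lapply(tolower(analytes), function(a) paste0(a, "_", slots)))
}

#' Build CBC trios from longitudinal results
#'
#' A *draw* is a `(patient_id, drawn_at)` group reporting every requested
#' analyte simultaneously; incomplete draws never form the centre of a trio.
#' For each complete draw, the most recent earlier complete draw within
#' `window_h` hours supplies the prior values and (by default) the earliest
#' later complete draw within the window supplies the post values. Draws
#' lacking either neighbour produce no trio. Values are coerced with
#' [coerce_numeric()] first; non-numeric results are dropped, and exact
#' timestamp duplicates keep the highest `seq` (latest reported).
#'
#' @param results Long-format lab results (`patient_id`, `drawn_at`,
#'   `analyte`, `value_raw`, optionally `seq`).
#' @param window_h Neighbour window in hours, boundary inclusive.
#' @param analytes Analyte set forming a panel; default the CBC analytes.
#'   Pass [BMP_ANALYTES][analyte_codes] via `bmp_analytes()` semantics to
#'   build BMP "trios" for the cross-check module.
#' @param delta_mode `"absolute"` (default): `delta_prior = current - prior`,
#'   `delta_post = post - current`. `"relative"`: the same differences
#'   divided by the reference value (prior and current respectively).
#' @param post_rule `"earliest"` (default): the post draw is the earliest
#'   subsequent complete draw within the window — the next result a
#'   clinician saw. `"latest"`: the latest within the window.
#' @return A wide tibble, one row per trio: `trio_id`, `patient_id`,
#'   `t_prior`, `t_current`, `t_post`, and per analyte
#'   `{analyte}_{prior,current,post,delta_prior,delta_post}`. The analyte
#'   set and delta mode are attached as attributes.
#' @export
build_trios <- function(results, window_h = 48,
                        analytes = CBC_ANALYTES,
                        delta_mode = c("absolute", "relative"),
                        post_rule = c("earliest", "latest")) {
  delta_mode <- match.arg(delta_mode)
  post_rule <- match.arg(post_rule)
  if (window_h <= 0) stop_config("window_h must be > 0")
  empty <- empty_trios(analytes, delta_mode)
  if (is.null(results) || nrow(results) == 0) return(empty)
  if (!"seq" %in% names(results)) results$seq <- seq_len(nrow(results))

  res <- results %>%
    filter(.data$analyte %in% analytes) %>%
    mutate(value = coerce_numeric(.data$value_raw)) %>%
    filter(!is.na(.data$value)) %>%
    # duplicate (patient, time, analyte): keep the latest reported
    group_by(.data$patient_id, .data$drawn_at, .data$analyte) %>%
    slice_max(.data$seq, n = 1, with_ties = FALSE) %>%
    ungroup()
  if (nrow(res) == 0) return(empty)

  draws <- res %>%
    select("patient_id", "drawn_at", "analyte", "value") %>%
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  have <- intersect(analytes, names(draws))
  if (length(have) < length(analytes)) return(empty)
  draws <- draws[stats::complete.cases(draws[analytes]), , drop = FALSE] %>%
    arrange(.data$patient_id, .data$drawn_at)
  if (nrow(draws) == 0) return(empty)

  # neighbour indices per patient: prior = most recent earlier complete
  # draw (always the immediately preceding one); post = earliest or latest
  # subsequent complete draw within the window
  win <- window_h * 3600
  t_num <- as.numeric(draws$drawn_at)
  grp <- as.integer(factor(draws$patient_id, levels = unique(draws$patient_id)))
  i <- seq_len(nrow(draws))
  prior_idx <- ifelse(i > 1 & grp == lag(grp, default = 0L), i - 1L, NA_integer_)
  if (post_rule == "earliest") {
    post_idx <- ifelse(i < nrow(draws) & grp == lead(grp, default = 0L),
                       i + 1L, NA_integer_)
  } else {
    post_idx <- vapply(i, function(j) {
      ok <- which(grp == grp[j] & t_num > t_num[j] & t_num - t_num[j] <= win)
      if (length(ok)) max(ok) else NA_integer_
    }, integer(1))
  }
  keep <- !is.na(prior_idx) & !is.na(post_idx) &
    (t_num - t_num[replace(prior_idx, is.na(prior_idx), 1L)]) <= win &
    (t_num[replace(post_idx, is.na(post_idx), 1L)] - t_num) <= win
  if (!any(keep)) return(empty)

  out <- draws[keep, , drop = FALSE] %>% rename(t_current = "drawn_at")
  out$t_prior <- draws$drawn_at[prior_idx[keep]]
  out$t_post <- draws$drawn_at[post_idx[keep]]
  for (a in analytes) {
    names(out)[names(out) == a] <- paste0(tolower(a), "_current")
    out[[paste0(tolower(a), "_prior")]] <- draws[[a]][prior_idx[keep]]
    out[[paste0(tolower(a), "_post")]] <- draws[[a]][post_idx[keep]]
  }
  out$trio_id <- paste0(out$patient_id, "@",
                        format(out$t_current, "%Y-%m-%dT%H:%M", tz = "UTC"))
  out <- out %>% select("trio_id", "patient_id", "t_prior", "t_current",
                        "t_post", dplyr::all_of(paste0(
                          rep(tolower(analytes), each = 3),
                          c("_prior", "_current", "_post"))))
  compute_deltas(structure(out, analytes = analytes), mode = delta_mode)
}

empty_trios <- function(analytes, delta_mode = "absolute") {
  cols <- c("trio_id", "patient_id")
  out <- tibble(trio_id = character(), patient_id = character(),
                t_prior = as.POSIXct(character(), tz = "UTC"),
                t_current = as.POSIXct(character(), tz = "UTC"),
                t_post = as.POSIXct(character(), tz = "UTC"))
  for (col in trio_value_cols(analytes)) out[[col]] <- double()
  attr(out, "analytes") <- analytes
  attr(out, "delta_mode") <- delta_mode
  out
}

#' Recompute trio deltas
#'
#' Absolute mode stores signed differences (`current - prior`,
#' `post - current`) per analyte; relative mode divides those differences by
#' the reference value (the prior and the current result respectively). The
#' mode is recorded in the `"delta_mode"` attribute so feature construction
#' can document it.
#'
#' @param trios A trio table from [build_trios()].
#' @param mode `"absolute"` or `"relative"`.
#' @return The trio table with `{analyte}_delta_prior` / `_delta_post`
#'   recomputed.
#' @export
compute_deltas <- function(trios, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  analytes <- attr(trios, "analytes") %||% CBC_ANALYTES
  for (a in tolower(analytes)) {
    prior <- trios[[paste0(a, "_prior")]]
    current <- trios[[paste0(a, "_current")]]
    post <- trios[[paste0(a, "_post")]]
    if (mode == "absolute") {
      trios[[paste0(a, "_delta_prior")]] <- current - prior
      trios[[paste0(a, "_delta_post")]] <- post - current
    } else {
      if (any(prior == 0, na.rm = TRUE) || any(current == 0, na.rm = TRUE))
        stop_data("relative deltas undefined: zero reference value")
      trios[[paste0(a, "_delta_prior")]] <- (current - prior) / prior
      trios[[paste0(a, "_delta_post")]] <- (post - current) / current
    }
  }
  attr(trios, "analytes") <- analytes
  attr(trios, "delta_mode") <- mode
  trios
}

#' Write and read trio tables
#'
#' One row per trio, timestamps in ISO-8601 UTC; the analyte set and delta
#' mode round-trip via companion columns.
#'
#' @param trios A trio table.
#' @param path `.csv` or `.parquet` path.
#' @export
write_trios <- function(trios, path) {
  out <- trios %>%
    mutate(dplyr::across(c("t_prior", "t_current", "t_post"),
                         ~format(.x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  out$.analytes <- paste(attr(trios, "analytes") %||% CBC_ANALYTES, collapse = "|")
  out$.delta_mode <- attr(trios, "delta_mode") %||% "absolute"
  write_table(out, path)
}

#' @rdname write_trios
#' @export
read_trios <- function(path) {
  df <- if (is_parquet(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_usage("the arrow package is required for parquet input")
    as_tibble(arrow::read_parquet(path))
  } else {
    as_tibble(utils::read.csv(path, na.strings = "", colClasses = NA,
                              stringsAsFactors = FALSE))
  }
  analytes <- strsplit(df$.analytes[1], "|", fixed = TRUE)[[1]]
  mode <- df$.delta_mode[1]
  df <- df %>% select(-".analytes", -".delta_mode")
  for (col in c("t_prior", "t_current", "t_post"))
    df[[col]] <- as.POSIXct(df[[col]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (col in trio_value_cols(analytes)) df[[col]] <- as.numeric(df[[col]])
  if ("contaminated" %in% names(df)) df$contaminated <- as.integer(df$contaminated)
  if ("rho" %in% names(df)) df$rho <- as.numeric(df$rho)
  attr(df, "analytes") <- analytes
  attr(df, "delta_mode") <- mode
  df
}
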