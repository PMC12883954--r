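#' Quality-control configuration
#'
#' Thresholds for plausibility filtering and missing-data handling of
#' wearable daily summaries: resting heart rate outside [30, 120] bpm,
#' RMSSD above 200 ms or sleep efficiency above 100% are implausible and
#' removed; days with at most 10% missing values are linearly interpolated,
#' and participants with more than 10% missing days are excluded.
#'
#' @param rhr_min,rhr_max Plausible resting-heart-rate bounds (bpm).
#' @param hrv_max Maximum plausible RMSSD (ms).
#' @param sleep_eff_max Maximum plausible sleep efficiency (%).
#' @param day_missing_threshold Highest per-day missing-value fraction that
#'   is still imputed (0-1 scale).
#' @param participant_missing_threshold Highest per-participant
#'   missing-day fraction before exclusion (0-1 scale).
#' @return A list of class `"qc_config"`.
#' @export
qc_config <- function(rhr_min = 30, rhr_max = 120, hrv_max = 200,
                      sleep_eff_max = 100, day_missing_threshold = 0.10,
                      participant_missing_threshold = 0.10) {
  if (!(rhr_min < rhr_max))
    stop("invalid qc_config: rhr_min must be below rhr_max", call. = FALSE)
  for (f in c("day_missing_threshold", "participant_missing_threshold")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("invalid qc_config field '", f, "': must lie in (0, 1]",
           call. = FALSE)
  }
  structure(list(rhr_min = rhr_min, rhr_max = rhr_max, hrv_max = hrv_max,
                 sleep_eff_max = sleep_eff_max,
                 day_missing_threshold = day_missing_threshold,
                 participant_missing_threshold = participant_missing_threshold),
            class = "qc_config")
}

#' Flag and remove physiologically implausible daily records
#'
#' Removes participant-days whose resting heart rate, RMSSD or sleep
#' efficiency fall outside plausible ranges.  Fractions in the report are
#' computed on pre-filter totals; `NA` values are not treated as outliers
#' (missingness is handled by [impute_and_exclude()]).
#'
#' @param daily_table Data frame with at least `rhr`, `rmssd` and
#'   `sleep_efficiency` columns.
#' @param qc A [qc_config()].
#' @param n_minute_records Optional count of minute-level records in the
#'   same dataset; if given, the report also expresses the flagged count
#'   as a fraction of all records (days + minutes).
#' @return A list with `clean` (retained rows) and `report` (a
#'   `"qc_report"` with counts and fractions).
#' @examples
#' d <- data.frame(rhr = c(25, 60), rmssd = c(40, 40),
#'                 sleep_efficiency = c(90, 101))
#' flag_outliers(d, qc_config())$report$n_flagged_records
#' @export
flag_outliers <- function(daily_table, qc = qc_config(),
                          n_minute_records = NULL) {
  req <- c("rhr", "rmssd", "sleep_efficiency")
  miss <- setdiff(req, names(daily_table))
  if (length(miss))
    stop("daily table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- (!is.na(daily_table$rhr) &
            (daily_table$rhr < qc$rhr_min | daily_table$rhr > qc$rhr_max)) |
    (!is.na(daily_table$rmssd) & daily_table$rmssd > qc$hrv_max) |
    (!is.na(daily_table$sleep_efficiency) &
       daily_table$sleep_efficiency > qc$sleep_eff_max)
  n_total <- nrow(daily_table)
  report <- structure(list(
    n_total_records = n_total,
    n_flagged_records = sum(bad),
    n_retained_records = n_total - sum(bad),
    flagged_fraction = if (n_total > 0) sum(bad) / n_total else 0,
    flagged_fraction_incl_minutes =
      if (!is.null(n_minute_records) && n_total + n_minute_records > 0)
        sum(bad) / (n_total + n_minute_records) else NA_real_
  ), class = "qc_report")
  list(clean = daily_table[!bad, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (f in names(x))
    if (length(x[[f]]) <= 8)
      cat(sprintf("  %s: %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  invisible(x)
}

daily_measurement_cols <- function() {
  c("panas", "sleep_efficiency", "rmssd", "sdnn", "rhr", "waso",
    "total_sleep_time", "listening_duration", "mean_tempo",
    "valence", "arousal")
}

#' Impute missing values and exclude high-missingness participants
#'
#' A participant-day's missing fraction counts its missing minute samples
#' and missing daily measurements jointly.  Days at or below the day
#' threshold are retained and linearly interpolated over time (minutes
#' within the day, daily fields across days within the participant); days
#' above it count as missing days and are dropped.  Participants whose
#' missing-day fraction exceeds the participant threshold are excluded,
#' as is any participant left without an interpolation anchor.
#'
#' @param cohort A `"fatnet_cohort"`, typically after
#'   [inject_missingness()].
#' @param qc A [qc_config()].
#' @return A list with `cohort` (imputed, exclusions applied) and
#'   `report` (a `"qc_report"` with `n_imputed_days`, `n_dropped_days`,
#'   `excluded_participants` and reason codes).
#' @export
impute_and_exclude <- function(cohort, qc = qc_config()) {
  stopifnot(inherits(cohort, "fatnet_cohort"))
  meas <- intersect(daily_measurement_cols(), names(cohort$daily))
  T <- if (!is.null(cohort$config)) cohort$config$T else
    max(cohort$minutes$minute_index)

  key_m <- paste(cohort$minutes$participant_id, cohort$minutes$day_index)
  key_d <- paste(cohort$daily$participant_id, cohort$daily$day_index)
  na_min <- tapply(is.na(cohort$minutes$hr_bpm), key_m, sum)
  na_min <- as.integer(na_min[key_d])
  na_min[is.na(na_min)] <- 0L
  na_day <- rowSums(is.na(cohort$daily[, meas, drop = FALSE]))
  frac <- (na_min + na_day) / (T + length(meas))

  day_missing <- frac > qc$day_missing_threshold |
    isTRUE_vec(cohort$daily$day_missing)
  imputable <- frac > 0 & !day_missing

  excluded <- character(0); reasons <- character(0)
  for (p in unique(cohort$daily$participant_id)) {
    rows <- cohort$daily$participant_id == p
    miss_frac <- mean(day_missing[rows])
    if (miss_frac > qc$participant_missing_threshold) {
      excluded <- c(excluded, p)
      reasons <- c(reasons, "missing_days_exceed_threshold")
    } else if (sum(rows & !day_missing) == 1L && any(imputable[rows])) {
      # a single usable day with gaps has no flanking day to interpolate from
      obs_ok <- rows & !day_missing
      if (any(na_day[obs_ok] > 0)) {
        excluded <- c(excluded, p)
        reasons <- c(reasons, "single_day_uninterpolable")
      }
    }
  }

  n_imputed <- 0L
  for (i in which(imputable)) {
    p <- cohort$daily$participant_id[i]
    if (p %in% excluded) next
    d <- cohort$daily$day_index[i]
    if (na_min[i] > 0L) {
      sel <- cohort$minutes$participant_id == p & cohort$minutes$day_index == d
      hr <- cohort$minutes$hr_bpm[sel]
      cohort$minutes$hr_bpm[sel] <-
        zoo::na.approx(hr, x = cohort$minutes$minute_index[sel],
                       na.rm = FALSE, rule = 2)
    }
    n_imputed <- n_imputed + 1L
  }
  # daily fields: linear interpolation across days within participant
  for (p in setdiff(unique(cohort$daily$participant_id), excluded)) {
    rows <- which(cohort$daily$participant_id == p & !day_missing)
    if (length(rows) < 2L) next
    for (cc in meas) {
      v <- cohort$daily[[cc]][rows]
      if (anyNA(v) && sum(!is.na(v)) >= 2L)
        cohort$daily[[cc]][rows] <-
          zoo::na.approx(v, x = cohort$daily$day_index[rows],
                         na.rm = FALSE, rule = 2)
    }
  }

  keep <- !(cohort$daily$participant_id %in% excluded) & !day_missing
  n_dropped_days <- sum(day_missing & !(cohort$daily$participant_id %in%
                                          excluded))
  key_keep <- key_d[keep]
  cohort$daily <- cohort$daily[keep, , drop = FALSE]
  cohort$daily$day_missing <- FALSE
  cohort$minutes <- cohort$minutes[key_m %in% key_keep, , drop = FALSE]
  cohort$truth <- cohort$truth[
    paste(cohort$truth$participant_id, cohort$truth$day_index) %in% key_keep,
    , drop = FALSE]
  cohort$profiles <- cohort$profiles[
    !(cohort$profiles$participant_id %in% excluded), , drop = FALSE]
  rownames(cohort$daily) <- rownames(cohort$minutes) <-
    rownames(cohort$truth) <- rownames(cohort$profiles) <- NULL

  report <- structure(list(
    n_imputed_days = n_imputed,
    n_dropped_days = n_dropped_days,
    excluded_participants = excluded,
    exclusion_reasons = reasons
  ), class = "qc_report")
  list(cohort = cohort, report = report)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Engineer day-level features
#'
#' Adds the derived predictors used by all models: `delta_hrv`, the
#' day-to-day change in RMSSD (ms; 0 on each participant's first retained
#' day, the no-change prior); `listening_intensity`, BPM-weighted
#' listening duration (min x BPM); and `sleep_fragmentation`, WASO divided
#' by total sleep time (unitless).  A zero total sleep time leaves
#' fragmentation undefined: the record is flagged in `frag_undefined`
#' rather than divided.
#'
#' @param daily_table Data frame with `participant_id`, `day_index`,
#'   `rmssd`, `listening_duration`, `mean_tempo`, `waso` and
#'   `total_sleep_time` columns.
#' @return The table with `delta_hrv`, `listening_intensity`,
#'   `sleep_fragmentation` and `frag_undefined` columns appended.
#' @examples
#' d <- data.frame(participant_id = "P1", day_index = 1:2,
#'                 rmssd = c(40, 45), listening_duration = c(30, 10),
#'                 mean_tempo = c(120, 100), waso = c(30, 20),
#'                 total_sleep_time = c(400, 410))
#' engineer_features(d)$delta_hrv
#' @export
engineer_features <- function(daily_table) {
  req <- c("participant_id", "day_index", "rmssd", "listening_duration",
           "mean_tempo", "waso", "total_sleep_time")
  miss <- setdiff(req, names(daily_table))
  if (length(miss))
    stop("daily table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ord <- order(daily_table$participant_id, daily_table$day_index)
  daily_table <- daily_table[ord, , drop = FALSE]
  dh <- stats::ave(daily_table$rmssd, daily_table$participant_id,
                   FUN = function(v) c(0, diff(v)))
  daily_table$delta_hrv <- dh
  daily_table$listening_intensity <-
    daily_table$listening_duration * daily_table$mean_tempo
  tst <- daily_table$total_sleep_time
  undef <- !is.na(tst) & tst == 0
  frag <- rep(NA_real_, nrow(daily_table))
  ok <- !is.na(tst) & tst > 0
  frag[ok] <- daily_table$waso[ok] / tst[ok]
  daily_table$sleep_fragmentation <- frag
  daily_table$frag_undefined <- undef
  rownames(daily_table) <- NULL
  daily_table
}

#' Standardize continuous features with explicit fit/apply semantics
#'
#' `z = (x - mu) / sigma` with the sample-standard-deviation convention.
#' With `stats = NULL` the location and scale are fitted on `table` (the
#' fitting split) and returned for reuse; passing a previously fitted
#' `"feature_stats"` applies those statistics unchanged, which is how
#' validation and test data must be transformed to avoid leakage.
#'
#' @param table Data frame of features.
#' @param stats `NULL` to fit, or a `"feature_stats"` object to apply.
#' @param cols Character vector of columns to standardize; by default all
#'   numeric columns with more than two distinct values.
#' @return A list with `table` (standardized) and `stats` (a
#'   `"feature_stats"` with `mu`, `sigma`, `cols` and a `provenance`
#'   attribute recording the fitting call).
#' @examples
#' standardize_features(data.frame(x = c(1, 2, 3)))$table$x
#' @export
standardize_features <- function(table, stats = NULL, cols = NULL) {
  if (is.null(stats)) {
    if (is.null(cols)) {
      num <- vapply(table, is.numeric, TRUE)
      nuniq <- vapply(table, function(v) length(unique(v[!is.na(v)])), 0L)
      cols <- names(table)[num & nuniq > 2L]
    }
    mu <- vapply(table[cols], function(v) mean(v, na.rm = TRUE), 0)
    sigma <- vapply(table[cols], function(v) stats::sd(v, na.rm = TRUE), 0)
    if (any(!is.finite(sigma) | sigma == 0))
      stop("constant column(s) cannot be standardized: ",
           paste(cols[!is.finite(sigma) | sigma == 0], collapse = ", "),
           call. = FALSE)
    stats <- structure(list(mu = mu, sigma = sigma, cols = cols),
                       class = "feature_stats",
                       provenance = "fitted")
  } else {
    if (!inherits(stats, "feature_stats"))
      stop("stats must be NULL or a 'feature_stats' object", call. = FALSE)
    cols <- stats$cols
    miss <- setdiff(cols, names(table))
    if (length(miss))
      stop("table is missing fitted column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cc in cols)
    table[[cc]] <- (table[[cc]] - stats$mu[[cc]]) / stats$sigma[[cc]]
  list(table = table, stats = stats)
}
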