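#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set controlling [generate_cohort()].
#' The defaults emulate the study conditions the package is designed around:
#' a cohort of community-dwelling adults aged 60+ observed for 45 +/- 10 days
#' each, with a latent daily-wellness factor driving correlated
#' PANAS/sleep/HRV components and a minute-level music-heart-rate interaction
#' that carries next-day predictive signal.
#'
#' @param n_participants Number of participants (>= 1).
#' @param days_mean,days_sd Mean and SD of the per-participant day count
#'   (normal draw, rounded, truncated at a minimum of 7 days).
#' @param T Minutes per daily observation window (>= 10).  240 by default
#'   (a music-relevant afternoon window); 1440 gives full days.
#' @param ar_rho AR(1) coefficient of the latent wellness process, in [0, 1).
#' @param component_loading Loading of latent wellness on each of the three
#'   score components (PANAS, sleep efficiency, RMSSD), in (0, 1].
#' @param rating_loading Loading of latent wellness on the 1-10 global
#'   health rating, in (0, 1].
#' @param music_effect_beta Weight of the standardized minute-level
#'   music-HR interaction count on next-day wellness.  The default
#'   `sqrt(0.35)` makes the interaction contribute an R-squared increment
#'   of 0.35 for next-day wellness over the persistence-only predictor.
#' @param dip_response_prob Probability that, on a day with at least one
#'   high-tempo music block, one such block elicits the rise-then-dip
#'   heart-rate response.
#' @param missing_day_rate,missing_minute_rate Missingness probabilities
#'   used by [inject_missingness()], both in [0, 1].
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#'
#' @return A list of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_participants = 5, days_mean = 10, T = 120, seed = 1)
#' @export
cohort_config <- function(n_participants = 92L,
                          days_mean = 45,
                          days_sd = 10,
                          T = 240L,
                          ar_rho = 0.5,
                          component_loading = sqrt(0.5),
                          rating_loading = sqrt(0.9),
                          music_effect_beta = sqrt(0.35),
                          dip_response_prob = 0.5,
                          missing_day_rate = 0,
                          missing_minute_rate = 0,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    days_mean = days_mean, days_sd = days_sd, T = as.integer(T),
    ar_rho = ar_rho, component_loading = component_loading,
    rating_loading = rating_loading, music_effect_beta = music_effect_beta,
    dip_response_prob = dip_response_prob,
    missing_day_rate = missing_day_rate,
    missing_minute_rate = missing_minute_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid cohort_config field '", field, "': ", why,
                  call. = FALSE)
  }
  chk(length(cfg$n_participants) == 1L && !is.na(cfg$n_participants) &&
        cfg$n_participants >= 1L, "n_participants", "must be >= 1")
  chk(is.numeric(cfg$days_mean) && cfg$days_mean > 0, "days_mean",
      "must be positive")
  chk(is.numeric(cfg$days_sd) && cfg$days_sd >= 0, "days_sd",
      "must be non-negative")
  chk(cfg$T >= 10L, "T", "must be >= 10 minutes")
  chk(is.numeric(cfg$ar_rho) && cfg$ar_rho >= 0 && cfg$ar_rho < 1,
      "ar_rho", "must lie in [0, 1)")
  chk(cfg$component_loading > 0 && cfg$component_loading <= 1,
      "component_loading", "must lie in (0, 1]")
  chk(cfg$rating_loading > 0 && cfg$rating_loading <= 1,
      "rating_loading", "must lie in (0, 1]")
  chk(is.numeric(cfg$music_effect_beta) && cfg$music_effect_beta >= 0,
      "music_effect_beta", "must be non-negative")
  chk(cfg$ar_rho^2 + cfg$music_effect_beta^2 < 1, "music_effect_beta",
      "ar_rho^2 + music_effect_beta^2 must be < 1 for unit wellness variance")
  for (f in c("dip_response_prob", "missing_day_rate", "missing_minute_rate"))
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f,
        "must lie in [0, 1]")
  invisible(cfg)
}

## Trailing mean of hr over the most recent (up to 30) music-off minutes,
## needing at least 5 observed off-minutes; NA where unavailable.
rolling_off_baseline <- function(hr, music_on, window = 30L, min_obs = 5L) {
  T <- length(hr)
  off_idx <- which(music_on == 0L)
  base <- rep(NA_real_, T)
  if (length(off_idx) == 0L) return(base)
  cs <- cumsum(hr[off_idx])
  # k[t] = number of off-minutes strictly before minute t
  k <- findInterval(seq_len(T) - 1L, off_idx)
  ok <- k >= min_obs
  lo <- pmax(k - window, 0L)
  prev <- numeric(T)
  prev[lo > 0L] <- cs[lo[lo > 0L]]
  base[ok] <- (cs[k[ok]] - prev[ok]) / (k[ok] - lo[ok])
  base
}

## One day's minute stream: baseline + circadian + AR(1) noise + music-block
## effects.  Returns hr, music_on, per-minute block tempo, and whether the
## day's response dip occurred.
simulate_day_minutes <- function(T, baseline_rhr, pref_tempo,
                                 dip_response_prob, start_minute = 540) {
  n_blocks <- sample.int(3L, 1L)
  starts <- integer(0); lens <- integer(0)
  for (b in seq_len(n_blocks)) {
    for (try in 1:20) {
      len <- sample(25:50, 1L)
      if (len + 2L >= T) len <- max(10L, T - 3L)
      st <- sample.int(max(1L, T - len), 1L)
      if (!length(starts) ||
          all(st > starts + lens + 5L | st + len + 5L < starts)) {
        starts <- c(starts, st); lens <- c(lens, len)
        break
      }
    }
  }
  n_blocks <- length(starts)
  # track tempos sit mostly above individual preferences (stimulating
  # playlists), so the response opportunity is near-constant across days
  # and daily tempo/duration summaries carry almost no information about
  # whether a dip occurred
  tempos <- pmin(pmax(stats::rnorm(n_blocks, 120, 15), 60), 180)

  music_on <- integer(T)
  tempo_min <- rep(NA_real_, T)
  effect <- numeric(T)
  qual <- which(tempos > pref_tempo)
  responder <- if (length(qual) && stats::runif(1) < dip_response_prob)
    qual[sample.int(length(qual), 1L)] else 0L
  dip <- FALSE
  for (b in seq_len(n_blocks)) {
    idx <- starts[b]:(starts[b] + lens[b] - 1L)
    music_on[idx] <- 1L
    tempo_min[idx] <- tempos[b]
    if (b == responder) {
      rise_len <- min(5L, lens[b])
      effect[idx[seq_len(rise_len)]] <- 5
      if (lens[b] > rise_len + 1L) {
        dip_len <- min(sample(15:35, 1L), lens[b] - rise_len)
        effect[idx[rise_len + seq_len(dip_len)]] <- -8
        dip <- TRUE
      }
    } else {
      effect[idx] <- 1
    }
  }
  # spontaneous bradycardia-like episodes (rest/naps) on every day, placed
  # outside music blocks: day-level HR mean/SD then carry no information
  # about whether the music-coincident response dip occurred - only the
  # minute-level conjunction (dip AND music AND high tempo) does
  n_spont <- sample.int(3L, 1L)
  for (sblk in seq_len(n_spont)) {
    for (try in 1:20) {
      slen <- sample(15:35, 1L)
      if (slen + 2L >= T) break
      st <- sample.int(T - slen, 1L)
      sidx <- st:(st + slen - 1L)
      if (!any(music_on[sidx] == 1L)) {
        effect[sidx] <- effect[sidx] - 8
        break
      }
    }
  }
  circ <- 2 * sin(2 * pi * (start_minute + seq_len(T)) / 1440)
  noise <- as.numeric(stats::arima.sim(list(ar = 0.8), n = T,
                                       sd = 1.0 * sqrt(1 - 0.8^2)))
  hr <- round(baseline_rhr + circ + noise + effect, 1)
  list(hr = hr, music_on = music_on, tempo_min = tempo_min,
       tempos = tempos, starts = starts, lens = lens, dip = dip)
}

#' Generate a synthetic wearable-music cohort
#'
#' Simulates a cohort of older adults with minute-resolution heart-rate and
#' music on/off streams plus daily summary measurements.  A latent
#' daily-wellness AR(1) factor `w` (stationary unit variance) drives three
#' correlated score components (PANAS positive affect, sleep efficiency,
#' resting RMSSD) and a 1-10 global health rating.  Minute streams are
#' exogenous: on some days one high-tempo music block elicits a heart-rate
#' rise followed by a multi-minute dip below the listener's rolling baseline;
#' the standardized count of such dip minutes (`g`) feeds next-day wellness
#' with weight `music_effect_beta`, so the minute stream carries predictive
#' signal that the daily summaries do not encode.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `"fatnet_cohort"`: a list with data frames
#'   `profiles`, `minutes` (long format: participant_id, day_index,
#'   minute_index, hr_bpm, music_on), `daily` (one row per participant-day),
#'   `truth` (latent wellness, dip-minute counts and ratings; test-only,
#'   never a model feature), and the `config` used.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 3, days_mean = 8,
#'                                      days_sd = 0, T = 60, seed = 7))
#' head(coh$daily)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  np <- config$n_participants
  T <- config$T

  profiles <- data.frame(
    participant_id = sprintf("P%03d", seq_len(np)),
    age = pmax(60L, as.integer(round(stats::rnorm(np, 67.8, 5.1)))),
    gender = sample(c("female", "male"), np, TRUE, prob = c(0.58, 0.42)),
    bmi = round(pmin(pmax(stats::rnorm(np, 26.4, 3.8), 15), 55), 1),
    hypertension = as.integer(stats::runif(np) < 0.45),
    diabetes = as.integer(stats::runif(np) < 0.2),
    baseline_rhr = round(pmin(pmax(stats::rnorm(np, 66, 6), 48), 90), 1),
    music_preference_tempo = round(stats::rnorm(np, 100, 8), 1),
    stringsAsFactors = FALSE
  )
  n_days <- pmax(7L, as.integer(round(stats::rnorm(np, config$days_mean,
                                                   config$days_sd))))

  ## Pass 1: exogenous minute streams and raw dip-minute counts g.
  minute_list <- vector("list", np)
  day_meta <- vector("list", np)
  for (p in seq_len(np)) {
    nd <- n_days[p]
    hr_mat <- matrix(0, nrow = T, ncol = nd)
    mus_mat <- matrix(0L, nrow = T, ncol = nd)
    g_raw <- numeric(nd)
    dur <- numeric(nd); tempo_day <- numeric(nd)
    for (d in seq_len(nd)) {
      dm <- simulate_day_minutes(T, profiles$baseline_rhr[p],
                                 profiles$music_preference_tempo[p],
                                 config$dip_response_prob)
      hr_mat[, d] <- dm$hr
      mus_mat[, d] <- dm$music_on
      base <- rolling_off_baseline(dm$hr, dm$music_on)
      g_raw[d] <- sum(dm$music_on == 1L &
                        !is.na(dm$tempo_min) &
                        dm$tempo_min > profiles$music_preference_tempo[p] &
                        !is.na(base) & dm$hr < base - 2.5)
      dur[d] <- sum(dm$lens)
      tempo_day[d] <- round(sum(dm$tempos * dm$lens) / sum(dm$lens), 1)
    }
    minute_list[[p]] <- list(hr = hr_mat, music = mus_mat)
    day_meta[[p]] <- data.frame(g_raw = g_raw, listening_duration = dur,
                                mean_tempo = tempo_day)
  }

  ## Cohort-wide standardization of the interaction count.
  all_g <- unlist(lapply(day_meta, `[[`, "g_raw"))
  g_mu <- mean(all_g); g_sd <- stats::sd(all_g)
  if (!is.finite(g_sd) || g_sd == 0) g_sd <- 1
  v_g <- stats::var((all_g - g_mu) / g_sd)   # 1, or 0 when degenerate

  ## Pass 2: latent wellness recursion, components, ratings, summaries.
  ## Innovation variance keeps the stationary wellness variance at 1 even
  ## when the observation window is too short for music sessions (v_g = 0).
  lam <- config$component_loading
  rl <- config$rating_loading
  beta <- config$music_effect_beta
  eta_sd <- sqrt(max(0, 1 - config$ar_rho^2 - beta^2 * v_g))
  daily <- vector("list", np); truth <- vector("list", np)
  minutes <- vector("list", np)
  for (p in seq_len(np)) {
    nd <- n_days[p]
    g_std <- (day_meta[[p]]$g_raw - g_mu) / g_sd
    w <- numeric(nd)
    w[1] <- stats::rnorm(1)
    if (nd > 1) for (d in 2:nd)
      w[d] <- config$ar_rho * w[d - 1] + beta * g_std[d - 1] +
        stats::rnorm(1, sd = eta_sd)
    e <- matrix(stats::rnorm(3 * nd), nd)
    z <- lam * w + sqrt(1 - lam^2) * e
    panas <- pmin(pmax(as.integer(round(30 + 6 * z[, 1])), 10L), 50L)
    sleff <- round(pmin(pmax(85 + 7 * z[, 2], 40), 100), 1)
    rmssd <- round(pmin(pmax(35 + 10 * z[, 3], 5), 199), 1)
    rating <- pmin(pmax(as.integer(round(
      5.5 + 1.5 * (rl * w + sqrt(1 - rl^2) * stats::rnorm(nd)))), 1L), 10L)
    sdnn <- round(pmin(pmax(1.3 * rmssd + stats::rnorm(nd, 0, 5), 10), 250), 1)
    rhr <- round(profiles$baseline_rhr[p] + stats::rnorm(nd, 0, 2), 1)
    tst <- pmin(pmax(as.integer(round(stats::rnorm(nd, 420, 30))), 240L), 600L)
    tib <- tst / (sleff / 100)
    waso <- round(pmax(0, (tib - tst) * 0.8), 1)
    valence <- round(pmin(pmax(stats::rnorm(nd, 5.5, 1.5), 1), 9), 1)
    arousal <- round(pmin(pmax(stats::rnorm(nd, 5.0, 1.5), 1), 9), 1)
    daily[[p]] <- data.frame(
      participant_id = profiles$participant_id[p], day_index = seq_len(nd),
      panas = panas, sleep_efficiency = sleff, rmssd = rmssd, sdnn = sdnn,
      rhr = rhr, waso = waso, total_sleep_time = tst,
      listening_duration = day_meta[[p]]$listening_duration,
      mean_tempo = day_meta[[p]]$mean_tempo,
      valence = valence, arousal = arousal,
      age = profiles$age[p], gender = profiles$gender[p],
      bmi = profiles$bmi[p], hypertension = profiles$hypertension[p],
      diabetes = profiles$diabetes[p], day_missing = FALSE,
      stringsAsFactors = FALSE
    )
    truth[[p]] <- data.frame(
      participant_id = profiles$participant_id[p], day_index = seq_len(nd),
      wellness = w, g_raw = day_meta[[p]]$g_raw, g_std = g_std,
      rating = rating, stringsAsFactors = FALSE
    )
    minutes[[p]] <- data.frame(
      participant_id = profiles$participant_id[p],
      day_index = rep(seq_len(nd), each = T),
      minute_index = rep(seq_len(T), nd),
      hr_bpm = as.numeric(minute_list[[p]]$hr),
      music_on = as.integer(minute_list[[p]]$music),
      stringsAsFactors = FALSE
    )
  }

  out <- list(profiles = profiles,
              minutes = do.call(rbind, minutes),
              daily = do.call(rbind, daily),
              truth = do.call(rbind, truth),
              config = config)
  rownames(out$daily) <- rownames(out$truth) <- rownames(out$minutes) <- NULL
  class(out) <- "fatnet_cohort"
  out
}

#' @export
print.fatnet_cohort <- function(x, ...) {
  cat("Synthetic wearable-music cohort\n")
  cat(sprintf("  participants: %d\n", nrow(x$profiles)))
  cat(sprintf("  participant-days: %d\n", nrow(x$daily)))
  cat(sprintf("  minutes/day (T): %d\n", x$config$T))
  cat(sprintf("  missing days flagged: %d\n", sum(x$daily$day_missing)))
  invisible(x)
}

#' Inject missing data into a cohort
#'
#' Marks whole days and individual minutes missing at the configured rates,
#' emulating non-wear and dropout.  A missing day has all its daily
#' measurements and minute samples set to `NA` and is flagged in
#' `daily$day_missing`; a missing minute has `hr_bpm` set to `NA`.
#' Latent truth records are never masked.
#'
#' @param cohort A `"fatnet_cohort"` object.
#' @param config A [cohort_config()]; only `missing_day_rate` and
#'   `missing_minute_rate` are used (draws come from the current RNG
#'   stream, so seed via [set.seed()] for reproducibility).
#' @return The cohort with missingness applied.
#' @export
inject_missingness <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "fatnet_cohort"))
  for (f in c("missing_day_rate", "missing_minute_rate"))
    if (config[[f]] < 0 || config[[f]] > 1)
      stop("invalid cohort_config field '", f, "': must lie in [0, 1]",
           call. = FALSE)
  if (config$missing_day_rate > 0) {
    miss <- stats::runif(nrow(cohort$daily)) < config$missing_day_rate
    cohort$daily$day_missing <- cohort$daily$day_missing | miss
    meas <- c("panas", "sleep_efficiency", "rmssd", "sdnn", "rhr", "waso",
              "total_sleep_time", "listening_duration", "mean_tempo",
              "valence", "arousal")
    cohort$daily[miss, meas] <- NA
    key_m <- paste(cohort$minutes$participant_id, cohort$minutes$day_index)
    key_d <- paste(cohort$daily$participant_id, cohort$daily$day_index)
    cohort$minutes$hr_bpm[key_m %in% key_d[miss]] <- NA_real_
  }
  if (config$missing_minute_rate > 0) {
    miss_m <- stats::runif(nrow(cohort$minutes)) < config$missing_minute_rate
    cohort$minutes$hr_bpm[miss_m] <- NA_real_
  }
  cohort
}

#' Export / import a cohort as plain CSV files
#'
#' `export_cohort()` writes `cohort_profiles.csv`, `cohort_minutes.csv`,
#' `cohort_daily.csv`, `cohort_truth.csv` and a `cohort_config.json`
#' sidecar into `path`.  `import_cohort()` reads them back; the round trip
#' is exact on all feature fields.  The truth file is a test-only oracle
#' and is never consumed by model code.
#'
#' @param cohort A `"fatnet_cohort"` object.
#' @param path Directory to write to / read from (created if needed).
#' @return `export_cohort()` returns `path` invisibly; `import_cohort()`
#'   returns a `"fatnet_cohort"`.
#' @export
export_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fatnet_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$profiles, file.path(path, "cohort_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$minutes, file.path(path, "cohort_minutes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$daily, file.path(path, "cohort_daily.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(path, "cohort_truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(unclass(cfg), file.path(path, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_csv_checked <- function(file, required) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  x <- tryCatch(utils::read.csv(file, stringsAsFactors = FALSE),
                error = function(e)
                  stop("parse error in ", basename(file), ": ",
                       conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("file ", basename(file), " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x
}

#' @rdname export_cohort
#' @export
import_cohort <- function(path) {
  profiles <- read_csv_checked(
    file.path(path, "cohort_profiles.csv"),
    c("participant_id", "age", "gender", "bmi", "baseline_rhr",
      "music_preference_tempo"))
  minutes <- read_csv_checked(
    file.path(path, "cohort_minutes.csv"),
    c("participant_id", "day_index", "minute_index", "hr_bpm", "music_on"))
  daily <- read_csv_checked(
    file.path(path, "cohort_daily.csv"),
    c("participant_id", "day_index", "panas", "sleep_efficiency", "rmssd"))
  truth <- read_csv_checked(
    file.path(path, "cohort_truth.csv"),
    c("participant_id", "day_index", "wellness", "g_std", "rating"))
  cfgfile <- file.path(path, "cohort_config.json")
  config <- NULL
  if (file.exists(cfgfile)) {
    config <- jsonlite::read_json(cfgfile, simplifyVector = TRUE)
    class(config) <- "cohort_config"
  }
  if ("day_missing" %in% names(daily))
    daily$day_missing <- as.logical(daily$day_missing)
  out <- list(profiles = profiles, minutes = minutes, daily = daily,
              truth = truth, config = config)
  class(out) <- "fatnet_cohort"
  out
}
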