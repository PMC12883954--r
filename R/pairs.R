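#' Build next-day prediction pairs
#'
#' Assembles the supervised dataset for all forecasting models: each
#' sample pairs the minute-level streams and daily summary features of
#' day *i* with the composite Health Score of day *i+1* of the same
#' participant.  Pairs are formed only for strictly consecutive day
#' indices and never cross participants, so each participant's last day
#' is never an input's target-free end and their first day is never a
#' target's own input.
#'
#' @param daily Engineered daily table (see [engineer_features()]),
#'   one row per retained participant-day.
#' @param minutes Long-format minute table aligned with `daily`
#'   (`participant_id`, `day_index`, `minute_index`, `hr_bpm`,
#'   `music_on`).
#' @param score Numeric target vector aligned with the rows of `daily`
#'   (typically `health_score(daily)$score`).
#' @param T Minutes per day window; inferred from `minutes` when `NULL`.
#' @return An object of class `"fatnet_dataset"`: a list with
#'   `x_min` (N x T x 2 array: heart rate, music on/off), `x_day`
#'   (N x d_ds numeric feature matrix), `y` (length-N targets),
#'   `participant_id`, `day_index` (the input day), and a
#'   `continuous` attribute marking which daily columns are continuous.
#' @export
build_pairs <- function(daily, minutes, score, T = NULL) {
  if (length(score) != nrow(daily))
    stop("score must align with the rows of daily", call. = FALSE)
  if (is.null(T)) T <- max(minutes$minute_index)
  ord <- order(daily$participant_id, daily$day_index)
  daily <- daily[ord, , drop = FALSE]
  score <- score[ord]

  key_d <- paste(daily$participant_id, daily$day_index)
  key_next <- paste(daily$participant_id, daily$day_index + 1L)
  nxt <- match(key_next, key_d)
  in_rows <- which(!is.na(nxt))
  if (!length(in_rows)) stop("no consecutive-day pairs found", call. = FALSE)

  ## minute array for the input days
  mkey <- paste(minutes$participant_id, minutes$day_index)
  pos_day <- match(mkey, key_d[in_rows])
  sel <- !is.na(pos_day)
  N <- length(in_rows)
  hr <- matrix(NA_real_, T, N)
  mus <- matrix(0, T, N)
  idx <- (pos_day[sel] - 1L) * T + minutes$minute_index[sel]
  hr[idx] <- minutes$hr_bpm[sel]
  mus[idx] <- minutes$music_on[sel]
  x_min <- array(0, dim = c(N, T, 2L),
                 dimnames = list(NULL, NULL, c("hr_bpm", "music_on")))
  x_min[, , 1L] <- t(hr)
  x_min[, , 2L] <- t(mus)

  x_day <- daily_feature_matrix(daily[in_rows, , drop = FALSE])
  out <- list(x_min = x_min, x_day = x_day$x, y = score[nxt[in_rows]],
              participant_id = daily$participant_id[in_rows],
              day_index = daily$day_index[in_rows])
  attr(out, "continuous") <- x_day$continuous
  attr(out, "split") <- NA_character_
  class(out) <- "fatnet_dataset"
  out
}

## Fixed model feature set: engineered daily summaries + demographics.
daily_feature_matrix <- function(daily) {
  cont_cols <- c("panas", "sleep_efficiency", "rmssd", "sdnn", "rhr",
                 "waso", "total_sleep_time", "listening_duration",
                 "mean_tempo", "valence", "arousal", "delta_hrv",
                 "listening_intensity", "sleep_fragmentation",
                 "age", "bmi")
  bin_cols <- c("hypertension", "diabetes")
  cont_cols <- intersect(cont_cols, names(daily))
  bin_cols <- intersect(bin_cols, names(daily))
  x <- as.matrix(daily[, c(cont_cols, bin_cols), drop = FALSE])
  if ("gender" %in% names(daily)) {
    x <- cbind(x, gender_female = as.numeric(daily$gender == "female"))
    bin_cols <- c(bin_cols, "gender_female")
  }
  storage.mode(x) <- "double"
  list(x = x, continuous = colnames(x) %in% cont_cols)
}

## channel ch of the minute array as an N x T matrix (robust to N = 1)
channel_matrix <- function(ds, ch) {
  matrix(ds$x_min[, , ch], nrow = dim(ds$x_min)[1])
}

#' Number of samples in a dataset
#' @param ds A `"fatnet_dataset"`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) length(ds$y)

#' Subset a dataset by sample index
#' @param ds A `"fatnet_dataset"`.
#' @param idx Integer or logical sample index.
#' @return The subsetted `"fatnet_dataset"`.
#' @export
dataset_subset <- function(ds, idx) {
  out <- list(x_min = ds$x_min[idx, , , drop = FALSE],
              x_day = ds$x_day[idx, , drop = FALSE],
              y = ds$y[idx],
              participant_id = ds$participant_id[idx],
              day_index = ds$day_index[idx])
  if (!is.null(ds$provenance)) out$provenance <- ds$provenance[idx]
  attributes(out)[c("continuous", "split")] <-
    attributes(ds)[c("continuous", "split")]
  class(out) <- "fatnet_dataset"
  out
}

#' Concatenate datasets sample-wise
#' @param ... `"fatnet_dataset"` objects with identical schemas.
#' @return The combined `"fatnet_dataset"`.
#' @export
dataset_bind <- function(...) {
  parts <- list(...)
  x_min <- do.call(abind_1, lapply(parts, `[[`, "x_min"))
  out <- list(x_min = x_min,
              x_day = do.call(rbind, lapply(parts, `[[`, "x_day")),
              y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
              participant_id = unlist(lapply(parts, `[[`, "participant_id"),
                                      use.names = FALSE),
              day_index = unlist(lapply(parts, `[[`, "day_index"),
                                 use.names = FALSE))
  prov <- lapply(parts, function(p)
    if (is.null(p$provenance)) rep("original", n_samples(p)) else p$provenance)
  out$provenance <- unlist(prov, use.names = FALSE)
  attributes(out)[c("continuous", "split")] <-
    attributes(parts[[1]])[c("continuous", "split")]
  class(out) <- "fatnet_dataset"
  out
}

## bind 3-d arrays along the first margin
abind_1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0))
  out <- array(0, dim = c(n, d[2], d[3]), dimnames = dimnames(arrs[[1]]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.fatnet_dataset <- function(x, ...) {
  cat(sprintf(
    "fatnet_dataset: %d samples, T = %d minutes x %d channels, %d daily features\n",
    n_samples(x), dim(x$x_min)[2], dim(x$x_min)[3], ncol(x$x_day)))
  if (!is.null(x$provenance))
    print(table(x$provenance))
  invisible(x)
}
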