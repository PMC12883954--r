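#' Augmentation configuration
#'
#' Parameters of the four training-set augmentation techniques: Gaussian
#' jittering (noise SD = 2% of each feature's training range), time
#' warping (stretch factor uniform in [0.9, 1.1]), magnitude scaling
#' (scale factor uniform in [0.9, 1.1]) and SMOTE in composite
#' health-score space (k = 5 nearest neighbours).
#'
#' @param jitter_sigma_frac Noise SD as a fraction of the per-feature
#'   training range, in [0, 1).
#' @param warp_factor_range,scale_factor_range Two-element positive,
#'   well-ordered ranges.
#' @param smote_k Neighbour count for SMOTE (>= 1).
#' @param seed RNG seed used by [augment_fourfold()].
#' @return A list of class `"augmentation_config"`.
#' @export
augmentation_config <- function(jitter_sigma_frac = 0.02,
                                warp_factor_range = c(0.9, 1.1),
                                scale_factor_range = c(0.9, 1.1),
                                smote_k = 5L, seed = 1L) {
  if (jitter_sigma_frac < 0 || jitter_sigma_frac >= 1)
    stop("jitter_sigma_frac must lie in [0, 1)", call. = FALSE)
  for (rng in list(warp_factor_range, scale_factor_range))
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2])
      stop("factor ranges must be positive and well-ordered", call. = FALSE)
  if (smote_k < 1) stop("smote_k must be >= 1", call. = FALSE)
  structure(list(jitter_sigma_frac = jitter_sigma_frac,
                 warp_factor_range = warp_factor_range,
                 scale_factor_range = scale_factor_range,
                 smote_k = as.integer(smote_k), seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Per-feature training ranges used for jitter calibration
#'
#' @param ds A training-split `"fatnet_dataset"`.
#' @return A list with `day` (named range per continuous daily feature)
#'   and `hr` (range of the heart-rate channel).
#' @export
feature_ranges <- function(ds) {
  cont <- attr(ds, "continuous")
  rng <- apply(ds$x_day[, cont, drop = FALSE], 2,
               function(v) diff(range(v, na.rm = TRUE)))
  list(day = rng, hr = diff(range(channel_matrix(ds, 1), na.rm = TRUE)))
}

#' Jittering: Gaussian noise on continuous features
#'
#' Adds independent Gaussian noise with SD equal to
#' `jitter_sigma_frac` times the training range of each continuous
#' feature - per daily feature and per heart-rate minute.  Binary fields
#' (music on/off, comorbidities, gender) are untouched, zero-range
#' features receive no noise, and targets are unchanged.
#'
#' @param ds A `"fatnet_dataset"`.
#' @param config An [augmentation_config()].
#' @param ranges Training-range list from [feature_ranges()]; defaults
#'   to ranges of `ds` itself.
#' @return The jittered dataset with provenance `"jitter"`.
#' @export
jitter_samples <- function(ds, config = augmentation_config(),
                           ranges = feature_ranges(ds)) {
  n <- n_samples(ds)
  cont_idx <- which(attr(ds, "continuous"))
  for (j in seq_along(cont_idx)) {
    s <- config$jitter_sigma_frac * ranges$day[j]
    if (is.finite(s) && s > 0)
      ds$x_day[, cont_idx[j]] <- ds$x_day[, cont_idx[j]] +
        stats::rnorm(n, 0, s)
  }
  s_hr <- config$jitter_sigma_frac * ranges$hr
  if (is.finite(s_hr) && s_hr > 0)
    ds$x_min[, , 1] <- ds$x_min[, , 1] +
      stats::rnorm(length(ds$x_min[, , 1]), 0, s_hr)
  ds$provenance <- rep("jitter", n)
  ds
}

warp_one <- function(x, f) {
  T <- length(x)
  src <- 1 + (seq_len(T) - 1) / f
  src <- pmin(src, T)
  lo <- floor(src); hi <- ceiling(src); w <- src - lo
  x[lo] * (1 - w) + x[hi] * w
}

#' Time warping: stretch/compress the minute axis
#'
#' Rescales each sample's time axis by a factor drawn uniformly from
#' `warp_factor_range` and linearly interpolates the values back onto the
#' original T-minute grid (the first sample is preserved exactly; beyond
#' the shared support the last value is carried forward).  The binary
#' music channel is re-thresholded at 0.5.  Targets are unchanged.
#'
#' @inheritParams jitter_samples
#' @return The warped dataset with provenance `"warp_scale"`.
#' @export
time_warp <- function(ds, config = augmentation_config()) {
  T <- dim(ds$x_min)[2]
  if (T < 2) stop("time warping needs series length >= 2", call. = FALSE)
  n <- n_samples(ds)
  f <- stats::runif(n, config$warp_factor_range[1],
                    config$warp_factor_range[2])
  for (i in seq_len(n)) {
    ds$x_min[i, , 1] <- warp_one(ds$x_min[i, , 1], f[i])
    ds$x_min[i, , 2] <- as.numeric(warp_one(ds$x_min[i, , 2], f[i]) >= 0.5)
  }
  ds$provenance <- rep("warp_scale", n)
  ds
}

#' Magnitude scaling: one factor per daily feature vector
#'
#' Multiplies all continuous daily features of a sample by a single
#' factor drawn uniformly from `scale_factor_range`, emulating day-level
#' physiological fluctuation.  Targets are unchanged.
#'
#' @inheritParams jitter_samples
#' @return The scaled dataset with provenance `"warp_scale"`.
#' @export
magnitude_scale <- function(ds, config = augmentation_config()) {
  n <- n_samples(ds)
  s <- stats::runif(n, config$scale_factor_range[1],
                    config$scale_factor_range[2])
  cont <- attr(ds, "continuous")
  ds$x_day[, cont] <- ds$x_day[, cont, drop = FALSE] * s
  ds$provenance <- rep("warp_scale", n)
  ds
}

#' SMOTE on the distribution tails of the composite score
#'
#' Generates synthetic samples in the tails of the health-score
#' distribution (score below the first or above the third quartile).
#' Each synthetic sample interpolates a random tail sample towards one of
#' its k nearest same-tail neighbours (Euclidean distance in standardized
#' daily-feature + score space) with a single mixing weight
#' `u ~ Uniform(0, 1)` applied jointly to the daily features, the score
#' and - element-wise - the minute series, keeping modalities consistent.
#' Synthetic samples carry fresh `SMOTE_i` identifiers.
#'
#' @inheritParams jitter_samples
#' @param n_out Number of synthetic samples (default: `n_samples(ds)`).
#' @return A dataset of `n_out` synthetic samples, provenance `"smote"`.
#' @export
smote_tail <- function(ds, config = augmentation_config(),
                       n_out = n_samples(ds)) {
  q <- stats::quantile(ds$y, c(0.25, 0.75), type = 7, names = FALSE)
  tail_lo <- which(ds$y < q[1]); tail_hi <- which(ds$y > q[2])
  if (length(tail_lo) < 2 || length(tail_hi) < 2)
    stop("tail bins too small for SMOTE", call. = FALSE)
  k <- config$smote_k
  min_tail <- min(length(tail_lo), length(tail_hi))
  if (min_tail < k + 1) {
    k <- min_tail - 1L
    warning("tail bin smaller than smote_k + 1; reducing k to ", k)
  }
  cont <- attr(ds, "continuous")
  Z <- cbind(scale(ds$x_day[, cont, drop = FALSE]), scale(ds$y))
  Z[!is.finite(Z)] <- 0

  new_min <- array(0, dim = c(n_out, dim(ds$x_min)[2], dim(ds$x_min)[3]),
                   dimnames = dimnames(ds$x_min))
  new_day <- matrix(0, n_out, ncol(ds$x_day),
                    dimnames = list(NULL, colnames(ds$x_day)))
  new_y <- numeric(n_out)
  tails <- list(tail_lo, tail_hi)
  pick_tail <- sample.int(2L, n_out, replace = TRUE)
  for (i in seq_len(n_out)) {
    tl <- tails[[pick_tail[i]]]
    a <- tl[sample.int(length(tl), 1L)]
    others <- setdiff(tl, a)
    d2 <- rowSums((Z[others, , drop = FALSE] -
                     matrix(Z[a, ], length(others), ncol(Z), TRUE))^2)
    nn <- others[order(d2)[seq_len(min(k, length(others)))]]
    b <- nn[sample.int(length(nn), 1L)]
    u <- stats::runif(1)
    new_day[i, ] <- (1 - u) * ds$x_day[a, ] + u * ds$x_day[b, ]
    new_y[i] <- (1 - u) * ds$y[a] + u * ds$y[b]
    new_min[i, , ] <- (1 - u) * ds$x_min[a, , ] + u * ds$x_min[b, , ]
  }
  out <- list(x_min = new_min, x_day = new_day, y = new_y,
              participant_id = sprintf("SMOTE_%d", seq_len(n_out)),
              day_index = rep(NA_integer_, n_out),
              provenance = rep("smote", n_out))
  attributes(out)[c("continuous", "split")] <-
    attributes(ds)[c("continuous", "split")]
  class(out) <- "fatnet_dataset"
  out
}

#' Fourfold training-set expansion
#'
#' Expands a training split to four times its size: the originals, a
#' jittered copy, a time-warped and magnitude-scaled copy, and a SMOTE
#' copy, each contributing exactly N samples with provenance tags
#' `original` / `jitter` / `warp_scale` / `smote`.  Deterministic given
#' `config$seed`.  Applying augmentation to a validation or test split
#' is an evaluation-integrity violation and raises an error.
#'
#' @param ds A `"fatnet_dataset"` whose `"split"` attribute is
#'   `"train"` (see [split_data()]), or unset.
#' @param config An [augmentation_config()].
#' @return The 4N-sample augmented `"fatnet_dataset"`.
#' @examples
#' \dontrun{
#' aug <- augment_fourfold(train_ds, augmentation_config(seed = 42))
#' table(aug$provenance)
#' }
#' @export
augment_fourfold <- function(ds, config = augmentation_config()) {
  split <- attr(ds, "split")
  if (!is.null(split) && !is.na(split) && !identical(split, "train"))
    stop("augment_fourfold() must only be applied to the training split ",
         "(got split = '", split, "'); augmenting evaluation data leaks",
         call. = FALSE)
  set.seed(config$seed)
  ranges <- feature_ranges(ds)
  orig <- ds
  orig$provenance <- rep("original", n_samples(ds))
  out <- dataset_bind(
    orig,
    jitter_samples(ds, config, ranges),
    time_warp(magnitude_scale(ds, config), config),
    smote_tail(ds, config)
  )
  out
}
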