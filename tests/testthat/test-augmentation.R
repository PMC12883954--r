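test_that("jitter calibration and identities hold", {
  coh <- tiny_cohort(seed = 71)
  ds <- tiny_pairs(coh)
  # sigma fraction 0 is the identity
  same <- jitter_samples(ds, augmentation_config(jitter_sigma_frac = 0))
  expect_equal(same$x_day, ds$x_day)
  expect_equal(same$x_min, ds$x_min)
  # noise SD = 2% of the training range: range 50 -> sd 1
  n <- 1e5
  one <- list(x_min = array(0, c(n, 1, 2)),
              x_day = matrix(runif(n) * 50, n, 1,
                             dimnames = list(NULL, "f")),
              y = rep(0, n), participant_id = as.character(seq_len(n)),
              day_index = rep(1L, n))
  attr(one, "continuous") <- TRUE
  class(one) <- "fatnet_dataset"
  rng <- feature_ranges(one)
  set.seed(72)
  jit <- jitter_samples(one, augmentation_config(), rng)
  delta <- jit$x_day[, 1] - one$x_day[, 1]
  expect_lt(abs(stats::sd(delta) - 0.02 * rng$day[[1]]), 0.02)
  # law of large numbers: mean shift within 3 sd / sqrt(n)
  expect_lt(abs(mean(delta)), 3 * stats::sd(delta) / sqrt(n))
  # binary channels untouched
  expect_equal(jit$x_min[, , 2], one$x_min[, , 2])
  # targets unchanged
  expect_equal(jit$y, one$y)
})

test_that("time warping interpolates back onto the original grid", {
  T <- 50
  ds <- list(x_min = array(0, c(2, T, 2)),
             x_day = matrix(0, 2, 1, dimnames = list(NULL, "f")),
             y = c(0, 0), participant_id = c("a", "b"),
             day_index = c(1L, 1L))
  ds$x_min[1, , 1] <- seq_len(T)          # linear ramp
  ds$x_min[2, , 1] <- 7                   # constant series
  ds$x_min[, , 2] <- rep(c(0, 1), each = T / 2)
  attr(ds, "continuous") <- TRUE
  class(ds) <- "fatnet_dataset"
  # degenerate factor range [1, 1] is the identity
  same <- time_warp(ds, augmentation_config(warp_factor_range = c(1, 1)))
  expect_equal(same$x_min[1, , 1], as.numeric(seq_len(T)))
  # constant series unchanged for any factor
  set.seed(73)
  w <- time_warp(ds, augmentation_config())
  expect_equal(w$x_min[2, , 1], rep(7, T))
  # fixed stretch 1.1: ramp becomes 1 + (t-1)/1.1 on the shared support
  s11 <- time_warp(ds, augmentation_config(warp_factor_range = c(1.1, 1.1)))
  expect_equal(s11$x_min[1, , 1], pmin(1 + (seq_len(T) - 1) / 1.1, T),
               tolerance = 1e-6)
  # first sample preserved exactly; music stays binary
  expect_equal(s11$x_min[1, 1, 1], 1)
  expect_true(all(s11$x_min[, , 2] %in% c(0, 1)))
})

test_that("magnitude scaling applies one factor per sample", {
  coh <- tiny_cohort(seed = 74)
  ds <- tiny_pairs(coh)
  same <- magnitude_scale(ds, augmentation_config(scale_factor_range = c(1, 1)))
  expect_equal(same$x_day, ds$x_day)
  set.seed(75)
  sc <- magnitude_scale(ds, augmentation_config())
  cont <- which(attr(ds, "continuous"))
  ratio <- sc$x_day[, cont] / ds$x_day[, cont]
  ratio[!is.finite(ratio)] <- NA
  # within a sample all finite ratios agree (single factor)
  spread <- apply(ratio, 1, function(r) diff(range(r, na.rm = TRUE)))
  expect_lt(max(spread), 1e-10)
  expect_true(all(ratio >= 0.9 - 1e-9 & ratio <= 1.1 + 1e-9, na.rm = TRUE))
  # fixed factor 0.9 scales a feature of 100 to 90
  ds$x_day[1, cont[1]] <- 100
  s9 <- magnitude_scale(ds, augmentation_config(scale_factor_range = c(0.9, 0.9)))
  expect_equal(s9$x_day[1, cont[1]], 90)
})

test_that("SMOTE interpolates within score tails", {
  coh <- tiny_cohort(seed = 76, np = 8, days = 10)
  ds <- tiny_pairs(coh)
  set.seed(77)
  sm <- smote_tail(ds, augmentation_config(), n_out = 40)
  expect_equal(n_samples(sm), 40)
  # synthetic ids never reuse originals
  expect_false(any(sm$participant_id %in% ds$participant_id))
  # scores stay inside the tail hull
  q <- stats::quantile(ds$y, c(0.25, 0.75))
  tails <- ds$y < q[1] | ds$y > q[2]
  expect_true(all(sm$y >= min(ds$y[tails]) - 1e-9 &
                    sm$y <= max(ds$y[tails]) + 1e-9))
  # degenerate 1-D two-point tails: synthetics lie on the segments
  two <- list(x_min = array(0, c(6, 2, 2)),
              x_day = matrix(c(0, 0.05, 0.5, 0.5, 0.95, 1), 6, 1,
                             dimnames = list(NULL, "f")),
              y = c(0, 0.05, 0.5, 0.5, 0.95, 1),
              participant_id = letters[1:6], day_index = 1:6)
  attr(two, "continuous") <- TRUE
  class(two) <- "fatnet_dataset"
  set.seed(78)
  expect_warning(s2 <- smote_tail(two, augmentation_config(smote_k = 5),
                                  n_out = 10), "reducing")
  expect_true(all((s2$y >= 0 & s2$y <= 0.05 + 1e-9) |
                    (s2$y >= 0.95 - 1e-9 & s2$y <= 1)))
})

test_that("fourfold expansion has exact provenance structure", {
  coh <- tiny_cohort(seed = 79, np = 8, days = 10)
  ds <- tiny_pairs(coh)
  attr(ds, "split") <- "train"
  aug <- augment_fourfold(ds, augmentation_config(seed = 80))
  expect_equal(n_samples(aug), 4 * n_samples(ds))
  expect_equal(unname(table(aug$provenance)[c("original", "jitter",
                                              "warp_scale", "smote")]),
               rep(n_samples(ds), 4), ignore_attr = TRUE)
  # schema, channel count and T are unchanged
  expect_equal(dim(aug$x_min)[2:3], dim(ds$x_min)[2:3])
  expect_equal(colnames(aug$x_day), colnames(ds$x_day))
  # deterministic given the seed
  aug2 <- augment_fourfold(ds, augmentation_config(seed = 80))
  expect_identical(aug$x_day, aug2$x_day)
  expect_identical(aug$x_min, aug2$x_min)
  # jitter/warp/scale copies keep their target; originals come first
  expect_equal(aug$y[aug$provenance == "jitter"], ds$y)
  expect_equal(aug$y[aug$provenance == "warp_scale"], ds$y)
})

test_that("augmenting an evaluation split is refused", {
  coh <- tiny_cohort(seed = 81, np = 8, days = 10)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, seed = 1)
  expect_error(augment_fourfold(sp$test), "leak")
  expect_error(augment_fourfold(sp$val), "leak")
  expect_silent(invisible(augment_fourfold(sp$train,
                                           augmentation_config(seed = 1))))
})
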