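test_that("next-day pairs are aligned and never cross participants", {
  coh <- tiny_cohort(seed = 111, np = 4, days = 9, T = 30)
  eng <- engineer_features(coh$daily)
  hs <- health_score(eng)
  ds <- build_pairs(eng, coh$minutes, hs$score)
  # each participant contributes n_days - 1 pairs
  expect_equal(n_samples(ds), 4 * 8)
  key <- paste(eng$participant_id, eng$day_index)
  for (i in seq_len(n_samples(ds))) {
    j <- match(paste(ds$participant_id[i], ds$day_index[i] + 1L), key)
    expect_false(is.na(j))
    expect_equal(ds$y[i], hs$score[j])
  }
  # last day never appears as an input
  expect_false(any(ds$day_index == 9))
  # a gap in the day sequence breaks the pair across it
  eng2 <- eng[!(eng$participant_id == "P001" & eng$day_index == 5), ]
  hs2 <- health_score(eng2)
  ds2 <- build_pairs(eng2, coh$minutes, hs2$score)
  expect_equal(n_samples(ds2), 4 * 8 - 2)   # days 4 and 5 lose their pair
  expect_false(any(ds2$participant_id == "P001" & ds2$day_index %in% c(4, 5)))
})

test_that("participant-grouped splits are proportional and disjoint", {
  coh <- tiny_cohort(seed = 112, np = 10, days = 6, T = 30)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, c(0.8, 0.1, 0.1), seed = 7)
  n_ids <- function(s) length(unique(s$participant_id))
  expect_equal(c(n_ids(sp$train), n_ids(sp$val), n_ids(sp$test)),
               c(8, 1, 1))
  ids <- lapply(sp, function(s) unique(s$participant_id))
  expect_length(Reduce(intersect, ids), 0)
  expect_setequal(unlist(ids), unique(ds$participant_id))
  expect_equal(sum(vapply(sp, n_samples, 0L)), n_samples(ds))
  # reproducible under the same seed
  sp2 <- split_data(ds, seed = 7)
  expect_identical(lapply(sp, `[[`, "participant_id"),
                   lapply(sp2, `[[`, "participant_id"))
  expect_error(split_data(dataset_subset(ds, ds$participant_id %in%
                                           c("P001", "P002")), seed = 1),
               "3 participants")
  expect_error(split_data(ds, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("metrics match hand values and brute-force definitions", {
  m <- compute_metrics(c(3, 4), c(3, 4))
  expect_equal(unname(m), c(0, 0, 1, 1))
  m2 <- compute_metrics(c(0, 0), c(3, 4))
  expect_equal(m2[["rmse"]], sqrt(12.5))
  expect_equal(m2[["mae"]], 3.5)
  y <- c(-1, 0, 1)
  expect_equal(compute_metrics(-y, y)[["pearson_r"]], -1)
  expect_error(compute_metrics(c(1, 2), c(5, 5)), "constant")
  set.seed(113)
  for (i in 1:5) {
    yh <- rnorm(50); yy <- rnorm(50)
    m <- compute_metrics(yh, yy)
    expect_equal(m[["rmse"]], sqrt(sum((yh - yy)^2) / 50), tolerance = 1e-12)
    expect_equal(m[["mae"]], sum(abs(yh - yy)) / 50, tolerance = 1e-12)
    expect_equal(m[["r2"]], 1 - sum((yh - yy)^2) / sum((yy - mean(yy))^2),
                 tolerance = 1e-12)
    expect_equal(m[["pearson_r"]],
                 sum(scale(yh) * scale(yy)) / 49, tolerance = 1e-10)
  }
})

test_that("improvement percentages follow the sign conventions", {
  base <- c(rmse = 0.453, mae = 0.4, r2 = 0.74, pearson_r = 0.86)
  model <- c(rmse = 0.35, mae = 0.35, r2 = 0.87, pearson_r = 0.93)
  imp <- improvement_pct(model, base)
  expect_equal(imp[["rmse"]], 22.7, tolerance = 0.01)
  expect_gt(imp[["r2"]], 0)
  expect_equal(unname(improvement_pct(base, base)), rep(0, 4))
})

test_that("tabular baselines learn a single-feature identity map", {
  set.seed(114)
  n <- 400
  mk <- function(idx) {
    ds <- list(x_min = array(rnorm(length(idx) * 8), c(length(idx), 4, 2)),
               x_day = matrix(seq(0, 1, length.out = n)[idx], ncol = 1,
                              dimnames = list(NULL, "f")),
               y = seq(0, 1, length.out = n)[idx],
               participant_id = as.character(idx), day_index = idx)
    attr(ds, "continuous") <- TRUE
    class(ds) <- "fatnet_dataset"
    ds
  }
  # interleaved hold-out: tree ensembles interpolate but cannot extrapolate
  test_idx <- seq(4, n, by = 5)
  train <- mk(setdiff(seq_len(n), test_idx)); test <- mk(test_idx)
  for (kind in c("rf", "xgb")) {
    fit <- fit_tabular_baseline(kind, train, baseline_config(seed = 9))
    m <- compute_metrics(predict(fit, test), test$y)
    expect_gt(m[["r2"]], 0.95)
    # deterministic given the seed
    fit2 <- fit_tabular_baseline(kind, train, baseline_config(seed = 9))
    expect_equal(predict(fit2, test), predict(fit, test))
  }
  # constant target: predictions collapse to the constant
  ctrain <- train; ctrain$y <- rep(2, 300)
  rf <- fit_tabular_baseline("rf", ctrain)
  expect_lt(sqrt(mean((predict(rf, test) - 2)^2)), 1e-6)
})

test_that("TCN receptive field covers the configured horizon", {
  coh <- tiny_cohort(seed = 115, np = 6, days = 8, T = 60)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, seed = 10)
  fit <- fit_sequence_baseline("tcn", sp$train, sp$val,
                               tiny_net_config(60, max_epochs = 1L))
  expect_equal(fit$receptive_field, 1 + 6 * (1 + 4 + 16))
  expect_gte(fit$receptive_field, baseline_config()$coverage)
})

test_that("sequence baselines learn a planted temporal signal", {
  coh <- tiny_cohort(seed = 116, np = 10, days = 10, T = 48)
  ds <- tiny_pairs(coh)
  # target carried by the minute stream only: fraction of music minutes
  ds$y <- as.numeric(scale(rowMeans(ds$x_min[, , 2])))
  sp <- split_data(ds, seed = 11)
  for (kind in c("lstm", "tcn")) {
    fit <- fit_sequence_baseline(kind, sp$train, sp$val,
                                 tiny_net_config(48, max_epochs = 25L,
                                                 patience = 25L))
    untrained <- mean(abs(sp$val$y - mean(sp$train$y)))
    expect_lt(fit$history$best_val_mae, untrained)
    h <- fit$history
    if (h$n_epochs < 25) expect_gte(h$n_epochs - h$best_epoch, 25)
  }
})

test_that("the comparison protocol reports all models and round-trips", {
  coh <- tiny_cohort(seed = 117, np = 8, days = 10, T = 48)
  ds <- tiny_pairs(coh)
  rep <- run_comparison(ds, tiny_net_config(48, max_epochs = 2L),
                        baseline_config(seed = 1), n_runs = 2L,
                        seeds = c(21L, 22L))
  expect_equal(nrow(rep$per_run), 5 * 2)
  expect_setequal(unique(rep$per_run$model),
                  c("fatnet", "rf", "xgb", "lstm", "tcn"))
  expect_equal(rownames(rep$improvement), c("rf", "xgb", "lstm", "tcn"),
               ignore_attr = TRUE)
  expect_true(all(rep$per_run$rmse >= 0 & rep$per_run$mae >= 0))
  expect_true(all(rep$per_run$r2 <= 1))
  expect_true(all(abs(rep$per_run$pearson_r) <= 1))
  d <- withr::local_tempdir()
  export_report(rep, d)
  back <- import_report(d)
  expect_equal(back$per_run, rep$per_run, tolerance = 1e-12)
  expect_equal(back$improvement, rep$improvement, tolerance = 1e-12)
  # identical model vs itself: improvement must be 0 by the formula
  same <- improvement_pct(c(rmse = 1, mae = 1, r2 = 0.5, pearson_r = 0.7),
                          c(rmse = 1, mae = 1, r2 = 0.5, pearson_r = 0.7))
  expect_equal(unname(same), rep(0, 4))
})
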