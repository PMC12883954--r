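#' Participant-grouped train/validation/test split
#'
#' Partitions a dataset so that every participant's days land in exactly
#' one split (preventing identity leakage), with split sizes proportional
#' to participant counts within one participant of the requested ratios.
#'
#' @param ds A `"fatnet_dataset"`.
#' @param ratios Length-3 vector of train/validation/test fractions
#'   summing to 1.
#' @param seed Integer seed controlling the participant shuffle.
#' @return A list with `train`, `val` and `test` datasets, each tagged
#'   with a `"split"` attribute.
#' @examples
#' \dontrun{
#' sp <- split_data(pairs, c(0.8, 0.1, 0.1), seed = 1)
#' }
#' @export
split_data <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8)
    stop("split ratios must sum to 1", call. = FALSE)
  ids <- unique(ds$participant_id)
  P <- length(ids)
  if (P < 3) stop("need at least 3 participants to split", call. = FALSE)
  set.seed(seed)
  ids <- sample(ids)
  n_val <- max(1L, round(ratios[2] * P))
  n_test <- max(1L, round(ratios[3] * P))
  n_train <- P - n_val - n_test
  if (n_train < 1) stop("ratios leave no training participants",
                        call. = FALSE)
  grp <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  assign_split <- function(which) {
    out <- dataset_subset(ds, ds$participant_id %in% ids[grp == which])
    attr(out, "split") <- which
    out
  }
  list(train = assign_split("train"), val = assign_split("val"),
       test = assign_split("test"))
}

#' Baseline model configuration
#'
#' Hyperparameters of the comparison models: Random Forest (100 trees,
#' maximum depth 10), XGBoost (100 trees, maximum depth 6, learning rate
#' 0.1), and the LSTM / TCN sequence regressors, which share the
#' training-loop contract of the fusion model (AdamW, batch 16, up to
#' 100 epochs, early stopping patience 10).
#'
#' @param rf_trees,rf_depth Random Forest size and depth.
#' @param xgb_trees,xgb_depth,xgb_lr Gradient-boosting size, depth and
#'   learning rate.
#' @param tcn_kernel,tcn_dilations Dilated causal convolution schedule of
#'   the TCN baseline (channels mirror the fusion model's conv filters).
#' @param coverage Minimum required TCN receptive field, minutes.
#' @param seed Integer seed.
#' @return A list of class `"baseline_config"`.
#' @export
baseline_config <- function(rf_trees = 100L, rf_depth = 10L,
                            xgb_trees = 100L, xgb_depth = 6L, xgb_lr = 0.1,
                            tcn_kernel = 7L, tcn_dilations = c(1L, 4L, 16L),
                            coverage = 120L, seed = 1L) {
  stopifnot(rf_trees > 0, rf_depth > 0, xgb_trees > 0, xgb_depth > 0,
            xgb_lr > 0, xgb_lr <= 1)
  structure(list(rf_trees = as.integer(rf_trees),
                 rf_depth = as.integer(rf_depth),
                 xgb_trees = as.integer(xgb_trees),
                 xgb_depth = as.integer(xgb_depth), xgb_lr = xgb_lr,
                 tcn_kernel = as.integer(tcn_kernel),
                 tcn_dilations = as.integer(tcn_dilations),
                 coverage = as.integer(coverage),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

## daily features + coarse temporal aggregates for the tabular models
tabular_features <- function(ds) {
  hr <- channel_matrix(ds, 1)
  mus <- channel_matrix(ds, 2)
  cbind(ds$x_day,
        hr_mean = rowMeans(hr),
        hr_sd = apply(hr, 1, stats::sd),
        music_minutes = rowSums(mus))
}

#' Fit a tabular baseline (Random Forest or XGBoost)
#'
#' Trains an ensemble regressor on the daily summary features plus
#' coarse temporal aggregates (mean and SD of minute heart rate, total
#' music minutes) - summaries that deliberately do not encode the
#' minute-level interaction structure.
#'
#' @param kind `"rf"` or `"xgb"`.
#' @param train Training `"fatnet_dataset"`.
#' @param config A [baseline_config()].
#' @return A `"tabular_baseline"` object with a `predict` method.
#' @export
fit_tabular_baseline <- function(kind = c("rf", "xgb"), train,
                                 config = baseline_config()) {
  kind <- match.arg(kind)
  if (n_samples(train) == 0L) stop("empty training set", call. = FALSE)
  x <- tabular_features(train)
  y <- train$y
  if (stats::sd(y) == 0)      # degenerate target: constant predictor
    return(structure(list(kind = kind, constant = y[1],
                          features = colnames(x)),
                     class = "tabular_baseline"))
  fit <- if (kind == "rf") {
    ranger::ranger(x = as.data.frame(x), y = y,
                   num.trees = config$rf_trees,
                   max.depth = config$rf_depth,
                   seed = config$seed, num.threads = 1)
  } else {
    xgboost::xgboost(x, y, nrounds = config$xgb_trees,
                     max_depth = config$xgb_depth,
                     learning_rate = config$xgb_lr,
                     objective = "reg:squarederror", verbosity = 0,
                     nthreads = 1, seed = config$seed)
  }
  structure(list(kind = kind, fit = fit, features = colnames(x)),
            class = "tabular_baseline")
}

#' @export
predict.tabular_baseline <- function(object, newdata, ...) {
  x <- tabular_features(newdata)
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(x)))
  if (object$kind == "rf")
    as.numeric(stats::predict(object$fit,
                              data = as.data.frame(x))$predictions)
  else
    as.numeric(stats::predict(object$fit, newdata = x))
}

#' Fit a sequence baseline (LSTM or TCN)
#'
#' Single-stream deep baselines on the minute series with the summary
#' vector concatenated before the prediction head, trained under the
#' same loop contract as the fusion model (AdamW, early stopping on
#' validation MAE).
#'
#' @param kind `"lstm"` or `"tcn"`.
#' @param train,val Training and validation datasets.
#' @param config A [fatnet_config()] (network widths and training loop);
#'   TCN kernel/dilations come from `baseline`.
#' @param baseline A [baseline_config()].
#' @param verbose Print epochs.
#' @return A fitted `"fatnet_seq_baseline"` model.
#' @export
fit_sequence_baseline <- function(kind = c("lstm", "tcn"), train, val,
                                  config = fatnet_config(T = dim(train$x_min)[2]),
                                  baseline = baseline_config(),
                                  verbose = FALSE) {
  kind <- match.arg(kind)
  config$tcn_kernel <- baseline$tcn_kernel
  config$tcn_dilations <- baseline$tcn_dilations
  fit <- .fit_nn(kind, train, val, config, verbose)
  if (kind == "tcn") {
    rf <- nn_receptive_field(.nn_handle(fit))
    if (rf < baseline$coverage)
      warning("TCN receptive field (", rf, " min) below configured ",
              "coverage (", baseline$coverage, " min)")
    fit$receptive_field <- rf
  }
  fit
}

#' Regression metrics
#'
#' RMSE, MAE, the coefficient of determination `R2 = 1 - SSE/SST`, and
#' Pearson's correlation between predictions and observations.
#'
#' @param y_hat,y Equal-length numeric vectors; `y` must be non-constant
#'   for `r2` and `pearson_r`.
#' @return Named numeric vector `c(rmse, mae, r2, pearson_r)`.
#' @examples
#' compute_metrics(c(0, 0), c(3, 4))[c("rmse", "mae")]
#' @export
compute_metrics <- function(y_hat, y) {
  n <- length(y)
  if (length(y_hat) != n || n == 0)
    stop("y_hat and y must be non-empty and of equal length", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("constant y: r2 and pearson_r are undefined", call. = FALSE)
  err <- y_hat - y
  # a constant prediction vector has no defined correlation; report NA
  pr <- if (stats::sd(y_hat) == 0) NA_real_ else stats::cor(y_hat, y)
  c(rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r2 = 1 - sum(err^2) / sum((y - mean(y))^2),
    pearson_r = pr)
}

#' Percentage improvement of the fusion model over a baseline
#'
#' For the error metrics the sign convention is
#' `(baseline - model) / baseline * 100` (positive = error reduced); for
#' `r2` and `pearson_r` it is `(model - baseline) / baseline * 100`
#' (positive = agreement increased).
#'
#' @param model_metrics,baseline_metrics Outputs of [compute_metrics()].
#' @return Named vector of percentage improvements.
#' @export
improvement_pct <- function(model_metrics, baseline_metrics) {
  c(rmse = 100 * (baseline_metrics["rmse"] - model_metrics["rmse"]) /
      baseline_metrics["rmse"],
    mae = 100 * (baseline_metrics["mae"] - model_metrics["mae"]) /
      baseline_metrics["mae"],
    r2 = 100 * (model_metrics["r2"] - baseline_metrics["r2"]) /
      baseline_metrics["r2"],
    pearson_r = 100 * (model_metrics["pearson_r"] -
                         baseline_metrics["pearson_r"]) /
      baseline_metrics["pearson_r"]) |>
    stats::setNames(c("rmse", "mae", "r2", "pearson_r"))
}

#' Multi-run model comparison
#'
#' The evaluation protocol: for each run, draw a fresh participant-grouped
#' split (or reuse a fixed one), train the fusion model and the selected
#' baselines, and score all of them on the held-out test participants.
#' Aggregates report mean and SD per model and metric over runs, plus the
#' percentage-improvement matrix of the fusion model against each
#' baseline.  A model failure is recorded and the run marked incomplete;
#' the report is still produced.
#'
#' @param ds Full `"fatnet_dataset"` of next-day pairs.
#' @param config A [fatnet_config()] shared by the deep models.
#' @param baseline A [baseline_config()].
#' @param models Character vector among
#'   `c("fatnet", "rf", "xgb", "lstm", "tcn")`.
#' @param n_runs Number of independent runs (10 in the full protocol).
#' @param seeds Integer seeds, one per run; defaults to `1:n_runs`.
#' @param fixed_split Reuse the run-1 split for every run (re-initializing
#'   weights only).
#' @param verbose Print progress.
#' @return An `"experiment_report"`: `per_run` data frame
#'   (model x run x metrics), `aggregate` (mean/sd), `improvement`
#'   matrix, and `failures`.
#' @export
run_comparison <- function(ds, config = fatnet_config(T = dim(ds$x_min)[2]),
                           baseline = baseline_config(),
                           models = c("fatnet", "rf", "xgb", "lstm", "tcn"),
                           n_runs = 10L, seeds = seq_len(n_runs),
                           fixed_split = FALSE, verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  if (!"fatnet" %in% models)
    stop("the comparison needs the fusion model itself", call. = FALSE)
  rows <- list(); failures <- list()
  for (r in seq_len(n_runs)) {
    seed_r <- as.integer(seeds[r])
    sp <- split_data(ds, seed = if (fixed_split) as.integer(seeds[1])
                     else seed_r)
    for (m in models) {
      cfg <- config; cfg$seed <- seed_r
      bas <- baseline; bas$seed <- seed_r
      res <- tryCatch({
        fit <- switch(m,
          fatnet = fat_net(sp$train, sp$val, cfg, verbose = verbose),
          rf = fit_tabular_baseline("rf", sp$train, bas),
          xgb = fit_tabular_baseline("xgb", sp$train, bas),
          lstm = fit_sequence_baseline("lstm", sp$train, sp$val, cfg, bas),
          tcn = fit_sequence_baseline("tcn", sp$train, sp$val, cfg, bas))
        compute_metrics(predict(fit, sp$test), sp$test$y)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(run = r, model = m, message = conditionMessage(res))
        if (verbose) message("run ", r, " ", m, " FAILED: ",
                             conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(run = r, model = m, rmse = res["rmse"],
                     mae = res["mae"], r2 = res["r2"],
                     pearson_r = res["pearson_r"], row.names = NULL)
        if (verbose) message(sprintf("run %d %-6s rmse %.4f mae %.4f",
                                     r, m, res["rmse"], res["mae"]))
      }
    }
  }
  per_run <- do.call(rbind, rows)
  metrics <- c("rmse", "mae", "r2", "pearson_r")
  agg <- do.call(rbind, lapply(split(per_run, per_run$model), function(d)
    data.frame(model = d$model[1],
               n_runs = nrow(d),
               t(vapply(metrics, function(mm)
                 c(mean = mean(d[[mm]]), sd = stats::sd(d[[mm]])),
                 c(mean = 0, sd = 0))))))
  fat_mean <- vapply(metrics, function(mm)
    mean(per_run[[mm]][per_run$model == "fatnet"]), 0)
  base_models <- setdiff(unique(per_run$model), "fatnet")
  improvement <- t(vapply(base_models, function(bm) {
    bmean <- vapply(metrics, function(mm)
      mean(per_run[[mm]][per_run$model == bm]), 0)
    improvement_pct(fat_mean, bmean)
  }, stats::setNames(numeric(4), metrics)))
  structure(list(per_run = per_run, aggregate = agg,
                 improvement = improvement, failures = failures,
                 n_runs = n_runs, fixed_split = fixed_split),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Model comparison over %d run(s)%s\n", x$n_runs,
              if (x$fixed_split) " (fixed split)" else ""))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-7s RMSE %.4f+/-%.4f  MAE %.4f+/-%.4f  R2 %.3f  r %.3f\n",
                agg$model[i], agg$rmse.mean[i], agg$rmse.sd[i],
                agg$mae.mean[i], agg$mae.sd[i], agg$r2.mean[i],
                agg$pearson_r.mean[i]))
  if (nrow(x$improvement)) {
    cat("  improvement of the fusion model (%):\n")
    print(round(x$improvement, 1))
  }
  if (length(x$failures))
    cat(sprintf("  %d model run(s) failed\n", length(x$failures)))
  invisible(x)
}

#' Export / import an experiment report
#'
#' Writes `report.json` (lossless full report),
#' `per_run_metrics.csv` and `improvement_matrix.csv` into `path`;
#' `import_report()` restores the report from `report.json`.
#'
#' @param report An `"experiment_report"`.
#' @param path Directory.
#' @return `export_report()` returns `path` invisibly;
#'   `import_report()` the report.
#' @export
export_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  payload <- list(per_run = report$per_run,
                  improvement = as.data.frame(report$improvement) |>
                    (\(d) cbind(baseline = rownames(report$improvement),
                                d))(),
                  failures = report$failures,
                  n_runs = report$n_runs, fixed_split = report$fixed_split)
  jsonlite::write_json(payload, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_run, file.path(path, "per_run_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(baseline = rownames(report$improvement),
                              report$improvement),
                   file.path(path, "improvement_matrix.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname export_report
#' @export
import_report <- function(path) {
  p <- jsonlite::read_json(file.path(path, "report.json"),
                           simplifyVector = TRUE)
  imp <- as.matrix(p$improvement[, -1, drop = FALSE])
  rownames(imp) <- p$improvement$baseline
  per_run <- p$per_run
  metrics <- c("rmse", "mae", "r2", "pearson_r")
  agg <- do.call(rbind, lapply(split(per_run, per_run$model), function(d)
    data.frame(model = d$model[1], n_runs = nrow(d),
               t(vapply(metrics, function(mm)
                 c(mean = mean(d[[mm]]), sd = stats::sd(d[[mm]])),
                 c(mean = 0, sd = 0))))))
  structure(list(per_run = per_run, aggregate = agg, improvement = imp,
                 failures = p$failures, n_runs = p$n_runs,
                 fixed_split = p$fixed_split),
            class = "experiment_report")
}
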