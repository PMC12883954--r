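#' Configuration of the dual-stream fusion network
#'
#' Architecture and training hyperparameters of FAT-Net.  The temporal
#' stream passes the T x 2 minute matrix (heart rate, music on/off)
#' through three Conv1D layers (filters 32/64/128, kernels 5/3/3, same
#' padding, each with LayerNorm, GELU and dropout 0.1), a BiLSTM with
#' h/2 units per direction, and multi-head self-attention pooled by the
#' time mean.  The summary stream embeds the daily feature vector with a
#' three-layer MLP (d_ds -> 64 -> 128 -> h, BatchNorm/ReLU/dropout 0.2).
#' Cross-modal attention runs in both directions over per-feature summary
#' tokens and the attended temporal sequence, and a feed-forward block
#' plus a two-layer head (2h -> 256 -> 1) predicts the next-day score.
#' Training uses AdamW (learning rate 3e-4, weight decay 1e-5, batch 16)
#' with early stopping on validation MAE (patience 10, up to 100 epochs).
#'
#' @param T Minutes per day window.
#' @param d_ds Number of daily summary features (set automatically by
#'   [fat_net()] when `NULL`).
#' @param h Embedding width (even; default 64).
#' @param n_heads Attention heads (must divide `h`).
#' @param conv_filters,conv_kernels,conv_dropout Temporal Conv1D stack.
#' @param mlp_dims,mlp_dropout Summary MLP hidden widths and dropout.
#' @param ffn_hidden Post-fusion feed-forward widths.
#' @param head_hidden,head_dropout Prediction head.
#' @param lr,weight_decay,batch_size,max_epochs,patience Training loop.
#' @param min_epochs Early-stopping burn-in: the patience rule cannot end
#'   training before this many epochs (the best-validation parameters are
#'   still tracked from epoch 1).  0 disables the floor.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A list of class `"fatnet_config"`.
#' @export
fatnet_config <- function(T = 240L, d_ds = NULL, h = 64L, n_heads = 4L,
                          conv_filters = c(32L, 64L, 128L),
                          conv_kernels = c(5L, 3L, 3L),
                          conv_dropout = 0.1,
                          mlp_dims = c(64L, 128L), mlp_dropout = 0.2,
                          ffn_hidden = c(512L, 512L),
                          head_hidden = 256L, head_dropout = 0.2,
                          lr = 3e-4, weight_decay = 1e-5,
                          batch_size = 16L, max_epochs = 100L,
                          patience = 10L, min_epochs = 0L, seed = 1L) {
  cfg <- list(T = as.integer(T), d_ts = 2L,
              d_ds = if (is.null(d_ds)) NULL else as.integer(d_ds),
              h = as.integer(h), n_heads = as.integer(n_heads),
              conv_filters = as.integer(conv_filters),
              conv_kernels = as.integer(conv_kernels),
              conv_dropout = conv_dropout,
              mlp_dims = as.integer(mlp_dims), mlp_dropout = mlp_dropout,
              ffn_hidden = as.integer(ffn_hidden),
              head_hidden = as.integer(head_hidden),
              head_dropout = head_dropout,
              lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              min_epochs = as.integer(min_epochs), seed = as.integer(seed))
  class(cfg) <- "fatnet_config"
  validate_fatnet_config(cfg)
  cfg
}

validate_fatnet_config <- function(cfg) {
  if (cfg$h %% 2L != 0L)
    stop("config error: h must be even (the BiLSTM halves it)",
         call. = FALSE)
  if (cfg$h %% cfg$n_heads != 0L)
    stop("config error: n_heads must divide h", call. = FALSE)
  if (cfg$T < max(cfg$conv_kernels))
    stop("config error: T is smaller than the largest convolution kernel",
         call. = FALSE)
  dims <- c(cfg$conv_filters, cfg$mlp_dims, cfg$ffn_hidden,
            cfg$head_hidden, cfg$h, cfg$n_heads, cfg$batch_size,
            cfg$max_epochs, cfg$patience)
  if (any(dims <= 0)) stop("config error: all dimensions must be positive",
                           call. = FALSE)
  for (p in c("conv_dropout", "mlp_dropout", "head_dropout"))
    if (cfg[[p]] < 0 || cfg[[p]] >= 1)
      stop("config error: ", p, " must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

## Fit input-standardization stats on a training dataset: z-scores for the
## continuous daily columns, binaries untouched.  The heart-rate channel is
## instance-normalized per day (each day's own mean and SD), which needs no
## fitted statistics and makes within-day excursions comparable across
## participants with different resting levels.
fit_input_stats <- function(train) {
  cont <- attr(train, "continuous")
  mu <- colMeans(train$x_day)
  sg <- apply(train$x_day, 2, stats::sd)
  mu[!cont] <- 0; sg[!cont] <- 1
  sg[sg == 0 | !is.finite(sg)] <- 1
  structure(list(mu = mu, sigma = sg),
            class = "input_stats", provenance = "fitted")
}

apply_input_stats <- function(ds, st) {
  stopifnot(inherits(st, "input_stats"))
  ds$x_day <- sweep(sweep(ds$x_day, 2, st$mu), 2, st$sigma, "/")
  hr <- channel_matrix(ds, 1)
  mu <- rowMeans(hr)
  sg <- pmax(apply(hr, 1, stats::sd), 1e-6)
  ds$x_min[, , 1] <- (hr - mu) / sg
  ds
}

.nn_handle <- function(object) {
  env <- object$.cache
  if (is.null(env$ptr)) {
    env$ptr <- nn_create(object$type, object$config, object$config$seed)
    nn_set_params(env$ptr, object$params)
  }
  env$ptr
}

.fit_nn <- function(type, train, val, config, verbose = FALSE) {
  if (n_samples(train) == 0L) stop("empty training set", call. = FALSE)
  if (n_samples(val) == 0L) stop("empty validation set", call. = FALSE)
  if (is.null(config$d_ds)) config$d_ds <- ncol(train$x_day)
  if (config$d_ds != ncol(train$x_day))
    stop("d_ds mismatch: config says ", config$d_ds, ", data has ",
         ncol(train$x_day), call. = FALSE)
  validate_fatnet_config(config)
  stats <- fit_input_stats(train)
  tr <- apply_input_stats(train, stats)
  vl <- apply_input_stats(val, stats)
  ptr <- nn_create(type, config, config$seed)
  nn_set_data(ptr, tr$x_min, tr$x_day, tr$y, "train")
  nn_set_data(ptr, vl$x_min, vl$x_day, vl$y, "val")
  history <- nn_train(ptr, config$lr, config$weight_decay,
                      config$batch_size, config$max_epochs,
                      config$patience, config$min_epochs, verbose)
  val_pred <- as.numeric(nn_predict(ptr, vl$x_min, vl$x_day))
  obj <- structure(list(
    type = type, config = config, params = nn_get_params(ptr),
    n_params = nn_n_params(ptr), history = history,
    input_stats = stats, feature_names = colnames(train$x_day),
    val_y = val$y, val_pred = val_pred,
    .cache = new.env(parent = emptyenv())
  ), class = c(if (type == "fatnet") "fatnet" else "fatnet_seq_baseline",
               "fatnet_model"))
  obj$.cache$ptr <- ptr
  obj
}

#' Fit the dual-stream fusion network
#'
#' The central fitting function: trains FAT-Net on next-day prediction
#' pairs with AdamW and early stopping on validation MAE, restoring the
#' best-epoch parameters.  Input standardization (continuous daily
#' features and the heart-rate channel) is fitted on the training split
#' only and stored with the model, so evaluation data are always
#' transformed with training statistics.
#'
#' @param train,val Training and validation `"fatnet_dataset"` splits
#'   (see [build_pairs()] and [split_data()]).
#' @param config A [fatnet_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `"fatnet"` with `predict`, `print`,
#'   `summary`, `plot`, `residuals` and `coef` methods, the training
#'   `history`, and the fitted input statistics.
#' @examples
#' \dontrun{
#' fit <- fat_net(train_ds, val_ds, fatnet_config(T = 240, h = 32))
#' predict(fit, test_ds)
#' }
#' @export
fat_net <- function(train, val, config = fatnet_config(T = dim(train$x_min)[2]),
                    verbose = FALSE) {
  .fit_nn("fatnet", train, val, config, verbose)
}

#' @export
predict.fatnet_model <- function(object, newdata, ...) {
  ds <- apply_input_stats(newdata, object$input_stats)
  as.numeric(nn_predict(.nn_handle(object), ds$x_min, ds$x_day))
}

#' @export
print.fatnet_model <- function(x, ...) {
  cat(sprintf("%s regressor (%d parameters)\n",
              switch(x$type, fatnet = "Dual-stream fusion (FAT-Net)",
                     lstm = "Single-stream LSTM baseline",
                     tcn = "Dilated causal TCN baseline"),
              x$n_params))
  cat(sprintf("  T = %d min x %d channels, %d summary features, h = %d\n",
              x$config$T, x$config$d_ts, x$config$d_ds, x$config$h))
  cat(sprintf("  trained %d epochs; best epoch %d, validation MAE %.4f\n",
              x$history$n_epochs, x$history$best_epoch,
              x$history$best_val_mae))
  invisible(x)
}

#' @export
summary.fatnet_model <- function(object, ...) {
  print(object)
  cat("  training-loss trajectory (MSE): ",
      paste(sprintf("%.3f", utils::head(unlist(object$history$train_loss), 8)),
            collapse = " "), " ...\n", sep = "")
  m <- compute_metrics(object$val_pred, object$val_y)
  cat(sprintf("  validation: RMSE %.4f, MAE %.4f, R2 %.3f, r %.3f\n",
              m["rmse"], m["mae"], m["r2"], m["pearson_r"]))
  invisible(object)
}

#' @export
coef.fatnet_model <- function(object, ...) object$params

#' @export
residuals.fatnet_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$val_y - object$val_pred)
  newdata$y - predict(object, newdata)
}

#' @export
plot.fatnet_model <- function(x, ...) {
  tl <- unlist(x$history$train_loss)
  vm <- unlist(x$history$val_mae)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(seq_along(tl), tl, type = "l", xlab = "epoch",
                 ylab = "training MSE", main = "Training loss", ...)
  graphics::plot(seq_along(vm), vm, type = "l", xlab = "epoch",
                 ylab = "validation MAE", main = "Early-stopping criterion",
                 ...)
  graphics::abline(v = x$history$best_epoch, lty = 2)
  invisible(x)
}

#' Training objective
#'
#' The explicit loss the optimizer minimizes: mean squared error of the
#' next-day predictions plus `lambda` times the squared L2 norm of the
#' parameters.  During training the penalty is realized as decoupled
#' AdamW weight decay; this function recomputes the explicit formula for
#' reporting.
#'
#' @param y_hat,y Equal-length prediction and target vectors.
#' @param theta Parameter vector (e.g. `coef(model)`); may be omitted
#'   for the pure-MSE value.
#' @param lambda Weight-decay coefficient.
#' @return The scalar loss.
#' @export
fatnet_loss <- function(y_hat, y, theta = numeric(0), lambda = 1e-5) {
  if (length(y_hat) != length(y))
    stop("y_hat and y must have equal length", call. = FALSE)
  if (!length(y)) stop("empty batch", call. = FALSE)
  mean((y_hat - y)^2) + lambda * sum(theta^2)
}

#' Extract attention maps from a fitted model
#'
#' Runs one sample through the network in evaluation mode and returns the
#' attention weights: per-head T x T self-attention over time
#' (query step x key step), the d_ds x T cross-modal map (summary-feature
#' query x minute), and the aggregated weights of the temporal query over
#' the summary tokens.  All rows are probability distributions.
#'
#' @param model A fitted [fat_net()] object.
#' @param ds A `"fatnet_dataset"`.
#' @param sample Index of the sample within `ds`.
#' @return A list of class `"fatnet_attention"` with `self`
#'   (T x T x n_heads array), `cross` (d_ds x T matrix, rows named by
#'   feature) and `cross_temporal` (length-d_ds vector).
#' @export
extract_attention <- function(model, ds, sample = 1L) {
  stopifnot(inherits(model, "fatnet"))
  one <- dataset_subset(ds, sample)
  one <- apply_input_stats(one, model$input_stats)
  maps <- nn_attention(.nn_handle(model), one$x_min, one$x_day)
  rownames(maps$cross) <- model$feature_names
  maps$cross_temporal <- stats::setNames(as.numeric(maps$cross_temporal),
                                         model$feature_names)
  structure(maps, class = "fatnet_attention")
}

#' Export attention maps as CSV files
#'
#' Writes `self_attn_<sample>.csv` (head-averaged T x T) and
#' `cross_attn_<sample>.csv` (d_ds x T, rows named by summary feature)
#' for one sample.
#'
#' @inheritParams extract_attention
#' @param path Output directory.
#' @return The paths written, invisibly.
#' @export
export_attention <- function(model, ds, sample = 1L, path = ".") {
  maps <- extract_attention(model, ds, sample)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  self_avg <- apply(maps$self, c(1, 2), mean)
  colnames(self_avg) <- paste0("minute_", seq_len(ncol(self_avg)))
  f1 <- file.path(path, sprintf("self_attn_%s.csv", sample))
  utils::write.csv(self_avg, f1, row.names = FALSE)
  cross <- maps$cross
  colnames(cross) <- paste0("minute_", seq_len(ncol(cross)))
  f2 <- file.path(path, sprintf("cross_attn_%s.csv", sample))
  utils::write.csv(data.frame(feature = rownames(cross), cross,
                              check.names = FALSE), f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Save / load a fitted model as a JSON checkpoint
#'
#' A single-file text archive holding the architecture configuration, the
#' learned parameter vector, the input statistics and the training
#' history.
#'
#' @param model A fitted `"fatnet_model"`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fatnet_model"))
  payload <- list(type = model$type, config = unclass(model$config),
                  params = model$params,
                  input_stats = unclass(model$input_stats),
                  feature_names = model$feature_names,
                  history = model$history,
                  val_y = model$val_y, val_pred = model$val_pred)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- p$config
  int_fields <- c("T", "d_ts", "d_ds", "h", "n_heads", "conv_filters",
                  "conv_kernels", "mlp_dims", "ffn_hidden", "head_hidden",
                  "batch_size", "max_epochs", "patience", "seed")
  for (f in intersect(int_fields, names(cfg))) cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "fatnet_config"
  st <- p$input_stats
  class(st) <- "input_stats"
  attr(st, "provenance") <- "fitted"
  obj <- structure(list(
    type = p$type, config = cfg, params = as.numeric(p$params),
    n_params = length(p$params), history = p$history,
    input_stats = st, feature_names = p$feature_names,
    val_y = p$val_y, val_pred = p$val_pred,
    .cache = new.env(parent = emptyenv())
  ), class = c(if (p$type == "fatnet") "fatnet" else "fatnet_seq_baseline",
               "fatnet_model"))
  obj
}
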