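# The compiled backend's analytic gradients are validated against central
# finite differences at tiny dimensions.  ReLU kinks can make individual
# finite differences unreliable, so the check is on the error distribution.
test_that("analytic gradients match finite differences for all networks", {
  set.seed(91)
  N <- 3; T <- 8; dts <- 2; dds <- 4
  cfg <- list(T = T, d_ts = dts, d_ds = dds, h = 8L, n_heads = 2L,
              conv_filters = c(3L, 4L, 5L), conv_kernels = c(5L, 3L, 3L),
              conv_dropout = 0, mlp_dims = c(6L, 7L), mlp_dropout = 0,
              ffn_hidden = c(9L, 10L), head_hidden = 6L, head_dropout = 0)
  xmin <- array(rnorm(N * T * dts), c(N, T, dts))
  xday <- matrix(rnorm(N * dds), N, dds)
  y <- rnorm(N)
  for (type in c("fatnet", "lstm", "tcn")) {
    ptr <- fatnet:::nn_create(type, cfg, 42L)
    g <- fatnet:::nn_loss_grad(ptr, xmin, xday, y, lambda = 1e-3)$grad
    p0 <- fatnet:::nn_get_params(ptr)
    idx <- sort(sample(length(p0), 60))
    eps <- 5e-3
    num <- vapply(idx, function(k) {
      p <- p0; p[k] <- p0[k] + eps
      fatnet:::nn_set_params(ptr, p)
      lp <- fatnet:::nn_loss_grad(ptr, xmin, xday, y, 1e-3, FALSE)$loss
      p[k] <- p0[k] - eps
      fatnet:::nn_set_params(ptr, p)
      lm <- fatnet:::nn_loss_grad(ptr, xmin, xday, y, 1e-3, FALSE)$loss
      (lp - lm) / (2 * eps)
    }, 0)
    rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-3)
    expect_lt(stats::median(rel), 0.005)
    expect_lt(sort(rel)[ceiling(0.9 * length(rel))], 0.05)
  }
})

test_that("tensor shapes follow the architecture contract", {
  coh <- tiny_cohort(seed = 92, T = 120)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, seed = 1)
  cfg <- fatnet_config(T = 120, h = 64, max_epochs = 1, patience = 1,
                       seed = 1)
  fit <- fat_net(sp$train, sp$val, cfg)
  one <- fatnet:::apply_input_stats(dataset_subset(sp$test, 1),
                                    fit$input_stats)
  tr <- fatnet:::nn_trace(fatnet:::.nn_handle(fit), one$x_min, one$x_day)
  dds <- ncol(ds$x_day)
  expect_equal(dim(tr$H_ts), c(120, 64))      # BiLSTM keeps length T
  expect_equal(dim(tr$U), c(120, 64))         # attention keeps T x h
  expect_length(tr$v_ts, 64)
  expect_length(tr$v_ds, 64)
  expect_equal(dim(tr$tokens), c(dds, 64))    # one token per summary feature
  expect_length(tr$F0, 128)                   # fused embedding is 2h
  expect_length(tr$y_hat, 1)
  # pooled vector is exactly the time mean of the attended sequence
  expect_equal(as.numeric(tr$v_ts), unname(colMeans(tr$U)),
               tolerance = 1e-5)
})

test_that("attention maps are row-stochastic and eval-deterministic", {
  coh <- tiny_cohort(seed = 93, T = 60)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, seed = 2)
  fit <- fat_net(sp$train, sp$val, tiny_net_config(60))
  att <- extract_attention(fit, sp$test, 1)
  for (hh in seq_len(dim(att$self)[3]))
    expect_equal(rowSums(att$self[, , hh]), rep(1, 60), tolerance = 1e-4)
  expect_equal(rowSums(att$cross), rep(1, nrow(att$cross)),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(sum(att$cross_temporal), 1, tolerance = 1e-4)
  expect_true(all(att$self >= 0 & att$self <= 1 + 1e-6))
  att2 <- extract_attention(fit, sp$test, 1)
  expect_identical(att$self, att2$self)
  # predictions are deterministic in evaluation mode
  expect_identical(predict(fit, sp$test), predict(fit, sp$test))
})

test_that("configuration invariants are enforced", {
  expect_error(fatnet_config(h = 63), "even")
  expect_error(fatnet_config(h = 64, n_heads = 3), "n_heads")
  expect_error(fatnet_config(T = 3), "kernel")
  expect_error(fatnet_config(conv_dropout = 1), "conv_dropout")
})

test_that("the explicit loss formula is arithmetic on MSE and theta", {
  expect_equal(fatnet_loss(c(1, 2), c(1, 2), theta = numeric(0)), 0)
  expect_equal(fatnet_loss(c(2, 3), c(1, 2), lambda = 0), 1)
  theta <- rep(1, 100)                      # ||theta||^2 = 100
  expect_equal(fatnet_loss(c(1, 2), c(1, 2), theta, lambda = 1e-5), 1e-3)
  expect_error(fatnet_loss(1:3, 1:2), "length")
  expect_error(fatnet_loss(numeric(0), numeric(0)), "empty")
})

test_that("training is seeded, early-stops, and restores the best epoch", {
  coh <- tiny_cohort(seed = 94, np = 8, days = 10, T = 60)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, seed = 3)
  cfg <- tiny_net_config(60, max_epochs = 30L, patience = 3L)
  fit1 <- fat_net(sp$train, sp$val, cfg)
  fit2 <- fat_net(sp$train, sp$val, cfg)
  expect_identical(fit1$params, fit2$params)
  expect_equal(unlist(fit1$history$val_mae), unlist(fit2$history$val_mae))
  h <- fit1$history
  if (h$n_epochs < cfg$max_epochs)          # early-stop contract
    expect_gte(h$n_epochs - h$best_epoch, cfg$patience)
  expect_equal(h$best_val_mae, min(unlist(h$val_mae)), tolerance = 1e-7)
  # two seeds give different (finite) trajectories
  fit3 <- fat_net(sp$train, sp$val, tiny_net_config(60, seed = 8L))
  expect_false(identical(fit1$params, fit3$params))
  expect_true(all(is.finite(unlist(fit3$history$train_loss))))
})

test_that("a noiseless linear target is learnable", {
  coh <- tiny_cohort(seed = 95, np = 10, days = 12, T = 60)
  ds <- tiny_pairs(coh)
  z <- scale(ds$x_day[, "panas"])
  ds$y <- as.numeric(0.8 * z)               # deterministic in one feature
  sp <- split_data(ds, seed = 4)
  cfg <- tiny_net_config(60, max_epochs = 40L, patience = 40L)
  fit <- fat_net(sp$train, sp$val, cfg)
  untrained_mae <- mean(abs(sp$val$y - mean(sp$train$y)))
  expect_lt(fit$history$best_val_mae, untrained_mae)
})

test_that("input standardization is fitted on training data only", {
  coh <- tiny_cohort(seed = 96, np = 8, days = 10, T = 60)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, seed = 5)
  fit <- fat_net(sp$train, sp$val, tiny_net_config(60))
  expect_identical(attr(fit$input_stats, "provenance"), "fitted")
  cont <- attr(ds, "continuous")
  expect_equal(unname(fit$input_stats$mu[cont]),
               unname(colMeans(sp$train$x_day)[cont]))
  # pooled statistics would differ
  expect_false(isTRUE(all.equal(unname(fit$input_stats$mu[cont]),
                                unname(colMeans(ds$x_day)[cont]))))
})

test_that("checkpoints round-trip through the JSON archive", {
  coh <- tiny_cohort(seed = 97, np = 6, days = 8, T = 60)
  ds <- tiny_pairs(coh)
  sp <- split_data(ds, seed = 6)
  fit <- fat_net(sp$train, sp$val, tiny_net_config(60))
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_equal(predict(back, sp$test), predict(fit, sp$test),
               tolerance = 1e-6)
  expect_equal(back$history$best_val_mae, fit$history$best_val_mae)
})
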