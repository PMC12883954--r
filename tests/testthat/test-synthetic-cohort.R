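test_that("generation is byte-identical under a fixed seed", {
  a <- tiny_cohort(seed = 11)
  b <- tiny_cohort(seed = 11)
  expect_identical(a$minutes, b$minutes)
  expect_identical(a$daily, b$daily)
  expect_identical(a$truth, b$truth)
  c2 <- tiny_cohort(seed = 12)
  expect_false(identical(a$minutes$hr_bpm, c2$minutes$hr_bpm))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(ar_rho = 1.2), "ar_rho")
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(T = 5), "T")
  expect_error(cohort_config(missing_day_rate = 1.5), "missing_day_rate")
  expect_error(cohort_config(component_loading = 0), "component_loading")
  expect_error(cohort_config(ar_rho = 0.9, music_effect_beta = 0.9),
               "music_effect_beta")
})

test_that("latent wellness is stationary with unit variance", {
  coh <- generate_cohort(cohort_config(n_participants = 120, days_mean = 45,
                                       days_sd = 5, T = 30, seed = 21))
  expect_gt(nrow(coh$truth), 5000)
  expect_lt(abs(stats::var(coh$truth$wellness) - 1), 0.1)
})

test_that("score components are equicorrelated at loading^2", {
  coh <- generate_cohort(cohort_config(n_participants = 60, days_mean = 40,
                                       days_sd = 5, T = 30, seed = 22))
  expect_gt(nrow(coh$daily), 2000)
  R <- stats::cor(coh$daily[, c("panas", "sleep_efficiency", "rmssd")])
  off <- R[upper.tri(R)]
  expect_true(all(abs(off - 0.5) < 0.05))
})

test_that("wellness has no persistence when ar_rho and beta are zero", {
  coh <- generate_cohort(cohort_config(n_participants = 40, days_mean = 40,
                                       days_sd = 0, T = 30, ar_rho = 0,
                                       music_effect_beta = 0, seed = 23))
  w <- coh$truth$wellness
  lag <- ave(w, coh$truth$participant_id, FUN = function(v) c(v[-1], NA))
  ok <- !is.na(lag)
  expect_lt(abs(stats::cor(w[ok], lag[ok])), 3 / sqrt(sum(ok)) + 0.02)
})

test_that("music interaction raises next-day R2 by the configured share", {
  coh <- generate_cohort(cohort_config(n_participants = 40, days_mean = 30,
                                       days_sd = 0, T = 120, seed = 24))
  tr <- coh$truth[order(coh$truth$participant_id, coh$truth$day_index), ]
  nxt <- ave(tr$wellness, tr$participant_id, FUN = function(v) c(v[-1], NA))
  ok <- !is.na(nxt)
  r2_w <- summary(stats::lm(nxt[ok] ~ tr$wellness[ok]))$r.squared
  r2_wg <- summary(stats::lm(nxt[ok] ~ tr$wellness[ok] + tr$g_std[ok]))$r.squared
  expect_lt(abs((r2_wg - r2_w) - 0.35), 0.05)
})

test_that("missingness injection matches the configured rates", {
  coh <- tiny_cohort(seed = 31)
  same <- inject_missingness(coh, cohort_config(missing_day_rate = 0,
                                                missing_minute_rate = 0))
  expect_identical(same$minutes, coh$minutes)
  all_na <- inject_missingness(coh, cohort_config(missing_minute_rate = 1))
  expect_true(all(is.na(all_na$minutes$hr_bpm)))
  # binomial count: 10,000 minutes at rate 0.05
  coh2 <- generate_cohort(cohort_config(n_participants = 5, days_mean = 10,
                                        days_sd = 0, T = 200, seed = 32))
  expect_equal(nrow(coh2$minutes), 10000)
  set.seed(33)
  inj <- inject_missingness(coh2, cohort_config(missing_minute_rate = 0.05))
  n_miss <- sum(is.na(inj$minutes$hr_bpm))
  expect_lt(abs(n_miss - 500), 3 * sqrt(475))
})

test_that("missing days mask measurements and can exceed exclusion counts", {
  coh <- generate_cohort(cohort_config(n_participants = 92, days_mean = 45,
                                       days_sd = 10, T = 30, seed = 34))
  set.seed(35)
  inj <- inject_missingness(coh, cohort_config(missing_day_rate = 0.12))
  expect_true(any(is.na(inj$daily$panas)))
  frac <- tapply(inj$daily$day_missing, inj$daily$participant_id, mean)
  expect_gte(sum(frac > 0.10), 8)
})

test_that("export/import round-trips all feature fields", {
  coh <- tiny_cohort(seed = 41, np = 3, days = 5, T = 30)
  d <- withr::local_tempdir()
  export_cohort(coh, d)
  back <- import_cohort(d)
  expect_equal(back$minutes$hr_bpm, coh$minutes$hr_bpm)
  expect_equal(back$daily[names(back$daily) != "gender"],
               coh$daily[names(coh$daily) != "gender"],
               ignore_attr = TRUE)
  expect_equal(back$daily$gender, coh$daily$gender)
  expect_equal(back$truth$wellness, coh$truth$wellness)
  expect_equal(back$config$seed, coh$config$seed)
})

test_that("import reports missing required columns by name", {
  coh <- tiny_cohort(seed = 42, np = 2, days = 5, T = 30)
  d <- withr::local_tempdir()
  export_cohort(coh, d)
  m <- utils::read.csv(file.path(d, "cohort_minutes.csv"))
  m$hr_bpm <- NULL
  utils::write.csv(m, file.path(d, "cohort_minutes.csv"), row.names = FALSE)
  expect_error(import_cohort(d), "hr_bpm")
})

test_that("an empty cohort survives the round trip", {
  coh <- tiny_cohort(seed = 43, np = 2, days = 5, T = 30)
  for (f in c("profiles", "minutes", "daily", "truth"))
    coh[[f]] <- coh[[f]][0, , drop = FALSE]
  d <- withr::local_tempdir()
  export_cohort(coh, d)
  back <- import_cohort(d)
  expect_equal(nrow(back$minutes), 0)
  expect_equal(nrow(back$daily), 0)
})
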