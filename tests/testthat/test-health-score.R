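test_that("component z-scores match hand computation", {
  comp <- standardize_components(c(1, 2, 3), c(10, 20, 30), c(5, 6, 7))
  expect_equal(comp$Z_M, c(-1, 0, 1))
  expect_equal(comp$Z_S, c(-1, 0, 1))
  # a row at the cohort mean has z = 0
  expect_equal(comp$Z_H[2], 0)
  # duplicating the cohort leaves z-scores essentially unchanged (exactly,
  # up to the sample-sd degrees-of-freedom factor)
  set.seed(60)
  M <- rnorm(300, 30, 6); S <- rnorm(300, 85, 7); H <- rnorm(300, 35, 10)
  single <- standardize_components(M, S, H)
  dup <- standardize_components(rep(M, 2), rep(S, 2), rep(H, 2))
  expect_equal(dup$Z_M[1:300], single$Z_M, tolerance = 2e-3)
  expect_error(standardize_components(c(1, 1), c(1, 2), c(1, 2)), "M")
  expect_error(standardize_components(1, c(1, 2), c(1, 2)), "length")
})

test_that("equal-weight score averages the three z-scores", {
  comp <- standardize_components(c(1, 2, 3), c(10, 20, 30), c(5, 6, 7))
  expect_equal(equal_weight_score(comp), rowMeans(
    cbind(comp$Z_M, comp$Z_S, comp$Z_H)))
  # hand value: z-rows (-1,-1,-1) -> -1, (0,0,0) -> 0
  expect_equal(equal_weight_score(comp)[2], 0)
  expect_equal(mean(equal_weight_score(comp)), 0, tolerance = 1e-12)
})

test_that("PCA score matches eigenstructure expectations", {
  # rank-1 input: perfectly collinear components -> PC1 carries 100%
  z <- c(-1.2, 0.3, 0.9, -0.5, 0.5)
  comp1 <- standardize_components(z, 2 * z + 1, 3 * z - 2)
  p <- pca_score(comp1)
  expect_equal(p$pc1_variance_fraction, 100, tolerance = 1e-8)
  # sign convention: positive correlation with the equal-weight score
  expect_gt(stats::cor(p$score, equal_weight_score(comp1)), 0)
})

test_that("equicorrelated components give lambda = 1 + 2r and 66.7%", {
  coh <- generate_cohort(cohort_config(n_participants = 60, days_mean = 40,
                                       days_sd = 5, T = 30, seed = 61))
  comp <- standardize_components(coh$daily$panas,
                                 coh$daily$sleep_efficiency,
                                 coh$daily$rmssd)
  p <- pca_score(comp)
  expect_lt(abs(p$pc1_variance_fraction - 66.7), 3.5)
  ev <- eigen(stats::cor(cbind(comp$Z_M, comp$Z_S, comp$Z_H)))$values
  expect_lt(abs(ev[1] - 2.0), 0.12)
  expect_lt(abs(ev[2] - 0.5), 0.08)
  # under equicorrelation PC1 weights equalize, so the PCA score is
  # (nearly) proportional to the equal-weight score
  eq <- equal_weight_score(comp)
  cosine <- sum(p$score * eq) / sqrt(sum(p$score^2) * sum(eq^2))
  expect_gt(cosine, 0.999)
})

test_that("PCA agrees with an independent prcomp decomposition", {
  set.seed(62)
  for (i in 1:5) {
    X <- matrix(rnorm(300), ncol = 3) %*% matrix(rnorm(9), 3)
    comp <- standardize_components(X[, 1], X[, 2], X[, 3])
    p <- pca_score(comp)
    pr <- stats::prcomp(cbind(comp$Z_M, comp$Z_S, comp$Z_H), scale. = TRUE)
    expect_equal(p$pc1_variance_fraction,
                 100 * pr$sdev[1]^2 / sum(pr$sdev^2), tolerance = 1e-10)
    expect_equal(abs(stats::cor(p$score, pr$x[, 1])), 1, tolerance = 1e-8)
  }
  # independent components at large n: fraction approaches 1/3
  set.seed(63)
  comp <- standardize_components(rnorm(5000), rnorm(5000), rnorm(5000))
  expect_lt(abs(pca_score(comp)$pc1_variance_fraction - 33.3), 2.5)
})

test_that("Cronbach's alpha matches theory and a brute-force oracle", {
  z <- c(-1, 0, 1, 2, -2)
  expect_equal(cronbach_alpha(cbind(z, z, z)), 1)
  # pairwise r = 0.5 unit-variance items -> alpha = 0.75
  set.seed(64)
  w <- rnorm(20000)
  X <- sqrt(0.5) * w + sqrt(0.5) * matrix(rnorm(60000), ncol = 3)
  expect_lt(abs(cronbach_alpha(X) - 0.75), 0.01)
  # independent items -> alpha near 0
  X0 <- matrix(rnorm(30000), ncol = 3)
  expect_lt(abs(cronbach_alpha(X0)), 0.05)
  # brute-force variance decomposition on random tables
  set.seed(65)
  for (i in 1:10) {
    Y <- matrix(rnorm(60, sd = runif(1, 0.5, 3)), ncol = 3)
    k <- 3
    brute <- k / (k - 1) *
      (1 - sum(diag(stats::cov(Y))) / sum(stats::cov(Y)))
    expect_equal(cronbach_alpha(Y), brute, tolerance = 1e-10)
  }
})

test_that("distribution checks behave on symmetric, normal and bad input", {
  d <- distribution_checks(c(-2, 0, 2, -1, 0, 1))
  expect_equal(d$skewness, 0, tolerance = 1e-12)
  set.seed(66)
  d2 <- distribution_checks(rnorm(4000))
  expect_lt(abs(d2$skewness), 0.2)
  expect_lt(abs(d2$kurtosis), 0.5)
  expect_gt(d2$shapiro_p, 1e-4)
  expect_error(distribution_checks(rep(1, 10)), "constant")
  expect_error(distribution_checks(c(1, 2)), "3")
})

test_that("responsiveness is rank-based on within-participant changes", {
  id <- rep(c("a", "b"), each = 6)
  s <- c(1, 2, 4, 3, 5, 6, 2, 1, 3, 5, 4, 6)
  # a positive affine transform of the score has rho = 1 (both series are
  # differenced, so only order-preserving *changes* give perfect agreement)
  expect_equal(responsiveness(s, 3 * s + 2, id), 1)
  set.seed(67)
  id2 <- rep(sprintf("p%02d", 1:50), each = 40)
  s2 <- rnorm(2000)
  expect_lt(abs(responsiveness(s2, rnorm(2000), id2)), 0.08)
  expect_error(responsiveness(1:3, 1:3, c("a", "a", "b")), "3")
})

test_that("default generator responsiveness exceeds 0.6", {
  coh <- generate_cohort(cohort_config(n_participants = 60, days_mean = 40,
                                       days_sd = 5, T = 120, seed = 68))
  expect_gt(nrow(coh$daily), 2000)
  hs <- health_score(engineer_features(coh$daily))
  rho <- responsiveness(hs$score, coh$truth$rating,
                        coh$daily$participant_id)
  expect_gt(rho, 0.6)
  expect_lt(abs(rho - 0.69), 0.06)
})

test_that("binary labels follow the strict 75th-percentile rule", {
  expect_equal(sum(binary_label(1:100) == "Good"), 25)
  expect_equal(sum(binary_label(rep(3, 10)) == "Good"), 0)
  expect_equal(sum(binary_label(c(1, 2, 3, 4)) == "Good"), 1)
  expect_error(binary_label(1:3), "4")
})

test_that("the composite score is invariant to affine component rescaling", {
  coh <- tiny_cohort(seed = 69)
  a <- health_score(coh$daily)$score
  re <- coh$daily
  re$panas <- re$panas * 7 - 100
  re$sleep_efficiency <- re$sleep_efficiency / 3 + 2
  b <- health_score(re)$score
  expect_equal(a, b, tolerance = 1e-10)
})
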