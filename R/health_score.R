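#' Standardize the three Health Score components
#'
#' The composite targets are built from three day-level wellbeing
#' dimensions: `M` (PANAS positive-affect sum, 10-50), `S` (sleep
#' efficiency, %) and `H` (resting RMSSD, ms).  Each is standardized to
#' zero mean and unit variance across the whole cohort (this cohort-wide
#' standardization *defines* the target, unlike predictor standardization
#' which is fit on the training split only).
#'
#' @param M,S,H Numeric vectors of equal length (>= 2), non-constant.
#' @return A data frame of class `"health_components"` with the raw
#'   values and z-scores `Z_M`, `Z_S`, `Z_H`; cohort means and SDs are
#'   stored in the `"mu"` and `"sigma"` attributes.
#' @examples
#' standardize_components(c(30, 36, 42), c(80, 85, 90), c(25, 35, 45))$Z_M
#' @export
standardize_components <- function(M, S, H) {
  n <- length(M)
  if (length(S) != n || length(H) != n)
    stop("component vectors must have equal length", call. = FALSE)
  if (n < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  mu <- c(M = mean(M), S = mean(S), H = mean(H))
  sigma <- c(M = stats::sd(M), S = stats::sd(S), H = stats::sd(H))
  if (any(sigma == 0 | !is.finite(sigma)))
    stop("constant component(s): ",
         paste(names(sigma)[sigma == 0 | !is.finite(sigma)], collapse = ", "),
         call. = FALSE)
  out <- data.frame(M = M, S = S, H = H,
                    Z_M = (M - mu["M"]) / sigma["M"],
                    Z_S = (S - mu["S"]) / sigma["S"],
                    Z_H = (H - mu["H"]) / sigma["H"])
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  class(out) <- c("health_components", "data.frame")
  out
}

z_matrix <- function(components) {
  stopifnot(inherits(components, "health_components"))
  as.matrix(components[, c("Z_M", "Z_S", "Z_H")])
}

#' Equal-weight composite Health Score
#'
#' `Health_i = (Z_M + Z_S + Z_H) / 3`; the cohort mean is zero by
#' construction.
#'
#' @param components A [standardize_components()] result.
#' @return Numeric score vector.
#' @export
equal_weight_score <- function(components) {
  rowMeans(z_matrix(components))
}

#' PCA-derived composite Health Score
#'
#' Projects the standardized components on the first eigenvector of their
#' 3x3 correlation matrix, a data-driven alternative weighting.  The
#' eigenvector sign is fixed so the score correlates positively with the
#' equal-weight score ("higher = healthier").
#'
#' @param components A [standardize_components()] result with >= 3 rows.
#' @return A list with `score`, `pc1_variance_fraction` (percent of total
#'   variance explained by the first component, `lambda_1 / 3 * 100`) and
#'   the `weights` (loadings) used.
#' @export
pca_score <- function(components) {
  Z <- z_matrix(components)
  if (nrow(Z) < 3) stop("need at least 3 rows for PCA", call. = FALSE)
  R <- stats::cor(Z)
  ev <- eigen(R, symmetric = TRUE)
  w <- ev$vectors[, 1]
  score <- as.numeric(Z %*% w)
  eq <- rowMeans(Z)
  if (stats::sd(score) > 0 && stats::sd(eq) > 0 &&
      stats::cor(score, eq) < 0) {
    w <- -w; score <- -score
  } else if (sum(w) < 0) {
    w <- -w; score <- -score
  }
  list(score = score,
       pc1_variance_fraction = 100 * ev$values[1] / sum(ev$values),
       weights = w)
}

#' Cronbach's alpha of the score components
#'
#' Internal-consistency reliability of the three-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))` with
#' `k = 3`.  Values above 0.7 indicate adequate consistency for an
#' equal-weight composite.
#'
#' @param components A [standardize_components()] result, or a numeric
#'   matrix/data frame of item columns.
#' @return The alpha coefficient.
#' @export
cronbach_alpha <- function(components) {
  X <- if (inherits(components, "health_components")) z_matrix(components)
       else as.matrix(components)
  k <- ncol(X)
  if (k < 2 || nrow(X) < 2)
    stop("need >= 2 items and >= 2 rows", call. = FALSE)
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop("zero total variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / total_var)
}

sample_skewness <- function(x) {
  n <- length(x); m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^4) / s^4 - 3
}

#' Distributional diagnostics of a composite score
#'
#' Shapiro-Wilk normality p-value (on a fixed-seed subsample of 5000 when
#' n exceeds the test's limit), moment-based sample skewness and excess
#' kurtosis.  An approximately normal composite has `|skewness|` and
#' `|kurtosis|` within 1.
#'
#' @param score Numeric vector, length >= 3, non-constant.
#' @return A list with `shapiro_p`, `skewness` and `kurtosis`.
#' @export
distribution_checks <- function(score) {
  if (length(score) < 3)
    stop("need at least 3 observations for distribution checks",
         call. = FALSE)
  if (stats::sd(score) == 0)
    stop("score is constant; distribution checks undefined", call. = FALSE)
  sub <- score
  if (length(sub) > 5000) {
    old <- .Random.seed_safe()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(20260101L)
    sub <- sample(score, 5000L)
  }
  list(shapiro_p = stats::shapiro.test(sub)$p.value,
       skewness = sample_skewness(score),
       kurtosis = sample_excess_kurtosis(score))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Responsiveness of the score to self-reported global health
#'
#' Correlates *day-to-day changes* of the composite score with day-to-day
#' changes of the 1-10 global health rating: both series are
#' first-differenced within participant, the differences pooled across
#' participants, and Spearman's rank correlation computed on the pool.
#'
#' @param score,rating Aligned numeric vectors (one entry per
#'   participant-day).
#' @param participant_id Vector of participant identifiers aligning the
#'   two series; days are differenced in the order supplied within each
#'   participant.
#' @return Spearman's rho of the pooled differences.
#' @export
responsiveness <- function(score, rating, participant_id) {
  n <- length(score)
  if (length(rating) != n || length(participant_id) != n)
    stop("score, rating and participant_id must align", call. = FALSE)
  ds <- unlist(tapply(score, participant_id, diff, simplify = FALSE),
               use.names = FALSE)
  dr <- unlist(tapply(rating, participant_id, diff, simplify = FALSE),
               use.names = FALSE)
  if (length(ds) < 3)
    stop("fewer than 3 pooled difference pairs", call. = FALSE)
  stats::cor(ds, dr, method = "spearman")
}

#' Binary Good / Not-Good labelling
#'
#' Labels a day "Good" when its score strictly exceeds the cohort's 75th
#' percentile (linear-interpolation quantile); ties at or below the
#' threshold are "Not-Good".
#'
#' @param score Numeric vector, length >= 4.
#' @return Character vector of `"Good"` / `"Not-Good"` labels.
#' @export
binary_label <- function(score) {
  if (length(score) < 4)
    stop("need at least 4 scores for quartile labelling", call. = FALSE)
  thr <- stats::quantile(score, 0.75, type = 7, names = FALSE)
  ifelse(score > thr, "Good", "Not-Good")
}

#' Compute composite Health Scores and their diagnostics for a cohort
#'
#' Convenience wrapper running the full target-construction pipeline on a
#' daily table: component standardization, equal-weight and PCA scores,
#' binary labels, reliability (Cronbach's alpha, PC1 variance fraction),
#' distributional checks, and - when ratings are supplied - responsiveness.
#'
#' @param daily_table Data frame with `panas`, `sleep_efficiency`,
#'   `rmssd` and (for responsiveness) `participant_id` columns.
#' @param rating Optional aligned vector of 1-10 global health ratings
#'   (diagnostics only; never a model feature).
#' @param method Which score the `score` element carries:
#'   `"equal"` (default) or `"pca"`.
#' @return A list of class `"health_score"` with `scores` (data frame:
#'   ids, `equal_weight`, `pca_score`, `label`), `score` (the selected
#'   target vector), `components` and `diagnostics`.
#' @export
health_score <- function(daily_table, rating = NULL,
                         method = c("equal", "pca")) {
  method <- match.arg(method)
  req <- c("panas", "sleep_efficiency", "rmssd")
  miss <- setdiff(req, names(daily_table))
  if (length(miss))
    stop("daily table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  comp <- standardize_components(daily_table$panas,
                                 daily_table$sleep_efficiency,
                                 daily_table$rmssd)
  eq <- equal_weight_score(comp)
  pc <- pca_score(comp)
  diagnostics <- c(
    list(cronbach_alpha = cronbach_alpha(comp),
         pc1_variance_fraction = pc$pc1_variance_fraction),
    distribution_checks(eq)
  )
  if (!is.null(rating) && "participant_id" %in% names(daily_table))
    diagnostics$responsiveness_rho <-
      responsiveness(eq, rating, daily_table$participant_id)
  scores <- data.frame(
    participant_id = if ("participant_id" %in% names(daily_table))
      daily_table$participant_id else NA,
    day_index = if ("day_index" %in% names(daily_table))
      daily_table$day_index else seq_along(eq),
    equal_weight = eq, pca_score = pc$score, label = binary_label(eq),
    stringsAsFactors = FALSE
  )
  structure(list(scores = scores,
                 score = if (method == "equal") eq else pc$score,
                 method = method, components = comp,
                 pca_weights = pc$weights, diagnostics = diagnostics),
            class = "health_score")
}

#' @export
print.health_score <- function(x, ...) {
  cat("Composite Health Score (", x$method, "-weight target)\n", sep = "")
  cat(sprintf("  days scored: %d\n", nrow(x$scores)))
  d <- x$diagnostics
  cat(sprintf("  Cronbach's alpha: %.3f\n", d$cronbach_alpha))
  cat(sprintf("  PC1 variance fraction: %.1f%%\n", d$pc1_variance_fraction))
  cat(sprintf("  skewness %.2f, excess kurtosis %.2f, Shapiro p %.3f\n",
              d$skewness, d$kurtosis, d$shapiro_p))
  if (!is.null(d$responsiveness_rho))
    cat(sprintf("  responsiveness (Spearman rho of daily changes): %.3f\n",
                d$responsiveness_rho))
  cat(sprintf("  'Good' days (above 75th percentile): %d\n",
              sum(x$scores$label == "Good")))
  invisible(x)
}
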