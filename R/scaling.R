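#' Reference isometric slopes for spiracle metrics
#'
#' Under geometric similarity (mass proportional to volume), areas scale with
#' mass^0.67, lengths with mass^0.33, so area/depth scales with mass^0.33 and
#' area^2/depth with mass^1.
#'
#' @param metric one of `depth`, `area`, `diff_index`, `adv_index`,
#'   `total_diff`, `total_adv` (vectorized).
#' @return Named numeric vector of reference slopes.
#' @export
isometric_slope <- function(metric) {
  ref <- c(depth = 0.33, area = 0.67, diff_index = 0.33, adv_index = 1,
           total_diff = 0.33, total_adv = 1)
  bad <- !metric %in% names(ref)
  if (any(bad)) stop("unknown metric: ", paste(metric[bad], collapse = ", "))
  ref[metric]
}

#' Ordinary least squares fit on log10-log10 axes
#'
#' Allometric power-law fit: regresses `log10(value)` on `log10(mass)` by
#' OLS. The residual standard deviation uses the n - 2 denominator.
#'
#' @param mass body masses, g (> 0).
#' @param value trait values (> 0), same length.
#' @param metric optional metric name carried in the result.
#' @return A `scaling_fit` object with `slope`, `intercept` (log10 trait at
#'   1 g), `residual_sd`, `n`.
#' @examples
#' m <- c(1, 10); loglog_ols(m, 10 * m)  # slope 1, intercept 1
#' @export
loglog_ols <- function(mass, value, metric = NULL) {
  if (length(mass) != length(value)) stop("loglog_ols: length mismatch")
  if (any(!is.finite(mass)) || any(mass <= 0) ||
      any(!is.finite(value)) || any(value <= 0))
    stop("loglog_ols: mass and value must be finite and > 0")
  if (length(unique(mass)) < 2L)
    stop("degenerate design: need at least 2 distinct masses")
  x <- log10(mass); y <- log10(value)
  fit <- stats::lm(y ~ x)
  n <- length(x)
  res_sd <- if (n > 2L) sqrt(sum(stats::residuals(fit)^2) / (n - 2L)) else 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = res_sd, n = n, metric = metric),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("log10-log10 OLS fit%s: slope %.4f, intercept %.4f, resid sd %.4f (n = %d)\n",
              if (is.null(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$slope, x$intercept, x$residual_sd, x$n))
  invisible(x)
}

# Fast OLS summaries for a B x n index matrix (case resampling).
# Returns slope, intercept, resid_sd per row.
.boot_ols_rows <- function(idx, x, y) {
  B <- nrow(idx); n <- ncol(idx)
  X <- matrix(x[idx], B, n)
  Y <- matrix(y[idx], B, n)
  xb <- rowMeans(X); yb <- rowMeans(Y)
  sxx <- rowSums(X * X) - n * xb * xb
  sxy <- rowSums(X * Y) - n * xb * yb
  syy <- rowSums(Y * Y) - n * yb * yb
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  sse <- pmax(syy - slope * sxy, 0)
  list(slope = slope, intercept = intercept,
       resid_sd = sqrt(sse / pmax(n - 2L, 1L)),
       degenerate = rowSums(X == X[, 1]) == n)
}

#' Nonparametric case-resampling bootstrap of a log-log scaling fit
#'
#' Resamples (mass, value) pairs with replacement `B` times, refitting the
#' OLS regression each time, and summarises slope, intercept and residual
#' standard deviation. Percentile confidence intervals use linear
#' interpolation between order statistics (`stats::quantile` type 7), so CI
#' endpoints are re-derivable from the retained sample vectors. Resamples in
#' which all masses coincide leave the slope undefined and are redrawn; the
#' number of redraws is recorded.
#'
#' @param mass,value as in [loglog_ols()]; n >= 3 required.
#' @param B number of bootstrap replicates (default 10000; below 100 a
#'   warning is issued).
#' @param seed RNG seed for reproducibility (NULL: use current RNG state).
#' @param ci_level confidence level for percentile intervals.
#' @param metric optional metric name carried in the result.
#' @return A `bootstrap_fit` object: the point `fit`, sample vectors
#'   `slope_samples`, `intercept_samples`, `resid_sd_samples`, percentile
#'   `ci` rows for slope/intercept, `B`, `seed`, `ci_level`, `n_redraws`.
#' @export
bootstrap_fit <- function(mass, value, B = 10000, seed = NULL,
                          ci_level = 0.95, metric = NULL) {
  fit <- loglog_ols(mass, value, metric = metric)
  n <- fit$n
  if (n < 3L) stop("bootstrap_fit: need n >= 3")
  if (B < 100) warning("bootstrap_fit: B < 100 gives unstable intervals")
  if (!is.null(seed)) set.seed(seed)
  x <- log10(mass); y <- log10(value)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
  res <- .boot_ols_rows(idx, x, y)
  n_redraws <- 0L
  bad <- which(res$degenerate)
  while (length(bad)) {
    n_redraws <- n_redraws + length(bad)
    idx[bad, ] <- sample.int(n, n * length(bad), replace = TRUE)
    res <- .boot_ols_rows(idx, x, y)
    bad <- which(res$degenerate)
  }
  a <- (1 - ci_level) / 2
  probs <- c(a, 1 - a)
  ci <- rbind(slope = stats::quantile(res$slope, probs, names = FALSE),
              intercept = stats::quantile(res$intercept, probs, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(fit = fit, B = B, seed = seed, ci_level = ci_level,
                 slope_samples = res$slope,
                 intercept_samples = res$intercept,
                 resid_sd_samples = res$resid_sd,
                 ci = ci, n_redraws = n_redraws, metric = metric),
            class = "bootstrap_fit")
}

#' @export
print.bootstrap_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  bootstrap (B = %d): slope %d%% CI [%.4f, %.4f]\n",
              x$B, round(100 * x$ci_level), x$ci["slope", 1], x$ci["slope", 2]))
  invisible(x)
}

#' Bootstrap test of a scaling slope against a reference (e.g. isometry)
#'
#' Two-sided bootstrap p-value: the fraction of replicates at least as
#' extreme as the reference on each side, doubled and clipped to 1 —
#' `p = min(1, 2 * min(mean(s <= ref), mean(s >= ref)))`.
#'
#' @param boot a [bootstrap_fit()] result.
#' @param reference_slope reference value (e.g. 0.67 for area isometry).
#' @param statistic which sampled statistic to test.
#' @return p-value in `[0, 1]`.
#' @export
isometry_test <- function(boot, reference_slope,
                          statistic = c("slope", "intercept")) {
  statistic <- match.arg(statistic)
  s <- boot[[paste0(statistic, "_samples")]]
  p <- 2 * min(mean(s <= reference_slope), mean(s >= reference_slope))
  min(1, p)
}

#' Relative variability of a scaling relationship
#'
#' Residual standard deviation of the log-log fit divided by
#' `10^intercept` — the predicted trait value for a 1 g animal — giving a
#' dimensionless spread that can be compared across spiracles of very
#' different absolute size. For a bootstrap or posterior object the
#' statistic is computed per sample and summarised by its median and a
#' percentile interval.
#'
#' @param x a `scaling_fit`, `bootstrap_fit` or `posterior_summary`.
#' @param probs interval probabilities for the sample-based variants.
#' @param ... unused.
#' @return For a `scaling_fit`: a number. Otherwise a list with `samples`,
#'   `median`, `interval`.
#' @export
relative_variability <- function(x, ...) UseMethod("relative_variability")

#' @rdname relative_variability
#' @export
relative_variability.scaling_fit <- function(x, ...) {
  x$residual_sd / 10^x$intercept
}

#' @rdname relative_variability
#' @export
relative_variability.bootstrap_fit <- function(x, probs = c(0.025, 0.975), ...) {
  s <- x$resid_sd_samples / 10^x$intercept_samples
  list(samples = s, median = stats::median(s),
       interval = stats::quantile(s, probs, names = FALSE))
}

#' @rdname relative_variability
#' @export
relative_variability.posterior_summary <- function(x, probs = c(0.03, 0.97), ...) {
  s <- x$draws[, "sigma"] / 10^x$draws[, "intercept"]
  list(samples = s, median = stats::median(s),
       interval = stats::quantile(s, probs, names = FALSE))
}
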