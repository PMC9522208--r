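#' Shortest (highest-posterior-density) interval of a sample
#'
#' @param samples numeric vector of posterior draws.
#' @param mass probability mass the interval must contain (default 0.95;
#'   0.94 reproduces the "3rd-97th" convention used in the figures).
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("hpd_interval: mass must be in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(s[1], s[n]))
  widths <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(widths)
  c(s[i], s[i + k])
}

#' Weakly informative default priors for the Bayesian log-log regression
#'
#' Normal(0, 5) on slope and intercept and HalfNormal(1) on the residual
#' standard deviation, all on the log10 scale — diffuse relative to any
#' biologically plausible allometric exponent.
#'
#' @param slope_mean,slope_sd slope prior.
#' @param intercept_mean,intercept_sd intercept prior.
#' @param sigma_sd scale of the half-normal prior on sigma.
#' @return A named list of prior hyperparameters.
#' @export
default_priors <- function(slope_mean = 0, slope_sd = 5,
                           intercept_mean = 0, intercept_sd = 5,
                           sigma_sd = 1) {
  stopifnot(slope_sd > 0, intercept_sd > 0, sigma_sd > 0)
  list(slope_mean = slope_mean, slope_sd = slope_sd,
       intercept_mean = intercept_mean, intercept_sd = intercept_sd,
       sigma_sd = sigma_sd)
}

.bayes_model_string <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(intercept + slope * x[i], tau)
  }
  slope ~ dnorm(slope_mean, 1 / (slope_sd * slope_sd))
  intercept ~ dnorm(intercept_mean, 1 / (intercept_sd * intercept_sd))
  sigma ~ dnorm(0, 1 / (sigma_sd * sigma_sd)) T(0,)
  tau <- 1 / (sigma * sigma)
}"

#' Bayesian log-log allometric regression
#'
#' Normal likelihood with mean given by a line in log10-log10 space,
#' sampled with JAGS (Gibbs/slice sampling via \pkg{rjags}). Medians, HPD
#' intervals at 94% (the "3rd-97th" figure convention) and 95%, and an
#' effective-sample-size diagnostic are returned; non-convergence (minimum
#' ESS below `min_ess`) is flagged in the result, never silent.
#'
#' With zero-length data the posterior is the prior; that degenerate case is
#' sampled directly from the prior distributions (JAGS does not accept
#' zero-length data loops).
#'
#' @param mass,value as in [loglog_ols()] (may be empty for a prior-only run).
#' @param priors see [default_priors()].
#' @param draws posterior draws to keep.
#' @param warmup adaptation + burn-in iterations.
#' @param seed RNG seed (reproducible draws for a fixed seed).
#' @param min_ess convergence threshold on the minimum effective sample size.
#' @return A `posterior_summary` object: `draws` matrix (columns `slope`,
#'   `intercept`, `sigma`), `medians`, `hpd94`, `hpd95`, `ess`, `converged`.
#' @export
bayes_loglog <- function(mass, value, priors = default_priors(),
                         draws = 4000, warmup = 1000, seed = 1,
                         min_ess = 100) {
  if (length(mass) != length(value)) stop("bayes_loglog: length mismatch")
  if (length(mass) == 0L) {
    set.seed(seed)
    mat <- cbind(slope = stats::rnorm(draws, priors$slope_mean, priors$slope_sd),
                 intercept = stats::rnorm(draws, priors$intercept_mean,
                                          priors$intercept_sd),
                 sigma = abs(stats::rnorm(draws, 0, priors$sigma_sd)))
    return(.posterior_summary(mat, converged = TRUE, prior_only = TRUE))
  }
  if (length(mass) < 3L) stop("bayes_loglog: need n >= 3 (or n = 0 for prior-only)")
  if (any(mass <= 0) || any(value <= 0))
    stop("bayes_loglog: mass and value must be > 0")
  dat <- c(list(x = log10(mass), y = log10(value), N = length(mass)), priors)
  model <- rjags::jags.model(
    textConnection(.bayes_model_string), data = dat,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed),
    n.chains = 1, n.adapt = max(100, warmup %/% 2), quiet = TRUE)
  stats::update(model, n.iter = max(100, warmup %/% 2), progress.bar = "none")
  samp <- rjags::coda.samples(model, c("slope", "intercept", "sigma"),
                              n.iter = draws, progress.bar = "none")
  mat <- as.matrix(samp)[, c("slope", "intercept", "sigma"), drop = FALSE]
  ess <- coda::effectiveSize(samp)[c("slope", "intercept", "sigma")]
  .posterior_summary(mat, converged = all(ess >= min_ess), ess = ess)
}

.posterior_summary <- function(mat, converged, ess = NULL, prior_only = FALSE) {
  structure(list(
    draws = mat,
    medians = apply(mat, 2, stats::median),
    hpd94 = t(apply(mat, 2, hpd_interval, mass = 0.94)),
    hpd95 = t(apply(mat, 2, hpd_interval, mass = 0.95)),
    ess = ess, converged = converged, prior_only = prior_only
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(if (x$prior_only) "Prior-only sample" else "Posterior summary",
      sprintf("(%d draws%s):\n", nrow(x$draws),
              if (x$converged) "" else "; NOT CONVERGED"))
  tab <- cbind(median = x$medians, hpd95_low = x$hpd95[, 1],
               hpd95_high = x$hpd95[, 2])
  print(round(tab, 4))
  invisible(x)
}
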