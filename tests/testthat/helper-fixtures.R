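# Fixtures and independent oracles shared across the test files.

# One measurement row in the long-form table dialect.
measurement_row <- function(specimen_id, species, mass, spiracle,
                            d_t, d_s, depth, sex = "F") {
  data.frame(specimen_id = specimen_id, species = species, sex = sex,
             mass_g = mass, spiracle = spiracle,
             d_transverse_mm = d_t, d_sagittal_mm = d_s, depth_mm = depth,
             stringsAsFactors = FALSE)
}

# A complete 8-spiracle specimen with distinct, hand-checkable dimensions.
complete_specimen <- function(specimen_id = "b1", species = "spA",
                              mass = 1, scale = 1) {
  labs <- spiracle_labels()
  do.call(rbind, lapply(seq_along(labs), function(k) {
    measurement_row(specimen_id, species, mass, labs[k],
                    d_t = scale * (1 + 0.2 * k),
                    d_s = scale * (0.5 + 0.1 * k),
                    depth = scale * (0.8 + 0.05 * k))
  }))
}

# Independent OLS oracle: closed-form normal equations, no lm().
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       residual_sd = sqrt(sum(r^2) / (n - 2)))
}

# Brute-force sum-then-double oracle for specimen totals.
totals_oracle <- function(tab) {
  a <- pi * tab$d_transverse_mm / 2 * tab$d_sagittal_mm / 2 / 100
  d <- tab$depth_mm / 10
  c(diff = 2 * sum(a / d), adv = 2 * sum(a^2 / d))
}

# Whitening oracle for GLS: Cholesky-transform both sides, then plain OLS.
gls_whitening_oracle <- function(mass, value, V) {
  W <- solve(t(chol(V)))
  X <- W %*% cbind(1, log10(mass))
  y <- W %*% log10(value)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}
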