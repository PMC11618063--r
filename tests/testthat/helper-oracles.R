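# Independent oracles and small fixtures used across the suite.

# Monte-Carlo oracle for the replication probability: sample the posterior
# of SNR given z by brute force (component ~ pi_k, SNR ~ component normal),
# then z_repl ~ N(sqrt(m) SNR, 1), and count same-direction significant
# draws. Returns the estimate and its binomial standard error.
mc_replication_oracle <- function(mix, z, m = 1, alpha = 0.05,
                                  n_draws = 1e6, seed = 1) {
  stopifnot(inherits(mix, "z_mixture"))
  cc <- qnorm(1 - alpha / 2)
  set.seed(seed)
  dens <- mix$weights * dnorm(z, 0, mix$sigma)
  pi_k <- dens / sum(dens)
  shrink <- (mix$sigma^2 - 1) / mix$sigma^2
  k <- sample.int(length(pi_k), n_draws, replace = TRUE, prob = pi_k)
  snr <- rnorm(n_draws, z * shrink[k], sqrt(shrink[k]))
  z_repl <- rnorm(n_draws, sqrt(m) * snr, 1)
  hit <- if (z > 0) z_repl > cc else if (z < 0) z_repl < -cc else abs(z_repl) > cc
  p <- mean(hit)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Brute-force marginal moments of z under an SNR mixture: z | k is
# N(0, 1 + tau_k^2), so the second and fourth moments follow directly.
mixture_z_moments <- function(weights, tau) {
  s2 <- 1 + tau^2
  list(m2 = sum(weights * s2), m4 = sum(weights * 3 * s2^2))
}

# Method-of-moments intraclass correlation for unbalanced one-way layouts
# (between/within mean squares with the usual n0 correction).
moment_icc <- function(value, group) {
  tab <- split(value, group)
  n_j <- lengths(tab)
  tab <- tab[n_j >= 1]
  J <- length(tab)
  N <- sum(n_j)
  grand <- mean(value)
  means <- vapply(tab, mean, numeric(1))
  ssb <- sum(n_j * (means - grand)^2)
  ssw <- sum(vapply(tab, function(x) sum((x - mean(x))^2), numeric(1)))
  msb <- ssb / (J - 1)
  msw <- ssw / (N - J)
  n0 <- (N - sum(n_j^2) / N) / (J - 1)
  vu <- max(0, (msb - msw) / n0)
  vu / (vu + msw)
}

# Random scale mixture for property tests.
random_z_mixture <- function(K = sample(1:4, 1)) {
  w <- rexp(K) + 0.05
  z_mixture(w / sum(w), sort(1 + rexp(K, rate = 0.7)))
}

# Write a small effects CSV and return its path.
write_toy_effects <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

toy_effect_rows <- function() {
  tibble::tibble(
    ma = c("m1", "m1", "m1", "m2", "m2"),
    study = c("s1", "s1", "s2", "s3", "s4"),
    yi = c(0.5, 0.1, -0.2, 0.8, NA),
    vi = c(0.0625, 0.04, 0.09, 0, NA),
    label = c("Smith 2001", "Smith 2001", "Jones 2002", "Lee 2003", "Kim 2004")
  )
}

load_toy_effects <- function(rows = toy_effect_rows()) {
  load_effects(write_toy_effects(rows), es_col = "yi", var_col = "vi",
               study_col = "study", meta_col = "ma", label_col = "label")
}
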