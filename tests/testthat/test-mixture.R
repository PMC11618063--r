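test_that("z_density matches hand-computed values and integrates to one", {
  expect_equal(z_density(z_mixture(1, 1), 0), dnorm(0), tolerance = 1e-12)
  m <- z_mixture(c(0.5, 0.5), c(1, 2))
  expect_equal(z_density(m, 0), 0.5 * dnorm(0) + 0.5 * dnorm(0, 0, 2),
               tolerance = 1e-12)
  expect_equal(z_density(m, 1.3), z_density(m, -1.3), tolerance = 1e-14)
  quad <- stats::integrate(function(z) z_density(m, z), -50, 50,
                           rel.tol = 1e-9)
  expect_equal(quad$value, 1, tolerance = 1e-6)
})

test_that("deconvolution subtracts unit variance and round-trips exactly", {
  m <- z_mixture(c(0.2, 0.3, 0.5), c(1, sqrt(2), sqrt(5)))
  s <- deconvolve(m)
  expect_equal(s$tau, c(0, 1, 2), tolerance = 1e-12)
  expect_equal(s$weights, m$weights)
  back <- reconvolve(s)
  expect_equal(back$sigma, m$sigma, tolerance = 1e-14)
  expect_equal(back$weights, m$weights)
  # convolving each component with unit noise reproduces sigma^2
  expect_equal(s$tau^2 + 1, m$sigma^2, tolerance = 1e-14)
})

test_that("posterior component probabilities, means and shrinkage are correct", {
  m <- z_mixture(c(0.5, 0.5), c(1, 2))
  p0 <- posterior_snr(m, 0)
  expect_equal(p0$prob, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(p0$mean, c(0, 0))

  p2 <- posterior_snr(z_mixture(1, sqrt(2)), 2)
  expect_equal(p2$mean, 1, tolerance = 1e-12)
  expect_equal(p2$variance, 0.5, tolerance = 1e-12)

  many <- posterior_snr(m, c(-3, 0, 1, 4))
  sums <- tapply(many$prob, many$z, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(many$variance >= 0 & many$variance < 1))
})

test_that("the posterior mean always shrinks the observed z", {
  set.seed(4)
  for (i in 1:20) {
    m <- random_z_mixture()
    z <- runif(1, -6, 6)
    post <- posterior_snr(m, z)
    expect_lte(abs(sum(post$prob * post$mean)), abs(z) + 1e-12)
  }
})

test_that("marginalizing the posterior against f(z) recovers the SNR density", {
  m <- z_mixture(c(0.5, 0.5), c(1.5, 3))
  smix <- deconvolve(m)
  zg <- seq(-40, 40, by = 0.05)
  fz <- z_density(m, zg)
  sg <- seq(-8, 8, by = 0.1)
  post <- posterior_snr(m, zg)
  K <- length(m$weights)
  prob <- matrix(post$prob, ncol = K, byrow = TRUE)
  mu <- matrix(post$mean, ncol = K, byrow = TRUE)
  sd_k <- sqrt(post$variance[seq_len(K)])
  # g_hat(s) = sum_z dz f(z) sum_k pi_k(z) N(s; mu_k(z), v_k)
  ghat <- vapply(sg, function(s) {
    comp <- vapply(seq_len(K), function(k) {
      sum(fz * prob[, k] * dnorm(s, mu[, k], sd_k[k]))
    }, numeric(1))
    0.05 * sum(comp)
  }, numeric(1))
  expect_lt(max(abs(ghat - snr_density(smix, sg))), 1e-3)
})

test_that("the weighted EM log-likelihood is non-decreasing across iterations", {
  set.seed(7)
  z <- c(rnorm(150), rnorm(100, 0, 3))
  w <- rep(c(1, 0.5), length.out = 250)
  tbl <- tibble::tibble(z = z, weight = w)
  lls <- vapply(1:12, function(i) {
    suppressWarnings(
      fit_z_mixture(tbl, K = 2, restarts = 1, max_iter = i, tol = 0)$loglik
    )
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("fitting pure-noise z statistics recovers the standard normal", {
  set.seed(12)
  tbl <- tibble::tibble(z = rnorm(20000))
  fit <- fit_z_mixture(tbl, K = 4, restarts = 3)
  zg <- seq(-6, 6, by = 0.01)
  Fhat <- vapply(zg, function(t) {
    sum(fit$mixture$weights * pnorm(t / fit$mixture$sigma))
  }, numeric(1))
  expect_lt(max(abs(Fhat - pnorm(zg))), 0.01)
  td <- tidy(fit)
  expect_lt(sum(td$weight * td$tau^2), 0.05)
})

test_that("the fit recovers a two-component truth at cohort scale", {
  truth <- z_mixture(c(0.6, 0.4), c(1.5, 4))
  co <- generate_cohort(cohort_config(
    n_studies = 20000, rho = 0,
    true_mixture = deconvolve(truth), seed = 91
  ))
  fit <- fit_z_mixture(co, K = 4, restarts = 3, seed = 2)
  zg <- seq(-12, 12, by = 0.02)
  Fhat <- vapply(zg, function(t) {
    sum(fit$mixture$weights * pnorm(t / fit$mixture$sigma))
  }, numeric(1))
  Ftru <- vapply(zg, function(t) {
    sum(truth$weights * pnorm(t / truth$sigma))
  }, numeric(1))
  expect_lt(max(abs(Fhat - Ftru)), 0.015)
})

test_that("restart seeds lead to the same optimum within per-study tolerance", {
  co <- generate_cohort(cohort_config(n_studies = 5000, seed = 17))
  lls <- vapply(1:5, function(s) {
    fit_z_mixture(co, K = 2, restarts = 3, seed = s)$loglik
  }, numeric(1))
  expect_lt((max(lls) - min(lls)) / 5000, 1e-4)
})

test_that("fit validation rejects bad inputs", {
  tbl <- tibble::tibble(z = c(1, 2, NA), weight = 1)
  expect_error(fit_z_mixture(tbl, K = 2), class = "replimix_validation_error")
  expect_error(fit_z_mixture(tibble::tibble(z = rnorm(10)), K = 0),
               class = "replimix_config_error")
  expect_error(fit_z_mixture(tibble::tibble(z = rep(1, 10)), K = 2),
               class = "replimix_validation_error")
  expect_error(z_mixture(c(0.5, 0.5), c(0.8, 2)),
               class = "replimix_invalid_mixture")
})

test_that("mixture serialization round-trips exactly", {
  co <- generate_cohort(cohort_config(n_studies = 500, seed = 6))
  fit <- fit_z_mixture(co, K = 2, restarts = 2)
  path <- tempfile(fileext = ".json")
  write_mixture(fit, path)
  back <- read_mixture(path)
  expect_identical(back$mixture$weights, fit$mixture$weights)
  expect_identical(back$mixture$sigma, fit$mixture$sigma)
  expect_identical(back$loglik, fit$loglik)
  expect_identical(back$n_obs, fit$n_obs)
})
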