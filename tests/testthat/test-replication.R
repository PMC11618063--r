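test_that("under a pure-null mixture every replication succeeds with prob alpha/2", {
  null <- z_mixture(1, 1)
  for (z in c(-3, 0.5, 1.96, 4)) {
    for (m in c(0.5, 1, 4, 100)) {
      expect_equal(replication_probability(null, z, m = m), 0.025,
                   tolerance = 1e-12)
    }
  }
})

test_that("single-component closed form matches hand derivation and the MC oracle", {
  m1 <- z_mixture(1, sqrt(2))
  # posterior at z = 2: SNR ~ N(1, 0.5); z_repl ~ N(1, 1.5)
  byhand <- 1 - pnorm((qnorm(0.975) - 1) / sqrt(1.5))
  got <- replication_probability(m1, 2, m = 1)
  expect_equal(got, byhand, tolerance = 1e-12)
  mc <- mc_replication_oracle(m1, 2, m = 1, n_draws = 4e5, seed = 3)
  expect_lt(abs(got - mc$p), 3 * mc$se)
})

test_that("closed form matches the MC oracle for random mixtures", {
  set.seed(99)
  for (i in 1:5) {
    mix <- random_z_mixture()
    z <- sample(c(-1, 1), 1) * runif(1, 0.3, 4)
    m <- runif(1, 0.25, 6)
    got <- replication_probability(mix, z, m = m)
    mc <- mc_replication_oracle(mix, z, m = m, n_draws = 2e5, seed = i)
    expect_lt(abs(got - mc$p), max(4 * mc$se, 1e-4))
  }
})

test_that("replication probability is symmetric in z and monotone in m", {
  mix <- z_mixture(c(0.6, 0.4), c(1.5, 4))
  expect_identical(replication_probability(mix, 2.2),
                   replication_probability(mix, -2.2))
  ms <- c(0.25, 0.5, 1, 2, 4, 16)
  ps <- vapply(ms, function(m) replication_probability(mix, 1.5, m = m),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  # m -> 0 limit is alpha/2 (significance by luck in the right direction)
  expect_equal(replication_probability(mix, 2, m = 1e-10), 0.025,
               tolerance = 1e-3)
})

test_that("z = 0 returns the significance-only probability with a warning", {
  mix <- z_mixture(c(0.5, 0.5), c(1, 2))
  expect_warning(p0 <- replication_probability(mix, 0), "ill-posed")
  expect_gt(p0, 0.025)
  expect_lt(p0, 1)
})

test_that("replication curves are monotone in z and dominated by larger m", {
  mix <- z_mixture(c(0.6, 0.4), c(1.5, 4))
  cur1 <- replication_curve(mix, seq(0, 6, length.out = 200), m = 1)
  expect_true(all(diff(cur1$replication_probability[cur1$z > 0]) > -1e-12))
  expect_true(all(cur1$replication_probability >= 0 &
                    cur1$replication_probability <= 1))
  cur4 <- replication_curve(mix, seq(0.1, 6, length.out = 50), m = 4)
  ref <- replication_curve(mix, seq(0.1, 6, length.out = 50), m = 1)
  expect_true(all(cur4$replication_probability > ref$replication_probability))
  # spot-check the m = 4 dominance against the MC oracle
  i196 <- which.min(abs(cur4$z - 1.96))
  mc <- mc_replication_oracle(mix, cur4$z[i196], m = 4, n_draws = 2e5, seed = 8)
  expect_lt(abs(cur4$replication_probability[i196] - mc$p), 4 * mc$se)
})

test_that("power matches its closed form at the reference SNRs", {
  expect_equal(power_of_snr(0), 0.05, tolerance = 1e-12)
  cc <- qnorm(0.975)
  expect_equal(power_of_snr(1.96),
               pnorm(-cc - 1.96) + 1 - pnorm(cc - 1.96), tolerance = 1e-12)
  expect_equal(power_of_snr(1.96), 0.5, tolerance = 1e-3)
  expect_equal(power_of_snr(2.80), 0.80, tolerance = 1e-3)
})

test_that("power distribution is the monotone transform of |SNR|", {
  # degenerate null: all mass at power = alpha
  nullmix <- snr_mixture(1, 0)
  pd0 <- power_distribution(nullmix, powers = c(0.1, 0.5, 0.9))
  expect_equal(pd0$cdf, rep(1, 3))
  expect_equal(power_quantiles(pd0)$power, rep(0.05, 3))

  tau1 <- snr_mixture(1, 1)
  pd <- power_distribution(tau1, powers = 0.5, probs = 0.5)
  expect_equal(pd$cdf, 2 * pnorm(1.96) - 1, tolerance = 1e-3)
  med_abs_snr <- qnorm(0.75)  # median of |N(0,1)|
  expect_equal(power_quantiles(pd)$power, power_of_snr(med_abs_snr),
               tolerance = 1e-6)
  expect_error(power_distribution(tau1, powers = 0.04),
               class = "replimix_domain_error")
})

test_that("average replicability is constant under the null and weight-renormalized", {
  co <- generate_cohort(cohort_config(n_studies = 2000, seed = 3))
  expect_equal(average_replicability(z_mixture(1, 1), co), 0.025,
               tolerance = 1e-10)
  mix <- z_mixture(c(0.6, 0.4), c(1.5, 4))
  cc <- qnorm(0.975)
  sig <- co[abs(co$z) > cc, ]
  manual <- sum(sig$weight * replication_probability(mix, sig$z)) /
    sum(sig$weight)
  expect_equal(average_replicability(mix, co), manual, tolerance = 1e-12)
  expect_error(
    average_replicability(mix, tibble::tibble(z = c(0.1, -0.5), weight = 1)),
    class = "replimix_empty_result"
  )
})

test_that("required sample factor matches the closed-form planning case", {
  # tau = 1, z = 2: posterior mean 1, need sqrt(m) * 1 = threshold
  m_needed <- required_sample_factor(z_mixture(1, sqrt(2)), z = 2, target = 0.5)
  expect_equal(m_needed, qnorm(0.975)^2, tolerance = 1e-3)
  # already-achieved targets return m <= 1
  expect_lte(required_sample_factor(z_mixture(1, sqrt(2)), 2, 0.1), 1)
  # a pure null can never exceed alpha/2
  expect_error(required_sample_factor(z_mixture(1, 1), 2, 0.5),
               class = "replimix_unattainable")
})
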