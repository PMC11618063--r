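#' Probability of a successful exact replication
#'
#' A replication succeeds when it reaches two-sided significance in the same
#' direction as the original study: \eqn{z \cdot z_{repl} > 0} and
#' \eqn{|z_{repl}| > c} with \eqn{c = \Phi^{-1}(1-\alpha/2)}. If the
#' replication uses an `m`-fold larger sample, its SNR grows by
#' \eqn{\sqrt{m}}, so \eqn{z_{repl} \mid SNR \sim N(\sqrt{m}\,SNR, 1)}.
#' Averaging over the posterior of the SNR given the observed z (a normal
#' mixture, see [posterior_snr()]) gives, for \eqn{z > 0},
#' \deqn{P = \sum_k \pi_k(z)\left[1 -
#'   \Phi\!\left(\frac{c - \sqrt{m}\,\mu_k(z)}{\sqrt{m v_k + 1}}\right)\right],}
#' and by symmetry for \eqn{z < 0}. At `z = 0` the direction is ill-posed;
#' the significance-only probability is returned with a warning.
#'
#' @param mix A [z_mixture()] or [fit_z_mixture()] fit.
#' @param z Observed z statistic(s) of the original study (vectorized).
#' @param m Fold increase of the replication sample size, `> 0`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' # under a pure-null mixture every replication succeeds with prob alpha/2
#' replication_probability(z_mixture(1, 1), z = 2.5)
replication_probability <- function(mix, z, m = 1, alpha = 0.05) {
  mix <- as_z_mixture(mix)
  if (!is.numeric(m) || length(m) != 1 || m <= 0) {
    abort("m must be a single positive number", class = "replimix_domain_error")
  }
  cc <- two_sided_threshold(alpha)
  if (any(z == 0)) {
    warn("replication direction is ill-posed at z = 0; returning the significance-only probability there")
  }
  shrink <- (mix$sigma^2 - 1) / mix$sigma^2
  vapply(z, function(zi) {
    dens <- mix$weights * dnorm(zi, 0, mix$sigma)
    pi_k <- dens / sum(dens)
    mu <- abs(zi) * shrink
    sd_pred <- sqrt(m * shrink + 1)
    if (zi == 0) {
      sum(pi_k * 2 * pnorm(-cc / sd_pred))
    } else {
      sum(pi_k * pnorm((sqrt(m) * mu - cc) / sd_pred))
    }
  }, numeric(1))
}

#' Replication probability along a grid of observed z statistics
#'
#' @param mix A [z_mixture()] or fit.
#' @param z_grid Increasing non-negative z values (default 200 points on
#'   \[0, 6\]).
#' @param m Fold increase of the replication sample size.
#' @param alpha Two-sided level.
#' @return A tibble of class `replication_curve` with columns `z`, `m`,
#'   `replication_probability`.
#' @export
replication_curve <- function(mix, z_grid = seq(0, 6, length.out = 200),
                              m = 1, alpha = 0.05) {
  stopifnot(length(z_grid) >= 1, !is.unsorted(z_grid))
  prob <- suppressWarnings(
    replication_probability(mix, z_grid, m = m, alpha = alpha)
  )
  out <- tibble::tibble(z = z_grid, m = m, replication_probability = prob)
  class(out) <- c("replication_curve", class(out))
  out
}

#' Statistical power as a function of the signal-to-noise ratio
#'
#' Two-sided rejection probability at level `alpha` for a study whose SNR is
#' known: \eqn{\Phi(-c - SNR) + 1 - \Phi(c - SNR)}. This includes
#' rejections in the wrong direction, so power is exactly `alpha` at
#' SNR = 0 and is increasing in |SNR|.
#'
#' @param snr Signal-to-noise ratio(s).
#' @param alpha Two-sided level (default 0.05).
#' @return Power in \[alpha, 1\].
#' @export
#' @examples
#' power_of_snr(2.80)  # the classic ~80% power point
power_of_snr <- function(snr, alpha = 0.05) {
  cc <- two_sided_threshold(alpha)
  pnorm(-cc - snr) + 1 - pnorm(cc - snr)
}

# Invert power_of_snr on |SNR| >= 0 (strictly increasing there).
invert_power <- function(p, alpha = 0.05, tol = 1e-10) {
  if (p <= alpha || p >= 1) {
    abort("power must lie strictly between alpha and 1",
          class = "replimix_domain_error")
  }
  uniroot(function(s) power_of_snr(s, alpha) - p,
          lower = 0, upper = 50, tol = tol)$root
}

# P(|SNR| <= s) under an snr_mixture (point masses at 0 count fully).
abs_snr_cdf <- function(mix, s) {
  vapply(seq_along(s), function(i) {
    sum(mix$weights * ifelse(mix$tau > 0,
                             2 * pnorm(s[i] / mix$tau) - 1,
                             as.numeric(s[i] >= 0)))
  }, numeric(1))
}

#' Distribution of statistical power implied by an SNR mixture
#'
#' Because power is a strictly increasing function of |SNR|
#' (see [power_of_snr()]), the power distribution is a monotone transform of
#' the |SNR| distribution: \eqn{P(power \le p) = P(|SNR| \le s(p))} with
#' \eqn{s(p)} the numerical inverse of the power function.
#'
#' @param mix An [snr_mixture()] (e.g. from [deconvolve()]).
#' @param powers Power values at which to evaluate the CDF; default an even
#'   grid on (alpha, 1).
#' @param probs Quantile levels to report (default quartiles).
#' @param alpha Two-sided level of the underlying test.
#' @return A tibble of class `power_distribution` with columns `power`,
#'   `cdf`; the requested quantiles are attached as attribute `"quantiles"`
#'   (tibble `prob`, `power`) and printed by [power_quantiles()].
#' @export
power_distribution <- function(mix, powers = NULL,
                               probs = c(0.25, 0.5, 0.75), alpha = 0.05) {
  stopifnot(inherits(mix, "snr_mixture"))
  if (is.null(powers)) {
    powers <- seq(alpha + 1e-4, 1 - 1e-4, length.out = 200)
  }
  if (any(powers <= alpha) || any(powers >= 1)) {
    abort("requested power values must lie strictly between alpha and 1",
          class = "replimix_domain_error")
  }
  s_of_p <- vapply(powers, invert_power, numeric(1), alpha = alpha)
  out <- tibble::tibble(power = powers, cdf = abs_snr_cdf(mix, s_of_p))

  null_mass <- sum(mix$weights[mix$tau == 0])
  qs <- vapply(probs, function(q) {
    if (q <= null_mass) return(alpha)
    s_q <- uniroot(function(s) abs_snr_cdf(mix, s) - q,
                   lower = 0, upper = 1e6, tol = 1e-10)$root
    power_of_snr(s_q, alpha)
  }, numeric(1))
  attr(out, "quantiles") <- tibble::tibble(prob = probs, power = qs)
  class(out) <- c("power_distribution", class(out))
  out
}

#' Quantiles attached to a power distribution
#'
#' @param x A [power_distribution()] result.
#' @return A tibble with columns `prob`, `power`.
#' @export
power_quantiles <- function(x) {
  q <- attr(x, "quantiles")
  if (is.null(q)) abort("no quantiles attribute found",
                        class = "replimix_type_error")
  q
}

#' Average replicability over observed significant effects
#'
#' Weighted mean of the replication probability over the observed z
#' statistics that meet the significance condition |z| > c, with cluster
#' weights renormalized over that subset.
#'
#' @param mix A [z_mixture()] or fit.
#' @param data Data frame with columns `z` and (optionally) `weight`.
#' @param m Fold increase for the hypothetical replications.
#' @param alpha Two-sided level defining both the significance condition and
#'   the replication threshold.
#' @param weighted Use the `weight` column (default) or weight all effects
#'   equally.
#' @return A single probability.
#' @export
average_replicability <- function(mix, data, m = 1, alpha = 0.05,
                                  weighted = TRUE) {
  stopifnot("z" %in% names(data))
  cc <- two_sided_threshold(alpha)
  sel <- abs(data$z) > cc & is.finite(data$z)
  if (!any(sel)) {
    abort("no statistically significant effects in the data",
          class = "replimix_empty_result")
  }
  w <- if (weighted && "weight" %in% names(data)) data$weight[sel] else rep(1, sum(sel))
  p <- replication_probability(mix, data$z[sel], m = m, alpha = alpha)
  sum(w * p) / sum(w)
}

#' Sample-size factor needed to reach a target replication probability
#'
#' Finds the smallest fold increase `m` of the replication sample size such
#' that the replication probability at the observed `z` reaches `target`,
#' by bisection on log m over \eqn{[10^{-6}, 10^4]} (the probability is
#' strictly increasing in m whenever the posterior puts mass on nonzero
#' SNR). The continuous `m` is returned; callers planning studies usually
#' take `ceiling(m)`.
#'
#' @param mix A [z_mixture()] or fit.
#' @param z Observed z statistic of the original study.
#' @param target Desired replication probability, in (alpha/2, 1).
#' @param alpha Two-sided level.
#' @param tol Probability tolerance of the bisection (default 1e-4).
#' @return The continuous fold increase `m`.
#' @export
#' @examples
#' # posterior mean SNR is 1 at z = 2 under a single tau = 1 component:
#' required_sample_factor(z_mixture(1, sqrt(2)), z = 2, target = 0.5)
required_sample_factor <- function(mix, z, target, alpha = 0.05, tol = 1e-4) {
  mix <- as_z_mixture(mix)
  if (target <= 0 || target >= 1) {
    abort("target must lie in (0, 1)", class = "replimix_domain_error")
  }
  pr <- function(m) replication_probability(mix, z, m = m, alpha = alpha)
  lo <- 1e-6
  hi <- 1e4
  p_hi <- pr(hi)
  if (p_hi < target) {
    abort(
      sprintf(
        "target %.4g unattainable: replication probability approaches about %.4g as m grows (posterior mass near SNR = 0)",
        target, p_hi
      ),
      class = "replimix_unattainable"
    )
  }
  if (pr(lo) >= target) return(lo)
  llo <- log(lo); lhi <- log(hi)
  for (i in 1:200) {
    mid <- (llo + lhi) / 2
    pm <- pr(exp(mid))
    if (pm >= target) lhi <- mid else llo <- mid
    if (abs(pm - target) < tol && (lhi - llo) < 1e-6) break
  }
  exp(lhi)
}
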