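#' Configuration for a synthetic meta-analytic cohort
#'
#' Bundles the generative settings for [generate_cohort()]. The generator
#' emulates the statistical structure the downstream analysis assumes: each
#' study contributes a cluster of correlated effects, the true
#' signal-to-noise ratio (SNR) of each effect is drawn from a zero-centred
#' Gaussian scale mixture, and the observed z statistic is the SNR plus
#' unit-variance estimation noise.
#'
#' @param n_studies Number of independent studies J.
#' @param lambda Rate of the zero-truncated Poisson governing effects per
#'   study. The default 6.817 gives a mean cluster size of about 6.82,
#'   matching the scale of large meta-analytic databases in ecology and
#'   evolution (roughly 88,000 effects from 13,000 studies).
#' @param true_mixture An [snr_mixture()] giving the ground-truth SNR
#'   distribution. Default: weights (0.6, 0.4) with scales
#'   \eqn{\tau = (\sqrt{1.25}, \sqrt{15})}, i.e. z-scale standard deviations
#'   1.5 and 4 — a mostly-modest-signal population with a heavy tail.
#' @param rho Fraction of SNR variance shared within a study, in \[0, 1\].
#'   Effects in the same study share a latent study effect with variance
#'   `rho * tau_k^2`; the remainder is effect-specific. Default 0.5.
#' @param se_meanlog,se_sdlog Log-normal parameters for drawing standard
#'   errors (cosmetic: they set the `es`/`se` decomposition of each z but do
#'   not affect z itself).
#' @param effect_type_probs Named simplex over effect-size metrics; the
#'   labels are cosmetic. Default SMD/lnRR/Zr/other = 0.45/0.36/0.15/0.04,
#'   the approximate composition of the field's meta-analytic literature.
#' @param selection_prob Retention probability for non-significant effects
#'   when selection thinning is applied (1 = no selection).
#' @param n_meta Number of meta-analyses the studies are partitioned into;
#'   default about one per 27.7 studies.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_studies = 1000,
                          lambda = 6.817,
                          true_mixture = snr_mixture(
                            weights = c(0.6, 0.4),
                            tau = sqrt(c(1.5, 4)^2 - 1)
                          ),
                          rho = 0.5,
                          se_meanlog = -0.5,
                          se_sdlog = 0.6,
                          effect_type_probs = c(
                            SMD = 0.45, lnRR = 0.36, Zr = 0.15, other = 0.04
                          ),
                          selection_prob = 1,
                          n_meta = max(1L, round(n_studies / 27.7)),
                          seed = 1L) {
  stopifnot(is.numeric(n_studies), n_studies >= 1)
  if (!inherits(true_mixture, "snr_mixture")) {
    abort("true_mixture must be an snr_mixture()", class = "replimix_config_error")
  }
  if (lambda <= 0) {
    abort("lambda must be positive", class = "replimix_config_error")
  }
  if (rho < 0 || rho > 1) {
    abort("rho must lie in [0, 1]", class = "replimix_config_error")
  }
  if (selection_prob <= 0 || selection_prob > 1) {
    abort("selection_prob must lie in (0, 1]", class = "replimix_config_error")
  }
  if (any(effect_type_probs < 0) ||
      abs(sum(effect_type_probs) - 1) > 1e-8) {
    abort("effect_type_probs must be a simplex", class = "replimix_config_error")
  }
  structure(
    list(
      n_studies = as.integer(n_studies), lambda = lambda,
      true_mixture = true_mixture, rho = rho,
      se_meanlog = se_meanlog, se_sdlog = se_sdlog,
      effect_type_probs = effect_type_probs,
      selection_prob = selection_prob,
      n_meta = as.integer(n_meta), seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Zero-truncated Poisson draws by CDF inversion.
rztpois <- function(n, lambda) {
  u <- runif(n, min = dpois_zero(lambda), max = 1)
  qpois(u, lambda)
}

dpois_zero <- function(lambda) exp(-lambda)

#' Generate a synthetic meta-analytic cohort with known ground truth
#'
#' Simulates J studies. For study j: the cluster size \eqn{n_j} is
#' zero-truncated Poisson; a mixture component \eqn{k_j} is drawn from the
#' true SNR mixture; a shared study effect \eqn{u_j \sim N(0, \rho\tau_k^2)}
#' induces within-study correlation. Each effect i gets
#' \eqn{SNR_{ij} = u_j + e_{ij}}, \eqn{e_{ij} \sim N(0, (1-\rho)\tau_k^2)},
#' and an observed \eqn{z_{ij} = SNR_{ij} + \epsilon}, \eqn{\epsilon \sim
#' N(0,1)}. Standard errors are log-normal and `es = z * se`.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when supplied.
#' @return A tibble in the layout of [load_effects()] plus ground-truth
#'   sidecar columns `snr_true` (true SNR), `component` (mixture component
#'   index) and `study_latent` (shared study effect), with cluster weights
#'   attached. If `config$selection_prob < 1`, selection thinning is applied
#'   via [apply_selection()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_studies = 50, seed = 7))
#' dplyr::count(cohort, effect_type)
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  mix <- config$true_mixture
  K <- length(mix$weights)
  with_seed(seed, {
    J <- config$n_studies
    n_j <- rztpois(J, config$lambda)
    k_j <- sample.int(K, J, replace = TRUE, prob = mix$weights)
    tau_j <- mix$tau[k_j]
    u_j <- rnorm(J, 0, sqrt(config$rho) * tau_j)

    idx <- rep.int(seq_len(J), n_j)
    n <- length(idx)
    e <- rnorm(n, 0, sqrt(1 - config$rho) * tau_j[idx])
    snr <- u_j[idx] + e
    z <- snr + rnorm(n)
    se <- rlnorm(n, config$se_meanlog, config$se_sdlog)
    type <- sample(names(config$effect_type_probs), n, replace = TRUE,
                   prob = config$effect_type_probs)

    meta_of_study <- rep_len(seq_len(config$n_meta), J)
    out <- tibble::tibble(
      meta_id = sprintf("M%04d", meta_of_study[idx]),
      study_id = sprintf("S%06d", idx),
      effect_id = as.character(seq_len(n)),
      effect_type = type,
      es = z * se,
      se = se,
      var = se^2,
      z = z,
      snr_true = snr,
      component = k_j[idx],
      study_latent = u_j[idx]
    )
    out <- compute_weights(out)
    if (config$selection_prob < 1) {
      out <- apply_selection(out, s = config$selection_prob,
                             seed = seed + 1L)
    }
    out
  })
}

#' Thin non-significant effects to mimic selective reporting
#'
#' Statistically significant effects (|z| above the two-sided threshold) are
#' always retained; the rest survive independently with probability `s`.
#' This is the simplest caricature of publication bias and exists so that
#' its distorting effect on fitted replication probabilities can be studied;
#' the estimation machinery itself assumes no selection.
#'
#' @param data Effect table with a `z` column.
#' @param s Retention probability for non-significant effects, in (0, 1].
#' @param seed Integer seed for the thinning draws.
#' @param alpha Two-sided significance level defining the threshold.
#' @return Thinned tibble with recomputed cluster weights (`s = 1` returns
#'   the input with weights refreshed).
#' @export
apply_selection <- function(data, s, seed = 1L, alpha = 0.05) {
  stopifnot("z" %in% names(data))
  if (s <= 0 || s > 1) {
    abort("retention probability s must lie in (0, 1]",
          class = "replimix_config_error")
  }
  if (s == 1) {
    return(compute_weights(data))
  }
  cc <- two_sided_threshold(alpha)
  keep <- with_seed(seed, {
    abs(data$z) > cc | runif(nrow(data)) < s
  })
  compute_weights(data[keep, , drop = FALSE])
}
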