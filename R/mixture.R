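#' Zero-mean Gaussian scale mixture for z statistics
#'
#' The marginal density of the z statistics is modelled as
#' \deqn{f(z) = \sum_k w_k \, \varphi(z/\sigma_k)/\sigma_k, \qquad
#'   \sigma_k \ge 1,}
#' a mixture of zero-mean normals differing only in scale. Because
#' \eqn{z \mid SNR \sim N(SNR, 1)}, every component scale satisfies
#' \eqn{\sigma_k^2 = 1 + \tau_k^2} where \eqn{\tau_k} is the SNR scale of
#' that component; hence the floor at 1.
#'
#' @param weights Component probabilities, non-negative, summing to 1.
#' @param sigma Component standard deviations on the z scale, all `>= 1`.
#' @return An object of class `z_mixture` (components sorted by `sigma`).
#' @seealso [snr_mixture()], [deconvolve()], [fit_z_mixture()]
#' @export
z_mixture <- function(weights, sigma) {
  stopifnot(length(weights) == length(sigma), length(sigma) >= 1)
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("weights must be non-negative and finite",
          class = "replimix_invalid_mixture")
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    abort("weights must sum to 1", class = "replimix_invalid_mixture")
  }
  if (any(!is.finite(sigma)) || any(sigma < 1)) {
    abort("all sigma must be finite and >= 1 (unit estimation noise)",
          class = "replimix_invalid_mixture")
  }
  ord <- order(sigma)
  structure(
    list(weights = as.numeric(weights[ord]), sigma = as.numeric(sigma[ord])),
    class = "z_mixture"
  )
}

#' Zero-mean Gaussian scale mixture for the signal-to-noise ratio
#'
#' The deconvolved counterpart of [z_mixture()]: the SNR density is
#' \deqn{g(SNR) = \sum_k w_k \, \varphi(SNR/\tau_k)/\tau_k,}
#' with \eqn{\tau_k = \sqrt{\sigma_k^2 - 1}}. A component with
#' \eqn{\tau_k = 0} is a point mass at SNR = 0 (a null spike).
#'
#' @param weights Component probabilities summing to 1.
#' @param tau Component SNR standard deviations, all `>= 0`.
#' @return An object of class `snr_mixture`.
#' @export
snr_mixture <- function(weights, tau) {
  stopifnot(length(weights) == length(tau), length(tau) >= 1)
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    abort("weights must be a simplex", class = "replimix_invalid_mixture")
  }
  if (any(!is.finite(tau)) || any(tau < 0)) {
    abort("all tau must be finite and >= 0", class = "replimix_invalid_mixture")
  }
  ord <- order(tau)
  structure(
    list(weights = as.numeric(weights[ord]), tau = as.numeric(tau[ord])),
    class = "snr_mixture"
  )
}

#' Deconvolve a z mixture to the SNR distribution
#'
#' Removing the unit-variance estimation noise from a fitted z mixture
#' amounts to subtracting 1 from each component variance:
#' \eqn{\tau_k = \sqrt{\sigma_k^2 - 1}}, weights unchanged.
#'
#' @param x A [z_mixture()] or a fit from [fit_z_mixture()].
#' @return An [snr_mixture()].
#' @export
#' @examples
#' deconvolve(z_mixture(c(0.5, 0.5), c(1, sqrt(2))))
deconvolve <- function(x) {
  mix <- as_z_mixture(x)
  if (any(mix$sigma < 1)) {
    abort("cannot deconvolve: some sigma < 1",
          class = "replimix_invalid_mixture")
  }
  snr_mixture(mix$weights, sqrt(mix$sigma^2 - 1))
}

#' Convolve an SNR mixture with unit estimation noise
#'
#' Inverse of [deconvolve()]: \eqn{\sigma_k = \sqrt{\tau_k^2 + 1}}.
#'
#' @param x An [snr_mixture()].
#' @return A [z_mixture()].
#' @export
reconvolve <- function(x) {
  stopifnot(inherits(x, "snr_mixture"))
  z_mixture(x$weights, sqrt(x$tau^2 + 1))
}

as_z_mixture <- function(x) {
  if (inherits(x, "z_mixture")) return(x)
  if (inherits(x, "zmix_fit")) return(x$mixture)
  if (inherits(x, "snr_mixture")) return(reconvolve(x))
  abort("expected a z_mixture, snr_mixture or zmix_fit",
        class = "replimix_type_error")
}

#' Marginal density of the z statistic under a scale mixture
#'
#' @param mix A [z_mixture()] (or fit).
#' @param z Numeric vector of evaluation points.
#' @return `f(z)`, strictly positive and symmetric in `z`.
#' @export
z_density <- function(mix, z) {
  mix <- as_z_mixture(mix)
  dens <- vapply(seq_along(mix$weights),
                 function(k) mix$weights[k] * dnorm(z, 0, mix$sigma[k]),
                 numeric(length(z)))
  if (length(z) == 1) sum(dens) else rowSums(matrix(dens, nrow = length(z)))
}

#' Marginal density of the SNR under a deconvolved mixture
#'
#' Point-mass components (`tau = 0`) contribute nothing to the density away
#' from zero and `Inf` at zero; their weight is reported separately by
#' [tidy()] on the mixture.
#'
#' @param mix An [snr_mixture()].
#' @param snr Numeric vector of evaluation points.
#' @return `g(snr)` from the continuous components.
#' @export
snr_density <- function(mix, snr) {
  stopifnot(inherits(mix, "snr_mixture"))
  out <- numeric(length(snr))
  for (k in seq_along(mix$weights)) {
    if (mix$tau[k] > 0) {
      out <- out + mix$weights[k] * dnorm(snr, 0, mix$tau[k])
    } else {
      out <- out + ifelse(snr == 0, Inf, 0) * mix$weights[k]
    }
  }
  out
}

#' Posterior distribution of the SNR given an observed z
#'
#' Conditional on z, the SNR is again a normal mixture: component k is
#' selected with probability \eqn{\pi_k(z) \propto w_k
#' \varphi(z/\sigma_k)/\sigma_k} and contributes
#' \eqn{SNR \mid z, k \sim N(z\,\tau_k^2/\sigma_k^2,\; \tau_k^2/\sigma_k^2)}
#' — the usual normal-normal shrinkage within each component.
#'
#' @param mix A [z_mixture()] (or fit).
#' @param z Numeric vector of observed z statistics.
#' @return A tibble with one row per (z, component): columns `z`,
#'   `component`, `prob` (\eqn{\pi_k(z)}), `mean` and `variance` of the
#'   component posterior.
#' @export
#' @examples
#' posterior_snr(z_mixture(c(0.5, 0.5), c(1, 2)), z = 0)
posterior_snr <- function(mix, z) {
  mix <- as_z_mixture(mix)
  K <- length(mix$weights)
  shrink <- (mix$sigma^2 - 1) / mix$sigma^2
  grid <- tidyr::expand_grid(z = z, component = seq_len(K))
  dens <- mix$weights[grid$component] *
    dnorm(grid$z, 0, mix$sigma[grid$component])
  tot <- rowsum(dens, group = rep(seq_along(z), each = K))
  grid$prob <- dens / tot[rep(seq_along(z), each = K)]
  grid$mean <- grid$z * shrink[grid$component]
  grid$variance <- shrink[grid$component]
  grid
}

# ---- weighted EM fit ------------------------------------------------------

#' Fit a weighted zero-mean Gaussian scale mixture to z statistics
#'
#' Maximizes the cluster-weighted log-likelihood
#' \eqn{\sum_{ij} w_{ij} \log f(z_{ij})} over mixture weights and scales by
#' expectation-maximization, with every scale floored at 1 (the unit
#' estimation noise puts a hard lower bound on the marginal spread of z).
#' Effects are weighted inversely to their study's cluster size so each
#' study contributes equally. The best of `restarts` seeded starts is kept;
#' component scales are initialized on a geometric ladder spanning 1.1 to 8
#' and jittered per restart.
#'
#' @param data Data frame with the z statistics (typically from
#'   [compute_weights()] or [generate_cohort()]).
#' @param K Number of mixture components (default 4).
#' @param z,weight Columns holding the z statistic and the cluster weight
#'   (tidy-select); when no weight column exists, effects are equally
#'   weighted.
#' @param restarts Number of EM restarts (default 5).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-9).
#' @param max_iter Iteration cap per restart (default 10000).
#' @param seed Seed controlling restart jitter; the fit is deterministic
#'   given `(data, K, restarts, seed)`.
#' @param prune_tol Components with weight below this are dropped and near
#'   coincident scales merged (default 1e-8).
#' @return An object of class `zmix_fit`: list with `mixture`
#'   ([z_mixture()]), `loglik`, `n_iter`, `converged`, `restarts_used`,
#'   `seed`, `n_obs`, `n_studies`. Methods: [tidy()], [glance()],
#'   [autoplot()], [deconvolve()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_studies = 300, seed = 2))
#' fit <- fit_z_mixture(cohort, K = 2, restarts = 2)
#' glance(fit)
fit_z_mixture <- function(data, K = 4, z = z, weight = NULL,
                          restarts = 5, tol = 1e-9, max_iter = 10000,
                          seed = 1L, prune_tol = 1e-8) {
  if (K < 1) abort("K must be >= 1", class = "replimix_config_error")
  zq <- enquo(z)
  zv <- eval_tidy(zq, data)
  wq <- enquo(weight)
  wv <- eval_tidy(wq, data)
  if (is.null(wv)) {
    wv <- if ("weight" %in% names(data)) data$weight else rep(1, length(zv))
  }
  if (any(!is.finite(zv)) || any(!is.finite(wv)) || any(wv <= 0)) {
    abort("z must be finite and weights positive and finite",
          class = "replimix_validation_error")
  }
  if (length(unique(zv)) < K) {
    abort("need at least K distinct z values",
          class = "replimix_validation_error")
  }

  base_sigma <- exp(seq(log(1.1), log(8), length.out = max(K, 2)))[seq_len(K)]
  fits <- with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      s0 <- if (r == 1) base_sigma else {
        pmax(1, base_sigma * exp(runif(K, -0.25, 0.25)))
      }
      em_scale_mixture(zv, wv, s0, tol = tol, max_iter = max_iter)
    })
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]

  # prune empty components, merge numerically coincident scales
  w <- best$weights
  s <- best$sigma
  keep <- w > prune_tol
  w <- w[keep] / sum(w[keep])
  s <- s[keep]
  ord <- order(s)
  w <- w[ord]; s <- s[ord]
  if (length(s) > 1) {
    grp <- cumsum(c(TRUE, diff(s) > 1e-6))
    w <- as.numeric(tapply(w, grp, sum))
    s <- as.numeric(tapply(s, grp, function(x) x[[1]]))
  }
  mix <- z_mixture(w, s)
  loglik <- sum(wv * log(z_density(mix, zv)))

  n_studies <- if ("study_id" %in% names(data)) {
    dplyr::n_distinct(data$study_id)
  } else {
    NA_integer_
  }
  structure(
    list(
      mixture = mix, loglik = loglik, n_iter = best$n_iter,
      converged = best$converged, restarts_used = restarts,
      seed = seed, n_obs = length(zv), n_studies = n_studies
    ),
    class = "zmix_fit"
  )
}

# EM core. Monotone in the weighted log-likelihood; the sigma floor at 1 is
# the constrained M-step optimum because the per-component objective is
# unimodal in sigma^2.
em_scale_mixture <- function(z, w, sigma0, tol, max_iter) {
  K <- length(sigma0)
  n <- length(z)
  z2 <- z^2
  W <- sum(w)
  p <- rep(1 / K, K)
  s2 <- pmax(1, sigma0^2)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  dens <- matrix(0, n, K)
  repeat {
    it <- it + 1L
    for (k in seq_len(K)) {
      dens[, k] <- exp(-0.5 * z2 / s2[k]) / sqrt(2 * pi * s2[k])
    }
    fz <- dens %*% p
    fz[fz < 1e-300] <- 1e-300
    ll <- sum(w * log(fz))
    if (abs(ll - ll_old) <= tol * (abs(ll) + 1) || it >= max_iter) {
      converged <- abs(ll - ll_old) <= tol * (abs(ll) + 1)
      ll_old <- ll
      break
    }
    ll_old <- ll
    resp <- dens * matrix(p, n, K, byrow = TRUE) / as.numeric(fz)
    wk <- colSums(w * resp)
    p <- wk / W
    s2 <- pmax(1, colSums(w * resp * z2) / wk)
    s2[!is.finite(s2)] <- 1
    p[p < 1e-12] <- 1e-12
    p <- p / sum(p)
  }
  list(weights = p, sigma = sqrt(s2), loglik = ll_old,
       n_iter = it, converged = converged)
}

#' @export
print.z_mixture <- function(x, ...) {
  cat("Zero-mean Gaussian scale mixture (z scale),",
      length(x$weights), "component(s)\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
print.snr_mixture <- function(x, ...) {
  cat("Zero-mean Gaussian scale mixture (SNR scale),",
      length(x$weights), "component(s)\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
print.zmix_fit <- function(x, ...) {
  cat("Weighted Gaussian scale-mixture fit\n")
  cat(sprintf("  n_obs = %d, n_studies = %s, loglik = %.4f, %s in %d iter\n",
              x$n_obs, format(x$n_studies), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a mixture or mixture fit into one row per component
#'
#' @param x A `z_mixture`, `snr_mixture` or `zmix_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `weight`, `sigma` (z scale)
#'   and `tau` (SNR scale), as applicable.
#' @method tidy z_mixture
#' @export
tidy.z_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$weights),
    weight = x$weights,
    sigma = x$sigma,
    tau = sqrt(pmax(0, x$sigma^2 - 1))
  )
}

#' @rdname tidy.z_mixture
#' @method tidy snr_mixture
#' @export
tidy.snr_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$weights),
    weight = x$weights,
    tau = x$tau,
    sigma = sqrt(x$tau^2 + 1)
  )
}

#' @rdname tidy.z_mixture
#' @method tidy zmix_fit
#' @export
tidy.zmix_fit <- function(x, ...) tidy(x$mixture)

#' One-row summary of a mixture fit
#'
#' @param x A `zmix_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `K`, `loglik`, `n_iter`, `converged`,
#'   `restarts_used`, `n_obs`, `n_studies`, `seed`.
#' @method glance zmix_fit
#' @export
glance.zmix_fit <- function(x, ...) {
  tibble::tibble(
    K = length(x$mixture$weights),
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    restarts_used = x$restarts_used,
    n_obs = x$n_obs,
    n_studies = x$n_studies,
    seed = x$seed
  )
}

# ---- serialization --------------------------------------------------------

#' Write a fitted mixture to a JSON file
#'
#' @param x A `zmix_fit` or `z_mixture`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mixture <- function(x, path) {
  if (inherits(x, "z_mixture")) {
    x <- list(mixture = x, loglik = NA_real_, n_obs = NA_integer_,
              n_studies = NA_integer_, seed = NA_integer_)
  }
  payload <- list(
    version = "1",
    K = length(x$mixture$weights),
    weights = x$mixture$weights,
    sigmas = x$mixture$sigma,
    loglik = x$loglik,
    n_obs = x$n_obs,
    n_studies = x$n_studies,
    seed = x$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a fitted mixture from a JSON file
#'
#' Round-trips exactly with [write_mixture()].
#'
#' @param path File written by [write_mixture()].
#' @return A `zmix_fit` (with `NA` metadata where it was not stored).
#' @export
read_mixture <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      mixture = z_mixture(payload$weights, payload$sigmas),
      loglik = payload$loglik %||% NA_real_,
      n_iter = NA_integer_,
      converged = NA,
      restarts_used = NA_integer_,
      seed = payload$seed %||% NA_integer_,
      n_obs = payload$n_obs %||% NA_integer_,
      n_studies = payload$n_studies %||% NA_integer_
    ),
    class = "zmix_fit"
  )
}
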