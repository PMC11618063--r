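#' Geometric grid of SNR scales for the F-localization class
#'
#' The confidence construction searches over all zero-centred Gaussian
#' scale mixtures whose component scales lie on a dense geometric ladder:
#' \eqn{\sigma_j = 10^{-5} \cdot 1.05^{\,j-1}}, 365 values reaching
#' about 516.3. The smallest scale is numerically a null spike; the largest
#' comfortably exceeds any SNR seen in practice.
#'
#' @param n Number of grid points (default 365).
#' @param first Smallest scale (default 1e-5).
#' @param ratio Geometric ratio (default 1.05).
#' @return Numeric vector of SNR-scale standard deviations, increasing.
#' @export
build_sigma_grid <- function(n = 365, first = 1e-5, ratio = 1.05) {
  stopifnot(n >= 1, first > 0, ratio > 1)
  first * ratio^(seq_len(n) - 1)
}

#' Censoring window for the folded z statistic
#'
#' The band is built on |z| with values below `lower` and above `upper`
#' treated as two interval cells rather than exact observations. Censoring
#' near the significance cutoff guards against mild p-hacking around
#' |z| = 1.96 and against model misspecification near the origin; censoring
#' the far tail guards against outliers.
#'
#' @param lower,upper Censoring bounds on |z| (defaults 2.3 and 10).
#' @return A list of class `censor_spec`.
#' @export
censor_spec <- function(lower = 2.3, upper = 10) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower > 0, lower < upper)
  structure(list(lower = lower, upper = upper), class = "censor_spec")
}

#' Study-weighted empirical CDF of |z| with DKW localization
#'
#' Builds the weighted empirical CDF of the folded z statistic — each study
#' contributing total weight 1 via its cluster weights, divided by the
#' number of studies J — evaluated on points inside the censoring window,
#' plus the total masses of the two censored cells. The
#' Dvoretzky-Kiefer-Wolfowitz half-width
#' \eqn{\epsilon = \sqrt{\log(2/\alpha)/(2J)}} uses J = number of
#' independent studies, not the number of effects, which is how the
#' within-study dependence is absorbed.
#'
#' @param data Effect table with `z`, `study_id` and `weight` columns
#'   (weights are refreshed if absent).
#' @param censor A [censor_spec()].
#' @param eval_points Evaluation points for the CDF; default `n_eval`
#'   equally spaced points spanning the censoring window.
#' @param n_eval Number of default evaluation points (default 200).
#' @param alpha_band Complement of the band's simultaneous coverage
#'   (default 0.05 for 95% bands).
#' @return An object of class `dkw_localization`: list with `eval_points`,
#'   `emp_cdf`, `below` and `above` cell masses, `J`, `epsilon`,
#'   `alpha_band`, `censor`.
#' @export
weighted_folded_ecdf <- function(data, censor = censor_spec(),
                                 eval_points = NULL, n_eval = 200,
                                 alpha_band = 0.05) {
  stopifnot(all(c("z", "study_id") %in% names(data)))
  if (!"weight" %in% names(data)) data <- compute_weights(data)
  az <- abs(data$z)
  J <- dplyr::n_distinct(data$study_id)
  w <- data$weight / J
  if (is.null(eval_points)) {
    eval_points <- seq(censor$lower, censor$upper, length.out = n_eval)
  }
  eval_points <- sort(eval_points)
  if (any(eval_points < censor$lower) || any(eval_points > censor$upper)) {
    abort("eval_points must lie inside the censoring window",
          class = "replimix_domain_error")
  }
  inside <- az >= censor$lower & az <= censor$upper
  if (!any(inside)) {
    abort("no observations inside the censoring window",
          class = "replimix_empty_result")
  }
  emp_cdf <- vapply(eval_points, function(t) sum(w[az <= t]), numeric(1))
  structure(
    list(
      eval_points = eval_points,
      emp_cdf = emp_cdf,
      below = sum(w[az < censor$lower]),
      above = sum(w[az > censor$upper]),
      J = J,
      epsilon = dkw_epsilon(J, alpha_band),
      alpha_band = alpha_band,
      censor = censor
    ),
    class = "dkw_localization"
  )
}

#' Dvoretzky-Kiefer-Wolfowitz half-width
#'
#' \eqn{\epsilon = \sqrt{\log(2/\alpha)/(2J)}} for a simultaneous
#' \eqn{1-\alpha} envelope around an empirical CDF built from J independent
#' units (here, studies).
#'
#' @param J Number of independent studies.
#' @param alpha_band Envelope level complement (default 0.05).
#' @return The half-width epsilon.
#' @export
dkw_epsilon <- function(J, alpha_band = 0.05) {
  stopifnot(J >= 1, alpha_band > 0, alpha_band < 1)
  sqrt(log(2 / alpha_band) / (2 * J))
}

#' Folded-normal CDF matrix of the scale-mixture class
#'
#' Under grid component j the SNR is \eqn{N(0, \sigma_j^2)}, hence
#' \eqn{|z|} is folded normal with scale \eqn{\sqrt{1+\sigma_j^2}}:
#' \eqn{P(|z| \le t) = 2\Phi(t/\sqrt{1+\sigma_j^2}) - 1}. The matrix has
#' one row per evaluation point plus two censored-cell rows
#' (mass below `lower`, mass above `upper`).
#'
#' @param grid SNR-scale grid from [build_sigma_grid()].
#' @param censor A [censor_spec()].
#' @param eval_points Evaluation points inside the window.
#' @return Matrix with `length(eval_points) + 2` rows and `length(grid)`
#'   columns; row names `"below"` and `"above"` mark the censored cells.
#' @export
model_cdf_matrix <- function(grid, censor = censor_spec(), eval_points) {
  sz <- sqrt(1 + grid^2)
  A <- outer(eval_points, sz, function(t, s) 2 * pnorm(t / s) - 1)
  below <- 2 * pnorm(censor$lower / sz) - 1
  above <- 1 - (2 * pnorm(censor$upper / sz) - 1)
  out <- rbind(A, below, above)
  rownames(out) <- c(rep("", length(eval_points)), "below", "above")
  out
}

# Replication probability of a single grid component (SNR scale sigma_g)
# at observed z0 with fold increase m: the closed form of the replication
# module specialized to one component.
grid_replication_prob <- function(sigma_g, z0, m, alpha) {
  cc <- two_sided_threshold(alpha)
  v <- sigma_g^2 / (1 + sigma_g^2)
  mu <- abs(z0) * v
  if (z0 == 0) {
    2 * pnorm(-cc / sqrt(m * v + 1))
  } else {
    pnorm((sqrt(m) * mu - cc) / sqrt(m * v + 1))
  }
}

#' Simultaneous confidence band for the replication curve
#'
#' For every z in `z_grid`, minimizes and maximizes the conditional
#' replication probability over all mixture weight vectors \eqn{\pi} on the
#' scale grid whose censored folded-normal CDF stays within the DKW
#' envelope of the study-weighted empirical CDF (at every evaluation point
#' and at both censored cells). The target is the linear-fractional
#' functional
#' \deqn{R(\pi; z) = \frac{\sum_j \pi_j f_j(z)\, r_j(z, m)}
#'                        {\sum_j \pi_j f_j(z)},}
#' with \eqn{f_j} the component marginal density of z and \eqn{r_j} the
#' component replication probability; each extremum is one linear program
#' after the Charnes-Cooper transform. All z share one feasible set, so the
#' band is simultaneous at level `1 - alpha_band`.
#'
#' @param localization A [weighted_folded_ecdf()] result.
#' @param z_grid z values at which to bound the curve.
#' @param m Fold increase of the replication sample size.
#' @param grid Scale grid (default [build_sigma_grid()]).
#' @param alpha Two-sided significance level of the replication test.
#' @param A Optional precomputed [model_cdf_matrix()] for `grid` and the
#'   localization's censor/eval points (recomputed when `NULL`).
#' @return A tibble of class `flocal_band` with columns `z`, `lower`,
#'   `upper`, `m`; attributes `epsilon`, `J`, `censor`, `alpha_band`.
#' @export
band_for_replication <- function(localization, z_grid, m = 1,
                                 grid = build_sigma_grid(), alpha = 0.05,
                                 A = NULL) {
  stopifnot(inherits(localization, "dkw_localization"))
  if (is.null(A)) {
    A <- model_cdf_matrix(grid, localization$censor, localization$eval_points)
  }
  stopifnot(ncol(A) == length(grid),
            nrow(A) == length(localization$eval_points) + 2)
  eps <- localization$epsilon
  emp <- c(localization$emp_cdf, localization$below, localization$above)
  G <- length(grid)
  nr <- nrow(A)

  # Charnes-Cooper variables (y_1..y_G, t): envelope rows A y within
  # [(emp - eps) t, (emp + eps) t], sum(y) = t, density normalized to 1.
  A1 <- rbind(cbind(A, -(emp + eps)), cbind(-A, (emp - eps)))
  b1 <- rep(0, 2 * nr)
  sz <- sqrt(1 + grid^2)

  solve_z <- function(z0) {
    fj <- dnorm(z0, 0, sz)
    rj <- grid_replication_prob(grid, z0, m, alpha)
    obj <- c(fj * rj, 0)
    A3 <- rbind(c(rep(1, G), -1), c(fj, 0))
    b3 <- c(0, 1)
    lo <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                        maxi = FALSE, eps = 1e-10)
    hi <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                        maxi = TRUE, eps = 1e-10)
    if (lo$solved != 1 || hi$solved != 1) {
      abort(
        "F-localization is infeasible or unsolved; widen the censoring window or increase alpha_band",
        class = "replimix_infeasible"
      )
    }
    c(lower = min(max(lo$value, 0), 1), upper = min(max(hi$value, 0), 1))
  }

  bounds <- vapply(z_grid, solve_z, numeric(2))
  out <- tibble::tibble(
    z = z_grid,
    lower = pmin(bounds["lower", ], bounds["upper", ]),
    upper = pmax(bounds["lower", ], bounds["upper", ]),
    m = m
  )
  attr(out, "epsilon") <- eps
  attr(out, "J") <- localization$J
  attr(out, "censor") <- localization$censor
  attr(out, "alpha_band") <- localization$alpha_band
  class(out) <- c("flocal_band", class(out))
  out
}

#' One-call simultaneous band from an effect table
#'
#' Convenience wrapper: [weighted_folded_ecdf()] followed by
#' [band_for_replication()].
#'
#' @inheritParams weighted_folded_ecdf
#' @inheritParams band_for_replication
#' @return A `flocal_band` tibble.
#' @export
replication_band <- function(data, z_grid = seq(0.25, 6, length.out = 24),
                             m = 1, censor = censor_spec(),
                             n_eval = 200, alpha_band = 0.05,
                             grid = build_sigma_grid(), alpha = 0.05) {
  loc <- weighted_folded_ecdf(data, censor = censor, n_eval = n_eval,
                              alpha_band = alpha_band)
  band_for_replication(loc, z_grid = z_grid, m = m, grid = grid,
                       alpha = alpha)
}
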