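#' Plot a fitted scale mixture
#'
#' Shows the fitted marginal density of z and the deconvolved SNR density
#' (continuous part) on a shared axis.
#'
#' @param object A `zmix_fit` or `z_mixture`.
#' @param xlim Range of the axis (default c(-8, 8)).
#' @param n Number of grid points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zmix_fit
#' @export
autoplot.zmix_fit <- function(object, xlim = c(-8, 8), n = 400, ...) {
  mix <- as_z_mixture(object)
  smix <- deconvolve(mix)
  x <- seq(xlim[1], xlim[2], length.out = n)
  df <- dplyr::bind_rows(
    tibble::tibble(x = x, density = z_density(mix, x), which = "z statistic"),
    tibble::tibble(x = x, density = snr_density(smix, x), which = "SNR")
  )
  df <- df[is.finite(df$density), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.zmix_fit
#' @method autoplot z_mixture
#' @export
autoplot.z_mixture <- autoplot.zmix_fit

#' Plot a replication curve
#'
#' @param object A [replication_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot replication_curve
#' @export
autoplot.replication_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z,
                                       y = .data$replication_probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "observed z statistic",
                  y = "P(successful replication)") +
    ggplot2::theme_minimal()
}

#' Plot a simultaneous F-localization band
#'
#' @param object A `flocal_band` tibble from [band_for_replication()].
#' @param curve Optional [replication_curve()] to overlay as the point
#'   estimate.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flocal_band
#' @export
autoplot.flocal_band <- function(object, curve = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "observed z statistic",
                  y = "P(successful replication)") +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = .data$z, y = .data$replication_probability)
    )
  }
  p
}

#' Plot the power distribution
#'
#' @param object A [power_distribution()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_distribution
#' @export
autoplot.power_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$power, y = .data$cdf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "statistical power", y = "P(power ≤ p)") +
    ggplot2::theme_minimal()
}
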