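# ggplot2 visualizations of tallies and fits.

#' Plot a detector tally
#'
#' One-axis tallies are drawn as a line (log10 y for reflectance-type
#' detectors) with a standard-error ribbon when available; two-axis
#' tallies as a filled raster. Frequency-domain tallies plot the
#' magnitude.
#'
#' @param object An `mc_tally`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mc_tally
#' @export
autoplot.mc_tally <- function(object, ...) {
  df <- tidy(object)
  axes <- setdiff(names(df), c("mean", "magnitude", "std_error", "detector"))
  val <- if ("magnitude" %in% names(df)) "magnitude" else "mean"
  if (length(axes) == 0) {
    abort("a scalar tally has nothing to plot")
  }
  if (length(axes) == 1) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                          y = .data[[val]]))
    if ("std_error" %in% names(df) && !"magnitude" %in% names(df)) {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data[[val]] - .data$std_error,
                     ymax = .data[[val]] + .data$std_error),
        alpha = 0.25
      )
    }
    p +
      ggplot2::geom_line() +
      ggplot2::labs(x = axes[1], y = sprintf("%s [%s]", object$name,
                                             object$units)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                     y = .data[[axes[2]]],
                                     fill = .data[[val]])) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(fill = object$units, title = object$name) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 .data
NULL

#' Plot an inverse fit
#'
#' Measurement versus the converged pMC prediction on the shared rho grid.
#'
#' @param object An `mc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mc_fit
#' @export
autoplot.mc_fit <- function(object, ...) {
  df <- object$measurement
  df$prediction <- object$prediction
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$reflectance,
                                     colour = "measurement")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prediction,
                                    colour = "pMC fit")) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rho [mm]", y = "R(rho) [1/mm^2]", colour = NULL) +
    ggplot2::theme_minimal()
}
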