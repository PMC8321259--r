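#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a relaxation-time map
#'
#' Filled-raster view of the `T1`-`T2` amplitude map on log axes.
#'
#' @param object a [t1t2_dist] with its grid.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.t1t2_dist <- function(object, ...) {
  if (is.null(object$rg)) stop("plotting needs the relaxation grid", call. = FALSE)
  df <- tibble::tibble(
    T1 = rep(object$rg$T1 * 1000, times = ncol(object$F)),
    T2 = rep(object$rg$T2 * 1000, each = nrow(object$F)),
    amplitude = as.vector(object$F))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$T2, y = .data$T1, fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "T2 (ms)", y = "T1 (ms)", fill = "amplitude") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.solve_result <- function(object, ...) {
  autoplot(object$F, ...) +
    ggplot2::ggtitle(sprintf("%s, alpha = %.3g%s", object$method, object$alpha,
                             if (!is.null(object$k)) sprintf(", k = %d", object$k) else ""))
}

#' Picard plot
#'
#' Log-scale plot of the singular values, the spectral data coefficients
#' `|u_i' s|` and their ratio versus the index — the visual tool for locating
#' the discrete-Picard-condition break.
#'
#' @param object a [picard_data] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.picard_data <- function(object, ...) {
  df <- tibble::tibble(
    i = rep(object$i, 3L),
    value = c(object$sigma, object$fourier, object$ratio),
    quantity = rep(c("sigma_i", "|u_i' s|", "|u_i' s| / sigma_i"),
                   each = nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "index i", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Filter-factor plot
#'
#' Filter factors versus singular values on log-x axes, showing the
#' Tikhonov roll-off, the TSVD cut-off or the hybrid combination.
#'
#' @param object a `filter_spec` from [filter_factors()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.filter_spec <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma, y = .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sigma_i", y = "filter factor",
                  title = attr(object, "method")) +
    ggplot2::theme_minimal()
}
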