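#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a speckle image
#'
#' @param object A `speckle_image`.
#' @param ... Unused.
#' @return A ggplot raster plot in gray scale.
#' @method autoplot speckle_image
#' @export
autoplot.speckle_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$gray <- as.vector(t(px))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "gray",
                  title = if (is.na(object$ra_nm)) "speckle image" else
                    sprintf("speckle image, Ra = %.3g nm", object$ra_nm)) +
    ggplot2::theme_minimal()
}

#' Plot an exponential fit with its data
#'
#' @param object An `exp_fit`.
#' @param ... Unused.
#' @return A ggplot of the observations and fitted curve.
#' @method autoplot exp_fit
#' @export
autoplot.exp_fit <- function(object, ...) {
  if (!object$converged) stop("cannot plot a non-converged fit.",
                              call. = FALSE)
  grid <- tibble::tibble(
    x = seq(min(object$data$x), max(object$data$x), length.out = 200))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      subtitle = sprintf("y = %.4g + %.4g exp(-%.4g x),  R² = %.4f",
                         object$y0, object$A, object$B, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Scree plot of a PCA model
#'
#' @param object A `speckle_pca`.
#' @param n_max Number of leading components to show.
#' @param ... Unused.
#' @return A ggplot bar chart of variance fractions.
#' @method autoplot speckle_pca
#' @export
autoplot.speckle_pca <- function(object, n_max = 12L, ...) {
  df <- tidy(object, "eigenvalues")
  df <- df[seq_len(min(n_max, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$PC), .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "principal component",
                  y = "% of total variance") +
    ggplot2::theme_minimal()
}

#' Plot a roughness calibration curve
#'
#' @param object A `roughness_calibration`.
#' @param ... Unused.
#' @return A ggplot of PC1 score versus Ra with the fitted exponential.
#' @method autoplot roughness_calibration
#' @export
autoplot.roughness_calibration <- function(object, ...) {
  autoplot(object$fit) +
    ggplot2::labs(x = "Ra (nm)", y = "PC1 score",
                  title = "PC1 score vs surface roughness")
}

#' Haralick parameter distance-curves of one image
#'
#' Computes the stack of GLCMs and plots each requested parameter against
#' separation distance, one panel per parameter, coloured by direction.
#'
#' @param image A `speckle_image` or matrix.
#' @param distances,directions,levels,log_base As in [speckle_features()].
#' @param parameters Parameters to show.
#' @return A ggplot.
#' @export
plot_distance_curves <- function(image, distances = 1:10,
                                 directions = c(0, 45, 90, 135),
                                 parameters = c("ASM", "CON"),
                                 levels = 256L, log_base = exp(1)) {
  hf <- haralick_stack(glcm_stack(image, distances, directions, levels),
                       log_base)
  long <- tidyr::pivot_longer(hf, dplyr::all_of(parameters),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$distance, .data$value,
                                     colour = factor(.data$direction))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "separation distance (px)", y = NULL,
                  colour = "direction (°)") +
    ggplot2::theme_minimal()
}
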