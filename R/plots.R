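#' Plot experiment results
#'
#' `autoplot()` methods: a scatter of asymmetry against turn rate with the
#' fitted line (HTA); a signed colour map of relative protraction against
#' wall-point position, red for reduced and blue for increased protraction
#' (CIA); and the min/mean/max spread against whisk type (SR).
#'
#' @param object A result object.
#' @param saturate Colour-scale saturation for the CIA map (deg).
#' @param ... Unused.
#' @return A ggplot object.
#' @name vibrisim-autoplot
NULL

#' @rdname vibrisim-autoplot
#' @export
autoplot.hta_result <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$turn_rate, y = .data$asymmetry)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "head turn rate (deg/ms)",
                  y = "left - right mean protraction (deg)",
                  title = sprintf("Head-turning asymmetry: slope %.1f",
                                  object$slope)) +
    ggplot2::theme_minimal()
}

#' @rdname vibrisim-autoplot
#' @export
autoplot.cia_result <- function(object, saturate = 10, ...) {
  ggplot2::ggplot(object$map,
                  ggplot2::aes(x = .data$y, y = .data$x,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-saturate, saturate),
                                  oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "wall point, lateral (mm, +ipsilateral)",
                  y = "wall point, ahead (mm)",
                  fill = "rel. angle (deg)",
                  title = "Contact-induced asymmetry") +
    ggplot2::theme_minimal()
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @rdname vibrisim-autoplot
#' @export
autoplot.sr_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              cols = c("min_spread", "mean_spread",
                                       "max_spread"),
                              names_to = "stat", values_to = "spread")
  long$whisk <- factor(long$whisk, levels = c("pre", "first", "second"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$whisk, y = .data$spread,
                                     group = .data$stat,
                                     linetype = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "whisk", y = "angular spread (deg)",
                  title = "Spread reduction on wall approach") +
    ggplot2::theme_minimal()
}

#' Plot the fovea trajectory of a simulation log
#'
#' @param log A `sim_log`.
#' @return A ggplot object with the fovea path and any obstacles.
#' @export
plot_trajectory <- function(log) {
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$fovea_x,
                                         y = .data$fovea_y)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$t)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "t (s)") +
    ggplot2::theme_minimal()
  obst <- attr(log, "obstacles")
  if (!is.null(obst) && nrow(obst) > 0) {
    corners <- purrr::map_dfr(seq_len(nrow(obst)), function(i) {
      o <- obst[i, ]
      a <- o$angle * pi / 180
      hx <- o$width / 2
      hy <- o$height / 2
      cc <- rbind(c(-hx, -hy), c(hx, -hy), c(hx, hy), c(-hx, hy))
      tibble(id = i,
             x = o$cx + cos(a) * cc[, 1] - sin(a) * cc[, 2],
             y = o$cy + sin(a) * cc[, 1] + cos(a) * cc[, 2])
    })
    p <- p + ggplot2::geom_polygon(data = corners,
                                   ggplot2::aes(x = .data$x, y = .data$y,
                                                group = .data$id),
                                   inherit.aes = FALSE, fill = "grey70")
  }
  p
}
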