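# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.lc_hotspots <- function(object, ...) {
  tb <- object$table
  tb$class <- dplyr::case_when(
    tb$is_outlier ~ "occupancy outlier",
    tb$in_upper_quartile ~ "upper quartile",
    TRUE ~ "background")
  thr <- object$thresholds
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$residue_number,
                                   y = .data$max_occupancy_ns,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = thr$threshold[thr$metric == "max_occupancy"],
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      "occupancy outlier" = "#c0392b", "upper quartile" = "#f1c40f",
      "background" = "grey60")) +
    ggplot2::labs(x = "residue", y = "maximum occupancy (ns)",
                  colour = NULL,
                  title = "Contact hot spots",
                  subtitle = "dashed: Q3 + 1.5 IQR outlier threshold") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.lc_msd <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$lag_ns, y = .data$msd_A2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ns)", y = expression(MSD ~ (ring(A)^2)),
                  title = sprintf("Lateral MSD: %s",
                                  attr(object, "species", exact = TRUE))) +
    ggplot2::theme_minimal()
  if (!is.null(fit))
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = 4 * fit$D_A2_ns,
                                  colour = "#c0392b", linetype = "dashed")
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.lc_density_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$z_A, y = .data$density,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z relative to midplane (Å)",
                  y = expression(density ~ (ring(A)^-3)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.lc_density_map <- function(object, ...) {
  tb <- tidyr::expand_grid(x = object$x_A, y = object$y_A)
  tb$density <- as.vector(t(object$grid))
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  fill = expression(ring(A)^-2),
                  title = sprintf("2D density: %s", object$species)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.lc_dose_fit <- function(object, ...) {
  tb <- object$data
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data$conc_uM, .data$residual)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[inhibitor] (µM)", y = "residual current I/Icon") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(conc_uM = exp(seq(log(min(tb$conc_uM) / 2),
                                     log(max(tb$conc_uM) * 2), length.out = 120)))
    grid$residual <- hill_residual(grid$conc_uM, object$params[["ic50_uM"]],
                                   object$params[["h"]], object$params[["s"]])
    p <- p + ggplot2::geom_line(data = grid, colour = "#2980b9")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.lc_boltzmann_fit <- function(object, ...) {
  tb <- object$data
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data$v_mV, .data$i_norm)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Vm (mV)", y = "I / Imax") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(v_mV = seq(min(tb$v_mV), max(tb$v_mV), length.out = 120))
    grid$i_norm <- boltzmann_activation(grid$v_mV, object$params[["v_half"]],
                                        object$params[["k"]])
    p <- p + ggplot2::geom_line(data = grid, colour = "#2980b9")
  }
  p
}
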