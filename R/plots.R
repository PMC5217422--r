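#' Plot a Kaplan-Meier curve
#'
#' Step plot of the survivor function, one colour per stratum, censoring
#' marks at censored follow-up times.
#'
#' @param object An `efs_km` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.efs_km <- function(object, ...) {
  has_group <- "group" %in% names(object)
  mapping <- if (has_group) {
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$survival)
  }
  cens <- dplyr::filter(object, .data$n_censor > 0)
  ggplot2::ggplot(object, mapping) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Event-free survival") +
    ggplot2::theme_minimal()
}

#' Forest plot of Cox hazard ratios
#'
#' @param object An `efs_cox` object from [cox_fit()] or [cox_stepwise()].
#' @param ... Unused.
#' @return A ggplot object (log-scaled HR axis with 95% CIs).
#' @export
autoplot.efs_cox <- function(object, ...) {
  tab <- dplyr::filter(tidy(object), .data$estimable)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Axial slice of a PET volume
#'
#' @param object A [pet_volume()].
#' @param slice Axial (third-axis) slice index; middle slice by default.
#' @param ... Unused.
#' @return A ggplot raster of the slice in SUV units.
#' @export
autoplot.pet_volume <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$suv <- as.vector(object$values[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$suv)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed(ratio = object$spacing[2] / object$spacing[1]) +
    ggplot2::scale_fill_viridis_c(name = "SUV") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Axial slice %d", slice)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
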