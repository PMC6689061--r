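#' Plot a calibration sweep
#'
#' R versus medium-layer thickness, one line per incident energy, faceted
#' by compartment — the standard way of reading the calibration table.
#'
#' @param object A `proton_rtable` from [sweep_R()].
#' @param group Which cell group to draw (default the nine-cell average).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proton_rtable <- function(object, group = "all", ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$group == !!group)
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$thickness_um, .data$R,
                 colour = factor(.data$energy_mev))
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$compartment)) +
    ggplot2::labs(
      x = "medium-layer thickness (µm)",
      y = expression(R == D[A] / D[E]),
      colour = "energy (MeV)"
    ) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.proton_rtable
#' @export
plot_r_curves <- function(object, group = "all") {
  autoplot.proton_rtable(object, group = group)
}

#' Plot a detector dose curve
#'
#' @param object A `proton_ioc_dose` from [simulate_ioc_dose()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proton_ioc_dose <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$energy_mev, .data$dose_mev_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "incident proton energy (MeV)",
      y = expression(D[E] ~ "(MeV/g per source particle)")
    ) +
    ggplot2::theme_bw()
}

#' Plot a depth-dose (Bragg) curve
#'
#' @param object A `proton_depth_dose` from [simulate_depth_dose()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proton_depth_dose <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$depth_um, .data$dose_mev_g)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "depth (µm)",
      y = "dose (MeV/g per unit fluence)",
      title = sprintf("%g MeV protons in %s", attr(object, "energy_mev"),
                      attr(object, "material"))
    ) +
    ggplot2::theme_bw()
}
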