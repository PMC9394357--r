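# ggplot2 views of runs and profiles.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the energy (or temperature) history of a run
#'
#' @param object A `dpd_run`.
#' @param type `"energy"` (per-bead energy components), `"total"` or
#'   `"temperature"`.
#' @param stages Optional [stage_segmentation()]; its boundaries are drawn
#'   as vertical lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dpd_run <- function(object, type = c("energy", "total",
                                              "temperature"),
                             stages = NULL, ...) {
  type <- match.arg(type)
  d <- tidy(object)
  d <- switch(type,
              energy = d[d$observable %in% c("kinetic", "pair", "bond",
                                             "angle", "total"), ],
              total = d[d$observable == "total", ],
              temperature = d[d$observable == "temperature", ])
  p <- ggplot(d, aes(x = .data$time, y = .data$value,
                     colour = .data$observable)) +
    geom_line() +
    labs(x = "time (tau)",
         y = if (type == "temperature") "kBT" else "energy per bead (kBT)",
         colour = NULL) +
    theme_minimal()
  if (!is.null(stages)) {
    p <- p + geom_vline(xintercept = c(stages$t_initial_end,
                                       stages$t_adjust_end),
                        linetype = "dashed")
  }
  p
}

#' Plot a density profile
#'
#' @param profile A [density_profile()] or [radial_density_profile()]
#'   tibble.
#' @return A ggplot of density against the profile coordinate, coloured
#'   by species.
#' @export
plot_density_profile <- function(profile) {
  xvar <- if ("coord" %in% names(profile)) "coord" else "r"
  ggplot(profile, aes(x = .data[[xvar]], y = .data$density,
                      colour = .data$species)) +
    geom_line() +
    labs(x = paste0(if (xvar == "r") "r" else "position", " (rc)"),
         y = "density (beads/rc^3)", colour = NULL) +
    theme_minimal()
}

#' Plot an order-parameter profile
#'
#' @param profile An [order_parameter()] tibble (optionally with a
#'   `sub_chain` column to facet by).
#' @return A ggplot of mean P2 against position.
#' @export
plot_order_profile <- function(profile) {
  p <- ggplot(profile[!is.na(profile$p2), ],
              aes(x = .data$coord, y = .data$p2)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "position (rc)", y = "P2 order parameter") +
    theme_minimal()
  if ("sub_chain" %in% names(profile)) {
    p <- p + facet_wrap(~sub_chain)
  }
  p
}

#' Plot an interfacial-tension profile
#'
#' @param profile A [tension_profile()] tibble.
#' @return A ggplot of sigma_z against z.
#' @export
plot_tension_profile <- function(profile) {
  ggplot(profile, aes(x = .data$z, y = .data$sigma_z)) +
    geom_line() +
    labs(x = "z (rc)", y = "sigma_z (kBT/rc^3)") +
    theme_minimal()
}
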