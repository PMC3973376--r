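compartment_labels <- c(
  c1 = "stem cells", c2 = "progenitors", c3 = "neuroblasts",
  c4 = "neurons", c5 = "astrocytes",
  l1 = "BrdU+ stem cells", l2 = "BrdU+ progenitors", l3 = "BrdU+ neuroblasts",
  l4 = "BrdU+ neurons", l5 = "BrdU+ astrocytes"
)

#' Plot a simulated trajectory
#'
#' @param object An `ng_trajectory` from [ng_solve()] or
#'   [labeled_trajectory()].
#' @param log10 Plot counts on a log10 axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ng_trajectory <- function(object, log10 = FALSE, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "compartment", values_to = "count") |>
    dplyr::mutate(compartment = factor(
      compartment_labels[.data$compartment],
      levels = unname(compartment_labels)
    ))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$count,
                                          colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (model units)", y = "cells", colour = NULL) +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a parameter-sensitivity curve set
#'
#' @param object An `ng_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object, one facet per compartment, with the zero line
#'   marked (sign phases are read off against it).
#' @export
autoplot.ng_sensitivity <- function(object, ...) {
  param <- attr(object, "param")
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "quantity", values_to = "derivative") |>
    dplyr::mutate(quantity = factor(
      compartment_labels[.data$quantity],
      levels = unname(compartment_labels)
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$derivative)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (model units)",
                  y = sprintf("d count / d %s", param)) +
    ggplot2::theme_minimal()
}

#' Plot an age-series fit against its data
#'
#' @param object An `ng_fit` from [fit_age_series()].
#' @param ... Unused.
#' @return A ggplot object with observed means (error bars: s.e.m.) and the
#'   fitted curves, facetted by compartment.
#' @export
autoplot.ng_fit <- function(object, ...) {
  curves <- fitted_curves(object) |>
    dplyr::filter(.data$compartment %in% unique(object$data$compartment))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$age, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.25) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "age (model units)", y = "cells") +
    ggplot2::theme_minimal()
}
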