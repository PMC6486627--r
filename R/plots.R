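# ggplot2 visualisations of fits and conformation tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Michaelis-Menten fit
#'
#' Data points with the fitted rate curve.
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$data)
  e <- tidy(object)
  grid <- tibble::tibble(s = seq(0, max(d$s), length.out = 200))
  grid$v <- mm_velocity(grid$s, e$estimate[e$term == "kcat"],
                        e$estimate[e$term == "km"], object$e_uM)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[ATP] (mM)", y = expression(v[0] ~ (mu * M / s)),
                  title = sprintf("Michaelis-Menten fit: kcat = %.3g /s, Km = %.3g mM",
                                  e$estimate[e$term == "kcat"],
                                  e$estimate[e$term == "km"])) +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence-polarization binding fit
#'
#' Normalized fraction bound against protein concentration with the fitted
#' quadratic isotherm.
#'
#' @param object An `fp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fp_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$data)
  e <- tidy(object)
  kd <- e$estimate[e$term == "kd"]
  grid <- tibble::tibble(rt = seq(0, max(d$rt), length.out = 300))
  grid$fb <- fp_fraction_bound(grid$rt, kd, object$lt_uM)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rt, y = .data$fb)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[protein] (µM)", y = "fraction bound",
                  title = sprintf("Binding isotherm: Kd = %.3g µM", kd)) +
    ggplot2::theme_minimal()
}

#' Plot a conformation table
#'
#' RecA1-RecA2 center-of-mass distances per entry, coloured by the assigned
#' open/closed state, with the classification threshold drawn.
#'
#' @param conformation Tibble from [run_analysis()] (`$conformation`) or
#'   rows of [com_distance_protocol()] output with an `id` column.
#' @param threshold Threshold line, Angstrom.
#' @return A ggplot.
#' @export
plot_conformation <- function(conformation,
                              threshold = HELICORE_DCOM_THRESHOLD) {
  if (!"id" %in% names(conformation)) conformation$id <- conformation$target_id
  ggplot2::ggplot(conformation,
                  ggplot2::aes(x = stats::reorder(.data$id, .data$d_com),
                               y = .data$d_com, fill = .data$state)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "RecA1–RecA2 COM distance (Å)",
                  fill = "state") +
    ggplot2::theme_minimal()
}
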