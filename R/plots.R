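#' Plot a simulated trajectory
#'
#' Two standard views of a `dmt1_trajectory`: cumulative apical uptake per
#' challenge (`what = "uptake"`) or the transporter distribution over time
#' (`what = "fractions"`, membrane vs endocyted fraction), the latter
#' mirroring the endocytic-cycling panels of the model figures.
#'
#' @param object A `dmt1_trajectory`.
#' @param what `"uptake"` or `"fractions"`.
#' @param data Optional uptake dataset to overlay as points (uptake view).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmt1_trajectory <- function(object, what = c("uptake", "fractions"),
                                     data = NULL, ...) {
  what <- match.arg(what)
  geometry <- attr(object, "geometry")
  if (what == "uptake") {
    ups <- uptake_series(object, geometry,
                         challenge = unique(object$challenge))
    starts <- object |>
      dplyr::group_by(.data$challenge) |>
      dplyr::summarise(start = min(.data$time_min), .groups = "drop")
    ups <- dplyr::left_join(ups, starts, by = "challenge")
    ups$time_abs <- ups$time_min + ups$start
    p <- ggplot2::ggplot(ups, ggplot2::aes(.data$time_abs, .data$uptake_pmol,
                                           colour = factor(.data$challenge))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (min)", y = "cumulative uptake (pmol/insert)",
                    colour = "challenge",
                    title = sprintf("%s model: apical iron uptake",
                                    attr(object, "model")))
    if (!is.null(data)) {
      pts <- dplyr::left_join(data, starts, by = "challenge")
      pts$time_abs <- pts$time_min + pts$start
      p <- p + ggplot2::geom_point(
        data = pts,
        ggplot2::aes(.data$time_abs, .data$uptake_pmol,
                     colour = factor(.data$challenge)),
        inherit.aes = FALSE, alpha = 0.7)
    }
    p
  } else {
    long <- tidyr::pivot_longer(
      object[, c("time_min", "membrane_fraction", "endocyted_fraction")],
      -"time_min", names_to = "pool", values_to = "fraction")
    ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$fraction,
                                       colour = .data$pool)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (min)", y = "fraction of DMT1",
                    title = sprintf("%s model: DMT1 cycling",
                                    attr(object, "model")))
  }
}

#' Plot a sensitivity table
#'
#' Diverging bar chart of the +10% and -10% normalized sensitivity
#' coefficients per parameter, coloured by influence class.
#'
#' @param table Output of [sensitivity_table()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(table) {
  long <- tidyr::pivot_longer(table[, c("parameter", "r_plus", "r_minus",
                                        "influence")],
                              c("r_plus", "r_minus"),
                              names_to = "direction", values_to = "r")
  long$parameter <- factor(long$parameter, levels = rev(table$parameter))
  ggplot2::ggplot(long, ggplot2::aes(.data$r, .data$parameter,
                                     fill = .data$influence)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "normalized sensitivity coefficient", y = NULL)
}

#' Plot the mucosal-block summary
#'
#' Per-time percent reduction in mean uptake between the first and second
#' challenges.
#'
#' @param summary Output of [mucosal_block_summary()].
#' @return A ggplot object.
#' @export
plot_mucosal_block <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$time_min,
                                        .data$reduction_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time after challenge (min)",
                  y = "uptake reduction, challenge 2 vs 1 (%)")
}
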