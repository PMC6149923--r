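#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a population trajectory
#'
#' Cell counts (total, quiescent, apoptotic) over time, with the decaying
#' drug concentrations in a lower panel.
#'
#' @param object An `abm_trajectory` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abm_trajectory <- function(object, ...) {
  counts <- object |>
    dplyr::select("time_h", "n_alive", "n_quiescent", "n_apoptotic") |>
    tidyr::pivot_longer(-"time_h", names_to = "series", values_to = "count") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
      n_alive = "alive", n_quiescent = "quiescent", n_apoptotic = "apoptotic"
    ))
  ggplot2::ggplot(counts, ggplot2::aes(.data$time_h, .data$count,
    colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (h)", y = "cells", colour = NULL,
      title = "Population trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' Plot drug concentration decay for a trajectory
#'
#' @param trajectory An `abm_trajectory`.
#' @return A ggplot object.
#' @export
plot_drug_decay <- function(trajectory) {
  cfg <- attr(trajectory, "config")
  nm <- if (!is.null(cfg)) cfg$drugs$name else c("drug1", "drug2")
  df <- trajectory |>
    dplyr::select("time_h", "drug1_uM", "drug2_uM") |>
    tidyr::pivot_longer(-"time_h", names_to = "drug", values_to = "uM") |>
    dplyr::mutate(drug = ifelse(.data$drug == "drug1_uM", nm[1], nm[2]))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$uM, colour = .data$drug)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (uM)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose-inhibition table
#'
#' Replicate inhibition fractions against total dose, coloured by drug
#' pair, with the per-row mean overlaid.
#'
#' @param table A dose table with `dose1_uM`, `dose2_uM` and `rep*`
#'   columns.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(table) {
  long <- table |>
    dplyr::mutate(total_uM = .data$dose1_uM + .data$dose2_uM) |>
    tidyr::pivot_longer(dplyr::starts_with("rep"),
      names_to = "replicate", values_to = "inhibition"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$total_uM, .data$inhibition)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "steelblue") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "total dose (uM)", y = "inhibition fraction") +
    ggplot2::theme_minimal()
}

#' Plot a combination-index report
#'
#' Combination indices per ratio with the additive band (0.9-1.1) shaded
#' and the synergy thresholds marked.
#'
#' @param object An `abm_synergy_report` from [synergy_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abm_synergy_report <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$CI))
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio, .data$CI)) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf, ymin = 0.9, ymax = 1.1,
      alpha = 0.15, fill = "grey50"
    ) +
    ggplot2::geom_hline(yintercept = c(0.3, 0.9, 1.1), linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 3) +
    ggplot2::labs(
      x = "dose ratio (drug1:drug2)", y = "combination index",
      colour = NULL,
      title = paste(df$drug1[1], "+", df$drug2[1])
    ) +
    ggplot2::theme_minimal()
}
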