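# ggplot2 views of scoring results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ASCO score decomposition
#'
#' Stacked bars of the NHB components (clinical benefit, toxicity, bonuses)
#' per treatment, with the net health benefit annotated. Negative toxicity
#' points stack below zero.
#'
#' @param object An `asco_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(asco_score(rcc_trials()))
#' @export
autoplot.asco_scores <- function(object, ...) {
  long <- tidy(object) |>
    filter(.data$component != "nhb") |>
    mutate(component = factor(.data$component, levels = c(
      "clinical_benefit", "toxicity", "bonus_tail", "bonus_palliation",
      "bonus_qol", "bonus_tfi"
    )))
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$treatment_label, .data$points, sum),
    y = .data$points, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = object,
      ggplot2::aes(x = .data$treatment_label, y = .data$nhb),
      inherit.aes = FALSE, shape = 18, size = 3
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "points", fill = "component",
      title = "ASCO Value Framework net health benefit",
      subtitle = "diamond: net health benefit (sum of components)"
    )
}

#' Plot ESMO-MCBS grades
#'
#' Preliminary and final grades per treatment; an arrow marks an adjustment
#' upgrade.
#'
#' @param object An `esmo_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(esmo_score(rcc_trials()))
#' @export
autoplot.esmo_scores <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$treatment_label, .data$final_grade)
  )) +
    ggplot2::geom_segment(
      data = dat[dat$upgraded, ],
      ggplot2::aes(
        xend = .data$treatment_label,
        y = .data$preliminary_grade, yend = .data$final_grade
      ),
      arrow = grid::arrow(length = grid::unit(0.15, "cm"))
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$preliminary_grade, shape = "preliminary"),
      size = 3
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$final_grade, shape = "final"),
      size = 3
    ) +
    ggplot2::scale_y_continuous(breaks = 1:5, limits = c(1, 5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "grade", shape = NULL,
      title = "ESMO-MCBS grades (non-curative forms)",
      subtitle = "arrows: one-level adjustment upgrades"
    )
}
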