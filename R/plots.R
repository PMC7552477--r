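#' Plot a payment ledger
#'
#' Bar chart of department shares of the budget limit.
#'
#' @param object A `payment_ledger` from [remunerate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.payment_ledger <- function(object, ...) {
  dept <- ledger_departments(object)
  ggplot2::ggplot(dept, ggplot2::aes(x = .data$department_id, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "Department", y = "Share of budget limit",
      title = sprintf("Value-based payout (model %s, k = %.3g)",
                      attr(object, "model"), attr(object, "k"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a concept map
#'
#' Scatter of the statements on the MDS plane, coloured by cluster.
#'
#' @param object A `concept_map` from [concept_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concept_map <- function(object, ...) {
  ggplot2::ggplot(
    object$statements,
    ggplot2::aes(x = .data$x, y = .data$y, colour = factor(.data$cluster))
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Dimension 1", y = "Dimension 2", colour = "Cluster",
      title = sprintf("Concept map (stress %.1f)", object$stress)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of WHO-chapter odds ratios
#'
#' @param object A `chapter_contrast` from [chapter_contrast()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chapter_contrast <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$status == "ok")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$odds_ratio, y = factor(.data$chapter))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (cases vs controls)", y = "WHO chapter") +
    ggplot2::theme_minimal()
}
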