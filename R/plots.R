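# ggplot2 views of the main result types.

#' Plot a domain's backbone interval model
#'
#' Shows the `2^c` eta intervals with their class assignment and quota.
#'
#' @param spec A [domain_spec()].
#' @return A ggplot object.
#' @export
plot_backbone <- function(spec) {
  bb <- build_backbone(spec)
  ggplot2::ggplot(bb) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$lower, xmax = .data$upper, ymin = 0, ymax = 1,
        fill = .data$class
      ),
      color = "grey30"
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$lower + .data$upper) / 2, y = 0.5,
                   label = .data$quota)
    ) +
    ggplot2::scale_fill_manual(values = c(majority = "grey80", minority = "steelblue")) +
    ggplot2::labs(
      x = expression(eta), y = NULL,
      title = sprintf("Backbone: %s complexity (s=%d, i=%d)",
                      spec$complexity, spec$s, spec$i)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Bar chart of mean rank differences per method
#'
#' The plotted twin of the study's per-complexity rank-difference
#' panels: one bar per method, grouped by imbalance level, with stars
#' marking significant paired t-tests.
#'
#' @param object A `sim_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_study
#' @export
autoplot.sim_study <- function(object, ...) {
  df <- object$summary |>
    filter(.data$method != "none") |>
    mutate(i = factor(.data$i))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean_rank_diff,
                                   fill = .data$i)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_text(
      data = df |> filter(.data$significant),
      ggplot2::aes(label = "*"),
      position = ggplot2::position_dodge(width = 0.8), vjust = 0
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$complexity),
                        cols = ggplot2::vars(.data$s)) +
    ggplot2::scale_fill_grey(start = 0.8, end = 0.2, name = "imbalance i") +
    ggplot2::labs(x = NULL, y = "mean rank difference vs no resampling") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Precision-recall curve for one scored test set
#'
#' @param scores Classifier scores.
#' @param labels Binary labels (minority positive).
#' @return A ggplot object annotated with the AUPRC.
#' @export
plot_pr_curve <- function(scores, labels) {
  curve <- score_curve(scores, labels)
  ap <- auprc(scores, labels)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "recall", y = "precision",
      title = sprintf("Precision-recall curve (AUPRC = %.3f)", ap)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
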