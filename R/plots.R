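# ggplot2 front ends for the result objects.

#' Plot ROC / PR curves of an evaluation result
#'
#' @param object A `grn_eval` from [evaluate_ranking()].
#' @param type `"roc"` or `"pr"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.grn_eval <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                  colour = "grey60") +
      geom_step() +
      labs(x = "False positive rate", y = "True positive rate",
           title = sprintf("ROC curve (AUROC = %.3f)", object$auroc)) +
      coord_equal() +
      theme_minimal()
  } else {
    ggplot(object$pr_points, aes(x = .data$recall, y = .data$precision)) +
      geom_step(direction = "vh") +
      lims(x = c(0, 1), y = c(0, 1)) +
      labs(x = "Recall", y = "Precision",
           title = sprintf("Precision-recall curve (AUPR = %.3f)",
                           object$aupr)) +
      theme_minimal()
  }
}

#' Plot a prior-strength scan
#'
#' Shows how the agreement with the prior network (AUROC) and the data fit
#' (SSR) respond to the prior strength g.
#'
#' @param object A `g_scan` tibble from [g_scan()].
#' @param ... Ignored.
#' @return A ggplot object faceted by metric.
#' @export
autoplot.g_scan <- function(object, ...) {
  long <- pivot_longer(as_tibble(object), c("auroc_vs_prior", "ssr"),
                       names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$g, y = .data$value)) +
    geom_line() +
    geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "prior strength g", y = NULL) +
    theme_minimal()
}

#' Plot the stable-state landscape
#'
#' Basin fractions of the discovered stable states, labelled by their marker
#' signature.
#'
#' @param object A `stable_states` tibble from [find_stable_states()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.stable_states <- function(object, ...) {
  d <- as_tibble(object)
  d$state <- sprintf("state %d (%s)", d$state_id, d$label)
  ggplot(d, aes(x = .data$state, y = .data$basin_fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Basin fraction") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Heatmap of a confidence matrix
#'
#' @param object A [new_confidence_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.confidence_matrix <- function(object, ...) {
  genes <- rownames(object)
  d <- as_tibble(unclass(object), rownames = "regulator") |>
    pivot_longer(-"regulator", names_to = "target", values_to = "confidence")
  d$regulator <- factor(d$regulator, levels = genes)
  d$target <- factor(d$target, levels = genes)
  ggplot(d, aes(x = .data$target, y = .data$regulator,
                fill = .data$confidence)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(title = attr(object, "method") %||% "confidence") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}
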