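#' Plot Kaplan-Meier curves
#'
#' Step curves per group with censoring ticks.
#'
#' @param object A `km_fit` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_fit <- function(object, ...) {
  curves <- object$curves %>%
    group_by(.data$group) %>%
    group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, n_censor = 0L, estimate = 1),
      .x
    )) %>%
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$estimate, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(curves, .data$n_censor > 0),
      shape = 3, show.legend = FALSE
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Overall survival",
      colour = NULL,
      subtitle = if (is.na(object$logrank$p_value)) {
        NULL
      } else {
        sprintf("log-rank P = %.2g", object$logrank$p_value)
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample variant burden by subtype
#'
#' Box plots of per-sample counts with jittered points, one panel per scope
#' when a `scope` column is present.
#'
#' @param burden Tibble with `n_variants`, `group` and optionally `scope`.
#' @return A ggplot.
#' @export
plot_burden <- function(burden) {
  p <- ggplot2::ggplot(burden, ggplot2::aes(.data$group, .data$n_variants)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = NULL, y = "Variants per sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
  if ("scope" %in% names(burden)) {
    p <- p + ggplot2::facet_wrap(~scope, scales = "free_y")
  }
  p
}

#' Plot a signature's member genes
#'
#' Member genes ordered by P-value, coloured by direction.
#'
#' @param object A `mutation_signature`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mutation_signature <- function(object, ...) {
  d <- object$members %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, -log10(.data$p_value),
    colour = .data$direction
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Member rank", y = expression(-log[10](P)),
      title = sprintf("%s (%s) signature", object$source_gene, object$region_scope)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve behind a cut-off model
#'
#' Recomputes the full sensitivity/specificity path for display.
#'
#' @param values,labels The data the cut-off was derived from.
#' @param model The `cutoff_model` (its chosen operating point is marked).
#' @return A ggplot.
#' @export
plot_roc <- function(values, labels, model) {
  labels <- as.logical(labels)
  uniq <- sort(unique(values))
  thresholds <- c(uniq[1] - 1, (head(uniq, -1) + tail(uniq, -1)) / 2, uniq[length(uniq)] + 1)
  d <- tibble(
    sens = vapply(thresholds, function(t) mean(values[labels] >= t), numeric(1)),
    spec = vapply(thresholds, function(t) mean(values[!labels] < t), numeric(1))
  )
  ggplot2::ggplot(d, ggplot2::aes(1 - .data$spec, .data$sens)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::annotate("point",
      x = 1 - model$specificity, y = model$sensitivity,
      colour = "red"
    ) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s: cutoff %.4g, AUC %.3f", model$marker, model$cutoff, model$auc)
    ) +
    ggplot2::theme_minimal()
}
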