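#' Plot social information use by condition
#'
#' Mean social information use per peer-confidence level, split by own
#' certainty and faceted by group, with standard-error bars — the standard
#' way to display the two experimental manipulations.
#'
#' @param object A `pb_condition_summary` from [summarize_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_condition_summary
#' @export
autoplot.pb_condition_summary <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = factor(.data$peer_confidence), y = .data$mean_s,
                 colour = .data$certainty, group = .data$certainty)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_s - .data$se_s,
                   ymax = .data$mean_s + .data$se_s)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Peer confidence", y = "Social information use (s)",
                  colour = "Own certainty") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot group-level model comparison
#'
#' Delta-BIC (excess over the best model) per model and group; the winning
#' model sits at zero.
#'
#' @param object A `pb_model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_model_comparison
#' @export
autoplot.pb_model_comparison <- function(object, ...) {
  object$model_id <- factor(object$model_id, levels = pb_model_ids())
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$model_id, y = .data$delta_bic)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = NULL, y = expression(Delta * "BIC")) +
    ggplot2::theme_minimal()
}

#' Plot a model-recovery confusion matrix
#'
#' Fraction of simulated participants from each generating model (rows) won
#' by each candidate model (columns); a dark diagonal indicates good
#' recoverability.
#'
#' @param object A `pb_confusion` from [model_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_confusion
#' @export
autoplot.pb_confusion <- function(object, ...) {
  long <- tidy.pb_confusion(object)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$fitted, y = .data$generating,
                 fill = .data$fraction)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$fraction)),
      colour = "white", size = 3
    ) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Best-fitting model", y = "Generating model",
                  fill = "Fraction") +
    ggplot2::theme_minimal()
}

#' Plot parameter-recovery scatters
#'
#' Generating versus refitted parameter values, one facet per parameter,
#' with the identity line; annotations report the Pearson correlation.
#'
#' @param object A `pb_recovery` from [parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_recovery
#' @export
autoplot.pb_recovery <- function(object, ...) {
  scatter <- attr(object, "scatter")
  labels <- object |>
    dplyr::mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(
    scatter,
    ggplot2::aes(x = .data$generating, y = .data$fitted)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free") +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(label = .data$label), x = -Inf, y = Inf,
      hjust = -0.2, vjust = 1.5, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "Generating value", y = "Fitted value") +
    ggplot2::theme_minimal()
}

#' Plot a discretized response distribution
#'
#' The mixture distribution over slider responses: discretized beta mass
#' per bin plus the stay point mass at the first estimate.
#'
#' @param object A `pb_response_model` from [response_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_response_model
#' @export
autoplot.pb_response_model <- function(object, ...) {
  df <- tibble::tibble(
    response = 0:100,
    probability = object$bin_probs +
      ifelse(0:100 == object$e1_bin, object$stay_mass, 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response,
                                   y = .data$probability)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "Second estimate (slider)", y = "Probability") +
    ggplot2::theme_minimal()
}
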