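#' Plot theoretical signed-confidence distributions
#'
#' One panel per stimulus condition, signed confidence on the horizontal
#' axis, response probability on the vertical axis.
#'
#' @param object A [theoretical_confidence_distributions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot confidence_distribution
#' @export
autoplot.confidence_distribution <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_confidence, y = .data$prob)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$contrast),
                        cols = ggplot2::vars(.data$interval),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "signed confidence (sign = decision)",
                  y = "probability",
                  title = sprintf("%s model", attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.confidence_distribution
#' @param model,params,... Passed to
#'   [theoretical_confidence_distributions()].
#' @export
plot_confidence_distributions <- function(model, params, ...) {
  autoplot(theoretical_confidence_distributions(model, params, ...))
}

#' Plot a confidence-region map of sensory space
#'
#' Shows which signed confidence level a calibrated model assigns to every
#' point of the `(x1, x2)` plane, with the per-condition mean sensory
#' signals overlaid.
#'
#' @param object A [confidence_region_map()] result.
#' @param show_conditions Overlay the condition means (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_map
#' @export
autoplot.region_map <- function(object, show_conditions = TRUE, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$signed_confidence))) +
    ggplot2::scale_fill_viridis_d(name = "signed\nconfidence") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s model", attr(object, "model"))) +
    ggplot2::theme_minimal()
  if (isTRUE(show_conditions)) {
    grid <- condition_grid(attr(object, "contrasts"))
    means <- tibble(x1 = ifelse(grid$interval == 1L, grid$contrast, 0),
                    x2 = ifelse(grid$interval == 2L, grid$contrast, 0))
    p <- p + ggplot2::geom_point(data = means, colour = "red", size = 2)
  }
  p
}

#' Plot group log-evidence differences against a baseline model
#'
#' Sums per-subject log evidences per model and plots the difference to a
#' baseline model with two-standard-error bars (per-subject standard errors
#' combined in quadrature).
#'
#' @param table A tidy evidence table from [evidence_table()].
#' @param baseline Baseline model name (default `"difference"`).
#' @return A ggplot object.
#' @export
plot_evidence_differences <- function(table, baseline = "difference") {
  stopifnot(baseline %in% table$model)
  tot <- dplyr::summarise(dplyr::group_by(as_tibble(table), .data$model),
                          total = sum(.data$log_evidence),
                          se = sqrt(sum(.data$std_error^2)), .groups = "drop")
  base <- tot[tot$model == baseline, ]
  tot$diff <- tot$total - base$total
  tot$diff_se <- sqrt(tot$se^2 + base$se^2)
  tot$diff_se[tot$model == baseline] <- 0
  ggplot2::ggplot(tot, ggplot2::aes(x = .data$model, y = .data$diff)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$diff - 2 * .data$diff_se,
                                        ymax = .data$diff + 2 * .data$diff_se),
                           width = 0.15) +
    ggplot2::labs(x = NULL,
                  y = sprintf("log evidence relative to %s model", baseline)) +
    ggplot2::theme_minimal()
}

#' Plot per-subject log-evidence differences
#'
#' One point per subject: Bayes-minus-baseline log evidence against
#' Max-minus-baseline log evidence, with two-standard-error extents along
#' each axis.
#'
#' @inheritParams plot_evidence_differences
#' @return A ggplot object.
#' @export
plot_subject_differences <- function(table, baseline = "difference") {
  need <- c(baseline, "max", "bayes")
  stopifnot(all(need %in% table$model))
  wide_le <- tidyr::pivot_wider(as_tibble(table)[c("subject", "model", "log_evidence")],
                                names_from = "model", values_from = "log_evidence")
  wide_se <- tidyr::pivot_wider(as_tibble(table)[c("subject", "model", "std_error")],
                                names_from = "model", values_from = "std_error")
  df <- tibble(
    subject = wide_le$subject,
    dx = wide_le$max - wide_le[[baseline]],
    dy = wide_le$bayes - wide_le[[baseline]],
    sx = sqrt(wide_se$max^2 + wide_se[[baseline]]^2),
    sy = sqrt(wide_se$bayes^2 + wide_se[[baseline]]^2)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dx, y = .data$dy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dy - 2 * .data$sy,
                                        ymax = .data$dy + 2 * .data$sy), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$dx - 2 * .data$sx,
                                         xmax = .data$dx + 2 * .data$sx), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("log evidence: max - %s", baseline),
                  y = sprintf("log evidence: bayes - %s", baseline)) +
    ggplot2::theme_minimal()
}

#' Plot a random-effects model-comparison result
#'
#' Expected model frequencies and exceedance probabilities side by side.
#'
#' @param object A [random_effects_bms()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("expected_freq", "exceedance"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
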