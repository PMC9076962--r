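# ggplot2 renderings of the result objects.

#' Plot a survival-vs-delay curve
#'
#' Line plot of predicted 30-day survival probability against delay, with
#' the pointwise confidence ribbon when the curve carries one.
#'
#' @param object A `survival_curve` from [predict_curve()] or
#'   [survival_delay_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$p))
  if (all(c("lower", "upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80", alpha = 0.6
    )
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Delay (s from call answer)",
                  y = "Probability of 30-day survival") +
    ggplot2::coord_cartesian(ylim = c(0, NA)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted spline logistic model
#'
#' Predicted survival curve over the observed delay range with knot
#' positions marked.
#'
#' @param object An `rcs_logit` fit.
#' @param conf_level Confidence-band level; `NULL` suppresses the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rcs_logit
#' @export
autoplot.rcs_logit <- function(object, conf_level = 0.95, ...) {
  curve <- predict_curve(object, conf_level = conf_level)
  autoplot(curve) +
    ggplot2::geom_vline(xintercept = object$knots, linetype = "dotted",
                        colour = "grey50")
}

#' Plot the exclusion cascade
#'
#' Horizontal bar chart of the per-reason exclusion counts at each cascade
#' stage, with the stage cohort sizes in the subtitle.
#'
#' @param object A `cascade_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cascade_report
#' @export
autoplot.cascade_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$reason), ]
  df$stage <- factor(df$stage, levels = c(
    "study_exclusion", "recognizability_exclusion", "dacpr_exclusion"
  ), labels = c("Study-level", "Recognizability (AHA)", "DA-CPR (AHA)"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n, y = stats::reorder(.data$reason, .data$n)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "Excluded calls", y = NULL,
      title = "Cohort-construction exclusions",
      subtitle = sprintf(
        "%d audited; %d included; %d recognizable; %d available for DA-CPR",
        object$n_input, object$n_included, object$n_recognizable,
        object$n_dacpr_available
      )
    ) +
    ggplot2::theme_minimal()
}
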