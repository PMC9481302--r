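#' Plot the thermal-time curve with stage boundaries
#'
#' Cumulative growing degree-days over the season for each environment, with
#' vertical marks where each 100-GDD stage closes.
#'
#' @param gdd Output of [compute_gdd()].
#' @param stages Output of [assign_stages()].
#' @return A ggplot.
#' @export
plot_gdd_stages <- function(gdd, stages) {
  ggplot2::ggplot(gdd, ggplot2::aes(x = .data$date, y = .data$gdd)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = dplyr::filter(stages, .data$complete),
                        ggplot2::aes(xintercept = .data$end_date),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$env_id), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "cumulative GDD (deg C days)")
}

#' @export
autoplot.gddrn_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    {if ("conf.low" %in% names(d))
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             width = 0.2)} +
    ggplot2::labs(x = NULL, y = "posterior mean (co)variance",
                  title = sprintf("%s variance components", object$spec$model)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.gddrn_cv <- function(object, ...) {
  ggplot2::ggplot(object$pa,
                  ggplot2::aes(x = .data$type, y = .data$pa, fill = .data$type)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high), width = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait)) +
    ggplot2::labs(x = "prediction type", y = "predictive ability",
                  title = sprintf("%s %s predictive ability",
                                  object$spec$model, toupper(object$scheme)))
}
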