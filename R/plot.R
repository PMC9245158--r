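#' Plot cumulative transition hazards
#'
#' Step plot of every transition's cumulative hazard, coloured by transition
#' and with the hazard kind (observed / population / excess) as linetype.
#'
#' @param object An `msm_hazards` object.
#' @param time_unit `"years"` or `"days"` for the x axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msm_hazards <- function(object, time_unit = c("years", "days"), ...) {
  time_unit <- match.arg(time_unit)
  df <- tidy(object) |>
    dplyr::mutate(
      transition = paste(.data$from, "->", .data$to),
      t = if (time_unit == "years") days_to_years(.data$time) else .data$time
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$haz,
                                   colour = .data$transition,
                                   linetype = .data$kind)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = paste0("time (", time_unit, ")"),
                  y = "cumulative hazard",
                  colour = "transition", linetype = "kind") +
    ggplot2::theme_minimal()
}

#' Plot transition probabilities from one starting state
#'
#' @param object An `msm_probtrans` object.
#' @param from Starting state label (default: first state).
#' @param time_unit `"years"` or `"days"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msm_probtrans <- function(object, from = NULL,
                                   time_unit = c("years", "days"), ...) {
  time_unit <- match.arg(time_unit)
  if (is.null(from)) from <- object$structure$states[1]
  df <- tidy(object) |>
    dplyr::filter(.data$from == !!from) |>
    dplyr::mutate(t = if (time_unit == "years") days_to_years(.data$time)
                  else .data$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$prob, colour = .data$to)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = paste0("time (", time_unit, ")"),
                  y = paste0("P(", from, " -> state)"), colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot simulation performance summaries
#'
#' Relative bias per estimand and evaluation time.
#'
#' @param object An `msm_performance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msm_performance <- function(object, ...) {
  df <- object$summary |>
    dplyr::mutate(estimand = paste0(.data$measure, ": ", .data$from,
                                    " -> ", .data$to))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$time_years), .data$rel_bias)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~estimand, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = "relative bias") +
    ggplot2::theme_minimal()
}
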