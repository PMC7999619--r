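# ggplot2 displays for the study's result objects

#' @export
autoplot.tradeoff_curve <- function(object, ...) {
  cv <- object$curve
  df <- tidyr::pivot_longer(
    cv, c("price_eur_per_mj", "ei_score"),
    names_to = "measure", values_to = "value"
  )
  df$measure <- factor(df$measure, c("price_eur_per_mj", "ei_score"),
                       c("price (EUR / MJ NE)", "environmental score"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w_t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_wt, linetype = "dashed") +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = expression(w[t]),
                  title = "Cost-environment trade-off sweep",
                  subtitle = paste("selected w_t =", format(object$selected_wt))) +
    ggplot2::theme_minimal()
}

#' Zero-profit sensitivity bars
#'
#' Bar chart of the tolerable fattening-diet price increase and pig price
#' drop per line and diet.
#'
#' @param sensitivity sensitivity tibble from [run_study()] (columns
#'   `line_id`, `diet`, `diet_price_increase_pct`, `pig_price_drop_pct`).
#' @return a ggplot object.
#' @export
plot_sensitivity <- function(sensitivity) {
  df <- tidyr::pivot_longer(
    sensitivity, c("diet_price_increase_pct", "pig_price_drop_pct"),
    names_to = "margin", values_to = "pct"
  )
  df$margin <- factor(df$margin,
                      c("diet_price_increase_pct", "pig_price_drop_pct"),
                      c("diet price increase", "pig price drop"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diet, y = .data$pct, fill = .data$line_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~margin) +
    ggplot2::labs(x = NULL, y = "% change to zero profit", fill = "line") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.study_result <- function(object, ...) {
  plot_sensitivity(object$sensitivity)
}
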