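#' Plot mean days-to-fission against the transfer percentage
#'
#' One line per Nutrition/Sociality ratio (censored runs capped at the day
#' limit), showing how stronger social-relations transfer shortens the road
#' to irreversible fission.
#'
#' @inheritParams summarize_batch
#' @param n Optional group size filter.
#' @return A ggplot object.
#' @export
plot_transfer_response <- function(batch, n = NULL) {
  if (!is.null(n)) batch <- batch[batch$n %in% n, , drop = FALSE]
  s <- summarize_batch(batch, censor_policy = "cap_at_max")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$transfer, y = .data$mean_days,
                                  colour = factor(.data$ratio))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "social relations transfer (%)",
                  y = "mean days to irreversible fission",
                  colour = "Nutrition/Sociality ratio") +
    ggplot2::theme_minimal()
}

#' Plot the fission-time profile across Nutrition/Sociality ratios
#'
#' Mean (solid) with minimum and maximum (dotted) days before irreversible
#' fission per ratio on a log axis, pooled over transfer percentages of 20%
#' and above; censored runs are capped at the day limit. The U over the
#' fissioning range and the cohesive plateau at low ratios are the model's
#' characteristic signature.
#'
#' @inheritParams plot_transfer_response
#' @param exclude_transfer Transfer levels excluded (default 10).
#' @return A ggplot object.
#' @export
plot_ratio_profile <- function(batch, n = NULL, exclude_transfer = 10) {
  if (!is.null(n)) batch <- batch[batch$n %in% n, , drop = FALSE]
  batch <- batch[!batch$transfer %in% exclude_transfer, , drop = FALSE]
  s <- batch |>
    dplyr::group_by(.data$n, .data$ratio) |>
    dplyr::summarise(mean_days = mean(.data$days),
                     min_days = min(.data$days),
                     max_days = max(.data$days), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_days)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$min_days), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$max_days), linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Nutrition/Sociality ratio (log scale)",
                  y = "days to irreversible fission") +
    ggplot2::theme_minimal()
}
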