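#' Plot binned target-choice rates against set mean
#'
#' Visual analogue of the headline context-effect figure: the proportion of
#' ratings-maximizing choices per set-mean bin, optionally split by set
#' size.
#'
#' @param choice_table A [build_choice_table()] tibble.
#' @param by_set_size Facet by coarse set-size groups.
#' @param breaks Bin boundaries passed to [bin_target_rates()].
#' @return A ggplot object.
#' @export
plot_target_rate <- function(choice_table, by_set_size = FALSE,
                             breaks = c(-Inf, 3, 3.5, 4, Inf)) {
  d <- if (by_set_size) {
    choice_table |>
      dplyr::mutate(
        size_group = cut(.data$n_options, c(0, 3, 5, Inf),
                         labels = c("3", "4-5", "6+"))
      ) |>
      dplyr::mutate(bin = cut(.data$mean_set, breaks)) |>
      dplyr::summarise(n = dplyr::n(), target_rate = mean(.data$is_target),
                       .by = c("bin", "size_group"))
  } else {
    bin_target_rates(choice_table, breaks)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$target_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean displayed rating of choice set",
                  y = "P(ratings-maximizing choice)") +
    ggplot2::theme_minimal()
  if (by_set_size) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$size_group))
  p
}

#' Plot the choice-rating concordance
#'
#' Scatter of per-participant rating context effects against choice context
#' effects with the robust regression line.
#'
#' @param choice_effects,rating_effects Tibbles from [subject_effects()].
#' @param conc Optional precomputed [concordance()] result (for the line).
#' @return A ggplot object.
#' @export
plot_concordance <- function(choice_effects, rating_effects, conc = NULL) {
  d <- dplyr::inner_join(
    choice_effects |> dplyr::rename(choice_effect = "effect"),
    rating_effects |> dplyr::rename(rating_effect = "effect"),
    by = ".group"
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$choice_effect,
                                       y = .data$rating_effect)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "choice context effect (per participant)",
                  y = "rating context effect (per participant)") +
    ggplot2::theme_minimal()
  if (!is.null(conc)) {
    p <- p + ggplot2::geom_abline(intercept = conc$intercept,
                                  slope = conc$slope, colour = "firebrick")
  }
  p
}
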