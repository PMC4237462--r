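#' Plot a synthetic weather season
#'
#' Weekly summaries of the daily series: mean daily maximum temperature,
#' mean daily minimum relative humidity, mean wind speed, and weekly
#' rainfall totals.
#'
#' @param weather A daily series from [generate_weather()].
#' @return A ggplot object (facetted).
#' @export
plot_weather <- function(weather) {
  weekly <- weather |>
    mutate(week = (dplyr::row_number() - 1) %/% 7 + 1) |>
    group_by(.data$week) |>
    summarise(
      `max temperature (C)` = mean(.data$t_max),
      `min relative humidity (%)` = mean(.data$rh_min),
      `wind speed (m/s)` = mean(.data$u2),
      `rainfall (mm/week)` = sum(.data$rain),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"week")
  ggplot2::ggplot(weekly, ggplot2::aes(.data$week, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "week of season", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot weekly water balance for both treatments
#'
#' Weekly ET0, water inputs and the cumulative deficit for the watered
#' and rain-fed treatments.
#'
#' @param watered,rainfed Weekly tibbles from [weekly_deficits()].
#' @return A ggplot object.
#' @export
plot_water_balance <- function(watered, rainfed) {
  both <- bind_rows(
    watered |> mutate(treatment = "watered"),
    rainfed |> mutate(treatment = "rainfed")
  )
  ggplot2::ggplot(both, ggplot2::aes(.data$week, .data$cum_deficit,
                                     colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_col(ggplot2::aes(y = .data$deficit, fill = .data$treatment),
                      position = "dodge", alpha = 0.4, colour = NA) +
    ggplot2::labs(x = "week of season", y = "water deficit (mm)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
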