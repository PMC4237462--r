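#' Pair midday and predawn water potentials
#'
#' Matches each midday water-potential record to a predawn measurement of
#' the same plant (species x block x treatment x month) under the field
#' pairing rules: predawn values measured more than 48 h from the midday
#' measurement are invalid, and predawn values with rainfall in between
#' are discarded unless a repeat (a later candidate without intervening
#' rain) is available. Exclusions are returned with reason codes rather
#' than silently dropped.
#'
#' @param midday Data frame with columns `species`, `block`, `treatment`,
#'   `month`, `psi_midday` (MPa, < 0).
#' @param predawn Data frame with columns `species`, `block`,
#'   `treatment`, `month`, `psi_predawn` (MPa, < 0), `hours_between`
#'   (h between midday and predawn collection) and `rain_between`
#'   (logical). Multiple candidate rows per plant-month are allowed
#'   (repeats).
#' @param max_hours Longest valid midday-to-predawn separation, h.
#' @return A list with `pairs` (a tibble of valid `WaterPotentialPair`
#'   rows) and `exclusions` (a tibble of dropped plant-months with a
#'   `reason` of `RAIN_BETWEEN` or `TOO_LATE`).
#' @export
pair_measurements <- function(midday, predawn, max_hours = 48) {
  keys <- c("species", "block", "treatment", "month")
  predawn <- as_tibble(predawn)
  midday <- as_tibble(midday)
  candidates <- midday |>
    inner_join(predawn, by = keys, relationship = "many-to-many") |>
    mutate(
      valid = !.data$rain_between & .data$hours_between <= max_hours
    )
  picked <- candidates |>
    group_by(across(all_of(keys))) |>
    arrange(.data$hours_between, .by_group = TRUE) |>
    summarise(
      any_rain = any(.data$rain_between),
      all_late = all(.data$hours_between > max_hours),
      psi_midday = first(.data$psi_midday),
      psi_predawn = first(.data$psi_predawn[.data$valid]),
      hours_between = first(.data$hours_between[.data$valid]),
      rain_between = FALSE,
      .groups = "drop"
    )
  pairs <- picked |>
    filter(!is.na(.data$psi_predawn)) |>
    select(all_of(keys), "psi_predawn", "psi_midday", "hours_between",
           "rain_between")
  exclusions <- picked |>
    filter(is.na(.data$psi_predawn)) |>
    mutate(reason = ifelse(.data$all_late, "TOO_LATE", "RAIN_BETWEEN")) |>
    select(all_of(keys), "reason")
  list(pairs = pairs, exclusions = exclusions)
}

#' Hydrodynamic gradient from a predawn/midday pair
#'
#' The soil-to-leaf hydrodynamic gradient `delta_psi = psi_midday -
#' psi_predawn` (MPa): negative under daytime transpiration, with more
#' negative values indicating greater hydraulic strain. Non-negative
#' gradients are retained but flagged as degenerate (no daytime strain or
#' apparent reverse gradient).
#'
#' The opposite sign convention (`psi_predawn - psi_midday`, a positive
#' "drawdown") is available via `convention = "predawn-midday"`.
#'
#' @param pairs Data frame with columns `psi_predawn` and `psi_midday`
#'   (MPa).
#' @param convention `"midday-predawn"` (default) or `"predawn-midday"`.
#' @return The input as a tibble with `delta_psi` (MPa) and
#'   `degenerate` (logical, gradient showing no daytime strain) appended.
#' @examples
#' delta_psi(tibble::tibble(psi_predawn = -0.5, psi_midday = -1.7))
#' @export
delta_psi <- function(pairs, convention = c("midday-predawn", "predawn-midday")) {
  convention <- match.arg(convention)
  pairs <- as_tibble(pairs)
  d <- pairs$psi_midday - pairs$psi_predawn
  if (convention == "predawn-midday") d <- -d
  strainless <- if (convention == "midday-predawn") d >= 0 else d <= 0
  pairs$delta_psi <- d
  pairs$degenerate <- strainless
  pairs
}

#' Whole-plant leaf-specific hydraulic conductance
#'
#' `K_plant = E / (-delta_psi)` (mmol m-2 s-1 MPa-1): modelled
#' transpiration normalized by the hydrodynamic gradient (in the
#' midday-minus-predawn convention, where transpiring plants have
#' `delta_psi < 0`). Records with a zero gradient (division by zero,
#' code `DIV0`) or a positive gradient (negative conductance, code
#' `REVERSE_GRADIENT`) are excluded: `k_plant` is `NA` and the reason
#' recorded.
#'
#' @param data Data frame with columns `E` (mmol m-2 s-1) and
#'   `delta_psi` (MPa).
#' @return The input as a tibble with `k_plant` (mmol m-2 s-1 MPa-1) and
#'   `k_plant_excluded` (reason code, `""` when valid) appended.
#' @examples
#' k_plant(tibble::tibble(E = 1.2, delta_psi = -1.2))
#' @export
k_plant <- function(data) {
  data <- as_tibble(data)
  data |>
    mutate(
      k_plant_excluded = case_when(
        .data$delta_psi == 0 ~ "DIV0",
        .data$delta_psi > 0 ~ "REVERSE_GRADIENT",
        TRUE ~ ""
      ),
      k_plant = ifelse(.data$k_plant_excluded == "",
                       .data$E / (-.data$delta_psi), NA_real_)
    )
}
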