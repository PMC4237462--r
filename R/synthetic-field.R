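MONTH_LEVELS <- c("Nov", "Dec", "Jan", "Feb", "Mar", "Apr")

month_factor <- function(x) factor(x, levels = MONTH_LEVELS, ordered = TRUE)

#' Species and design table for the common garden
#'
#' Twelve grass species from four lineages (three per lineage): two C3
#' groups (tribe Paniceae and subfamily Danthonioideae) and two C4 groups
#' (tribe Andropogoneae and genus Aristida). Leaf widths are stand-ins
#' for published values; per-species trait baselines (multiplicative
#' deviations around the lineage-type mean) and the per-treatment
#' survivor counts at the end of the season complete the design metadata.
#' Survivor counts are design metadata for the mortality roster only; no
#' inference is run on them.
#'
#' @return A tibble with one row per species: `species`, `clade`,
#'   `photosynthetic_type`, `leaf_width` (m), trait factors `f_A`,
#'   `f_gs`, `f_psi` (dimensionless, mean 1 within each type), and
#'   `surviving_watered`, `surviving_rainfed` (out of 8 plants each).
#' @export
species_table <- function() {
  tbl <- tibble::tribble(
    ~species, ~clade, ~photosynthetic_type, ~leaf_width, ~f_A, ~f_gs, ~f_psi, ~surviving_watered, ~surviving_rainfed,
    "Alloteropsis semialata eckloniana", "Paniceae", "C3", 0.004, 1.10, 1.08, 0.95, 7L, 8L,
    "Panicum aequinerve", "Paniceae", "C3", 0.005, 1.00, 1.02, 1.00, 8L, 8L,
    "Panicum ecklonii", "Paniceae", "C3", 0.006, 0.88, 0.92, 1.08, 2L, 4L,
    "Heteropogon contortus", "Andropogoneae", "C4", 0.004, 1.08, 1.05, 0.96, 8L, 7L,
    "Hyparrhenia hirta", "Andropogoneae", "C4", 0.003, 1.02, 1.00, 1.02, 8L, 8L,
    "Themeda triandra", "Andropogoneae", "C4", 0.005, 0.95, 0.97, 1.03, 7L, 8L,
    "Karoochloa curva", "Danthonioideae", "C3", 0.002, 0.92, 0.95, 1.05, 5L, 7L,
    "Merxmuellera disticha", "Danthonioideae", "C3", 0.002, 1.05, 1.04, 0.94, 8L, 8L,
    "Pentaschistis curvifolia", "Danthonioideae", "C3", 0.002, 1.05, 0.99, 0.98, 6L, 6L,
    "Aristida congesta barbicollis", "Aristidoideae", "C4", 0.002, 1.05, 1.06, 0.97, 7L, 7L,
    "Aristida diffusa burkei", "Aristidoideae", "C4", 0.002, 0.95, 0.95, 1.04, 8L, 8L,
    "Aristida junciformis", "Aristidoideae", "C4", 0.0015, 0.95, 0.97, 0.98, 8L, 8L
  )
  # lineage identity fixes photosynthetic type; normalise trait factors to
  # mean exactly 1 within type so noiseless cell means equal the type truth
  stopifnot(
    all(tbl$photosynthetic_type[tbl$clade %in% c("Paniceae", "Danthonioideae")] == "C3"),
    all(tbl$photosynthetic_type[tbl$clade %in% c("Andropogoneae", "Aristidoideae")] == "C4"),
    all(tbl$leaf_width >= 0.001 & tbl$leaf_width <= 0.02)
  )
  tbl |>
    group_by(.data$photosynthetic_type) |>
    mutate(across(c("f_A", "f_gs", "f_psi"), ~ .x / mean(.x))) |>
    ungroup()
}

#' Experimental design configuration
#'
#' The blocked common-garden layout: paired watered and rain-fed plots in
#' each block, every species planted once per plot, with species
#' positions matched between the paired plots.
#'
#' @param species Species table, as from [species_table()].
#' @param n_blocks Number of blocks (default 8).
#' @param treatments Treatment labels.
#' @param months Ordered campaign months (default Nov-Apr).
#' @return A list of class `grassflux_design` with the species table, the
#'   design constants and a full plant `roster` tibble (one row per
#'   species x block x treatment).
#' @export
design_config <- function(species = species_table(), n_blocks = 8,
                          treatments = c("watered", "rainfed"),
                          months = MONTH_LEVELS) {
  if (n_blocks < 1) abort("`n_blocks` must be >= 1.")
  roster <- tidyr::expand_grid(
    species = species$species,
    block = seq_len(n_blocks),
    treatment = treatments
  ) |>
    left_join(select(species, "species", "clade",
                     type = "photosynthetic_type"),
              by = "species") |>
    mutate(plant_id = paste(abbreviate(.data$species, 8), .data$block,
                            substr(.data$treatment, 1, 1), sep = "_"))
  structure(
    list(species = species, n_blocks = n_blocks, treatments = treatments,
         months = months, roster = roster),
    class = "grassflux_design"
  )
}

#' Monthly weather targets for the synthetic season
#'
#' Default monthly climate statistics for the November-April growing
#' season that the generator reproduces: the mean of daily maximum
#' temperatures, the mean of daily minimum relative humidities, the
#' monthly rainfall total (matched exactly by rescaling), a mean wind
#' speed and a clear-sky midday PPFD. The January temperature (28 C),
#' February rainfall (139 mm), February minimum humidity (74%) and the
#' low-50s November / high-40s March-April humidities anchor the summer
#' drought cycle of the site.
#'
#' @param start Season start date.
#' @param monthly Tibble of monthly targets; see Details for columns.
#' @return A list of class `grassflux_weather_config`.
#' @export
weather_config <- function(start = as.Date("2008-11-01"),
                           monthly = NULL) {
  if (is.null(monthly)) {
    monthly <- tibble::tribble(
      ~month, ~t_max_mean, ~rh_min_mean, ~rain_total, ~u2_mean, ~ppfd_midday,
      "Nov", 24, 53, 55, 2.2, 1900,
      "Dec", 26, 55, 45, 2.1, 2000,
      "Jan", 28, 50, 30, 2.0, 2000,
      "Feb", 27, 74, 139, 1.9, 1850,
      "Mar", 25, 47, 35, 1.9, 1650,
      "Apr", 23, 47, 45, 1.8, 1400
    )
  }
  if (nrow(monthly) < 1) abort("season must cover at least one month.")
  if (any(monthly$rain_total < 0)) abort("rainfall targets must be >= 0.")
  if (any(!is.finite(unlist(monthly[-1])))) abort("weather targets must be finite.")
  structure(list(start = start, monthly = monthly),
            class = "grassflux_weather_config")
}

#' Generate a seeded synthetic daily weather series
#'
#' Simulates one growing season of daily weather with the configured
#' monthly structure: daily maximum temperatures recentred so each
#' month's mean of maxima equals its target; minimum relative humidities
#' recentred the same way; rainfall as gamma-distributed wet-day amounts
#' with first-order wet/dry persistence, rescaled so each monthly total
#' matches its target exactly; lognormal wind; and PPFD (midday and daily
#' mean) reduced on wet days. Midday conditions for the leaf model are
#' the daily maximum temperature and minimum humidity.
#'
#' @param config A [weather_config()].
#' @param seed Integer seed; the series is deterministic given
#'   `config` + `seed`.
#' @return A tibble of daily records: `date`, `month` (ordered factor),
#'   `t_max`, `t_min` (degC), `rh_max`, `rh_min` (%), `u2` (m s-1),
#'   `rain` (mm), `ppfd_mean`, `ppfd_midday` (umol m-2 s-1). The seed is
#'   recorded in the `seed` attribute.
#' @examples
#' w <- generate_weather(seed = 42)
#' dplyr::summarise(dplyr::group_by(w, month), rain = sum(rain))
#' @export
generate_weather <- function(config = weather_config(), seed = 1) {
  monthly <- config$monthly
  n_months <- nrow(monthly)
  # calendar days of each configured month from the season start
  dates <- seq(config$start, by = "day",
               length.out = 366)
  mon_lab <- format(dates, "%b")
  keep <- mon_lab %in% monthly$month &
    cumsum(!duplicated(format(dates, "%Y-%m"))) <= n_months
  dates <- dates[keep]
  mon_lab <- mon_lab[keep]

  withr::with_seed(seed, {
    out <- purrr::map(seq_len(n_months), function(i) {
      tgt <- monthly[i, ]
      d <- dates[mon_lab == tgt$month]
      n <- length(d)
      t_max <- rnorm(n, tgt$t_max_mean, 2.5)
      t_max <- t_max - mean(t_max) + tgt$t_max_mean # exact monthly mean
      t_min <- t_max - pmax(2, rnorm(n, 9, 2))
      rh_min <- rnorm(n, tgt$rh_min_mean, 6)
      rh_min <- rh_min - mean(rh_min) + tgt$rh_min_mean
      rh_min <- pmin(pmax(rh_min, 5), 98)
      rh_max <- pmin(rh_min + pmax(10, rnorm(n, 28, 6)), 100)
      u2 <- rlnorm(n, log(tgt$u2_mean) - 0.08, 0.4)
      # first-order wet/dry chain, gamma amounts rescaled to the target
      wet <- logical(n)
      wet[1] <- runif(1) < 0.3
      for (j in 2:n) {
        p <- if (wet[j - 1]) 0.55 else 0.25
        wet[j] <- runif(1) < p
      }
      if (!any(wet) && tgt$rain_total > 0) wet[sample.int(n, 3)] <- TRUE
      rain <- ifelse(wet, rgamma(n, shape = 0.7, scale = 8), 0)
      if (tgt$rain_total == 0) {
        rain[] <- 0
      } else {
        rain <- rain * tgt$rain_total / sum(rain)
      }
      cloud <- ifelse(wet, runif(n, 0.25, 0.6), runif(n, 0.85, 1))
      ppfd_midday <- tgt$ppfd_midday * cloud
      ppfd_mean <- ppfd_midday * runif(n, 0.26, 0.32)
      tibble(
        date = d, month = tgt$month, t_max = t_max, t_min = t_min,
        rh_max = rh_max, rh_min = rh_min, u2 = u2, rain = rain,
        ppfd_mean = ppfd_mean, ppfd_midday = ppfd_midday
      )
    }) |>
      purrr::list_rbind()
  })
  out$month <- month_factor(out$month)
  attr(out, "seed") <- seed
  out
}

#' Ground-truth effect structure for the synthetic experiment
#'
#' Defines the data-generating truth used by [generate_observations()]:
#' type-independent baselines for each physiological variable, additive
#' C4-minus-C3 offsets (`type_offsets`), per-type sensitivities of each
#' variable to the cumulative water deficit (`drought_response`), a
#' clade-by-month random-effect scale, and per-variable residual noise.
#' Setting all offsets to zero and equalising the drought sensitivities
#' yields a null truth with identical C3 and C4 cell means.
#'
#' Variables: `A` (umol m-2 s-1), `gs` (mol m-2 s-1), `psi_predawn`
#' (MPa) and `delta_psi` (MPa); the midday potential is derived as
#' `psi_predawn + delta_psi`. Drought enters through the cumulative
#' deficit D (per 100 mm): multiplicative decay `exp(-sens * D)` for `A`,
#' `gs` and `delta_psi`, and a linear slope (MPa per 100 mm) for
#' `psi_predawn`.
#'
#' @param base Named numeric baselines at zero deficit.
#' @param type_offsets Named numeric C4-minus-C3 offsets, added to C4
#'   cell means after the drought response.
#' @param offset_table Optional tibble with columns `variable`, `month`,
#'   `treatment`, `offset`: additional C4-minus-C3 offsets applied only
#'   to the named cells (on top of `type_offsets`). The hook for
#'   injecting a known effect into specific months or treatments.
#' @param drought_response Tibble with columns `type`, `variable`,
#'   `sens`.
#' @param clade_sd Log-scale SD of lognormal clade-by-month factors for
#'   `A` and `gs`.
#' @param clade_sd_psi As `clade_sd`, for the water-potential magnitudes.
#' @param residual_cv Named per-variable lognormal residual coefficients
#'   of variation (`psi` covers both potentials).
#' @return A list of class `grassflux_truth`.
#' @export
effect_truth <- function(base = c(A = 9, gs = 0.105, psi_predawn = -0.40,
                                  delta_psi = -1.25),
                         type_offsets = c(A = 4, gs = 0.02,
                                          psi_predawn = 0.08,
                                          delta_psi = 0.15),
                         offset_table = NULL,
                         drought_response = NULL,
                         clade_sd = 0.05,
                         clade_sd_psi = 0.04,
                         residual_cv = c(A = 0.30, gs = 0.30, psi = 0.12)) {
  if (is.null(drought_response)) {
    drought_response <- tibble::tribble(
      ~type, ~variable, ~sens,
      "C3", "A", 0.22,
      "C4", "A", 0.10,
      "C3", "gs", 0.25,
      "C4", "gs", 0.08,
      "C3", "psi_predawn", 0.22,
      "C4", "psi_predawn", 0.13,
      "C3", "delta_psi", 0.06,
      "C4", "delta_psi", -0.05
    )
  }
  vars <- c("A", "gs", "psi_predawn", "delta_psi")
  if (!all(vars %in% names(base)) || !all(vars %in% names(type_offsets))) {
    abort("truth must define base and type_offsets for A, gs, psi_predawn and delta_psi.")
  }
  if (clade_sd < 0 || clade_sd_psi < 0 || any(residual_cv < 0)) {
    abort("all truth scales must be >= 0.")
  }
  if (any(!is.finite(c(base, type_offsets, drought_response$sens)))) {
    abort("truth effects must be finite.")
  }
  if (!is.null(offset_table) &&
      !all(c("variable", "month", "treatment", "offset") %in%
             names(offset_table))) {
    abort("`offset_table` needs columns variable, month, treatment, offset.")
  }
  structure(
    list(base = base, type_offsets = type_offsets,
         offset_table = offset_table,
         drought_response = drought_response, clade_sd = clade_sd,
         clade_sd_psi = clade_sd_psi, residual_cv = residual_cv),
    class = "grassflux_truth"
  )
}

#' A null ground truth with no photosynthetic-type differences
#'
#' Zero C4-minus-C3 offsets and type-equal drought sensitivities (C3/C4
#' averages of the defaults), so both types share identical cell means.
#' Used for false-positive-rate checks of the inference layer.
#'
#' @inheritParams effect_truth
#' @return A `grassflux_truth` list.
#' @export
effect_truth_null <- function(clade_sd = 0.06, clade_sd_psi = 0.04,
                              residual_cv = c(A = 0.30, gs = 0.30, psi = 0.12)) {
  dr <- effect_truth()$drought_response |>
    group_by(.data$variable) |>
    mutate(sens = mean(.data$sens)) |>
    ungroup()
  effect_truth(
    type_offsets = c(A = 0, gs = 0, psi_predawn = 0, delta_psi = 0),
    drought_response = dr, clade_sd = clade_sd, clade_sd_psi = clade_sd_psi,
    residual_cv = residual_cv
  )
}

# expected (noise-free) cell means per variable x type x treatment x month
truth_cell_means <- function(truth, deficits) {
  grid <- tidyr::expand_grid(
    type = c("C3", "C4"),
    deficits,
    variable = c("A", "gs", "psi_predawn", "delta_psi")
  ) |>
    left_join(truth$drought_response, by = c("type", "variable"))
  extra <- truth$offset_table
  if (is.null(extra)) {
    extra <- tibble(variable = character(), month = character(),
                    treatment = character(), offset = numeric())
  }
  grid |>
    left_join(extra, by = c("variable", "month", "treatment")) |>
    mutate(
      d100 = .data$cum_deficit / 100,
      base = unname(truth$base[.data$variable]),
      offset = ifelse(.data$type == "C4",
                      unname(truth$type_offsets[.data$variable]) +
                        dplyr::coalesce(.data$offset, 0),
                      0),
      truth_mean = case_when(
        .data$variable == "psi_predawn" ~
          .data$base - .data$sens * .data$d100 + .data$offset,
        TRUE ~ .data$base * exp(-.data$sens * .data$d100) + .data$offset
      )
    ) |>
    select("variable", "type", "treatment", "month", "truth_mean") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "truth_mean") |>
    mutate(psi_midday = .data$psi_predawn + .data$delta_psi) |>
    tidyr::pivot_longer(cols = c("A", "gs", "psi_predawn", "delta_psi",
                                 "psi_midday"),
                        names_to = "variable", values_to = "truth_mean")
}

#' Thin the plant roster by the observed mortality
#'
#' Removes dead plants from the design roster. Death counts default to
#' the per-species, per-treatment survivor counts in the species table
#' (8 plants per species per treatment); which individual plants die is
#' seeded random.
#'
#' @param design A [design_config()].
#' @param deaths Optional tibble with columns `species`, `treatment`,
#'   `deaths`; defaults to `8 - surviving` from the species table.
#' @param seed Integer seed.
#' @return The surviving-plant roster tibble.
#' @export
apply_mortality <- function(design, deaths = NULL, seed = 1) {
  if (is.null(deaths)) {
    deaths <- design$species |>
      select("species", "surviving_watered", "surviving_rainfed") |>
      tidyr::pivot_longer(cols = c("surviving_watered", "surviving_rainfed"),
                          names_to = "treatment", names_prefix = "surviving_",
                          values_to = "surviving") |>
      mutate(deaths = design$n_blocks - .data$surviving) |>
      select("species", "treatment", "deaths")
  }
  if (any(deaths$deaths < 0)) abort("death counts must be >= 0.")
  if (any(deaths$deaths > design$n_blocks)) {
    abort("death counts cannot exceed the number of plants per species per treatment.")
  }
  withr::with_seed(seed, {
    dead <- deaths |>
      filter(.data$deaths > 0) |>
      purrr::pmap(function(species, treatment, deaths) {
        tibble(species = species, treatment = treatment,
               block = sample.int(design$n_blocks, deaths))
      }) |>
      purrr::list_rbind()
  })
  if (is.null(dead) || nrow(dead) == 0) return(design$roster)
  anti_join(design$roster, dead, by = c("species", "treatment", "block"))
}

#' Generate synthetic gas-exchange and water-potential observations
#'
#' Simulates one monthly measurement campaign per surviving plant. The
#' cumulative water deficit of each treatment (from the water-balance
#' chain run on the supplied weather) drives type-specific declines in
#' stomatal conductance, assimilation and water potential; clade-by-month
#' lognormal random effects and mean-one lognormal residual noise are
#' layered on top. Strictly positive variables stay positive and water
#' potentials stay negative by construction. Chamber bookkeeping fields
#' (CO2/H2O differentials, flow, edge widths, stabilization time, rolled
#' flag) are generated with realistic failure rates so the QC stage has
#' work to do.
#'
#' @param design A [design_config()].
#' @param truth A [effect_truth()].
#' @param weather A daily weather series from [generate_weather()].
#' @param seed Integer seed.
#' @param mortality Apply the species-table mortality roster
#'   (default TRUE).
#' @return A list of class `grassflux_observations`:
#' \describe{
#'   \item{gas_exchange}{one chamber record per plant x month}
#'   \item{water_potential}{one predawn/midday record per plant x month}
#'   \item{climate}{monthly midday climate (campaign-window means)}
#'   \item{deficits}{cumulative deficit per treatment at each campaign}
#'   \item{truth}{the injected noise-free cell means, for recovery tests}
#'   \item{seed}{the seed used}
#' }
#' @export
generate_observations <- function(design, truth = effect_truth(),
                                  weather = generate_weather(), seed = 1,
                                  mortality = TRUE) {
  et <- daily_et0(weather)
  irr <- watering_policy(weather$rain)
  months_present <- intersect(MONTH_LEVELS, unique(as.character(weather$month)))

  # campaign window: final two weeks of each month
  campaign <- weather |>
    mutate(row = dplyr::row_number()) |>
    group_by(.data$month) |>
    filter(.data$date > max(.data$date) - 14) |>
    ungroup()
  climate <- campaign |>
    group_by(month = as.character(.data$month)) |>
    summarise(
      t_air = mean(.data$t_max), rh = mean(.data$rh_min),
      u = mean(.data$u2), ppfd = mean(.data$ppfd_midday), .groups = "drop"
    )

  # cumulative deficit per treatment at the campaign midpoint
  daily_bal <- tibble(
    date = weather$date, month = as.character(weather$month),
    et0 = et$et0, rain = weather$rain, irrigation = irr$irrigation
  )
  mid_dates <- campaign |>
    group_by(month = as.character(.data$month)) |>
    summarise(mid = stats::median(.data$date), .groups = "drop")
  deficits <- tidyr::expand_grid(
    treatment = design$treatments,
    mid_dates
  ) |>
    rowwise() |>
    mutate(cum_deficit = {
      upto <- daily_bal[daily_bal$date <= .data$mid, ]
      inp <- upto$rain + if (.data$treatment == "watered") upto$irrigation else 0
      max(0, sum(upto$et0 - inp))
    }) |>
    ungroup() |>
    select("treatment", "month", "cum_deficit")

  cells <- truth_cell_means(truth, deficits)
  roster <- if (mortality) apply_mortality(design, seed = seed) else design$roster

  withr::with_seed(seed + 1L, {
    clade_fx <- tidyr::expand_grid(
      clade = unique(design$species$clade),
      month = months_present
    ) |>
      mutate(
        f_clade = exp(rnorm(dplyr::n(), 0, truth$clade_sd)),
        f_clade_psi = exp(rnorm(dplyr::n(), 0, truth$clade_sd_psi))
      )

    obs <- tidyr::expand_grid(roster, month = months_present) |>
      left_join(design$species |> select("species", "leaf_width",
                                         "f_A", "f_gs", "f_psi"),
                by = "species") |>
      left_join(cells |> tidyr::pivot_wider(names_from = "variable",
                                            values_from = "truth_mean"),
                by = c("type", "treatment", "month")) |>
      left_join(clade_fx, by = c("clade", "month"))

    n <- nrow(obs)
    # mean-one lognormal noise keeps arithmetic cell means on target
    ln_noise <- function(cv) {
      if (cv == 0) return(rep(1, n))
      s <- sqrt(log(1 + cv^2))
      rlnorm(n, -s^2 / 2, s)
    }
    cv <- truth$residual_cv
    obs <- obs |>
      mutate(
        A_obs = pmax(0, .data$A * .data$f_A * .data$f_clade * ln_noise(cv[["A"]])),
        gs_obs = pmax(1e-4, .data$gs * .data$f_gs * .data$f_clade * ln_noise(cv[["gs"]])),
        psi_predawn_obs = -pmax(0.01, -.data$psi_predawn * .data$f_psi *
                                  .data$f_clade_psi * ln_noise(cv[["psi"]])),
        psi_midday_obs = .data$psi_predawn_obs -
          pmax(0.01, -.data$delta_psi * .data$f_psi * .data$f_clade_psi *
                 ln_noise(cv[["psi"]])),
        ci = ifelse(.data$type == "C4", 145, 250) * exp(rnorm(n, 0, 0.08))
      )

    gas_exchange <- obs |>
      transmute(
        .data$species, .data$clade, .data$type, .data$block,
        .data$treatment, month = .data$month,
        A = .data$A_obs, gs = .data$gs_obs, ci = .data$ci,
        delta_co2 = pmax(1, .data$A_obs * 4 + rnorm(n, 0, 4)),
        delta_h2o = pmax(0.05, .data$gs_obs * 40 + rnorm(n, 0, 1.2)),
        flow = ifelse(runif(n) < 0.03, runif(n, 60, 99), runif(n, 150, 400)),
        widths_edge1 = pmax(0.5, rnorm(n, 4.3, 0.6)),
        widths_edge2 = pmax(0.5, .data$widths_edge1 + rnorm(n, 0, 0.4)),
        stabilization_s = rlnorm(n, log(85), 0.45),
        leaf_rolled = runif(n) < ifelse(.data$treatment == "rainfed", 0.12, 0.06)
      )

    water_potential <- obs |>
      transmute(
        .data$species, .data$clade, .data$type, .data$block,
        .data$treatment, month = .data$month,
        psi_predawn = .data$psi_predawn_obs,
        psi_midday = .data$psi_midday_obs,
        hours_between = ifelse(runif(n) < 0.04, runif(n, 49, 72),
                               runif(n, 12, 44)),
        rain_between = runif(n) < 0.05
      )
  })

  gas_exchange$month <- month_factor(gas_exchange$month)
  water_potential$month <- month_factor(water_potential$month)
  cells$month <- month_factor(cells$month)
  deficits$month <- month_factor(deficits$month)

  structure(
    list(gas_exchange = gas_exchange, water_potential = water_potential,
         climate = climate, deficits = deficits, truth = cells,
         seed = seed),
    class = "grassflux_observations"
  )
}
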