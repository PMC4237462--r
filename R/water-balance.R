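#' Daily net radiation over a reference grass surface
#'
#' FAO-56 style net radiation: shortwave is recovered from logged PPFD via
#' [ppfd_to_shortwave()], the albedo of the reference surface is 0.23, and
#' net longwave uses the Stefan-Boltzmann law with a humidity correction
#' and a clear-sky fraction estimated against extraterrestrial radiation
#' for the site latitude and day of year.
#'
#' @param doy Day of year (1-366).
#' @param latitude Site latitude, decimal degrees (negative in the
#'   southern hemisphere).
#' @param altitude Site elevation, m.
#' @param ppfd_mean Daily mean PPFD, umol m-2 s-1.
#' @param t_max,t_min Daily maximum and minimum air temperature, degrees C.
#' @param e_a Actual vapour pressure, kPa.
#' @return Net radiation, MJ m-2 day-1.
#' @export
net_radiation <- function(doy, latitude, altitude, ppfd_mean, t_max, t_min, e_a) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  # extraterrestrial radiation, MJ m-2 day-1
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  rso <- (0.75 + 2e-5 * altitude) * ra
  rs <- ppfd_to_shortwave(ppfd_mean) * 0.0864 # W m-2 -> MJ m-2 day-1
  rns <- (1 - 0.23) * rs
  tk4 <- ((t_max + 273.16)^4 + (t_min + 273.16)^4) / 2
  cloud <- pmax(0.05, pmin(1, ifelse(rso > 0, rs / rso, 0)))
  rnl <- 4.903e-9 * tk4 * (0.34 - 0.14 * sqrt(pmax(e_a, 0))) *
    (1.35 * cloud - 0.35)
  rns - rnl
}

#' Reference evapotranspiration combination equation
#'
#' The core FAO-56 combination equation for a well-watered reference grass
#' surface, taking pre-computed drivers. Negative results (possible on
#' cold, wet, still days) are clamped to zero.
#'
#' @param t_mean Daily mean air temperature, degrees C.
#' @param vpd Vapour pressure deficit, kPa.
#' @param delta Slope of the saturation vapour-pressure curve, kPa degC-1.
#' @param gamma Psychrometric constant, kPa degC-1.
#' @param rn Net radiation, MJ m-2 day-1 (soil heat flux taken as 0 at the
#'   daily step).
#' @param u2 Wind speed at 2 m, m s-1.
#' @return Reference evapotranspiration, mm day-1 (>= 0).
#' @export
et0_combination <- function(t_mean, vpd, delta, gamma, rn, u2) {
  num <- 0.408 * delta * rn + gamma * (900 / (t_mean + 273)) * u2 * vpd
  pmax(0, num / (delta + gamma * (1 + 0.34 * u2)))
}

#' Daily reference crop evapotranspiration from weather summaries
#'
#' Computes FAO-56 reference evapotranspiration (ET0, mm day-1) for each
#' daily weather summary. Daily mean temperature and relative humidity are
#' taken as the mean of the daily maximum and minimum; shortwave radiation
#' is estimated from logged PPFD.
#'
#' @param daily A data frame of daily summaries with columns `date`,
#'   `t_max`, `t_min`, `rh_max`, `rh_min`, `u2`, `rain`, `ppfd_mean`.
#' @param altitude Site elevation, m.
#' @param latitude Site latitude, decimal degrees.
#' @return The input as a tibble with an added `et0` column (mm day-1) and
#'   an `et0_clamped` flag marking days where the raw combination equation
#'   went negative.
#' @examples
#' w <- generate_weather(seed = 1)
#' head(daily_et0(w))
#' @export
daily_et0 <- function(daily, altitude = 642, latitude = -33.3) {
  required <- c("date", "t_max", "t_min", "rh_max", "rh_min", "u2", "rain", "ppfd_mean")
  missing_cols <- setdiff(required, names(daily))
  if (length(missing_cols)) {
    abort(paste0("`daily` is missing driver column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(daily$t_max < daily$t_min)) abort("t_max must be >= t_min.")
  daily <- as_tibble(daily)
  t_mean <- (daily$t_max + daily$t_min) / 2
  rh_mean <- (daily$rh_max + daily$rh_min) / 2
  psy <- psychrometrics(t_mean, rh_mean, altitude)
  doy <- as.integer(format(as.Date(daily$date), "%j"))
  rn <- net_radiation(doy, latitude, altitude, daily$ppfd_mean,
                      daily$t_max, daily$t_min, psy$e_a)
  raw <- 0.408 * psy$delta * rn +
    psy$gamma * (900 / (t_mean + 273)) * daily$u2 * (psy$e_s - psy$e_a)
  raw <- raw / (psy$delta + psy$gamma * (1 + 0.34 * daily$u2))
  daily$et0 <- pmax(0, raw)
  daily$et0_clamped <- raw < 0
  daily
}

#' Irrigation schedule with rainfall-triggered halts
#'
#' Applies the experiment's watering policy to a daily rainfall series:
#' a fixed event depth (volume over plot area) is added on an alternating
#' 2-/3-day cycle, except that whenever rainfall over any 48-h window
#' exceeds a threshold, watering is halted for a fixed number of days.
#'
#' @param rain Daily rainfall series, mm (or a data frame with `date` and
#'   `rain` columns).
#' @param event_volume_l Water added per event per plot, litres.
#' @param plot_area_m2 Plot area, m2 (must be > 0).
#' @param cycle Days between events, recycled (default `c(2, 3)`, i.e.
#'   "every 2-3 days").
#' @param halt_mm 48-h rainfall threshold that triggers a halt, mm.
#' @param halt_days Length of the halt, days.
#' @return A tibble with columns `day`, `rain`, `irrigation` (mm day-1),
#'   `scheduled` and `halted`.
#' @examples
#' watering_policy(rep(0, 14))
#' @export
watering_policy <- function(rain, event_volume_l = 28, plot_area_m2 = 4,
                            cycle = c(2, 3), halt_mm = 10, halt_days = 14) {
  if (is.data.frame(rain)) rain <- rain$rain
  if (plot_area_m2 <= 0) abort("`plot_area_m2` must be > 0.")
  if (any(rain < 0)) abort("daily rainfall must be >= 0.")
  n <- length(rain)
  depth <- event_volume_l / plot_area_m2 # 28 L over 4 m2 -> 7 mm
  # scheduled event days: day 1, then alternating cycle increments
  steps <- rep_len(cycle, n)
  sched <- cumsum(c(1, steps))
  sched <- sched[sched <= n]
  scheduled <- seq_len(n) %in% sched
  # 48-h rainfall totals (day i-1 + day i); a halt covers the 14 days
  # following the trigger day
  two_day <- rain + c(0, rain[-n])
  halted <- rep(FALSE, n)
  for (i in which(two_day > halt_mm)) {
    idx <- seq(i + 1, min(n, i + halt_days))
    if (i < n) halted[idx] <- TRUE
  }
  tibble(
    day = seq_len(n),
    rain = rain,
    irrigation = ifelse(scheduled & !halted, depth, 0),
    scheduled = scheduled,
    halted = halted
  )
}

#' Weekly and cumulative water deficits
#'
#' Sums ET0, rainfall and irrigation over consecutive 7-day windows from
#' the start of the season and forms the weekly water deficit
#' `et0 - (rain + irrigation)` together with its running total.
#'
#' @param et0 Daily ET0 series, mm.
#' @param rain Daily rainfall series, mm.
#' @param irrigation Daily irrigation series, mm (default all zero).
#' @return A tibble with one row per week: `week`, `et0_sum`, `rain_sum`,
#'   `irrigation_sum`, `deficit` and `cum_deficit` (all mm).
#' @export
weekly_deficits <- function(et0, rain, irrigation = rep(0, length(et0))) {
  n <- length(et0)
  if (length(rain) != n || length(irrigation) != n) {
    abort("`et0`, `rain` and `irrigation` must be aligned daily series of equal length.")
  }
  week <- (seq_len(n) - 1) %/% 7 + 1
  out <- tibble(week = week, et0 = et0, rain = rain, irrigation = irrigation) |>
    group_by(week) |>
    summarise(
      et0_sum = sum(.data$et0),
      rain_sum = sum(.data$rain),
      irrigation_sum = sum(.data$irrigation),
      .groups = "drop"
    ) |>
    mutate(
      deficit = .data$et0_sum - (.data$rain_sum + .data$irrigation_sum),
      cum_deficit = cumsum(.data$deficit)
    )
  out
}

#' Paired Wilcoxon signed-rank comparison of weekly deficits
#'
#' Two-sided Wilcoxon signed-rank test on paired weekly water deficits
#' from the watered and rain-fed treatments. Zero differences are dropped
#' (Wilcoxon's original treatment); the exact distribution is used for up
#' to 25 non-zero pairs and the normal approximation with continuity
#' correction above that.
#'
#' @param watered,rainfed Weekly deficit series: numeric vectors or
#'   tibbles from [weekly_deficits()] (the `deficit` column is used).
#'   Must be the same length and paired by week.
#' @param exact_max Largest number of non-zero pairs for which the exact
#'   null distribution is used.
#' @return A one-row tibble with `statistic` (V), `p_value`, `n_pairs`
#'   (non-zero pairs used) and `method`.
#' @export
compare_weekly_deficits <- function(watered, rainfed, exact_max = 25) {
  if (is.data.frame(watered)) watered <- watered$deficit
  if (is.data.frame(rainfed)) rainfed <- rainfed$deficit
  if (length(watered) != length(rainfed)) {
    abort("`watered` and `rainfed` must be equal-length paired weekly series.")
  }
  d <- watered - rainfed
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    # identical series carry no evidence either way
    return(tibble(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                  method = "degenerate (all differences zero)"))
  }
  if (n < 2) abort("fewer than 2 non-zero paired differences.")
  exact <- n <= exact_max
  ht <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    n_pairs = n,
    method = if (exact) "exact" else "normal approximation"
  )
}
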