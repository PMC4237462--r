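#' Boundary-layer conductance to heat for a flat leaf
#'
#' Forced-convection flat-plate relation for one side of a leaf of
#' characteristic dimension `d` (leaf width for grasses):
#' `g_bH = 0.135 * sqrt(u / d)` mol m-2 s-1. A still-air floor on wind
#' speed keeps the conductance physical in calm conditions.
#'
#' @param u Wind speed, m s-1.
#' @param d Characteristic dimension (leaf width), m. Must be > 0.
#' @param u_min Still-air floor on wind speed, m s-1.
#' @return One-sided boundary-layer conductance to heat, mol m-2 s-1.
#' @examples
#' boundary_layer_conductance(1, 0.01) # 1.35
#' @export
boundary_layer_conductance <- function(u, d, u_min = 0.1) {
  if (any(d <= 0)) abort("characteristic dimension `d` must be > 0.")
  if (any(u < 0)) abort("wind speed must be >= 0.")
  0.135 * sqrt(pmax(u, u_min) / d)
}

# total conductance to water vapour: measured stomatal conductance
# (already summed over leaf surfaces) in series with the two-sided
# boundary layer; the vapour boundary-layer conductance per side is
# 1.08 x the heat value
total_vapour_conductance <- function(gs, g_bh_side) {
  g_bv <- 2 * 1.08 * g_bh_side
  ifelse(gs <= 0, 0, gs * g_bv / (gs + g_bv))
}

# absorbed radiation for a horizontal leaf over a lawn: shortwave from
# PPFD on the upper side, longwave from clear sky above and lawn below
absorbed_radiation <- function(ppfd, e_a, t_air, t_background, absorptance,
                               emissivity) {
  sw <- absorptance * ppfd_to_shortwave(ppfd)
  eps_sky <- sky_emissivity(e_a, t_air)
  lw_sky <- eps_sky * SIGMA_SB * (t_air + 273.15)^4
  lw_lawn <- 0.97 * SIGMA_SB * (t_background + 273.15)^4
  sw + emissivity * (lw_sky + lw_lawn)
}

#' Solve the leaf energy balance for temperature and transpiration
#'
#' Finds the leaf temperature at which absorbed radiation balances
#' emitted longwave, sensible heat and latent heat for a horizontal leaf
#' suspended over a lawn, and returns the transpiration rate at that
#' temperature. The closure residual
#' `R_abs - L_out - H - LE` is driven to zero by a Newton iteration on
#' leaf temperature with an analytic derivative and a step clamp, which
#' converges across the full environmental envelope (including calm air,
#' wide leaves and high conductance, where a naively damped fixed point
#' can cycle).
#'
#' Fluxes (all W m-2, per unit projected leaf area):
#' \itemize{
#'   \item `R_abs`: absorbed short- plus longwave, sky above, lawn below;
#'   \item `L_out = 2 eps sigma T_leaf^4`, both sides;
#'   \item `H = c_p * g_bH * (T_leaf - T_air)` with the two-sided
#'     boundary-layer conductance to heat;
#'   \item `LE = lambda * E`, `E = g_tv (e_s(T_leaf) - e_a) / P_atm`, with
#'     the total vapour conductance (stomata in series with the two-sided
#'     boundary layer).
#' }
#'
#' @param t_air Air temperature, degrees C.
#' @param rh Relative humidity, percent.
#' @param u Wind speed, m s-1.
#' @param ppfd PPFD incident on the leaf, umol m-2 s-1.
#' @param gs Stomatal conductance to water vapour, mol m-2 s-1 (total
#'   across surfaces, as reported by a gas-exchange system).
#' @param d Leaf characteristic dimension (width), m.
#' @param P_atm Atmospheric pressure, kPa.
#' @param t_background Temperature of the lawn below, degrees C
#'   (defaults to air temperature).
#' @param absorptance Fraction of global shortwave absorbed (default 0.5).
#' @param emissivity Leaf longwave emissivity.
#' @param u_min Still-air wind floor, m s-1.
#' @param tol Convergence tolerance on the closure residual, W m-2.
#' @param max_iter Maximum Newton iterations.
#' @param t_init Starting leaf temperature for the iteration, degrees C
#'   (defaults to air temperature; the converged state is insensitive to
#'   this choice).
#' @return A one-row tibble (`LeafFluxResult`): `t_leaf` (degC), `E`
#'   (mmol m-2 s-1), `g_bH` (two-sided, mol m-2 s-1), `g_tv`
#'   (mol m-2 s-1), `R_abs`, `H`, `LE`, `L_out` (W m-2), `closure`
#'   (W m-2), `iterations`, `converged`, and `dew_flagged` (TRUE when a
#'   negative transpiration rate was clamped to zero).
#' @examples
#' solve_leaf_energy_balance(t_air = 25, rh = 50, u = 1, ppfd = 1500,
#'                           gs = 0.2, d = 0.005)
#' @export
solve_leaf_energy_balance <- function(t_air, rh, u, ppfd, gs, d,
                                      P_atm = 101.325,
                                      t_background = t_air,
                                      absorptance = 0.5,
                                      emissivity = 0.97,
                                      u_min = 0.1,
                                      tol = 0.01,
                                      max_iter = 100,
                                      t_init = t_air) {
  if (rh < 0 || rh > 100) abort("`rh` must lie in [0, 100].")
  if (u < 0) abort("`u` must be >= 0.")
  if (ppfd < 0) abort("`ppfd` must be >= 0.")
  if (gs < 0) abort("`gs` must be >= 0.")
  if (d <= 0) abort("`d` must be > 0.")

  e_a <- svp(t_air) * rh / 100
  g_bh_side <- boundary_layer_conductance(u, d, u_min)
  g_bh <- 2 * g_bh_side
  g_tv <- total_vapour_conductance(gs, g_bh_side)
  r_abs <- absorbed_radiation(ppfd, e_a, t_air, t_background,
                              absorptance, emissivity)

  lambda_mol <- function(t) latent_heat(t) * 18.015 * 1000 # J mol-1

  residual <- function(tl) {
    l_out <- 2 * emissivity * SIGMA_SB * (tl + 273.15)^4
    h <- CP_MOLAR * g_bh * (tl - t_air)
    e_mol <- g_tv * (svp(tl) - e_a) / P_atm
    le <- lambda_mol(tl) * e_mol
    r_abs - l_out - h - le
  }
  dresidual <- function(tl) {
    -(8 * emissivity * SIGMA_SB * (tl + 273.15)^3 +
        CP_MOLAR * g_bh +
        lambda_mol(tl) * g_tv * svp_slope(tl) / P_atm)
  }

  tl <- t_init
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- residual(tl)
    if (abs(f) < tol) {
      converged <- TRUE
      break
    }
    step <- -f / dresidual(tl)
    step <- max(min(step, 5), -5)
    tl <- tl + step
  }
  if (!converged && abs(residual(tl)) < tol) converged <- TRUE
  if (!converged) {
    warn(sprintf(
      "leaf energy balance did not converge within %d iterations (residual %.3g W m-2)",
      max_iter, residual(tl)))
  }

  l_out <- 2 * emissivity * SIGMA_SB * (tl + 273.15)^4
  h <- CP_MOLAR * g_bh * (tl - t_air)
  e_mol <- g_tv * (svp(tl) - e_a) / P_atm
  dew <- e_mol < 0
  e_mol <- max(0, e_mol)
  le <- lambda_mol(tl) * e_mol

  tibble(
    t_leaf = tl,
    E = e_mol * 1000,
    g_bH = g_bh,
    g_tv = g_tv,
    R_abs = r_abs,
    H = h,
    LE = le,
    L_out = l_out,
    closure = r_abs - l_out - h - le,
    iterations = iter,
    converged = converged,
    dew_flagged = dew
  )
}

#' Linearized (non-iterative) Penman-Monteith leaf transpiration
#'
#' Closed-form transpiration from a linearization of the energy balance
#' about air temperature, using isothermal net radiation and a radiative
#' conductance. Serves as an independent cross-check on the iterative
#' solver in the small leaf-to-air temperature difference regime.
#'
#' @inheritParams solve_leaf_energy_balance
#' @return A one-row tibble with `t_leaf` (degC) and `E` (mmol m-2 s-1).
#' @export
pm_transpiration_linearized <- function(t_air, rh, u, ppfd, gs, d,
                                        P_atm = 101.325,
                                        t_background = t_air,
                                        absorptance = 0.5,
                                        emissivity = 0.97,
                                        u_min = 0.1) {
  e_a <- svp(t_air) * rh / 100
  vpd <- svp(t_air) - e_a
  g_bh_side <- boundary_layer_conductance(u, d, u_min)
  g_bh <- 2 * g_bh_side
  g_tv <- total_vapour_conductance(gs, g_bh_side)
  r_abs <- absorbed_radiation(ppfd, e_a, t_air, t_background,
                              absorptance, emissivity)
  # isothermal net radiation and radiative "conductance"
  r_ni <- r_abs - 2 * emissivity * SIGMA_SB * (t_air + 273.15)^4
  g_r <- 8 * emissivity * SIGMA_SB * (t_air + 273.15)^3 / CP_MOLAR
  lam <- latent_heat(t_air) * 18.015 * 1000
  s <- svp_slope(t_air)
  dt <- (r_ni - lam * g_tv * vpd / P_atm) /
    (CP_MOLAR * (g_bh + g_r) + lam * g_tv * s / P_atm)
  e_mol <- max(0, g_tv * (vpd + s * dt) / P_atm)
  tibble(t_leaf = t_air + dt, E = e_mol * 1000)
}

#' Estimate monthly transpiration for every species-by-treatment cell
#'
#' Runs one leaf energy-balance solve per cell of a stomatal-conductance
#' table against the matching monthly midday climate, using each species'
#' leaf width as the boundary-layer characteristic dimension.
#'
#' @param gs_table Data frame with columns `species`, `month`,
#'   `treatment`, `gs` (mol m-2 s-1); one row per cell. Extra columns are
#'   carried through.
#' @param climate Data frame of monthly midday climate with columns
#'   `month`, `t_air`, `rh`, `u`, `ppfd`.
#' @param leaf_widths Data frame with columns `species`, `leaf_width` (m).
#' @param ... Further arguments passed to [solve_leaf_energy_balance()].
#' @return `gs_table` as a tibble with columns `E` (mmol m-2 s-1),
#'   `t_leaf` and `converged` appended.
#' @export
estimate_monthly_E <- function(gs_table, climate, leaf_widths, ...) {
  gs_table <- as_tibble(gs_table)
  missing_sp <- setdiff(unique(gs_table$species), leaf_widths$species)
  if (length(missing_sp)) {
    abort(paste0("missing leaf width for species: ",
                 paste(missing_sp, collapse = ", ")))
  }
  joined <- gs_table |>
    left_join(select(as_tibble(climate), "month", "t_air", "rh", "u", "ppfd"),
              by = "month") |>
    left_join(select(as_tibble(leaf_widths), "species", "leaf_width"),
              by = "species")
  if (anyNA(joined$t_air)) {
    abort("every `gs_table` month needs a matching `climate` row.")
  }
  sol <- purrr::pmap(
    list(joined$t_air, joined$rh, joined$u, joined$ppfd, joined$gs,
         joined$leaf_width),
    function(t_air, rh, u, ppfd, gs, d) {
      solve_leaf_energy_balance(t_air, rh, u, ppfd, gs, d, ...)[
        , c("E", "t_leaf", "converged")]
    }
  ) |>
    purrr::list_rbind()
  bind_cols(gs_table, sol)
}
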