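# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments to the ranks of |d| (zeros must be removed by the caller).
# Mirrors the classical two-sided rule: double the smaller tail of the
# exact null distribution of V, capped at 1.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Step-by-step FAO-56 reference evapotranspiration, recoded independently
# of the package (spreadsheet style, one named quantity per line).
oracle_et0 <- function(date, t_max, t_min, rh_max, rh_min, u2, ppfd_mean,
                       altitude, latitude) {
  t_mean <- (t_max + t_min) / 2
  rh_mean <- (rh_max + rh_min) / 2
  es_tmean <- 0.6108 * exp(17.27 * t_mean / (t_mean + 237.3))
  ea <- es_tmean * rh_mean / 100
  slope <- 4098 * es_tmean / (t_mean + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
  gamma <- 0.000665 * pressure
  doy <- as.integer(strftime(as.Date(date), "%j"))
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  delta_sol <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(-tan(phi) * tan(delta_sol))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta_sol) + cos(phi) * cos(delta_sol) * sin(ws))
  rso <- (0.75 + 2e-5 * altitude) * ra
  rs_wm2 <- ppfd_mean / 2.1
  rs <- rs_wm2 * 0.0864
  rns <- 0.77 * rs
  sb <- 4.903e-9
  tk4 <- ((t_max + 273.16)^4 + (t_min + 273.16)^4) / 2
  fcd <- max(0.05, min(1, rs / rso))
  rnl <- sb * tk4 * (0.34 - 0.14 * sqrt(ea)) * (1.35 * fcd - 0.35)
  rn <- rns - rnl
  numerator <- 0.408 * slope * rn +
    gamma * 900 / (t_mean + 273) * u2 * (es_tmean - ea)
  denominator <- slope + gamma * (1 + 0.34 * u2)
  max(0, numerator / denominator)
}

# default environmental envelope for energy-balance property tests
random_leaf_environments <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      t_air = runif(n, 5, 40),
      rh = runif(n, 10, 95),
      u = runif(n, 0, 10),
      ppfd = runif(n, 0, 2000),
      gs = runif(n, 0.01, 0.5),
      d = runif(n, 0.001, 0.02)
    )
  })
}

# small uniform species table: no species-level trait deviations, so
# noiseless cell means equal the type-level truth exactly
uniform_species_table <- function() {
  sp <- species_table()
  sp$f_A <- 1
  sp$f_gs <- 1
  sp$f_psi <- 1
  sp
}

# truth with every stochastic layer switched off
noiseless_truth <- function(...) {
  effect_truth(clade_sd = 0, clade_sd_psi = 0,
               residual_cv = c(A = 0, gs = 0, psi = 0), ...)
}
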