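test_that("weather generation is deterministic and hits its monthly targets", {
  w1 <- generate_weather(seed = 4)
  w2 <- generate_weather(seed = 4)
  expect_identical(w1, w2)
  expect_false(identical(w1, generate_weather(seed = 5)))

  monthly <- w1 |>
    dplyr::group_by(month) |>
    dplyr::summarise(tmax = mean(t_max), rhmin = mean(rh_min),
                     rain = sum(rain))
  # February rainfall is rescaled to its 139 mm target exactly
  expect_equal(monthly$rain[monthly$month == "Feb"], 139)
  # January mean of daily maxima within 0.5 C of 28 C
  expect_equal(monthly$tmax[monthly$month == "Jan"], 28, tolerance = 0.5 / 28)
  # early-November minimum humidity near its 53% target
  nov15 <- w1 |> dplyr::filter(month == "Nov", date <= as.Date("2008-11-15"))
  expect_equal(mean(nov15$rh_min), 53, tolerance = 0.05)
})

test_that("weather respects physical sign and ordering constraints", {
  for (seed in 1:5) {
    w <- generate_weather(seed = seed)
    expect_true(all(w$t_max >= w$t_min))
    expect_true(all(w$rh_min >= 0 & w$rh_max <= 100 & w$rh_min <= w$rh_max))
    expect_true(all(w$rain >= 0 & w$u2 >= 0 & w$ppfd_mean >= 0))
    expect_equal(nrow(w), 181) # Nov 2008 - Apr 2009
  }
})

test_that("degenerate weather configurations are rejected", {
  expect_error(weather_config(monthly = weather_config()$monthly[0, ]),
               "at least one month")
  bad <- weather_config()$monthly
  bad$rain_total[2] <- -5
  expect_error(weather_config(monthly = bad), ">= 0")
})

test_that("the design pairs species across treatments within blocks", {
  d <- design_config()
  expect_equal(nrow(d$roster), 12 * 8 * 2)
  by_plot <- d$roster |> dplyr::count(block, treatment)
  expect_true(all(by_plot$n == 12)) # every species once per plot
  # positions matched: same species set in both plots of each block
  sets <- d$roster |>
    dplyr::group_by(block, treatment) |>
    dplyr::summarise(s = paste(sort(species), collapse = "|"), .groups = "drop")
  expect_equal(length(unique(sets$s)), 1)
  # lineage identity fixes the photosynthetic type
  sp <- species_table()
  expect_setequal(sp$photosynthetic_type[sp$clade %in% c("Paniceae", "Danthonioideae")], "C3")
  expect_setequal(sp$photosynthetic_type[sp$clade %in% c("Andropogoneae", "Aristidoideae")], "C4")
})

test_that("mortality produces rosters of the requested size", {
  d <- design_config()
  none <- tibble::tibble(species = d$species$species[1], treatment = "watered",
                         deaths = 0L)
  expect_equal(nrow(apply_mortality(d, none, seed = 1)), nrow(d$roster))
  # table-driven default: 2 watered + 4 rain-fed survivors for P. ecklonii
  roster <- apply_mortality(d, seed = 1)
  pe <- roster |> dplyr::filter(species == "Panicum ecklonii")
  expect_equal(nrow(pe), 6)
  expect_equal(sum(pe$treatment == "watered"), 2)
  expect_equal(sum(pe$treatment == "rainfed"), 4)
  # total death toll matches the per-species bookkeeping
  expect_equal(nrow(roster), 192 - 23)
  # all plants of a species dying removes it from the roster entirely
  wipe <- tidyr::expand_grid(species = "Panicum ecklonii",
                             treatment = c("watered", "rainfed")) |>
    dplyr::mutate(deaths = 8L)
  gone <- apply_mortality(d, wipe, seed = 1)
  expect_false("Panicum ecklonii" %in% gone$species)
  expect_error(apply_mortality(d, dplyr::mutate(wipe, deaths = -1L)), ">= 0")
  expect_error(apply_mortality(d, dplyr::mutate(wipe, deaths = 9L)), "exceed")
})

test_that("observations are deterministic and respect sign constraints", {
  d <- design_config()
  w <- generate_weather(seed = 2)
  o1 <- generate_observations(d, effect_truth(), w, seed = 3)
  o2 <- generate_observations(d, effect_truth(), w, seed = 3)
  expect_identical(o1$gas_exchange, o2$gas_exchange)
  expect_identical(o1$water_potential, o2$water_potential)

  ge <- o1$gas_exchange
  expect_true(all(ge$A >= 0 & ge$gs > 0 & ge$flow > 0))
  wp <- o1$water_potential
  expect_true(all(wp$psi_predawn < 0 & wp$psi_midday < 0))
  expect_true(all(wp$psi_midday < wp$psi_predawn))
  # one record per surviving plant per month
  expect_equal(nrow(ge), (192 - 23) * 6)
})

test_that("a null truth with no noise gives identical C3 and C4 cell means", {
  d <- design_config(species = uniform_species_table())
  w <- generate_weather(seed = 2)
  truth <- effect_truth_null(clade_sd = 0, clade_sd_psi = 0,
                             residual_cv = c(A = 0, gs = 0, psi = 0))
  obs <- generate_observations(d, truth, w, seed = 3, mortality = FALSE)
  cell <- obs$gas_exchange |>
    dplyr::group_by(type, treatment, month) |>
    dplyr::summarise(A = mean(A), gs = mean(gs), .groups = "drop") |>
    tidyr::pivot_wider(names_from = type, values_from = c(A, gs))
  expect_equal(cell$A_C3, cell$A_C4)
  expect_equal(cell$gs_C3, cell$gs_C4)
})

test_that("noiseless observations reproduce the injected truth exactly", {
  d <- design_config(species = uniform_species_table())
  w <- generate_weather(seed = 2)
  obs <- generate_observations(d, noiseless_truth(), w, seed = 3,
                               mortality = FALSE)
  got <- obs$gas_exchange |>
    dplyr::group_by(type, treatment, month) |>
    dplyr::summarise(A = mean(A), .groups = "drop")
  want <- obs$truth |>
    dplyr::filter(variable == "A") |>
    dplyr::select(type, treatment, month, truth_mean)
  j <- dplyr::inner_join(got, want, by = c("type", "treatment", "month"))
  expect_equal(j$A, j$truth_mean)
})

test_that("default truth lands inside the printed C4 assimilation envelope", {
  d <- design_config()
  obs <- generate_observations(d, effect_truth(), generate_weather(seed = 1),
                               seed = 1)
  c4 <- obs$gas_exchange |>
    dplyr::filter(type == "C4") |>
    dplyr::group_by(treatment, month) |>
    dplyr::summarise(A = mean(A), .groups = "drop")
  expect_true(all(c4$A >= 5.1 & c4$A <= 14.7))
  # and the hydrodynamic gradient envelope by type
  dp <- obs$water_potential |>
    dplyr::group_by(type, treatment, month) |>
    dplyr::summarise(dpsi = mean(psi_midday - psi_predawn), .groups = "drop")
  expect_true(all(dp$dpsi >= -1.59 & dp$dpsi <= -0.73))
})

test_that("an injected cell-specific offset shifts exactly that truth cell", {
  inject <- tibble::tibble(variable = "A", month = "Jan",
                           treatment = "rainfed", offset = 4)
  t_base <- effect_truth()
  t_inj <- effect_truth(offset_table = inject)
  w <- generate_weather(seed = 2)
  d <- design_config()
  tr_b <- generate_observations(d, t_base, w, seed = 1)$truth
  tr_i <- generate_observations(d, t_inj, w, seed = 1)$truth
  j <- dplyr::inner_join(tr_b, tr_i,
                         by = c("type", "treatment", "month", "variable"),
                         suffix = c("_b", "_i"))
  shifted <- j$truth_mean_i - j$truth_mean_b
  hit <- j$variable == "A" & j$month == "Jan" & j$treatment == "rainfed" &
    j$type == "C4"
  expect_equal(shifted[hit], 4)
  expect_true(all(shifted[!hit] == 0))
})
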