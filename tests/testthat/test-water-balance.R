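test_that("combination equation limits behave analytically", {
  st <- psychrometrics(20, 50)
  # no radiation, no wind, no demand: both numerator terms vanish
  expect_equal(et0_combination(20, 0, st$delta, st$gamma, rn = 0, u2 = 0), 0)
  # aerodynamic term is linear in VPD at zero radiation
  one <- et0_combination(20, 1, st$delta, st$gamma, rn = 0, u2 = 2)
  two <- et0_combination(20, 2, st$delta, st$gamma, rn = 0, u2 = 2)
  expect_equal(two, 2 * one)
  expect_gt(one, 0)
})

test_that("daily ET0 equals an independently coded step-by-step evaluation", {
  day <- tibble::tibble(
    date = as.Date("2009-01-15"), t_max = 28, t_min = 12,
    rh_max = 85, rh_min = 45, u2 = 2, rain = 0, ppfd_mean = 560
  )
  got <- daily_et0(day, altitude = 642, latitude = -33.3)$et0
  want <- oracle_et0("2009-01-15", 28, 12, 85, 45, 2, 560,
                     altitude = 642, latitude = -33.3)
  expect_equal(got, want, tolerance = 1e-7)

  # a second, dissimilar day (cool, humid, windy autumn day)
  day2 <- tibble::tibble(
    date = as.Date("2009-04-02"), t_max = 19, t_min = 8,
    rh_max = 98, rh_min = 70, u2 = 4.5, rain = 6, ppfd_mean = 240
  )
  expect_equal(daily_et0(day2, altitude = 642, latitude = -33.3)$et0,
               oracle_et0("2009-04-02", 19, 8, 98, 70, 4.5, 240, 642, -33.3),
               tolerance = 1e-7)
})

test_that("ET0 is non-negative and monotone in demand and radiation", {
  grid <- expand.grid(rh_min = seq(20, 65, length.out = 10),
                      ppfd = seq(100, 1000, length.out = 10))
  et0 <- vapply(seq_len(nrow(grid)), function(i) {
    daily_et0(tibble::tibble(
      date = as.Date("2009-01-15"), t_max = 27, t_min = 13,
      rh_max = grid$rh_min[i] + 30, rh_min = grid$rh_min[i],
      u2 = 2, rain = 0, ppfd_mean = grid$ppfd[i]
    ), altitude = 642, latitude = -33.3)$et0
  }, numeric(1))
  m <- matrix(et0, nrow = 10) # rows: drier -> wetter air; cols: more light
  expect_true(all(et0 >= 0))
  expect_true(all(diff(m) <= 1e-12))        # more humid => lower ET0
  expect_true(all(t(diff(t(m))) >= -1e-12)) # more radiation => higher ET0
})

test_that("missing driver columns are reported", {
  expect_error(daily_et0(tibble::tibble(date = Sys.Date(), t_max = 20)),
               "missing driver")
})

test_that("watering events deliver the 7 mm plot-area depth on schedule", {
  pol <- watering_policy(rep(0, 30))
  expect_equal(unique(pol$irrigation[pol$irrigation > 0]), 7) # 28 L / 4 m2
  # alternating 2-3 day cycle from day 1
  expect_equal(head(pol$day[pol$scheduled], 5), c(1, 3, 6, 8, 11))
  expect_error(watering_policy(rep(0, 5), plot_area_m2 = 0), "> 0")
  expect_error(watering_policy(c(-1, 0)), ">= 0")
})

test_that("heavy 48-h rainfall halts watering for 14 days, light rain does not", {
  rain <- rep(0, 40)
  rain[5] <- 7
  rain[6] <- 5 # 12 mm over 48 h > 10 mm threshold
  pol <- watering_policy(rain)
  expect_true(all(pol$irrigation[7:20] == 0))
  expect_true(any(pol$irrigation[21:40] > 0))

  light <- rep(0, 40)
  light[5] <- 5
  light[6] <- 4 # 9 mm in 48 h: below threshold
  expect_equal(watering_policy(light)$irrigation,
               watering_policy(rep(0, 40))$irrigation)
})

test_that("weekly deficits do the arithmetic and telescope", {
  et0 <- rep(5, 14)
  rain <- c(rep(10 / 7, 7), rep(0, 7))
  irr <- c(rep(3, 7), rep(0, 7))
  wk <- weekly_deficits(et0, rain, irr)
  expect_equal(wk$deficit[1], 35 - 10 - 21)
  expect_equal(wk$deficit, wk$et0_sum - wk$rain_sum - wk$irrigation_sum)
  # conservation: weekly deficits sum to the season totals exactly
  expect_equal(sum(wk$deficit), sum(et0) - sum(rain) - sum(irr))
  # all-zero input
  z <- weekly_deficits(rep(0, 21), rep(0, 21), rep(0, 21))
  expect_true(all(z$deficit == 0))
  # irrigation matching et0 - rain telescopes the cumulative deficit to 0
  bal <- weekly_deficits(rep(4, 21), rep(1, 21), rep(3, 21))
  expect_equal(bal$cum_deficit, rep(0, 3))
  expect_error(weekly_deficits(1:7, 1:6), "aligned")
})

test_that("paired Wilcoxon matches exact enumeration for small n", {
  # every rain-fed deficit strictly larger: one-signed differences
  watered <- 1:10
  rainfed <- watered + runif(10, 0.5, 1.5)
  res <- compare_weekly_deficits(watered, rainfed)
  expect_equal(res$p_value, 2 / 2^10)
  expect_equal(res$p_value, exact_signed_rank_p(watered - rainfed))

  # symmetric 5/5 split is far from significance
  d <- c(1, -1.1, 2, -2.1, 3, -3.1, 4, -4.1, 5, -5.1)
  res2 <- compare_weekly_deficits(d, rep(0, 10))
  expect_gt(res2$p_value, 0.5)
  expect_equal(res2$p_value, exact_signed_rank_p(d))

  # agreement across random paired series for all n <= 12
  withr::with_seed(99, {
    for (n in 2:12) {
      diffs <- rnorm(n)
      expect_equal(compare_weekly_deficits(diffs, rep(0, n))$p_value,
                   exact_signed_rank_p(diffs),
                   info = paste("n =", n))
    }
  })
})

test_that("degenerate and undersized Wilcoxon inputs are handled", {
  expect_equal(compare_weekly_deficits(1:5, 1:5)$p_value, 1)
  expect_error(compare_weekly_deficits(c(1, 2, 3), c(1, 2, 3.5)),
               "fewer than 2")
  expect_error(compare_weekly_deficits(1:3, 1:4), "equal-length")
})
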