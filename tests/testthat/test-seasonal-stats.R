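toy_means <- function() {
  tidyr::expand_grid(
    clade = c("Paniceae", "Danthonioideae", "Andropogoneae", "Aristidoideae"),
    idx = 1:2,
    treatment = c("watered", "rainfed"),
    month = c("Jan", "Feb")
  ) |>
    dplyr::mutate(
      species = paste0(clade, idx),
      type = ifelse(clade %in% c("Paniceae", "Danthonioideae"), "C3", "C4"),
      variable = "A",
      mean = ifelse(type == "C4", 12, 8),
      n = 5L
    )
}

test_that("species-month means aggregate with replicate counts", {
  rec <- tibble::tibble(
    species = "sp", clade = "Paniceae", type = "C3", treatment = "watered",
    month = "Jan", A = c(2, 4, 6)
  )
  m <- species_month_means(rec, "A")
  expect_equal(m$mean, 4)
  expect_equal(m$n, 3L)
  one <- species_month_means(rec[1, ], "A")
  expect_equal(one$mean, 2)
  expect_equal(one$n, 1L)
  expect_error(species_month_means(rec[0, ], "A"), "no records")
  expect_error(species_month_means(rec, "gs"), "no column")
})

test_that("balancing drops low-replicate and unpaired means in order", {
  means <- toy_means()
  expect_equal(nrow(means), 32)
  # untouched when already balanced
  bal <- balance_dataset(means)
  expect_equal(nrow(bal$balanced), 32)
  expect_equal(nrow(bal$dropped), 0)

  # n = 2 is eliminated by the replicate rule...
  means$n[1] <- 2L
  bal <- balance_dataset(means)
  expect_true("REPLICATES" %in% bal$dropped$rule)
  # ...and its cross-treatment partner then falls to the pairing rule
  expect_true("UNPAIRED" %in% bal$dropped$rule)
  expect_equal(nrow(bal$balanced), 30)
  # every retained mean is paired across treatments
  pairs <- bal$balanced |> dplyr::count(species, month, variable)
  expect_true(all(pairs$n == 2))
})

test_that("an engineered fixture loses exactly the predicted four means", {
  # 12 means: 3 fail the replicate rule (one species loses both sides at
  # once), which strands exactly 1 partner for the pairing rule. The
  # retained count is necessarily even, since every survivor is paired.
  means <- toy_means() |>
    dplyr::filter(month == "Jan", clade %in% c("Paniceae", "Andropogoneae"))
  expect_equal(nrow(means), 8)
  extra <- toy_means() |>
    dplyr::filter(month == "Feb", species %in% c("Paniceae1", "Andropogoneae1"))
  means <- dplyr::bind_rows(means, extra) # 12 means
  means$n[means$species == "Paniceae1" & means$month == "Jan"] <- 2L      # both treatments
  means$n[means$species == "Andropogoneae1" & means$month == "Feb" &
            means$treatment == "watered"] <- 1L                          # one side
  bal <- balance_dataset(means)
  expect_equal(sum(bal$dropped$rule == "REPLICATES"), 3)
  expect_equal(sum(bal$dropped$rule == "UNPAIRED"), 1)
  expect_equal(nrow(bal$balanced), 8)
  expect_equal(nrow(bal$balanced) %% 2, 0)
})

test_that("the transform policy matches the modelling conventions", {
  expect_equal(transform_policy("A"), "log")
  expect_equal(transform_policy("A_over_E"), "identity")
  expect_equal(transform_policy("psi_midday"), "neglog")
  expect_equal(transform_policy("delta_psi"), "neglog")
})

test_that("a zero-variance dataset is fit exactly (saturated-mean limit)", {
  means <- toy_means()
  fit <- suppressWarnings(fit_seasonal_model(means, "A"))
  td <- tidy(fit)
  expect_equal(td$estimate[td$type == "C4"], rep(12, 4))
  expect_equal(td$estimate[td$type == "C3"], rep(8, 4))
  g <- glance(fit)
  expect_lt(g$sigma, 1e-6)
})

test_that("with no clade variance the mixed model matches a cell-means lm", {
  withr::with_seed(8, {
    means <- toy_means() |>
      dplyr::mutate(mean = mean * exp(rnorm(dplyr::n(), 0, 0.2)))
  })
  fit <- suppressWarnings(fit_seasonal_model(means, "A"))
  lm_fit <- stats::lm(log(mean) ~ 0 + interaction(type, treatment, month),
                      data = means)
  expect_equal(sort(unname(exp(stats::coef(lm_fit)))),
               sort(tidy(fit)$estimate), tolerance = 1e-6)
})

test_that("clade structure requirements and bad transforms error clearly", {
  single_clade <- toy_means() |> dplyr::filter(clade %in% c("Paniceae", "Andropogoneae"))
  expect_error(fit_seasonal_model(single_clade, "A"), ">= 2 clades")
  neg <- toy_means() |> dplyr::mutate(mean = -mean)
  expect_error(suppressWarnings(fit_seasonal_model(neg, "A")), "non-finite")
})

test_that("injected clade variance is recovered in order of magnitude", {
  d <- design_config(species = uniform_species_table())
  w <- generate_weather(seed = 6)
  est <- vapply(1:12, function(s) {
    obs <- generate_observations(
      d, effect_truth(clade_sd = 0.15, residual_cv = c(A = 0.1, gs = 0.1, psi = 0.05)),
      w, seed = s, mortality = FALSE)
    means <- species_month_means(obs$gas_exchange, "A")
    fit <- suppressWarnings(fit_seasonal_model(means, "A"))
    glance(fit)$re_sd
  }, numeric(1))
  # log-scale clade-month SD of 0.15 recovered within 50% on average
  expect_gt(median(est), 0.075)
  expect_lt(median(est), 0.225)
})

test_that("bootstrap intervals are seeded, ordered and sign-consistent", {
  withr::with_seed(21, {
    means <- toy_means() |>
      dplyr::mutate(mean = mean * exp(rnorm(dplyr::n(), 0, 0.15)))
  })
  fit <- suppressWarnings(fit_seasonal_model(means, "A"))
  b1 <- suppressWarnings(bootstrap_cis(fit, n_sim = 100, seed = 5))
  b2 <- suppressWarnings(bootstrap_cis(fit, n_sim = 100, seed = 5))
  expect_identical(b1$estimates, b2$estimates)
  expect_identical(b1$contrasts, b2$contrasts)
  est <- b1$estimates
  expect_true(all(est$ci_low <= est$ci_high))
  # back-transformed predictions from a logged model are strictly positive
  expect_true(all(est$ci_low > 0))
  # significance flag means exactly "interval excludes zero"
  ct <- b1$contrasts
  expect_equal(ct$significant, ct$ci_low > 0 | ct$ci_high < 0)
  # the large injected type effect is detected in every cell
  expect_true(all(ct$significant[ct$contrast == "type-within-treatment"]))
})

test_that("a degenerate zero-variance model has zero-width intervals", {
  means <- toy_means()
  fit <- suppressWarnings(fit_seasonal_model(means, "A"))
  b <- suppressWarnings(bootstrap_cis(fit, n_sim = 50, seed = 2))
  expect_lt(max(b$estimates$ci_high - b$estimates$ci_low), 1e-4)
})

test_that("detection power rises from null to large injected effects", {
  d <- design_config()
  w <- generate_weather(seed = 6)
  flag_for <- function(truth, seed) {
    obs <- generate_observations(d, truth, w, seed = seed)
    kept <- dplyr::filter(qc_filter(obs$gas_exchange), keep)
    bal <- balance_dataset(species_month_means(kept, "A"))
    fit <- suppressWarnings(fit_seasonal_model(bal$balanced, "A"))
    b <- suppressWarnings(bootstrap_cis(fit, n_sim = 100, seed = seed))
    ct <- b$contrasts
    ct$significant[ct$contrast == "type-within-treatment" &
                     ct$month == "Jan" & ct$group == "rainfed"]
  }
  null_flags <- vapply(1:4, function(s) flag_for(effect_truth_null(), s),
                       logical(1))
  big <- effect_truth(type_offsets = c(A = 8, gs = 0.02, psi_predawn = 0.08,
                                       delta_psi = 0.15))
  big_flags <- vapply(1:4, function(s) flag_for(big, s), logical(1))
  expect_lte(sum(null_flags), 1)
  expect_equal(sum(big_flags), 4)
})
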