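#' Species-by-month mean values
#'
#' Aggregates validated records to the species mean for each month x
#' treatment combination — the unit of analysis for the seasonal models —
#' with the replicate count retained for the balancing rules.
#'
#' @param records Data frame of QC-passed records with columns `species`,
#'   `clade`, `type`, `treatment`, `month` and the response variable.
#' @param variable Name of the response column.
#' @return A tibble with one row per species x treatment x month:
#'   identifiers, `variable`, `mean` (natural scale) and `n`.
#' @export
species_month_means <- function(records, variable) {
  if (nrow(records) == 0) abort("no records to aggregate.")
  if (!variable %in% names(records)) {
    abort(paste0("records have no column `", variable, "`."))
  }
  records |>
    filter(!is.na(.data[[variable]])) |>
    group_by(.data$species, .data$clade, .data$type, .data$treatment,
             .data$month) |>
    summarise(
      variable = .env$variable,
      mean = mean(.data[[variable]]),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Enforce the dataset balancing rules
#'
#' Applies the two pre-modelling rules in order: species-month means
#' based on two or fewer replicates are eliminated (`REPLICATES`), and
#' then any species mean left unpaired across the two treatments in a
#' given month is removed (`UNPAIRED`). Every retained mean therefore has
#' a counterpart in the other treatment.
#'
#' @param means A tibble from [species_month_means()].
#' @param min_replicates Replicate threshold; means with `n <=` this are
#'   dropped (default 2).
#' @return A list with `balanced` (the retained means) and `dropped`
#'   (the eliminated rows with a `rule` code).
#' @export
balance_dataset <- function(means, min_replicates = 2) {
  means <- as_tibble(means)
  low_n <- means$n <= min_replicates
  kept <- means[!low_n, ]
  pair_counts <- kept |>
    count(.data$species, .data$month, .data$variable, name = "n_treatments")
  kept2 <- kept |>
    left_join(pair_counts, by = c("species", "month", "variable"))
  unpaired <- kept2$n_treatments < 2
  dropped <- bind_rows(
    means[low_n, ] |> mutate(rule = "REPLICATES"),
    kept[unpaired, ] |> mutate(rule = "UNPAIRED")
  )
  list(
    balanced = kept[!unpaired, ],
    dropped = dropped
  )
}

#' Transform policy for the seasonal models
#'
#' All responses are log-transformed to stabilise the variance except
#' instantaneous water-use efficiency (`A_over_E`), which is modelled on
#' the natural scale. Water potentials and the hydrodynamic gradient are
#' negative-valued: they are negated before the log and re-negated after
#' back-transformation (`neglog`).
#'
#' @param variable Response variable name.
#' @return `"log"`, `"neglog"` or `"identity"`.
#' @export
transform_policy <- function(variable) {
  if (variable %in% c("A_over_E")) return("identity")
  if (variable %in% c("psi_predawn", "psi_midday", "delta_psi")) return("neglog")
  "log"
}

apply_transform <- function(x, transform) {
  switch(transform,
    log = log(x),
    neglog = log(-x),
    identity = x,
    abort(paste0("unknown transform `", transform, "`."))
  )
}

back_transform <- function(x, transform) {
  switch(transform,
    log = exp(x),
    neglog = -exp(x),
    identity = x
  )
}

#' Fit the seasonal cell-means mixed model
#'
#' Maximum-likelihood linear mixed model for one physiological variable
#' on species-month means: one fixed-effect cell mean per photosynthetic
#' type x treatment x month, with clade modelled as a random effect
#' dependent on the month of sampling (independent clade intercepts per
#' month by default; a by-clade month-slope structure is available).
#' Singular fits are reported with a warning, never masked.
#'
#' @param balanced Balanced means from [balance_dataset()] (`$balanced`).
#' @param variable Response variable name (used for the transform
#'   policy and labelling).
#' @param transform Response transform; defaults to
#'   [transform_policy()]`(variable)`.
#' @param random Random-effect structure: `"clade_by_month"` (independent
#'   clade x month intercepts, default) or `"month_within_clade"`
#'   (correlated month effects within clade).
#' @return An object of class `grassflux_seasonal_fit`: the `lme4` fit
#'   plus the transform and cell bookkeeping.
#' @export
fit_seasonal_model <- function(balanced, variable,
                               transform = transform_policy(variable),
                               random = c("clade_by_month",
                                          "month_within_clade")) {
  random <- match.arg(random)
  dat <- as_tibble(balanced)
  clades_per_type <- dat |>
    distinct(.data$type, .data$clade) |>
    count(.data$type)
  if (any(clades_per_type$n < 2)) {
    abort("each photosynthetic type needs >= 2 clades represented.")
  }
  dat <- dat |>
    mutate(
      y = apply_transform(.data$mean, transform),
      cell = interaction(.data$type, .data$treatment, .data$month,
                         drop = TRUE, sep = "|"),
      clade_month = interaction(.data$clade, .data$month, drop = TRUE)
    )
  if (any(!is.finite(dat$y))) {
    abort("transform produced non-finite responses; check signs of the data.")
  }
  form <- if (random == "clade_by_month") {
    y ~ 0 + cell + (1 | clade_month)
  } else {
    y ~ 0 + cell + (1 | clade/month)
  }
  fit <- lme4::lmer(form, data = dat, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  if (lme4::isSingular(fit)) {
    warn(paste0("singular random-effect fit for `", variable,
                "` (variance component estimated at zero)."))
  }
  cell_map <- dat |>
    distinct(.data$cell, .data$type, .data$treatment, .data$month) |>
    arrange(.data$cell)
  n_species <- dat |>
    count(.data$type, .data$treatment, .data$month, name = "n_species")
  structure(
    list(fit = fit, variable = variable, transform = transform,
         random = random, data = dat, cell_map = cell_map,
         n_species = n_species),
    class = "grassflux_seasonal_fit"
  )
}

# back-transformed cell predictions for one vector of fixed effects
cell_predictions <- function(fixef_vec, cell_map, transform) {
  nm <- sub("^cell", "", names(fixef_vec))
  tibble(cell = nm, .pred = back_transform(unname(fixef_vec), transform)) |>
    inner_join(cell_map |> mutate(cell = as.character(.data$cell)),
               by = "cell")
}

#' @export
print.grassflux_seasonal_fit <- function(x, ...) {
  cat("Seasonal cell-means mixed model for `", x$variable, "`\n", sep = "")
  cat("  transform:", x$transform, " random:", x$random, "\n")
  cat("  ", nrow(x$data), "species-month means,",
      nrow(x$cell_map), "cells\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the seasonal fit into back-transformed cell means
#'
#' @param x A `grassflux_seasonal_fit`.
#' @param ... Unused.
#' @return A tibble with one row per type x treatment x month cell:
#'   `estimate` on the natural scale and the number of contributing
#'   species means.
#' @export
tidy.grassflux_seasonal_fit <- function(x, ...) {
  cell_predictions(lme4::fixef(x$fit), x$cell_map, x$transform) |>
    left_join(x$n_species, by = c("type", "treatment", "month")) |>
    transmute(
      variable = x$variable, .data$type, .data$treatment, .data$month,
      estimate = .data$.pred, n_species = .data$n_species
    )
}

#' One-line model summary of a seasonal fit
#'
#' @param x A `grassflux_seasonal_fit`.
#' @param ... Unused.
#' @return A one-row tibble: log-likelihood, AIC, residual SD, the
#'   clade-by-month random-effect SD, singularity flag and sizes.
#' @export
glance.grassflux_seasonal_fit <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(
    variable = x$variable,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit),
    sigma = stats::sigma(x$fit),
    re_sd = vc$sdcor[1],
    singular = lme4::isSingular(x$fit),
    n_means = nrow(x$data),
    n_cells = nrow(x$cell_map)
  )
}

#' Parametric bootstrap confidence intervals and contrasts
#'
#' Simulates responses from the fitted model, refits, and collects the
#' back-transformed fixed-effect cell predictions: percentile 95%
#' intervals for each type x treatment x month cell mean, and the same
#' for the two families of contrasts (C4 - C3 within treatment, watered -
#' rain-fed within type). A contrast is flagged significant when its
#' interval excludes zero.
#'
#' @param object A `grassflux_seasonal_fit`.
#' @param n_sim Number of bootstrap simulations (default 1000).
#' @param seed Integer seed.
#' @param level Interval coverage (default 0.95).
#' @param max_fail Largest tolerated refit failure fraction before
#'   aborting with diagnostics.
#' @return An object of class `grassflux_boot`: a list with `estimates`
#'   (cell means with `ci_low`/`ci_high`), `contrasts` (with
#'   `significant` flags), and the bootstrap metadata (`n_sim`, `seed`,
#'   `n_failed`).
#' @export
bootstrap_cis <- function(object, n_sim = 1000, seed = 1, level = 0.95,
                          max_fail = 0.1) {
  stopifnot(inherits(object, "grassflux_seasonal_fit"))
  fit <- object$fit
  cell_map <- object$cell_map
  sims <- withr::with_seed(seed, stats::simulate(fit, nsim = n_sim))
  draws <- matrix(NA_real_, nrow = n_sim, ncol = length(lme4::fixef(fit)))
  colnames(draws) <- names(lme4::fixef(fit))
  n_failed <- 0L
  for (i in seq_len(n_sim)) {
    fe <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::fixef(lme4::refit(fit, newresp = sims[[i]]))
      )),
      error = function(e) NULL
    )
    if (is.null(fe)) n_failed <- n_failed + 1L else draws[i, names(fe)] <- fe
  }
  if (n_failed > max_fail * n_sim) {
    abort(sprintf(
      "bootstrap refit failure rate %.1f%% exceeds %.0f%% (variable `%s`, n_sim %d).",
      100 * n_failed / n_sim, 100 * max_fail, object$variable, n_sim))
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  bt <- back_transform(draws, object$transform)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  point <- cell_predictions(lme4::fixef(fit), cell_map, object$transform)
  key <- cell_map |> mutate(cell = as.character(.data$cell))
  col_key <- match(key$cell, sub("^cell", "", colnames(draws)))

  estimates <- key |>
    mutate(
      predicted = point$.pred[match(.data$cell, point$cell)],
      ci_low = apply(bt[, col_key, drop = FALSE], 2, quantile,
                     probs = probs[1])[seq_along(col_key)],
      ci_high = apply(bt[, col_key, drop = FALSE], 2, quantile,
                      probs = probs[2])[seq_along(col_key)]
    ) |>
    left_join(object$n_species, by = c("type", "treatment", "month")) |>
    select("type", "treatment", "month", "predicted", "ci_low", "ci_high",
           "n_species") |>
    mutate(variable = object$variable, .before = 1)

  contrast_tbl <- function(kind) {
    if (kind == "type-within-treatment") {
      pairs <- key |>
        select("treatment", "month") |>
        distinct()
      purrr::pmap(pairs, function(treatment, month) {
        c1 <- key$cell[key$type == "C4" & key$treatment == treatment &
                         key$month == month]
        c0 <- key$cell[key$type == "C3" & key$treatment == treatment &
                         key$month == month]
        if (!length(c1) || !length(c0)) return(NULL)
        delta <- bt[, match(c1, sub("^cell", "", colnames(bt)))] -
          bt[, match(c0, sub("^cell", "", colnames(bt)))]
        est <- point$.pred[match(c1, point$cell)] -
          point$.pred[match(c0, point$cell)]
        ci <- quantile(delta, probs)
        tibble(contrast = "type-within-treatment",
               group = treatment, month = month,
               estimate = est, ci_low = ci[1], ci_high = ci[2])
      }) |> purrr::list_rbind()
    } else {
      pairs <- key |>
        select("type", "month") |>
        distinct()
      purrr::pmap(pairs, function(type, month) {
        c1 <- key$cell[key$type == type & key$treatment == "watered" &
                         key$month == month]
        c0 <- key$cell[key$type == type & key$treatment == "rainfed" &
                         key$month == month]
        if (!length(c1) || !length(c0)) return(NULL)
        delta <- bt[, match(c1, sub("^cell", "", colnames(bt)))] -
          bt[, match(c0, sub("^cell", "", colnames(bt)))]
        est <- point$.pred[match(c1, point$cell)] -
          point$.pred[match(c0, point$cell)]
        ci <- quantile(delta, probs)
        tibble(contrast = "treatment-within-type",
               group = type, month = month,
               estimate = est, ci_low = ci[1], ci_high = ci[2])
      }) |> purrr::list_rbind()
    }
  }
  contrasts <- bind_rows(contrast_tbl("type-within-treatment"),
                         contrast_tbl("treatment-within-type")) |>
    mutate(
      variable = object$variable, .before = 1
    ) |>
    mutate(significant = .data$ci_low > 0 | .data$ci_high < 0)

  structure(
    list(estimates = estimates, contrasts = contrasts,
         n_sim = n_sim, n_failed = n_failed, seed = seed, level = level,
         variable = object$variable, transform = object$transform),
    class = "grassflux_boot"
  )
}

#' @export
print.grassflux_boot <- function(x, ...) {
  cat("Parametric bootstrap for `", x$variable, "` (", x$n_sim,
      " simulations, seed ", x$seed, ")\n", sep = "")
  print(x$estimates, n = 6)
  invisible(x)
}

#' Tidy bootstrap cell-mean estimates
#'
#' @param x A `grassflux_boot`.
#' @param ... Unused.
#' @return The `estimates` tibble.
#' @export
tidy.grassflux_boot <- function(x, ...) x$estimates

#' Plot bootstrap cell means with confidence intervals
#'
#' Pooled cell means and percentile intervals by month, photosynthetic
#' type and treatment, in the style of a seasonal-course figure.
#'
#' @param object A `grassflux_boot`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grassflux_boot <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$month, y = .data$predicted,
                                    colour = .data$type,
                                    group = .data$type)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.3)) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(y = object$variable, x = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
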