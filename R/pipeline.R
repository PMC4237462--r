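#' Default pipeline configuration
#'
#' Assembles the configuration for an end-to-end synthetic run: the
#' design, ground truth, weather targets, site constants, QC thresholds
#' and the inference settings. Any element can be overridden; the
#' configuration can also be loaded from a YAML/JSON file via
#' [read_pipeline_config()].
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param variables Responses to model in the inference stage.
#' @param n_sim Bootstrap simulations per model.
#' @param altitude,latitude Site constants for ET0.
#' @param outdir Optional output directory; when set, every stage writes
#'   its CSV there.
#' @return A list of class `grassflux_config`.
#' @export
pipeline_config <- function(seed = 1,
                            variables = c("A", "gs"),
                            n_sim = 200,
                            altitude = 642, latitude = -33.3,
                            outdir = NULL) {
  structure(
    list(seed = seed, variables = variables, n_sim = n_sim,
         altitude = altitude, latitude = latitude, outdir = outdir),
    class = "grassflux_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file whose keys match
#'   the arguments of [pipeline_config()].
#' @return A `grassflux_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

# write a stage CSV with a provenance header comment
write_stage_csv <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grassflux stage output; seed=%s; config=%s",
                     seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stage CSV written by the pipeline
#'
#' @param path CSV path (provenance header comments are skipped).
#' @return A tibble.
#' @export
read_stage_csv <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order — weather simulation, ET0 and
#' water deficits with the paired treatment comparison, observation
#' generation, gas-exchange QC, leaf energy-balance transpiration,
#' hydraulics, and the seasonal mixed-model + bootstrap inference — and
#' returns all stage outputs together with a run manifest (seeds, record
#' counts in/out per stage, and output checksums when files are
#' written).
#'
#' @param config A [pipeline_config()] (or path to a YAML/JSON config).
#' @param design A [design_config()].
#' @param truth A [effect_truth()].
#' @return A list of class `grassflux_run` with elements `weather`,
#'   `water_balance` (daily ET0, weekly deficits per treatment, Wilcoxon
#'   comparison), `observations`, `qc`, `species_means`, `E`,
#'   `hydraulics`, `wue`, `fits`, `boots` and `manifest`.
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(seed = 1, variables = "A", n_sim = 50))
#' run$boots$A$contrasts
#' }
#' @export
run_pipeline <- function(config = pipeline_config(),
                         design = design_config(),
                         truth = effect_truth()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed
  cfg_hash <- rlang::hash(list(config[setdiff(names(config), "outdir")],
                               design$species, truth))
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[grassflux] %-14s in=%d out=%d", stage, n_in, n_out))
  }

  # 1. weather
  weather <- generate_weather(seed = seed)
  log_stage("simulate", 0L, nrow(weather))

  # 2. water balance
  et <- daily_et0(weather, altitude = config$altitude,
                  latitude = config$latitude)
  irr <- watering_policy(weather$rain)
  weeks_watered <- weekly_deficits(et$et0, weather$rain, irr$irrigation)
  weeks_rainfed <- weekly_deficits(et$et0, weather$rain)
  wilcoxon <- compare_weekly_deficits(weeks_watered, weeks_rainfed)
  log_stage("et0/deficit", nrow(weather), nrow(weeks_watered))

  # 3. observations
  obs <- generate_observations(design, truth, weather, seed = seed)
  log_stage("observe", nrow(weather), nrow(obs$gas_exchange))

  # 4. QC
  screened <- qc_filter(obs$gas_exchange)
  kept <- filter(screened, .data$keep)
  log_stage("qc", nrow(screened), nrow(kept))

  # 5. species-month means and modelled E
  mean_A <- species_month_means(kept, "A")
  mean_gs <- species_month_means(kept, "gs")
  gs_cells <- mean_gs |>
    select("species", "clade", "type", "treatment", "month", gs = "mean")
  widths <- design$species |> select("species", "leaf_width")
  e_tbl <- estimate_monthly_E(
    gs_cells |> mutate(month = as.character(.data$month)),
    obs$climate, widths
  ) |>
    mutate(month = month_factor(.data$month))
  if (any(!e_tbl$converged)) {
    warn("leaf energy balance failed to converge for some cells.")
  }
  log_stage("leafeb", nrow(gs_cells), nrow(e_tbl))

  # 6. hydraulics
  keys <- c("species", "block", "treatment", "month")
  wp <- obs$water_potential
  paired <- pair_measurements(
    wp |> select(all_of(keys), "psi_midday"),
    wp |> select(all_of(keys), "psi_predawn", "hours_between", "rain_between")
  )
  pairs <- delta_psi(paired$pairs) |>
    left_join(wp |> distinct(.data$species, .data$clade, .data$type),
              by = "species")
  psi_means <- bind_rows(
    species_month_means(pairs, "psi_predawn"),
    species_month_means(pairs, "psi_midday"),
    species_month_means(pairs, "delta_psi")
  )
  hydro <- psi_means |>
    filter(.data$variable == "delta_psi") |>
    select("species", "clade", "type", "treatment", "month",
           delta_psi = "mean", n_pairs = "n") |>
    inner_join(e_tbl |> select("species", "treatment", "month", "E"),
               by = c("species", "treatment", "month")) |>
    k_plant()
  log_stage("hydraulics", nrow(wp), nrow(hydro))

  # 7. water-use efficiency at the species-month level
  wue <- mean_A |>
    select("species", "clade", "type", "treatment", "month",
           A = "mean", n_A = "n") |>
    inner_join(gs_cells, by = c("species", "clade", "type",
                                "treatment", "month")) |>
    inner_join(e_tbl |> select("species", "treatment", "month", "E"),
               by = c("species", "treatment", "month")) |>
    derive_wue()

  # 8. seasonal inference; derived variables (one modelled value per
  # species cell) inherit the replicate count of the underlying means
  as_means <- function(df, v, value_col, n_col) {
    df |>
      transmute(.data$species, .data$clade, .data$type, .data$treatment,
                .data$month, variable = v, mean = .data[[value_col]],
                n = .data[[n_col]]) |>
      filter(!is.na(.data$mean))
  }
  response_table <- function(v) {
    switch(v,
      A = mean_A,
      gs = mean_gs,
      E = e_tbl |>
        left_join(mean_gs |> select("species", "treatment", "month", "n"),
                  by = c("species", "treatment", "month")) |>
        as_means("E", "E", "n"),
      A_over_gs = as_means(wue, "A_over_gs", "A_over_gs", "n_A"),
      A_over_E = as_means(wue, "A_over_E", "A_over_E", "n_A"),
      psi_predawn = psi_means |> filter(.data$variable == "psi_predawn"),
      psi_midday = psi_means |> filter(.data$variable == "psi_midday"),
      delta_psi = psi_means |> filter(.data$variable == "delta_psi"),
      k_plant = hydro |>
        filter(.data$k_plant_excluded == "") |>
        as_means("k_plant", "k_plant", "n_pairs"),
      abort(paste0("unknown response variable `", v, "`."))
    )
  }
  fits <- list()
  boots <- list()
  drop_counts <- list()
  for (v in config$variables) {
    means <- response_table(v)
    bal <- balance_dataset(means)
    drop_counts[[v]] <- nrow(bal$dropped)
    fits[[v]] <- fit_seasonal_model(bal$balanced, v)
    boots[[v]] <- bootstrap_cis(fits[[v]], n_sim = config$n_sim,
                                seed = seed + 100L)
    log_stage(paste0("fit:", v), nrow(means), nrow(bal$balanced))
  }

  outputs <- list(
    weather = weather,
    daily_et0 = et |> select("date", "month", "et0", "et0_clamped"),
    irrigation = irr,
    weekly_watered = weeks_watered,
    weekly_rainfed = weeks_rainfed,
    qc = screened |> select(all_of(keys), "keep", "qc_reasons", "leaf_area"),
    E = e_tbl,
    hydraulics = hydro,
    wue = wue
  )
  checksums <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- purrr::imap_chr(outputs, function(df, nm) {
      write_stage_csv(df, file.path(config$outdir, paste0(nm, ".csv")),
                      seed, cfg_hash)
    })
    for (v in names(boots)) {
      paths <- c(paths,
        write_stage_csv(boots[[v]]$estimates,
                        file.path(config$outdir, paste0("estimates_", v, ".csv")),
                        seed, cfg_hash),
        write_stage_csv(boots[[v]]$contrasts,
                        file.path(config$outdir, paste0("contrasts_", v, ".csv")),
                        seed, cfg_hash))
    }
    checksums <- tools::md5sum(unname(paths))
  }

  manifest <- list(
    config_hash = cfg_hash,
    seeds = list(master = seed, weather = seed, observations = seed,
                 bootstrap = seed + 100L),
    n_sim = config$n_sim,
    counts = list(
      weather_days = nrow(weather),
      records_generated = nrow(obs$gas_exchange),
      records_kept = nrow(kept),
      qc_rejected = nrow(screened) - nrow(kept),
      wp_pairs = nrow(pairs),
      wp_excluded = nrow(paired$exclusions),
      balance_dropped = drop_counts
    ),
    wilcoxon_p = wilcoxon$p_value,
    checksums = as.list(checksums)
  )
  if (!is.null(config$outdir)) {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    c(list(manifest = manifest,
           water_balance = list(daily = et, irrigation = irr,
                                watered = weeks_watered,
                                rainfed = weeks_rainfed,
                                wilcoxon = wilcoxon),
           observations = obs,
           species_means = list(A = mean_A, gs = mean_gs, psi = psi_means),
           fits = fits, boots = boots),
      outputs[c("weather", "qc", "E", "hydraulics", "wue")]),
    class = "grassflux_run"
  )
}

#' @export
print.grassflux_run <- function(x, ...) {
  cat("grassflux pipeline run\n")
  cat("  seed:", x$manifest$seeds$master, "\n")
  cat("  records kept:", x$manifest$counts$records_kept, "of",
      x$manifest$counts$records_generated, "\n")
  cat("  Wilcoxon (watered vs rain-fed weekly deficits) p =",
      format.pval(x$manifest$wilcoxon_p), "\n")
  cat("  fitted variables:", paste(names(x$fits), collapse = ", "), "\n")
  invisible(x)
}
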