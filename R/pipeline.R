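# End-to-end orchestration: synthetic inputs -> reef cross-sections ->
# roughness profiles -> copula wave conditions -> Boussinesq ensemble ->
# extreme-value analysis -> Bayesian run-up model, with a single global
# seed fanned out per stage, JSON-lines logging and a run manifest.

#' Default pipeline configuration
#'
#' The `desk` profile shrinks replicate counts, percentile resolution and
#' simulation duration for interactive use and testing; the `full` profile
#' uses the study-scale settings (100 replicates per year, 1000 percentile
#' conditions, all years).
#'
#' @param profile `"desk"` or `"full"`.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  list(
    profile = profile,
    synth = list(
      n_years_climate = 30, rho = 0.5,
      survey_years = if (desk) c(2011, 2016) else NULL,
      bathymetry = list()
    ),
    reef = list(
      n_replicates = if (desk) 10 else 100,
      strip_length = if (desk) 20 else 160,
      strip_width = 1,
      cell = if (desk) 0.05 else 0.01,
      n_per_taxon = if (desk) 4 else 10
    ),
    roughness = list(
      coefficients = list(reef_crest = 1, back_reef = 1),
      d50 = 63e-6,
      calibration_check = TRUE
    ),
    ensemble = list(
      n_percentiles = if (desk) 30 else 1000,
      states = if (desk) c(2011, 2016) else NULL, # NULL = all years
      duration = if (desk) 400 else 1200
    ),
    extremes = list(
      threshold = 0.90,
      return_periods = c(2, 5, 10, 20, 50, 100, 200, 500),
      reference_T = 100,
      healthy = 2016, unhealthy = 2011
    ),
    bayes = list(
      chains = 4,
      draws = if (desk) 1500 else 5000,
      warmup = if (desk) 500 else 1000
    )
  )
}

log_stage <- function(log_path, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes synthetic-data generation, reef construction and complexity,
#' roughness profiling, the wave-condition ensemble, extreme-value
#' analysis and the Bayesian run-up model in order, writing each stage's
#' outputs (CSV/JSON) plus a run manifest to `out_dir`.
#'
#' @param config A configuration list (see [pipeline_config()]), a YAML
#'   file path, or `NULL` for the profile default.
#' @param seed Global integer seed (fanned out per stage).
#' @param profile `"desk"` or `"full"` (ignored when `config` is given).
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the manifest and all in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = NULL, seed = 1,
                         profile = c("desk", "full"),
                         out_dir = tempfile("reefshield_run_"),
                         quiet = FALSE) {
  profile <- match.arg(profile)
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file '%s' does not exist", config))
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(pipeline_config(config$profile %||% profile),
                    config %||% list())
  if (!is.null(cfg$synth$bathymetry_file) &&
      !file.exists(cfg$synth$bathymetry_file)) {
    stop(sprintf("bathymetry file '%s' does not exist",
                 cfg$synth$bathymetry_file))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log.jsonl")
  say <- function(...) if (!quiet) message(sprintf(...))

  # config hash for the manifest
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  t0 <- Sys.time()

  ## stage 1: synthetic inputs ----------------------------------------------
  say("[synth] generating survey table, bathymetry, wave climate")
  survey <- generate_survey_table(seed = fan_seed(seed, 101))
  if (!is.null(cfg$synth$survey_years)) {
    survey <- survey[survey$year %in% cfg$synth$survey_years, ]
    class(survey) <- c("survey_table", "data.frame")
  }
  if (!is.null(cfg$synth$bathymetry_file)) {
    bathy <- read_bathymetry(cfg$synth$bathymetry_file)
  } else {
    bathy <- generate_bathymetry(cfg$synth$bathymetry)
  }
  climate <- generate_wave_climate(n_years = cfg$synth$n_years_climate,
                                   rho = cfg$synth$rho,
                                   seed = fan_seed(seed, 102))
  sdf <- survey
  sdf$size_samples <- NULL
  write.csv(sdf, file.path(out_dir, "survey.csv"), row.names = FALSE)
  write_bathymetry(bathy, file.path(out_dir, "bathymetry.csv"))
  write.csv(climate, file.path(out_dir, "climate.csv"), row.names = FALSE)
  log_stage(log_path, "synth", years = base::length(unique(survey$year)),
            climate_rows = nrow(climate))

  ## stage 2: reef construction and complexity ------------------------------
  say("[reef] building %d cross-sections per year",
      cfg$reef$n_replicates)
  bank <- default_shape_bank(n_per_taxon = cfg$reef$n_per_taxon,
                             seed = fan_seed(seed, 201))
  substrate <- substrate_from_bathymetry(bathy, "fore_reef",
                                         width = cfg$reef$strip_width)
  if (!is.null(cfg$reef$strip_length) &&
      cfg$reef$strip_length < substrate$length) {
    keep <- substrate$x <= cfg$reef$strip_length
    substrate$x <- substrate$x[keep]
    substrate$z <- substrate$z[keep]
    substrate$length <- max(substrate$x)
  }
  sc_ens <- complexity_ensemble(survey, substrate, bank,
                                n_replicates = cfg$reef$n_replicates,
                                seed = fan_seed(seed, 202),
                                cell = cfg$reef$cell)
  write.csv(sc_ens, file.path(out_dir, "sc_ensemble.csv"),
            row.names = FALSE)
  scs <- sc_summary(sc_ens)
  write.csv(scs, file.path(out_dir, "sc_summary.csv"), row.names = FALSE)
  log_stage(log_path, "reef", n_sc = nrow(sc_ens))

  ## stage 3: roughness ------------------------------------------------------
  say("[roughness] building kn profiles")
  kn_cal <- NULL
  if (isTRUE(cfg$roughness$calibration_check)) {
    pr <- generate_pressure_records(kn_true = 0.42, n_bursts = 4,
                                    burst_seconds = 600,
                                    seed = fan_seed(seed, 301))
    ea <- depth_correct_pressure(pr$pressure[, , 1], pr$depths[1],
                                 pr$rate_hz)
    eb <- depth_correct_pressure(pr$pressure[, , 2], pr$depths[2],
                                 pr$rate_hz)
    est <- estimate_kn_spectral(ea, eb, pr$separation, pr$depths,
                                pr$rate_hz)
    kn_cal <- median(est$kn, na.rm = TRUE)
  }
  kn_ens <- roughness_ensemble(sc_ens, bathy,
                               coefficients = cfg$roughness$coefficients,
                               d50 = cfg$roughness$d50)
  kn_states <- representative_kn_profile(kn_ens)
  rep_df <- do.call(rbind, kn_states)
  write.csv(rep_df, file.path(out_dir, "kn_profiles.csv"),
            row.names = FALSE)
  log_stage(log_path, "roughness", n_profiles = base::length(kn_states),
            kn_calibration_median = kn_cal)

  ## stage 4: wave conditions and ensemble -----------------------------------
  say("[ensemble] copula conditions and Boussinesq runs")
  cop <- fit_hs_tp_copula(climate)
  pct <- seq(100 / cfg$ensemble$n_percentiles, 100,
             length.out = cfg$ensemble$n_percentiles)
  conds <- build_conditions(climate, cop, percentiles = pct)
  write.csv(conds, file.path(out_dir, "conditions.csv"), row.names = FALSE)
  state_sel <- cfg$ensemble$states %||% unique(sc_ens$year)
  states <- kn_states[as.character(state_sel)]
  sc_by_state <- setNames(
    vapply(state_sel,
           function(y) median(sc_ens$sc[sc_ens$year == y]), numeric(1)),
    as.character(state_sel))
  ens <- run_ensemble(states, conds, bathy,
                      duration = cfg$ensemble$duration,
                      seed = fan_seed(seed, 401),
                      sc_by_state = sc_by_state)
  write.csv(ens, file.path(out_dir, "ensemble.csv"), row.names = FALSE)
  log_stage(log_path, "ensemble", rows = nrow(ens),
            failed = sum(ens$failed))

  ## stage 5: extremes --------------------------------------------------------
  say("[extremes] GPD return curves and frequency amplification")
  ey <- as.character(cfg$extremes$healthy)
  uy <- as.character(cfg$extremes$unhealthy)
  curves <- list()
  amp <- NULL
  ok <- ens[!ens$failed, ]
  for (st in unique(ok$state)) {
    cv <- try(fit_gpd(ok$r2[ok$state == st],
                      threshold = cfg$extremes$threshold,
                      min_exceedances = min(30, ceiling(
                        0.05 * sum(ok$state == st))),
                      state = st), silent = TRUE)
    if (!inherits(cv, "try-error")) curves[[st]] <- cv
  }
  if (!is.null(curves[[ey]]) && !is.null(curves[[uy]])) {
    Ts <- cfg$extremes$return_periods
    Ts <- Ts[Ts > 1 / curves[[ey]]$lambda_u & Ts > 1 / curves[[uy]]$lambda_u]
    amp <- data.frame(
      T = Ts,
      r2_healthy = vapply(Ts, function(t) return_level(curves[[ey]], t),
                          numeric(1)),
      r2_unhealthy = vapply(Ts, function(t) return_level(curves[[uy]], t),
                            numeric(1)),
      amplification = frequency_amplification(curves[[ey]], curves[[uy]],
                                              Ts))
    write.csv(amp, file.path(out_dir, "return_curves.csv"),
              row.names = FALSE)
  }
  log_stage(log_path, "extremes", states_fitted = base::length(curves))

  ## stage 6: Bayesian run-up model -------------------------------------------
  say("[bayes] fitting the run-up interaction model")
  fit <- fit_runup_model(ok, chains = cfg$bayes$chains,
                         draws = cfg$bayes$draws,
                         warmup = cfg$bayes$warmup,
                         seed = fan_seed(seed, 601))
  write.csv(data.frame(parameter = rownames(fit$summary), fit$summary),
            file.path(out_dir, "posterior_summary.csv"), row.names = FALSE)
  sc_rng <- range(ok$sc)
  preds <- predict_runup(fit, hs_grid = 1:6,
                         sc_grid = seq(sc_rng[1], sc_rng[2],
                                       length.out = 11))
  resid <- residual_runup(preds)
  write.csv(resid, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  log_stage(log_path, "bayes", retained = fit$n_retained,
            max_rhat = max(fit$rhat, na.rm = TRUE))

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefshield")),
    config_hash = cfg_hash, seed = seed, profile = cfg$profile,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = list.files(out_dir),
    kn_calibration_median = kn_cal,
    sc_summary = scs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, out_dir = out_dir, survey = survey,
                 bathymetry = bathy, climate = climate, sc_ensemble = sc_ens,
                 sc_summary = scs, kn_states = kn_states, copula = cop,
                 conditions = conds, ensemble = ens, curves = curves,
                 amplification = amp, posterior = fit,
                 predictions = resid))
}

#' Write / read a bathymetry profile (CSV plus JSON section sidecar)
#' @param bathymetry A `bathymetry_profile`.
#' @param path CSV path; the sidecar is `<path>.sections.json`.
#' @export
write_bathymetry <- function(bathymetry, path) {
  write.csv(bathymetry[, c("x", "z")], path, row.names = FALSE)
  r <- rle(bathymetry$section)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  jsonlite::write_json(
    data.frame(label = r$values, x_start = bathymetry$x[starts],
               x_end = bathymetry$x[ends]),
    paste0(path, ".sections.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bathymetry
#' @param path CSV path written by [write_bathymetry()].
#' @export
read_bathymetry <- function(path) {
  df <- read.csv(path)
  sec <- jsonlite::read_json(paste0(path, ".sections.json"),
                             simplifyVector = TRUE)
  df$section <- NA_character_
  for (i in seq_len(nrow(sec))) {
    df$section[df$x >= sec$x_start[i] & df$x <= sec$x_end[i]] <-
      sec$label[i]
  }
  class(df) <- c("bathymetry_profile", "data.frame")
  df
}
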