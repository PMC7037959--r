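# Configuration and the sequential processing chain: fixtures -> dilution
# parameters -> plume simulation -> exposure, with CSV/JSON artifacts and a
# run manifest carrying the seed and a config hash.

#' Default run configuration
#'
#' All model constants live here: the turbulence constant alpha = 0.1, the
#' initial plume height 5.5 m, the stability-dependent sigma_z scales, the
#' infiltration factor 0.56, the 0.1-s aerosol time step, 120 size sections,
#' the 1-s first-stage duration and the default dilution exponent 1.26.
#'
#' @param event_id ship event preset (default "A_20110111").
#' @param scenario scenario flag (default "base").
#' @param seed integer seed recorded in all outputs.
#' @return nested configuration list.
#' @export
default_config <- function(event_id = "A_20110111", scenario = "base",
                           seed = 1) {
  list(
    event_id = event_id,
    scenario = scenario,
    seed = seed,
    dilution = list(alpha = 0.1, t_first_stage_s = 1, H_P0_m = 5.5,
                    b_default = 1.26,
                    sigma_z_scales = c(unstable = 110.62, neutral = 86.49,
                                       stable = 61.14)),
    stack = list(S0_m2 = pi / 4, Vs_ms = 30, Te_K = 580),
    grid = list(n_sections = 120, d_min_nm = 1, d_max_nm = 1e4),
    simulation = list(duration_s = 900, dt_s = 0.1, output_interval_s = 1),
    chemistry = list(so3_fraction = 0.01, k_hydration_s = 10,
                     org_mult = c(7, 7, 11), daytime_oh = 3e6, night_oh = 1e4),
    exposure = list(F_inf = 0.56, time_at_home = 0.6, plume_minutes = 5,
                    ring_width_m = 40, max_radius_m = 3600,
                    sector_halfwidth_deg = 15,
                    schedule_min = c(420, 690, 1050, 1260),
                    population = list(extent_m = 7200,
                                      hotspots = list(list(center = c(4500, 4500),
                                                           total = 650,
                                                           sd_m = 400))))
  )
}

#' Read a run configuration from a YAML file
#'
#' Missing entries fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Write an aerosol state as a sectional CSV
#'
#' Columns: bin_center_nm, dN (cm^-3 per section) and one mass column per
#' component (ug m^-3).
#'
#' @param state an [aerosol_state()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(state, path) {
  df <- data.frame(bin_center_nm = state$grid$centers_nm, dN = state$number)
  df <- cbind(df, as.data.frame(state$mass))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write trajectory summaries as CSV
#'
#' One row per snapshot: time, downwind distance, plume height, NP/UFP/total
#' number and per-component UFP dry mass; mirrors the composition table at
#' the standard travel times when filtered.
#'
#' @param traj a `plume_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  rows <- lapply(seq_along(traj$time_s), function(i) {
    st <- traj$states[[i]]
    mass <- component_dry_mass(st, d_max_nm = 100)
    c(time_s = traj$time_s[i], x_m = traj$x_m[i], H_P_m = traj$H_P_m[i],
      np_cm3 = total_number(st, d_max_nm = 25),
      ufp_cm3 = total_number(st, d_max_nm = 100),
      total_pn_cm3 = total_number(st),
      stats::setNames(mass, paste0("ufp_", names(mass), "_ugm3")))
  })
  utils::write.csv(as.data.frame(do.call(rbind, rows)), path, row.names = FALSE)
  invisible(path)
}

#' Run the sequential model chain
#'
#' fixtures -> dilution parameters (fit to generated receptor samples) ->
#' plume simulation -> exposure, writing CSV/JSON artifacts and a manifest
#' (package version, seed, config hash) to `output_dir`.
#'
#' @param config configuration list (see [default_config()]) or a YAML path.
#' @param output_dir artifact directory (created if missing).
#' @return named list of artifact paths, invisibly; the `summary` element
#'   holds headline numbers (DR, fitted a/b, max excess %, excess risk %).
#' @export
run_chain <- function(config = default_config(), output_dir = tempfile("chain")) {
  if (is.character(config)) config <- read_config(config)
  if (!config$scenario %in% scenario_flags())
    stop("invalid scenario flag: ", config$scenario)
  if (!config$event_id %in% ship_event_ids())
    stop("unknown event id: ", config$event_id)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  event <- make_event(config$event_id)
  grid <- size_grid(config$grid$n_sections, config$grid$d_min_nm,
                    config$grid$d_max_nm)

  # stage 1: dilution parameters from generated receptor samples
  stack <- stack_spec(config$stack$S0_m2, config$stack$Vs_ms, config$stack$Te_K)
  DR <- first_stage_dilution_ratio(stack, event, alpha = config$dilution$alpha,
                                   t_end = config$dilution$t_first_stage_s)
  samples <- make_dilution_samples(5000, event$b,
                                   distances_m = seq(50, 2000, by = 50),
                                   noise_sd = 0.1, seed = config$seed)
  fit <- fit_power_law(samples)
  params <- dilution_params(DR = DR, a = fit$a, b = fit$b,
                            H_P0 = config$dilution$H_P0_m,
                            stability = event$stability)

  # stage 2: plume aerosol simulation
  traj <- simulate_plume(event, config$scenario,
                         duration_s = config$simulation$duration_s,
                         dt = config$simulation$dt_s, grid = grid,
                         params = params,
                         output_interval_s = config$simulation$output_interval_s)
  traj_csv <- file.path(output_dir, "trajectory.csv")
  write_trajectory_csv(traj, traj_csv)

  # stage 3: exposure
  ex_cfg <- config$exposure
  field <- build_plume_field(traj, ring_width_m = ex_cfg$ring_width_m,
                             max_radius_m = ex_cfg$max_radius_m,
                             sector_halfwidth_deg = ex_cfg$sector_halfwidth_deg)
  pop <- make_population_grid(ex_cfg$population$extent_m,
                              ex_cfg$population$hotspots, seed = config$seed)
  conc <- field_to_raster(field, pop)
  daily <- daily_mean_concentration(conc, ex_cfg$schedule_min,
                                    ex_cfg$plume_minutes, field$background_cm3)
  expo <- population_exposure(daily, pop, ex_cfg$time_at_home, ex_cfg$F_inf,
                              field$background_cm3)
  max_inc <- max(daily) - field$background_cm3
  expo_csv <- file.path(output_dir, "exposure.csv")
  utils::write.csv(data.frame(
    x_m = rep(pop$x, times = length(pop$y)),
    y_m = rep(pop$y, each = length(pop$x)),
    daily_cm3 = as.vector(daily),
    inhabitants = as.vector(pop$inhabitants),
    exposure = as.vector(expo$exposure)
  ), expo_csv, row.names = FALSE)

  summary <- list(
    event_id = config$event_id, scenario = config$scenario,
    seed = config$seed, DR = DR, fit_a = fit$a, fit_b = fit$b,
    max_excess_percent = expo$max_excess_percent,
    persons_in_impact_area = expo$persons_in_impact_area,
    excess_risk_percent = excess_risk(max_inc),
    total_exposure = expo$total
  )
  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "plumeufp",
    version = as.character(utils::packageVersion("plumeufp")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = c("trajectory.csv", "exposure.csv", "summary.json"),
    summary = summary
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    output_dir = output_dir, trajectory = traj_csv, exposure = expo_csv,
    manifest = file.path(output_dir, "manifest.json"),
    summary = summary
  ))
}
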