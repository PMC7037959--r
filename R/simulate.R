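# Plume aerosol simulation: follows an air parcel along the plume centerline
# from t0 = 1 s (end of the first dilution stage) for 15 min, advancing the
# gas phase and the sectional aerosol with a fixed operator sequence per
# 0.1-s step: chemistry -> nucleation -> condensation -> coagulation ->
# dry deposition -> dilution with background air.

.scenarios <- c("base", "2XSO3", "T310K", "NUHET", "HSULF")

#' Scenario flags
#' @return character vector of recognized scenario names.
#' @export
scenario_flags <- function() .scenarios

#' Initial plume gas state for an event
#'
#' Diluted-exhaust concentrations one second after release: SOx split into
#' SO2 and directly emitted SO3 (1% conversion; doubled under `2XSO3`),
#' organic vapors proportional to the SOx-derived sulfuric-acid potential,
#' NOx emitted as 90% NO / 10% NO2, and an O3-depleted plume core.
#'
#' @param event a `ship_event`.
#' @param scenario one of [scenario_flags()].
#' @param nox_ugm3 initial diluted NOx, ug m^-3 (default 300).
#' @param o3_ugm3 initial in-plume O3, ug m^-3 (default 10).
#' @param org_mult multipliers (c22, c28, c34) on the SO3-derived H2SO4
#'   potential for the organic vapors (default 7, 7, 11).
#' @return a [gas_state()] at t = 1 s.
#' @export
initial_gas_state <- function(event, scenario = "base", nox_ugm3 = 300,
                              o3_ugm3 = 10, org_mult = c(7, 7, 11)) {
  scenario <- match.arg(scenario, .scenarios)
  so3_frac <- if (scenario == "2XSO3") 0.02 else 0.01
  sox_total <- event$h2so4_init_cm3 / 0.01     # per-event SOx, cm^-3
  so3 <- sox_total * so3_frac
  so2 <- sox_total - so3
  base_h2so4 <- event$h2so4_init_cm3           # organic scaling uses base SOx
  gas_state(
    c(
      no = ugm3_to_molec(0.9 * nox_ugm3, 0.030),
      no2 = ugm3_to_molec(0.1 * nox_ugm3, 0.046),
      o3 = ugm3_to_molec(o3_ugm3, 0.048),
      so2 = so2, so3 = so3,
      oh = oh_level(event),
      c22h46 = org_mult[1] * base_h2so4,
      c28h58 = org_mult[2] * base_h2so4,
      c34h70 = org_mult[3] * base_h2so4
    ),
    temperature_K = event$air_temperature_K, rh = event$rh_pct, time_s = 1
  )
}

#' Background gas state
#'
#' Urban background concentrations (NO 2, NO2 10, O3 60, SO2 2 ug m^-3),
#' repartitioned to the photostationary state at the event's NO2 photolysis
#' frequency so the background is a fixed point of the in-plume chemistry.
#'
#' @param event a `ship_event` (for temperature/RH, prescribed OH and j_NO2).
#' @return a [gas_state()].
#' @export
background_gas_state <- function(event) {
  gs <- gas_state(
    c(
      no = ugm3_to_molec(2, 0.030), no2 = ugm3_to_molec(10, 0.046),
      o3 = ugm3_to_molec(60, 0.048), so2 = ugm3_to_molec(2, 0.064),
      oh = oh_level(event)
    ),
    temperature_K = event$air_temperature_K, rh = event$rh_pct, time_s = 1
  )
  gs$conc[c("no", "no2", "o3")] <- photostationary_state(
    gs$conc[["no"]], gs$conc[["no2"]], gs$conc[["o3"]],
    j_no2_level(event), gs$temperature_K
  )
  gs
}

#' Simulate the aerosol evolution in a dispersing ship plume
#'
#' @param event a `ship_event` or event id string.
#' @param scenario one of [scenario_flags()].
#' @param duration_s simulated time beyond t0, s (default 900).
#' @param dt aerosol-dynamics time step, s (default 0.1).
#' @param grid a [size_grid()] (default 120 sections, 1 nm - 10 um).
#' @param params a [dilution_params()]; defaults to the event's
#'   stability-dependent exponent with DR from the ROPAX stack.
#' @param exhaust initial diluted-exhaust [aerosol_state()]; defaults to the
#'   three-mode preset scaled to the event's diluted PN (Nuc_2 100% H2SO4
#'   under `HSULF`).
#' @param background background [aerosol_state()]; defaults to the
#'   `helsinki` preset.
#' @param gases,background_gases initial and background [gas_state()]s;
#'   defaults from the event and scenario.
#' @param processes named logical list switching operators on/off
#'   (chemistry, nucleation, condensation, coagulation, deposition,
#'   dilution); all TRUE by default.
#' @param output_interval_s snapshot spacing, s (default 1).
#' @param t0 start time, s (default 1; end of first-stage dilution).
#' @return object of class `plume_trajectory`: `time_s`, `x_m` (= U t),
#'   `H_P_m`, `states` (snapshots with diagnosed water), `gases`, `event`,
#'   `scenario`, `params`.
#' @export
simulate_plume <- function(event, scenario = "base", duration_s = 900,
                           dt = 0.1, grid = size_grid(), params = NULL,
                           exhaust = NULL, background = NULL, gases = NULL,
                           background_gases = NULL,
                           processes = list(), output_interval_s = 1,
                           t0 = 1) {
  if (is.character(event)) event <- make_event(event)
  scenario <- match.arg(scenario, .scenarios)
  proc <- utils::modifyList(
    list(chemistry = TRUE, nucleation = TRUE, condensation = TRUE,
         coagulation = TRUE, deposition = TRUE, dilution = TRUE),
    processes
  )
  if (is.null(params)) {
    DR <- first_stage_dilution_ratio(stack_spec(), event)
    params <- dilution_params(DR = DR, b = event$b, stability = event$stability)
  }
  T0 <- if (scenario == "T310K") 310 else event$air_temperature_K
  rh <- event$rh_pct
  if (is.null(exhaust)) {
    nuc2_comp <- if (scenario == "HSULF") c(sulfate = 1) else c(sulfate = 0.2, nv_pom = 0.8)
    modes <- exhaust_modes_preset(total_number_cm3 = event$pn_diluted_cm3,
                                  nuc2_composition = nuc2_comp)
    exhaust <- make_exhaust_distribution(modes, grid, T0, rh)
  }
  if (is.null(background))
    background <- make_background_distribution("helsinki", grid,
                                               event$air_temperature_K, rh)
  stopifnot(identical(exhaust$grid$n_sections, background$grid$n_sections))
  if (is.null(gases)) gases <- initial_gas_state(event, scenario)
  if (is.null(background_gases)) background_gases <- background_gas_state(event)
  mech <- if (scenario == "NUHET") "HET" else "BHN"
  j_no2 <- j_no2_level(event)

  state <- exhaust
  state$temperature_K <- T0
  gases$temperature_K <- T0
  U <- event$wind_speed_ms
  n_steps <- round(duration_s / dt)
  rec_every <- max(1L, round(output_interval_s / dt))
  n_rec <- floor(n_steps / rec_every) + 1L
  times <- numeric(n_rec); states <- vector("list", n_rec)
  gasrec <- vector("list", n_rec)
  rec <- 1L
  snapshot <- function(s) equilibrate_water(s)
  times[1] <- t0; states[[1]] <- snapshot(state); gasrec[[1]] <- gases
  coag_tab <- if (proc$coagulation) coagulation_tables(grid, state$temperature_K) else NULL
  coag_T <- state$temperature_K
  v_dep <- if (proc$deposition) deposition_velocity(grid$centers_nm, T = state$temperature_K) else NULL
  conv_h2so4 <- 0.098078 * 1e15 / .NA
  conv_c34 <- 0.47892 * 1e15 / .NA

  t <- t0
  for (step in seq_len(n_steps)) {
    if (proc$chemistry) {
      gases <- gas_step(gases, background_gases, params$b, t, dt, j_no2)
    }
    if (proc$nucleation) {
      nr <- nucleation_rate(state$temperature_K, rh, gases$conc[["h2so4"]],
                            mechanism = mech, organic = gases$conc[["c34h70"]])
      if (nr$J > 0) {
        # sulfuric acid (and organic, HET) availability limits the burst
        max_J <- 0.99 * gases$conc[["h2so4"]] / (nr$n_acid * dt)
        J <- min(nr$J, max_J)
        sec <- max(1L, min(findInterval(nr$d_crit_nm, grid$edges_nm),
                           grid$n_sections))
        dnum <- J * dt
        dacid <- dnum * nr$n_acid
        state$number[sec] <- state$number[sec] + dnum
        state$mass[sec, "sulfate"] <- state$mass[sec, "sulfate"] + dacid * conv_h2so4
        gases$conc[["h2so4"]] <- gases$conc[["h2so4"]] - dacid
        if (nr$n_org > 0) {
          dorg <- min(dnum * nr$n_org, gases$conc[["c34h70"]])
          state$mass[sec, "elv_om"] <- state$mass[sec, "elv_om"] + dorg * conv_c34
          gases$conc[["c34h70"]] <- gases$conc[["c34h70"]] - dorg
        }
      }
    }
    if (proc$condensation) {
      cs <- condensation_step(state, gases, dt)
      state <- cs$state; gases <- cs$gases
      state <- regrid_state(state)
    } else if (proc$nucleation) {
      state <- regrid_state(state)
    }
    if (proc$coagulation) {
      if (abs(state$temperature_K - coag_T) > 5) {
        coag_tab <- coagulation_tables(grid, state$temperature_K)
        coag_T <- state$temperature_K
      }
      state <- coagulation_step(state, dt, tables = coag_tab)
    }
    if (proc$deposition) {
      HP <- plume_height(t, U, params)
      state <- dry_deposition_step(state, dt, HP, v_d = v_dep)
    }
    if (proc$dilution) {
      state <- background_mixing_step(state, background, params$b, t, dt)
      if (scenario == "T310K") {
        fac <- dilution_factor(params$b, t, dt)
        state$temperature_K <- event$air_temperature_K +
          (state$temperature_K - event$air_temperature_K) * fac
        gases$temperature_K <- state$temperature_K
      }
    }
    t <- t0 + step * dt
    if (any(!is.finite(state$number)) || any(!is.finite(state$mass)))
      stop("non-finite aerosol state at t = ", t, " s")
    if (step %% rec_every == 0) {
      rec <- rec + 1L
      times[rec] <- t
      states[[rec]] <- snapshot(state)
      gasrec[[rec]] <- gases
    }
  }
  structure(
    list(time_s = times[seq_len(rec)], x_m = U * times[seq_len(rec)],
         H_P_m = plume_height(times[seq_len(rec)], U, params),
         states = states[seq_len(rec)], gases = gasrec[seq_len(rec)],
         event = event, scenario = scenario, params = params, grid = grid,
         background = background, t0 = t0),
    class = "plume_trajectory"
  )
}

#' @export
print.plume_trajectory <- function(x, ...) {
  cat(sprintf(
    "<plume_trajectory> %s [%s], t = %.0f..%.0f s, %d snapshots\n",
    x$event$event_id, x$scenario, x$time_s[1], x$time_s[length(x$time_s)],
    length(x$time_s)
  ))
  invisible(x)
}

# Snapshot nearest to travel time tau = t - t0.
trajectory_at <- function(traj, travel_time_s) {
  idx <- which.min(abs((traj$time_s - traj$t0) - travel_time_s))
  list(state = traj$states[[idx]], gases = traj$gases[[idx]],
       time_s = traj$time_s[idx])
}

#' Summarize a plume trajectory at a travel time
#'
#' Diagnostics of the sectional state after `travel_time_s` seconds of
#' plume travel (measured from the simulation start t0): nucleation-mode
#' particle number (NP, Dp < 25 nm), ultrafine number 25-100 nm, total PN,
#' Nuc_1 mode diameter (peak below 3 nm, where present), per-component
#' ultrafine (Dp < 100 nm) dry mass with fractions, and the water mass
#' fraction of the wet ultrafine mass.
#'
#' @param traj a `plume_trajectory`.
#' @param travel_time_s travel time, s.
#' @return list of diagnostics.
#' @export
summarize_plume <- function(traj, travel_time_s) {
  snap <- trajectory_at(traj, travel_time_s)
  st <- snap$state
  d <- st$grid$centers_nm
  dist <- dNdlogDp(st)
  sub3 <- which(d < 3)
  nuc1_d <- NA_real_
  if (length(sub3) && any(dist[sub3] > 0)) {
    pk <- sub3[which.max(dist[sub3])]
    if (dist[pk] > 1) nuc1_d <- d[pk]
  }
  ufp_mass <- component_dry_mass(st, d_max_nm = 100)
  water <- sum(st$mass[d < 100, "water"])
  list(
    travel_time_s = travel_time_s,
    np_number_cm3 = total_number(st, d_max_nm = 25),
    ufp_25_100_cm3 = total_number(st, 25, 100),
    total_pn_cm3 = total_number(st),
    nuc1_mode_diameter_nm = nuc1_d,
    ufp_dry_mass_ugm3 = ufp_mass,
    ufp_dry_fractions = dry_mass_fractions(ufp_mass),
    np_dry_mass_ugm3 = component_dry_mass(st, d_max_nm = 25),
    water_mass_fraction = if (sum(ufp_mass) + water > 0)
      water / (sum(ufp_mass) + water) else 0
  )
}

#' Growth rate of the freshly nucleated (Nuc_1) mode
#'
#' Identifies the local maximum of dN/dlogDp below 3 nm at early times and
#' tracks its diameter through the trajectory snapshots; the growth rate is
#' the slope of a linear fit of peak diameter against time, in nm h^-1.
#'
#' @param traj a `plume_trajectory`.
#' @param max_start_nm upper diameter bound for the initial peak, nm
#'   (default 3).
#' @param min_points minimum number of tracked points for a fit (default 5).
#' @return growth rate, nm h^-1, or NA (with a warning) if no mode is
#'   identifiable.
#' @export
nuc1_growth_rate <- function(traj, max_start_nm = 3, min_points = 5) {
  times <- traj$time_s
  peaks <- rep(NA_real_, length(times))
  prev <- NA_real_
  for (i in seq_along(times)) {
    st <- traj$states[[i]]
    d <- st$grid$centers_nm
    dist <- dNdlogDp(st)
    win <- if (is.na(prev)) which(d < max_start_nm)
           else which(d > prev * 0.75 & d < prev * 1.7)
    if (!length(win)) break
    pk <- win[which.max(dist[win])]
    if (dist[pk] <= 1) { if (is.na(prev)) next else break }
    # require a local maximum: the next section up must not dominate
    peaks[i] <- d[pk]
    prev <- d[pk]
  }
  ok <- !is.na(peaks)
  if (sum(ok) < min_points) {
    warning("no identifiable Nuc_1 mode")
    return(NA_real_)
  }
  fit <- stats::lm(peaks[ok] ~ times[ok])
  unname(stats::coef(fit)[2]) * 3600
}
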