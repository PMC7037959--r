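# Time-microenvironment-activity exposure stage: converts simulated
# centerline UFP concentrations into a sectored ship-impact field, composes
# daily mean concentrations from the harbor's arrival/departure schedule,
# and computes residential (ME_home) population exposure and excess
# mortality risk.

#' Build the sectored plume concentration field from a trajectory
#'
#' Ultrafine (Dp < 100 nm) number concentrations along the plume centerline
#' are averaged into 40-m downwind-distance intervals and inserted uniformly
#' into circle segments covering 15 degrees on each side of the centerline,
#' out to 3600 m. Rings beyond the trajectory's reach hold the background
#' concentration.
#'
#' @param traj a `plume_trajectory`.
#' @param background_cm3 background UFP concentration for cells outside the
#'   plume (default: from the trajectory's background state).
#' @param ring_width_m ring width, m (default 40).
#' @param max_radius_m maximum radius, m (default 3600).
#' @param sector_halfwidth_deg sector half-width each side of the
#'   centerline, degrees (default 15).
#' @return object of class `exposure_field`: ring concentrations (cm^-3),
#'   centerline direction (degrees, direction of plume travel =
#'   wind direction + 180), background, geometry.
#' @export
build_plume_field <- function(traj, background_cm3 = NULL, ring_width_m = 40,
                              max_radius_m = 3600, sector_halfwidth_deg = 15) {
  if (is.null(background_cm3))
    background_cm3 <- total_number(traj$background, d_max_nm = 100)
  ufp <- vapply(traj$states, total_number, numeric(1), d_max_nm = 100)
  n_rings <- ceiling(max_radius_m / ring_width_m)
  ring <- rep(NA_real_, n_rings)
  idx <- pmin(floor(traj$x_m / ring_width_m) + 1, n_rings)
  keep <- traj$x_m < max_radius_m
  if (any(keep)) {
    agg <- tapply(ufp[keep], idx[keep], mean)
    ring[as.integer(names(agg))] <- agg
  }
  ring[is.na(ring)] <- background_cm3
  ring <- pmax(ring, background_cm3)
  structure(
    list(
      ring_cm3 = ring, ring_width_m = ring_width_m,
      max_radius_m = n_rings * ring_width_m,
      sector_halfwidth_deg = sector_halfwidth_deg,
      centerline_deg = (traj$event$wind_direction_deg + 180) %% 360,
      background_cm3 = background_cm3
    ),
    class = "exposure_field"
  )
}

# Field value at points (x, y) relative to the ship anchor, m.
field_value_at <- function(field, x, y) {
  r <- sqrt(x^2 + y^2)
  bearing <- (atan2(x, y) * 180 / pi) %% 360   # compass bearing of the point
  dang <- abs(((bearing - field$centerline_deg + 180) %% 360) - 180)
  out <- rep(field$background_cm3, length(x))
  inside <- r < field$max_radius_m & dang <= field$sector_halfwidth_deg & r > 0
  if (any(inside)) {
    k <- pmin(floor(r[inside] / field$ring_width_m) + 1, length(field$ring_cm3))
    out[inside] <- field$ring_cm3[k]
  }
  out
}

#' Sample an exposure field onto a population raster
#'
#' Each 100-m cell receives the mean of the field over a fixed sub-grid of
#' sample points (approximate area-weighted overlap of the ring-sector
#' geometry with the cell).
#'
#' @param field an [build_plume_field()] result.
#' @param grid a [make_population_grid()] raster; the ship anchor is the
#'   domain center.
#' @param subsample sub-grid points per cell side (default 5).
#' @return matrix of concentrations (cm^-3) matching `grid$inhabitants`.
#' @export
field_to_raster <- function(field, grid, subsample = 5) {
  cs <- grid$cell_size_m
  off <- (seq_len(subsample) - 0.5) / subsample * cs - cs / 2
  cx <- grid$x - grid$extent_m / 2
  cy <- grid$y - grid$extent_m / 2
  out <- matrix(0, length(cx), length(cy))
  for (a in off) {
    for (b in off) {
      pts <- expand.grid(x = cx + a, y = cy + b)
      out <- out + matrix(field_value_at(field, pts$x, pts$y),
                          length(cx), length(cy))
    }
  }
  out / subsample^2
}

#' Daily mean concentration from an event schedule
#'
#' Each scheduled ship passage exposes a cell to the plume value for
#' `plume_minutes`; the rest of the day holds the background:
#' C_daily = (sum_events plume_minutes * C_cell +
#' (1440 - n_events * plume_minutes) * C_bg) / 1440. Overlapping plume
#' windows are merged with a warning.
#'
#' @param concentration plume concentration per cell (matrix or vector,
#'   cm^-3), e.g. from [field_to_raster()].
#' @param schedule_min event start times, minutes of day (0-1439).
#' @param plume_minutes plume presence per event, min (default 5).
#' @param background_cm3 background concentration.
#' @return daily mean concentration, same shape as `concentration`.
#' @export
daily_mean_concentration <- function(concentration, schedule_min,
                                     plume_minutes = 5, background_cm3) {
  stopifnot(all(schedule_min >= 0 & schedule_min < 1440))
  if (length(schedule_min) > 1) {
    s <- sort(schedule_min)
    if (any(diff(s) < plume_minutes)) {
      warning("overlapping plume windows merged")
      keep <- c(TRUE, diff(s) >= plume_minutes)
      s <- s[keep]
    }
    schedule_min <- s
  }
  tot_plume <- length(schedule_min) * plume_minutes
  stopifnot(tot_plume <= 1440)
  (tot_plume * concentration + (1440 - tot_plume) * background_cm3) / 1440
}

#' Infiltration of outdoor particles to the indoor microenvironment
#'
#' Indoor concentration of ambient origin = F_inf * outdoor.
#'
#' @param outdoor_cm3 outdoor concentration, cm^-3.
#' @param F_inf infiltration factor in \[0, 1\] (default 0.56, the mean of
#'   Northern-European residential UFP measurements).
#' @return indoor concentration, cm^-3.
#' @export
infiltrate <- function(outdoor_cm3, F_inf = 0.56) {
  if (F_inf < 0 || F_inf > 1) stop("F_inf must lie in [0, 1]")
  F_inf * outdoor_cm3
}

#' Residential population exposure
#'
#' E_i = F_inf * C_i * P_i * f_home per cell: the daily mean concentration
#' weighted by the people present in the home microenvironment and the
#' fraction of the day they spend there, infiltrated indoors.
#'
#' @param daily_cm3 daily mean concentration per cell (matrix, cm^-3).
#' @param population a [make_population_grid()] (dimensions must match).
#' @param time_at_home fraction of the day in ME_home (default 0.6).
#' @param F_inf infiltration factor (default 0.56).
#' @param background_cm3 background concentration for the excess comparison.
#' @return object of class `exposure_result`: `exposure` (cm^-3 persons per
#'   cell), `total`, `excess_percent` (per cell, over background-only
#'   exposure), `max_excess_percent`, `persons_in_impact_area` (persons in
#'   cells with any excess).
#' @export
population_exposure <- function(daily_cm3, population, time_at_home = 0.6,
                                F_inf = 0.56, background_cm3) {
  P <- population$inhabitants
  if (!all(dim(daily_cm3) == dim(P))) stop("misaligned concentration/population grids")
  E <- infiltrate(daily_cm3, F_inf) * P * time_at_home
  E_bg <- infiltrate(background_cm3, F_inf) * P * time_at_home
  excess <- ifelse(E_bg > 0, (E - E_bg) / E_bg * 100, 0)
  structure(
    list(
      exposure = E, total = sum(E),
      excess_percent = excess,
      max_excess_percent = max(excess),
      persons_in_impact_area = sum(P[daily_cm3 > background_cm3 + 1e-9])
    ),
    class = "exposure_result"
  )
}

#' Excess mortality risk from a daily mean UFP increment
#'
#' Linear dose-response: 4% excess risk per 6250 cm^-3 UFP increment.
#'
#' @param increment_cm3 daily mean UFP increment over background, cm^-3
#'   (>= 0).
#' @return excess risk, percent.
#' @export
excess_risk <- function(increment_cm3) {
  stopifnot(all(increment_cm3 >= 0))
  4 * increment_cm3 / 6250
}
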