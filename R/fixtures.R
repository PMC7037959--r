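# Generators for every input the model chain needs: multimodal lognormal
# exhaust/background size distributions, ship-event records, dilution-curve
# samples and population grids. All are deterministic functions of their
# parameters (and a seed where noise is requested).

#' Lognormal particle mode
#'
#' @param number_cm3 mode number concentration, cm^-3.
#' @param cmd_nm count median diameter, nm.
#' @param gsd geometric standard deviation (> 1).
#' @param composition named dry-mass fractions over (a subset of)
#'   [dry_components()]; must sum to 1.
#' @return object of class `lognormal_mode`.
#' @export
lognormal_mode <- function(number_cm3, cmd_nm, gsd, composition) {
  stopifnot(number_cm3 >= 0, cmd_nm > 0, gsd > 1)
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  if (length(setdiff(names(composition), dry_components())))
    stop("unknown composition components")
  structure(
    list(number_cm3 = number_cm3, cmd_nm = cmd_nm, gsd = gsd,
         composition = composition),
    class = "lognormal_mode"
  )
}

# Fraction of a lognormal mode's number below diameter d_nm.
mode_fraction_below <- function(mode, d_nm) {
  stats::pnorm((log(d_nm) - log(mode$cmd_nm)) / log(mode$gsd))
}

#' Discretize lognormal modes onto a sectional grid
#'
#' Integrates each mode's lognormal number density over the section edges and
#' assigns per-section component masses from the mode composition, with the
#' section-center particle volume and the mixture density implied by the
#' component mass fractions.
#'
#' @param modes list of [lognormal_mode()]s.
#' @param grid a [size_grid()].
#' @param temperature_K,rh carried into the state.
#' @return an [aerosol_state()].
#' @export
make_exhaust_distribution <- function(modes, grid, temperature_K = 288, rh = 70) {
  stopifnot(length(modes) >= 1)
  if (inherits(modes, "lognormal_mode")) modes <- list(modes)
  e <- grid$edges_nm
  for (m in modes) {
    if (m$cmd_nm <= e[1] || m$cmd_nm >= e[length(e)])
      stop("mode median diameter outside the size grid")
  }
  ns <- grid$n_sections
  comps <- aerosol_components()
  number <- numeric(ns)
  mass <- matrix(0, ns, length(comps), dimnames = list(NULL, comps))
  rho <- .comp_density * 1e-3  # g cm^-3
  for (m in modes) {
    cdf <- stats::pnorm((log(e) - log(m$cmd_nm)) / log(m$gsd))
    n_i <- m$number_cm3 * diff(cdf)
    number <- number + n_i
    # mixture density from dry-mass fractions: 1/rho_mix = sum(w_q / rho_q)
    w <- m$composition
    rho_mix <- 1 / sum(w / rho[names(w)])
    m_tot <- n_i * grid$volumes_cm3 * rho_mix * 1e12   # ug m^-3
    for (q in names(w)) mass[, q] <- mass[, q] + w[q] * m_tot
  }
  aerosol_state(grid, number, mass, temperature_K, rh)
}

#' Default multimodal ship-exhaust preset (diluted exhaust)
#'
#' Three modes: the primary exhaust nucleation mode Nuc_2 (median 5.5 nm,
#' GSD 1.35, liquid H2SO4 : primary organics = 20:80 by mass), an
#' intermediate soot/NV-POM mode near 40 nm, and an accumulation mode at
#' 100 nm. The Nuc_2 number weight is solved so the sub-25-nm number
#' fraction of the continuous distribution is exactly `np_fraction`
#' (default 0.29 of total number).
#'
#' @param total_number_cm3 total particle number, cm^-3 (diluted exhaust,
#'   typically 1e6-1e7).
#' @param np_fraction number fraction with Dp < 25 nm (default 0.29).
#' @param nuc2_composition named dry-mass fractions of the Nuc_2 mode;
#'   default 20% sulfate / 80% NV-POM. The HSULF scenario passes
#'   `c(sulfate = 1)`.
#' @return list of three [lognormal_mode()]s.
#' @export
exhaust_modes_preset <- function(total_number_cm3 = 3.2e6 / 0.29,
                                 np_fraction = 0.29,
                                 nuc2_composition = c(sulfate = 0.2, nv_pom = 0.8)) {
  # relative weights of the intermediate and accumulation modes; the
  # nucleation-mode weight is solved from the sub-25-nm constraint
  int_mode <- list(cmd = 40, gsd = 1.35)
  acc_mode <- list(cmd = 100, gsd = 1.55)
  w_int_rel <- 0.88                     # of the non-nucleation number
  nuc <- list(cmd = 5.5, gsd = 1.35)
  p_nuc <- stats::pnorm((log(25) - log(nuc$cmd)) / log(nuc$gsd))
  p_int <- stats::pnorm((log(25) - log(int_mode$cmd)) / log(int_mode$gsd))
  p_acc <- stats::pnorm((log(25) - log(acc_mode$cmd)) / log(acc_mode$gsd))
  p_rest <- w_int_rel * p_int + (1 - w_int_rel) * p_acc
  # f*p_nuc + (1-f)*p_rest = np_fraction
  f_nuc <- (np_fraction - p_rest) / (p_nuc - p_rest)
  stopifnot(f_nuc > 0, f_nuc < 1)
  n_rest <- total_number_cm3 * (1 - f_nuc)
  list(
    lognormal_mode(total_number_cm3 * f_nuc, nuc$cmd, nuc$gsd, nuc2_composition),
    lognormal_mode(n_rest * w_int_rel, int_mode$cmd, int_mode$gsd,
                   c(soot = 0.55, nv_pom = 0.45)),
    lognormal_mode(n_rest * (1 - w_int_rel), acc_mode$cmd, acc_mode$gsd,
                   c(soot = 0.45, nv_pom = 0.20, sv_om = 0.05, sulfate = 0.30))
  )
}

#' Urban background aerosol presets
#'
#' `helsinki` is a synthetic stand-in for the wintertime Helsinki urban
#' background (total PN 5400 cm^-3) with three modes and a composition
#' typical of aged urban aerosol. `zero` returns an empty state.
#'
#' @param preset `"helsinki"` or `"zero"`.
#' @param grid a [size_grid()].
#' @param temperature_K,rh carried into the state.
#' @return an [aerosol_state()].
#' @export
make_background_distribution <- function(preset = "helsinki", grid,
                                         temperature_K = 288, rh = 70) {
  preset <- match.arg(preset, c("helsinki", "zero"))
  if (preset == "zero") return(aerosol_state(grid, temperature_K = temperature_K, rh = rh))
  comp <- c(soot = 0.15, nv_pom = 0.20, sv_om = 0.25, sulfate = 0.40)
  modes <- list(
    lognormal_mode(5400 * 0.10, 10, 1.6, comp),
    lognormal_mode(5400 * 0.60, 28, 1.8, comp),
    lognormal_mode(5400 * 0.30, 95, 1.7, comp)
  )
  make_exhaust_distribution(modes, grid, temperature_K, rh)
}

#' Sample a power-law dilution curve
#'
#' Emulates receptor concentrations along the plume centerline,
#' y(x) = a x^-b, with optional multiplicative lognormal noise.
#'
#' @param a concentration scale (value at x = 1 m).
#' @param b dilution exponent (> 0 for a decaying plume).
#' @param distances_m distances from the stack, m (> 0).
#' @param noise_sd relative (lognormal) noise standard deviation; 0 for
#'   exact samples.
#' @param seed integer seed (noise is reproducible).
#' @return data.frame with columns `distance_m`, `concentration`.
#' @export
make_dilution_samples <- function(a, b, distances_m, noise_sd = 0, seed = 1) {
  stopifnot(a > 0, all(distances_m > 0), noise_sd >= 0)
  y <- a * distances_m^(-b)
  if (noise_sd > 0) {
    rng <- local({ set.seed(seed); stats::rnorm(length(y), 0, noise_sd) })
    y <- y * exp(rng)
  }
  data.frame(distance_m = distances_m, concentration = y)
}

# Ship-event table: per-event meteorology during the monitored arrivals and
# departures in Helsinki and Turku, plus synthetic per-event initial
# concentrations (diluted exhaust PN and SO3-derived H2SO4) standing in for
# the emission-data appendix. Columns month/hour come from the event id and
# start time and drive the daylight mapping for OH and j_NO2.
.ship_events <- local({
  df <- read.table(
    header = TRUE, stringsAsFactors = FALSE, text = "
event_id    site ta_K rh_pct u_ms wd_deg hour month pn_dil   h2so4_init
A_20110111  H2   271  90     4.3  289    11   1     2.0e6    2.0e10
A_20110912  H1   290  73     6.3  130    11   9     3.2e6    3.0e10
A_20110913  H2   290  82     4.8  213    11   9     3.0e6    2.8e10
B_20100803  H7   292  80     5.4  145    18   8     2.5e6    2.5e10
D_20110111  H2   274  81     5.1  232    17   1     2.2e6    2.2e10
D_20110908  H2   289  78     2.0  187    17   9     4.0e6    3.5e10
H_20100811  T8   292  71     5.5  249    8    8     2.8e6    2.6e10
H_20100817  T2   289  69     3.5  173    8    8     3.5e6    3.0e10
I_20100812  T2   295  61     3.0  233    19   8     3.0e6    2.5e10
I_20110207  T7   272  94     3.6  250    19   2     2.6e6    2.4e10
J_20100811  T7   292  72     4.6  219    9    8     3.2e6    3.0e10
J_20100817  T4   290  65     5.7  47     9    8     2.4e6    2.2e10
J_20110217  T2   258  79     2.4  175    7    2     4.5e6    4.0e10
K_20110802  T6   293  49     0.8  34     20   8     1.0e7    5.0e10
")
  df
})

# Stability class from wind speed and time of day: U >= 4 m/s in daytime ->
# unstable; 2-4 m/s -> neutral; < 2 m/s, or winter early morning -> stable.
event_stability <- function(u_ms, hour, month) {
  winter <- month %in% c(11, 12, 1, 2)
  daytime <- hour >= 8 & hour <= 18
  if (u_ms < 2 || (winter && hour < 9)) return("stable")
  if (u_ms >= 4 && daytime && !winter) return("unstable")
  "neutral"
}

#' Construct a ship event from the event table
#'
#' Returns the meteorology and (synthetic) initial-concentration record of
#' one of the 14 monitored ship arrivals/departures, plus the derived
#' stability class, dilution exponent and photochemistry drivers.
#'
#' @param event_id one of `ship_event_ids()`.
#' @return object of class `ship_event`: `air_temperature_K`, `rh_pct`,
#'   `wind_speed_ms`, `wind_direction_deg`, `stability`
#'   (unstable/neutral/stable), `b` (stability-dependent dilution exponent),
#'   `pn_diluted_cm3`, `h2so4_init_cm3`, `daylight`, `hour`, `month`.
#' @export
make_event <- function(event_id) {
  row <- .ship_events[.ship_events$event_id == event_id, ]
  if (nrow(row) != 1) stop("unknown ship event id: ", event_id)
  stab <- event_stability(row$u_ms, row$hour, row$month)
  b <- c(unstable = 1.40, neutral = 1.26, stable = 1.05)[[stab]]
  winter <- row$month %in% c(11, 12, 1, 2)
  daylight <- if (winter) row$hour >= 10 & row$hour <= 14 else row$hour >= 6 & row$hour <= 20
  structure(
    list(
      event_id = row$event_id, site = row$site,
      air_temperature_K = row$ta_K, rh_pct = row$rh_pct,
      wind_speed_ms = row$u_ms, wind_direction_deg = row$wd_deg,
      hour = row$hour, month = row$month,
      stability = stab, b = b, daylight = daylight,
      pn_diluted_cm3 = row$pn_dil, h2so4_init_cm3 = row$h2so4_init
    ),
    class = "ship_event"
  )
}

#' List the available ship event ids
#' @return character vector of 14 event ids.
#' @export
ship_event_ids <- function() .ship_events$event_id

#' ROPAX stack specification
#'
#' Default stack/exhaust parameters of the large ROPAX reference vessel:
#' funnel cross-section, exhaust exit velocity and exhaust temperature.
#'
#' @param S0_m2 funnel cross-sectional area, m^2 (default 0.785, a 1.0-m
#'   diameter funnel).
#' @param Vs_ms exhaust gas exit velocity, m s^-1 (default 30).
#' @param Te_K exhaust gas temperature, K (default 580).
#' @return object of class `stack_spec`.
#' @export
stack_spec <- function(S0_m2 = pi / 4, Vs_ms = 30, Te_K = 580) {
  stopifnot(S0_m2 > 0, Vs_ms >= 0, Te_K > 200)
  structure(list(S0_m2 = S0_m2, Vs_ms = Vs_ms, Te_K = Te_K),
            class = "stack_spec")
}

#' Synthetic population grid
#'
#' Generates a raster of inhabitants per 100 x 100 m^2 cell from Gaussian
#' population hotspots; counts are integer, nonnegative, and sum exactly to
#' the requested totals (multinomial assignment), reproducibly under `seed`.
#'
#' @param extent_m side length of the square domain, m (origin at the
#'   southwest corner; the ship anchor is the domain center).
#' @param hotspots list of `list(center = c(x, y), total = persons,
#'   sd_m = spread)`; empty list gives an all-zero grid.
#' @param seed integer seed.
#' @return object of class `population_grid`: `cell_size_m` (100),
#'   `x`, `y` (cell-center coordinates), `inhabitants` (matrix, rows = x).
#' @export
make_population_grid <- function(extent_m = 7200, hotspots = list(), seed = 1) {
  stopifnot(extent_m > 0)
  cs <- 100
  nc <- max(1L, as.integer(round(extent_m / cs)))
  xc <- (seq_len(nc) - 0.5) * cs
  pop <- matrix(0L, nc, nc)
  set.seed(seed)
  for (h in hotspots) {
    w <- outer(
      stats::dnorm(xc, h$center[1], h$sd_m),
      stats::dnorm(xc, h$center[2], h$sd_m)
    )
    if (sum(w) <= 0) next
    draw <- stats::rmultinom(1, size = h$total, prob = as.vector(w / sum(w)))
    pop <- pop + matrix(as.integer(draw), nc, nc)
  }
  structure(
    list(cell_size_m = cs, x = xc, y = xc, inhabitants = pop,
         extent_m = nc * cs),
    class = "population_grid"
  )
}
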