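# Reduced in-plume gas-phase chemistry. Only the pathways that control the
# condensable-vapor supply and the plume/background gas exchange are kept:
# fast hydration of co-emitted SO3 to H2SO4, OH-driven SO2 oxidation, the
# NO-NO2-O3 photostationary state, and power-law dilution of all gases
# toward their background values.

.gas_species <- c("no", "no2", "o3", "so2", "so3", "h2so4", "oh",
                  "c22h46", "c28h58", "c34h70")

#' Plume gas state
#'
#' All concentrations in molecules cm^-3.
#'
#' @param concentrations named numeric vector over (a subset of)
#'   no, no2, o3, so2, so3, h2so4, oh, c22h46, c28h58, c34h70; missing
#'   species are 0.
#' @param temperature_K air temperature, K.
#' @param rh relative humidity, percent.
#' @param time_s time since release, s.
#' @return object of class `gas_state`.
#' @export
gas_state <- function(concentrations = c(), temperature_K = 288, rh = 70,
                      time_s = 1) {
  conc <- stats::setNames(numeric(length(.gas_species)), .gas_species)
  if (length(concentrations)) {
    bad <- setdiff(names(concentrations), .gas_species)
    if (length(bad)) stop("unknown gas species: ", paste(bad, collapse = ", "))
    conc[names(concentrations)] <- concentrations
  }
  if (any(conc < 0)) stop("negative gas concentration")
  structure(list(conc = conc, temperature_K = temperature_K, rh = rh,
                 time_s = time_s),
            class = "gas_state")
}

#' @export
print.gas_state <- function(x, ...) {
  cat("<gas_state> molecules cm^-3 at t =", x$time_s, "s\n")
  print(signif(x$conc, 3))
  invisible(x)
}

# NO + O3 rate constant, cm^3 s^-1 (Arrhenius, standard evaluation).
k_no_o3 <- function(T) 1.4e-12 * exp(-1310 / T)

# SO2 + OH effective second-order rate constant, cm^3 s^-1 (termolecular,
# Troe form with k0 = 3.3e-31 (300/T)^4.3, kinf = 1.6e-12, Fc = 0.6).
k_so2_oh <- function(T, M = air_number_density(T)) {
  k0 <- 3.3e-31 * (300 / T)^4.3 * M
  kinf <- 1.6e-12
  x <- k0 / kinf
  (k0 / (1 + x)) * 0.6^(1 / (1 + log10(x)^2))
}

#' NO-NO2-O3 photostationary state
#'
#' Repartitions NO, NO2 and O3 to the photostationary state of the
#' NO2 photolysis / NO + O3 cycle, conserving total NOx (NO + NO2) and total
#' oxidant (O3 + NO2). At j_NO2 = 0 the available O3 titrates NO to NO2 up
#' to the limiting reagent.
#'
#' @param no,no2,o3 concentrations, molecules cm^-3.
#' @param j_no2 NO2 photolysis frequency, s^-1.
#' @param T temperature, K.
#' @return named vector (no, no2, o3).
#' @export
photostationary_state <- function(no, no2, o3, j_no2, T = 288) {
  stopifnot(no >= 0, no2 >= 0, o3 >= 0, j_no2 >= 0)
  nox <- no + no2
  ox <- o3 + no2
  k <- k_no_o3(T)
  if (nox == 0 || (ox == 0 && j_no2 == 0)) {
    return(c(no = no, no2 = no2, o3 = o3))
  }
  # k NO2^2 - (k (NOx + Ox) + j) NO2 + k NOx Ox = 0, smaller root
  bq <- k * (nox + ox) + j_no2
  disc <- bq^2 - 4 * k^2 * nox * ox
  no2_new <- (bq - sqrt(max(disc, 0))) / (2 * k)
  no2_new <- min(no2_new, nox, ox)
  c(no = nox - no2_new, no2 = no2_new, o3 = ox - no2_new)
}

#' Sulfuric-acid production over one chemistry substep
#'
#' SO3 hydrates to H2SO4 with a pseudo-first-order rate (fast relative to
#' dilution); SO2 is oxidized by OH with the standard termolecular rate.
#' Sulfur is conserved across SO2 + SO3 + H2SO4 (condensation and nucleation
#' sinks are applied elsewhere).
#'
#' @param state a [gas_state()].
#' @param dt substep, s (<= 0.1).
#' @param k_hydration SO3 + H2O pseudo-first-order rate, s^-1 (default 10).
#' @return updated [gas_state()].
#' @export
h2so4_production_step <- function(state, dt, k_hydration = 10) {
  stopifnot(dt > 0, dt <= 0.1 + 1e-12)
  cc <- state$conc
  d_so3 <- cc["so3"] * (1 - exp(-k_hydration * dt))
  d_so2 <- cc["so2"] * (1 - exp(-k_so2_oh(state$temperature_K) * cc["oh"] * dt))
  cc["so3"] <- cc["so3"] - d_so3
  cc["so2"] <- cc["so2"] - d_so2
  cc["h2so4"] <- cc["h2so4"] + d_so3 + d_so2
  state$conc <- cc
  state
}

#' Prescribed OH level for an event
#'
#' Daytime events use a constant in the 1-5e6 cm^-3 range (default 3e6);
#' nighttime and dark-winter events use 1e4 cm^-3.
#'
#' @param event a `ship_event`.
#' @param t time since release, s (unused by the default profile).
#' @param daytime_oh OH for daylight events, cm^-3 (default 3e6).
#' @param night_oh OH for dark events, cm^-3 (default 1e4).
#' @return OH concentration, molecules cm^-3.
#' @export
oh_level <- function(event, t = NULL, daytime_oh = 3e6, night_oh = 1e4) {
  if (isTRUE(event$daylight)) daytime_oh else night_oh
}

#' Prescribed NO2 photolysis frequency for an event
#'
#' @param event a `ship_event`.
#' @param summer_j,winter_j daylight values, s^-1.
#' @return j_NO2, s^-1 (0 for dark events).
#' @export
j_no2_level <- function(event, summer_j = 8e-3, winter_j = 2e-3) {
  if (!isTRUE(event$daylight)) return(0)
  if (event$month %in% c(11, 12, 1, 2)) winter_j else summer_j
}

#' Advance the gas phase by one time step
#'
#' Applies the reduced chemistry (SO3 hydration, SO2 + OH, photostationary
#' NO-NO2-O3) and then relaxes every species toward its background value with
#' the exact integral of dC/dt = -(b/t)(C - C_bg) over the step. Emitted
#' gases decay toward background; background O3 entrains (O3 rises toward
#' its background value without overshooting).
#'
#' @param state plume [gas_state()] at time `t`.
#' @param background background [gas_state()].
#' @param b dilution exponent.
#' @param t time since release, s (>= t0 > 0).
#' @param dt time step, s (<= 0.1).
#' @param j_no2 NO2 photolysis frequency, s^-1.
#' @param k_hydration SO3 hydration rate, s^-1.
#' @return updated [gas_state()] at `t + dt`.
#' @export
gas_step <- function(state, background, b, t, dt, j_no2 = 0, k_hydration = 10) {
  if (t <= 0) stop("gas_step requires t > 0")
  state <- h2so4_production_step(state, dt, k_hydration)
  pss <- photostationary_state(state$conc["no"], state$conc["no2"],
                               state$conc["o3"], j_no2, state$temperature_K)
  state$conc[c("no", "no2", "o3")] <- pss
  fac <- dilution_factor(b, t, dt)
  oh_hold <- state$conc["oh"]   # OH is prescribed, not diluted
  state$conc <- background$conc + (state$conc - background$conc) * fac
  state$conc["oh"] <- oh_hold
  state$time_s <- t + dt
  if (any(state$conc < -1e-6)) stop("negative gas concentration after step")
  state$conc[state$conc < 0] <- 0
  state
}
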