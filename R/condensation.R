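# Gas-particle mass transfer: analytical predictor of condensation (APC).
# The vapor is updated semi-analytically (implicit in the vapor, explicit in
# the per-section equilibrium concentrations), which conserves
# gas + particle mass of each species by construction. Equilibrium vapor
# concentrations over each section combine the pure-component saturation
# pressure (Clausius-Clapeyron), the Raoult mole-fraction term and the
# Kelvin curvature term. Sulfuric acid is treated as involatile.

# Saturation vapor concentration of a pure species, molecules cm^-3.
saturation_concentration <- function(species, T) {
  vp <- .vapor_table[.vapor_table$species == species, ]
  if (is.na(vp$psat_A)) return(0)
  psat <- exp(vp$psat_A - vp$psat_B / T)           # Pa
  psat / (.kB * T) * 1e-6
}

# Kelvin factor exp(4 sigma v_m / (kB T d)) for a particle of diameter d_nm.
kelvin_factor <- function(species, T, d_nm) {
  vp <- .vapor_table[.vapor_table$species == species, ]
  vm <- vp$M / (vp$rho * .NA)                      # molecular volume, m^3
  expo <- 4 * vp$sigma * vm / (.kB * T * (d_nm * 1e-9))
  exp(pmin(expo, 200))
}

# Mole fraction of the species in the absorbing particle phase per section.
# The two low-volatility alkanes share the SV-OM component equally; soot is
# non-absorbing.
raoult_mole_fraction <- function(state, species) {
  absorb <- c("nv_pom", "sv_om", "elv_om", "sulfate", "water")
  moles <- sweep(state$mass[, absorb, drop = FALSE], 2,
                 .comp_molar_mass[absorb], "/")
  tot <- rowSums(moles)
  comp <- .vapor_table$component[.vapor_table$species == species]
  share <- if (species %in% c("c22h46", "c28h58")) 0.5 else 1
  Mv <- .vapor_table$M[.vapor_table$species == species]
  x <- share * (state$mass[, comp] / Mv) / pmax(tot, 1e-300)
  x[tot <= 0] <- 0
  pmin(x, 1)
}

#' Equilibrium vapor concentration over a particle
#'
#' C_eq = C_sat(T) * x_mole * exp(4 sigma v_m / (kB T d)): the saturation
#' concentration modified by the Raoult mole-fraction term and the Kelvin
#' curvature term. Zero for sulfuric acid (involatile).
#'
#' @param species one of `vapor_properties()$species`.
#' @param T temperature, K.
#' @param state an [aerosol_state()] supplying the particle composition.
#' @param d_nm particle diameter(s), nm (defaults to section centers).
#' @return molecules cm^-3, per section.
#' @export
equilibrium_vapor_concentration <- function(species, T, state,
                                            d_nm = state$grid$centers_nm) {
  csat <- saturation_concentration(species, T)
  if (csat == 0) return(numeric(length(d_nm)))
  csat * raoult_mole_fraction(state, species) * kelvin_factor(species, T, d_nm)
}

# Per-particle transition-regime mass-transfer coefficient, cm^3 s^-1
# (2 pi d D * Fuchs-Sutugin correction, accommodation coefficient 1).
mass_transfer_coefficient <- function(species, T, d_nm) {
  vp <- .vapor_table[.vapor_table$species == species, ]
  D <- vp$D_air * (T / 298)^1.75
  cbar <- sqrt(8 * .Rgas * T / (pi * vp$M))        # m s^-1
  lam <- 3 * D / cbar
  d <- d_nm * 1e-9
  Kn <- 2 * lam / d
  beta <- (1 + Kn) / (1 + 1.71 * Kn + 1.333 * Kn^2)
  2 * pi * d * D * beta * 1e6                      # m^3 -> cm^3
}

#' One condensation/evaporation step (analytical predictor of condensation)
#'
#' For each condensable vapor the gas concentration is updated implicitly,
#' C' = (C + dt sum_i L_i Ceq_i) / (1 + dt sum_i L_i) with condensation sink
#' L_i = k_i N_i, and the per-section flux dt L_i (C' - Ceq_i) is added to
#' the corresponding particle component. Evaporation is limited to the mass
#' available in a section; the gas gets back exactly what the particles did
#' not keep, so gas + particle mass of each species is conserved to machine
#' precision.
#'
#' @param state an [aerosol_state()].
#' @param gases a [gas_state()].
#' @param dt time step, s (<= 0.1).
#' @param species vapors to transfer (default all condensable).
#' @return list `state`, `gases`.
#' @export
condensation_step <- function(state, gases, dt,
                              species = c("h2so4", "c22h46", "c28h58", "c34h70")) {
  stopifnot(dt > 0, dt <= 0.1 + 1e-12)
  T <- state$temperature_K
  d <- state$grid$centers_nm
  n <- state$number
  for (sp in species) {
    C <- gases$conc[[sp]]
    vp <- .vapor_table[.vapor_table$species == sp, ]
    L <- mass_transfer_coefficient(sp, T, d) * n       # s^-1 per section
    if (all(L == 0) || (C == 0 && all(state$mass[, vp$component] == 0))) next
    ceq <- equilibrium_vapor_concentration(sp, T, state, d)
    sumL <- sum(L)
    Cnew <- (C + dt * sum(L * ceq)) / (1 + dt * sumL)
    flux <- dt * L * (Cnew - ceq)                       # molecules cm^-3
    conv <- vp$M * 1e15 / .NA                           # molecules cm^-3 -> ug m^-3
    dm <- flux * conv
    # evaporation cannot remove more than the species' share of the component
    share <- if (sp %in% c("c22h46", "c28h58")) 0.5 else 1
    avail <- state$mass[, vp$component] * share
    dm <- pmax(dm, -avail)
    state$mass[, vp$component] <- state$mass[, vp$component] + dm
    gases$conc[[sp]] <- C - sum(dm) / conv
    if (gases$conc[[sp]] < 0) {
      # numerical safeguard; APC keeps this at rounding level
      state$mass[, vp$component] <- state$mass[, vp$component] +
        dm / sum(dm) * gases$conc[[sp]] * conv
      gases$conc[[sp]] <- 0
    }
  }
  list(state = state, gases = gases)
}

#' Project a sectional state back onto the fixed section centers
#'
#' After condensation (or nucleation insertion) the mean single-particle
#' volume of a section drifts away from the fixed section-center volume.
#' Each section's content is reassigned to the two sections whose center
#' volumes bracket its current mean particle volume, splitting the number so
#' that both number and total volume (hence each component's mass) are
#' conserved exactly. This is the growth operator of the fixed sectional
#' method.
#'
#' @param state an [aerosol_state()].
#' @return regridded [aerosol_state()].
#' @export
regrid_state <- function(state) {
  g <- state$grid
  vc <- g$volumes_cm3
  ns <- g$n_sections
  n <- state$number
  nz <- which(n > 0)
  if (!length(nz)) return(state)
  vbar <- mean_particle_volume(state)
  k <- findInterval(vbar, vc)
  # sections whose mean volume stays bracketed by their own center need no move
  new_n <- numeric(ns)
  new_m <- state$mass * 0
  for (i in nz) {
    ki <- k[i]
    if (ki < 1) {
      new_n[1] <- new_n[1] + n[i]
      new_m[1, ] <- new_m[1, ] + state$mass[i, ]
    } else if (ki >= ns) {
      new_n[ns] <- new_n[ns] + n[i]
      new_m[ns, ] <- new_m[ns, ] + state$mass[i, ]
    } else {
      f <- (vc[ki + 1] - vbar[i]) / (vc[ki + 1] - vc[ki])
      f <- min(max(f, 0), 1)
      new_n[ki] <- new_n[ki] + f * n[i]
      new_n[ki + 1] <- new_n[ki + 1] + (1 - f) * n[i]
      wk <- f * vc[ki] / vbar[i]
      new_m[ki, ] <- new_m[ki, ] + wk * state$mass[i, ]
      new_m[ki + 1, ] <- new_m[ki + 1, ] + (1 - wk) * state$mass[i, ]
    }
  }
  state$number <- new_n
  state$mass <- new_m
  state
}
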