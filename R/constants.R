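# Physical constants (SI) and component/vapor property tables used across the
# aerosol, chemistry and dilution modules.

.kB <- 1.380649e-23      # Boltzmann constant, J K^-1
.NA <- 6.02214076e23     # Avogadro constant, mol^-1
.Rgas <- 8.314462618     # molar gas constant, J mol^-1 K^-1
.P0 <- 101325            # standard pressure, Pa
.g0 <- 9.80665           # gravitational acceleration, m s^-2

#' Aerosol component names
#'
#' The multicomponent particle phase carries five dry components plus
#' diagnosed water: soot (elemental carbon), nonvolatile primary organic
#' matter (NV-POM), semivolatile organic matter (SV-OM), extremely
#' low-volatility organic matter (ELV-OM), sulfate (carried as H2SO4 mass)
#' and water.
#'
#' @return Character vector of component names.
#' @export
aerosol_components <- function() {
  c("soot", "nv_pom", "sv_om", "elv_om", "sulfate", "water")
}

#' Dry aerosol component names (water excluded)
#' @return Character vector.
#' @export
dry_components <- function() setdiff(aerosol_components(), "water")

# Component bulk densities, kg m^-3. Standard aerosol values: soot 1800,
# organic matter 1000, sulfate carried as liquid H2SO4 1830, water 1000.
.comp_density <- c(
  soot = 1800, nv_pom = 1000, sv_om = 1000, elv_om = 1000,
  sulfate = 1830, water = 1000
)

# Component molar masses, kg mol^-1 (used for Raoult mole fractions).
# Organics are represented by their proxy n-alkanes; NV-POM by a generic
# heavy organic; soot is treated as non-absorbing (no Raoult contribution).
.comp_molar_mass <- c(
  soot = 0.012, nv_pom = 0.400, sv_om = 0.353, elv_om = 0.479,
  sulfate = 0.098, water = 0.018
)

# Condensable vapor property table. Vapors: sulfuric acid and the three
# n-alkane proxies (two low-volatility, one extremely low-volatility,
# the latter a lubrication-oil constituent). psat follows a
# Clausius-Clapeyron form ln psat [Pa] = A - B/T; H2SO4 is treated as
# effectively involatile (saturation concentration zero).
# `component` maps each condensed vapor to the particle component it feeds.
.vapor_table <- data.frame(
  species   = c("h2so4", "c22h46", "c28h58", "c34h70"),
  M         = c(0.098078, 0.31060, 0.39476, 0.47892),    # kg mol^-1
  rho       = c(1830, 1000, 1000, 1000),                 # kg m^-3
  D_air     = c(9.4e-6, 5.0e-6, 4.2e-6, 3.6e-6),         # m^2 s^-1 at ~298 K
  sigma     = c(0.055, 0.030, 0.030, 0.030),             # surface tension N m^-1
  psat_A    = c(NA, 37.77, 40.93, 41.78),
  psat_B    = c(NA, 14000, 17000, 20000),                # K
  component = c("sulfate", "sv_om", "sv_om", "elv_om"),
  stringsAsFactors = FALSE
)

#' Condensable vapor property table
#'
#' @return data.frame with one row per condensable vapor (h2so4, c22h46,
#'   c28h58, c34h70): molar mass `M` (kg/mol), liquid density `rho`
#'   (kg/m3), gas diffusivity `D_air` (m2/s), surface tension `sigma`
#'   (N/m), Clausius-Clapeyron constants `psat_A`, `psat_B`
#'   (ln psat\[Pa\] = A - B/T; NA for H2SO4, treated as involatile) and the
#'   particle `component` the condensed vapor is assigned to.
#' @export
vapor_properties <- function() .vapor_table

#' Component densities
#' @return Named numeric vector, kg m^-3.
#' @export
component_densities <- function() .comp_density

# Dynamic viscosity of air, kg m^-1 s^-1 (Sutherland).
air_viscosity <- function(T) 1.458e-6 * T^1.5 / (T + 110.4)

# Mean free path of air molecules, m.
air_mean_free_path <- function(T, P = .P0) {
  2 * air_viscosity(T) / (P * sqrt(8 * 0.028966 / (pi * .Rgas * T)))
}

# Number density of air, molecules cm^-3.
air_number_density <- function(T, P = .P0) P / (.kB * T) * 1e-6

#' Convert gas concentration from micrograms per cubic meter to molecules per
#' cubic centimeter
#'
#' @param ugm3 concentration in ug m^-3.
#' @param M molar mass in kg mol^-1.
#' @return molecules cm^-3.
#' @export
ugm3_to_molec <- function(ugm3, M) ugm3 * 1e-9 / (M * 1e3) * .NA * 1e-6 * 1e3

#' Convert gas concentration from molecules per cubic centimeter to micrograms
#' per cubic meter
#'
#' @param n concentration in molecules cm^-3.
#' @param M molar mass in kg mol^-1.
#' @return ug m^-3.
#' @export
molec_to_ugm3 <- function(n, M) n / (.NA * 1e-6 * 1e3) * (M * 1e3) * 1e9
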