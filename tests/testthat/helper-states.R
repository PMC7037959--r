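# Shared fixtures, built in code: a coarse grid for fast microphysics tests
# and a few canonical states.

coarse_grid <- function(n = 60) size_grid(n_sections = n)

# Monodisperse state: N particles in the section whose center is nearest
# d_nm, with consistent single-component mass.
monodisperse_state <- function(grid, d_nm, number_cm3, component = "sulfate",
                               temperature_K = 288, rh = 70) {
  sec <- which.min(abs(grid$centers_nm - d_nm))
  n <- numeric(grid$n_sections)
  n[sec] <- number_cm3
  rho <- component_densities()[component] * 1e-3
  m <- matrix(0, grid$n_sections, 1, dimnames = list(NULL, component))
  m[sec, 1] <- number_cm3 * grid$volumes_cm3[sec] * rho * 1e12
  aerosol_state(grid, n, m, temperature_K, rh)
}

default_exhaust <- function(grid = size_grid()) {
  make_exhaust_distribution(exhaust_modes_preset(), grid)
}

# Combined condensable mass (all vapor species as mass + the particle
# components they feed), ug m^-3; conserved by a condensation step.
condensable_total_mass <- function(state, gases) {
  vp <- vapor_properties()
  conv <- vp$M * 1e15 / 6.02214076e23
  gas_mass <- sum(vapply(seq_len(nrow(vp)), function(i)
    gases$conc[[vp$species[i]]] * conv[i], numeric(1)))
  gas_mass + sum(state$mass[, unique(vp$component)])
}
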