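# Dry deposition and mixing with background aerosol.

#' Size-dependent dry deposition velocity
#'
#' Smooth-surface resistance parameterization: gravitational settling plus
#' the serial aerodynamic and quasi-laminar resistances,
#' v_d = v_s + 1/(r_a + r_b), with
#' r_b = 1 / (u* (Sc^-2/3 + 10^(-3/St))).
#'
#' @param d_nm particle diameter(s), nm.
#' @param u_star friction velocity, m s^-1 (default 0.3).
#' @param r_a aerodynamic resistance, s m^-1 (default 40).
#' @param T temperature, K.
#' @param rho_p particle density, kg m^-3.
#' @return deposition velocity, m s^-1.
#' @export
deposition_velocity <- function(d_nm, u_star = 0.3, r_a = 40, T = 288,
                                rho_p = 1400) {
  d <- d_nm * 1e-9
  mu <- air_viscosity(T)
  lam <- air_mean_free_path(T)
  Kn <- 2 * lam / d
  Cc <- 1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn))
  vs <- rho_p * d^2 * .g0 * Cc / (18 * mu)
  D <- .kB * T * Cc / (3 * pi * mu * d)
  nu <- mu / 1.2
  Sc <- nu / D
  St <- vs * u_star^2 / (.g0 * nu)
  rb <- 1 / (u_star * (Sc^(-2 / 3) + 10^(-3 / pmax(St, 1e-10))))
  vs + 1 / (r_a + rb)
}

#' One dry-deposition step
#'
#' First-order loss per section at rate v_d(Dp)/H_P, applied as an exact
#' exponential decay of both number and mass.
#'
#' @param state an [aerosol_state()].
#' @param dt time step, s.
#' @param H_P plume height, m (> 0).
#' @param v_d optional deposition velocities per section (m s^-1); computed
#'   from [deposition_velocity()] when missing.
#' @param ... passed to [deposition_velocity()].
#' @return updated state.
#' @export
dry_deposition_step <- function(state, dt, H_P, v_d = NULL, ...) {
  stopifnot(H_P > 0, dt > 0)
  if (is.null(v_d))
    v_d <- deposition_velocity(state$grid$centers_nm, T = state$temperature_K, ...)
  fac <- exp(-v_d * dt / H_P)
  state$number <- state$number * fac
  state$mass <- state$mass * fac
  state
}

#' One background-entrainment (dilution) step for particles
#'
#' Applies dN_i/dt = -(b/t)(N_i - N_BG,i) per section to the number and,
#' proportionally, per component to the mass, using the exact integral of
#' the dilution ODE over the step (no overshoot for any b > 0).
#'
#' @param state plume [aerosol_state()].
#' @param background background [aerosol_state()] on the same grid.
#' @param b dilution exponent.
#' @param t time since release, s (>= t0 > 0).
#' @param dt time step, s.
#' @return updated state.
#' @export
background_mixing_step <- function(state, background, b, t, dt) {
  if (t <= 0) stop("background mixing requires t > 0")
  stopifnot(identical(state$grid$n_sections, background$grid$n_sections))
  fac <- dilution_factor(b, t, dt)
  state$number <- background$number + (state$number - background$number) * fac
  state$mass <- background$mass + (state$mass - background$mass) * fac
  state$number[state$number < 0] <- 0
  state$mass[state$mass < 0] <- 0
  state
}
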