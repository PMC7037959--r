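# Two-stage dilution model. Stage 1: jet expansion of the exhaust over the
# first second after release, giving the first-stage dilution ratio DR and
# the initial in-plume temperature. Stage 2: empirical power-law decay of
# plume concentrations with downwind distance, with the plume height growing
# through a sigma_z-type dispersion term; every plume quantity relaxes
# toward its background value at the rate -(b/t)(C - C_bg).

#' Plume entrainment velocity
#'
#' sigma_w = sqrt((alpha U)^2 + sigma_wt^2 + (alpha u_jet)^2): turbulent
#' entrainment from the ambient wind, traffic-generated turbulence (zero for
#' ship events) and the jet effect of the exhaust gas.
#'
#' @param U mean wind speed, m s^-1.
#' @param u_jet plume jet velocity, m s^-1 (set equal to the exhaust exit
#'   velocity and held constant over the 1-s first stage).
#' @param sigma_wt traffic-generated turbulence, m s^-1 (default 0).
#' @param alpha proportionality constant wind -> mechanical turbulence
#'   (default 0.1).
#' @return entrainment velocity, m s^-1.
#' @export
entrainment_velocity <- function(U, u_jet, sigma_wt = 0, alpha = 0.1) {
  stopifnot(U >= 0, u_jet >= 0, sigma_wt >= 0, alpha >= 0)
  sqrt((alpha * U)^2 + sigma_wt^2 + (alpha * u_jet)^2)
}

#' Jet-expansion plume cross-section
#'
#' S(t) = (sqrt(S0) + t sigma_w)^2 - (t alpha V_S)^2. If the printed form
#' yields S(t) < S0 (a regime the expansion model does not describe) the
#' result is floored at S0 with a warning; a nonpositive area is an error.
#'
#' @param stack a [stack_spec()].
#' @param sigma_w entrainment velocity at release, m s^-1.
#' @param t time since release, s.
#' @param alpha turbulence proportionality constant (default 0.1).
#' @return cross-sectional area, m^2.
#' @export
plume_cross_section <- function(stack, sigma_w, t, alpha = 0.1) {
  S <- (sqrt(stack$S0_m2) + t * sigma_w)^2 - (t * alpha * stack$Vs_ms)^2
  if (any(S <= 0)) stop("nonpositive plume cross-section")
  if (any(S < stack$S0_m2 * (1 - 1e-12))) {
    warning("plume cross-section below the stack area; floored at S0")
    S <- pmax(S, stack$S0_m2)
  }
  S
}

#' First-stage dilution ratio
#'
#' DR = S(t_end)/S0 with the jet-expansion cross-section; the first dilution
#' stage ends 1 s after release.
#'
#' @param stack a [stack_spec()].
#' @param event a `ship_event` (or any list with `wind_speed_ms`).
#' @param alpha turbulence proportionality constant (default 0.1).
#' @param t_end duration of the first stage, s (default 1).
#' @param sigma_wt traffic turbulence, m s^-1 (default 0).
#' @return dimensionless DR >= 1.
#' @export
first_stage_dilution_ratio <- function(stack, event, alpha = 0.1, t_end = 1,
                                       sigma_wt = 0) {
  sw <- entrainment_velocity(event$wind_speed_ms, stack$Vs_ms, sigma_wt, alpha)
  plume_cross_section(stack, sw, t_end, alpha) / stack$S0_m2
}

#' Fraction of particles remaining after first-stage dilution alone
#'
#' Dilution by the factor DR leaves 1/DR of the stack concentration; for the
#' reference DR = 8 this is 0.125. Reported separately from the coagulation
#' fraction.
#'
#' @param DR first-stage dilution ratio (>= 1).
#' @return 1/DR.
#' @export
first_stage_fraction_remaining <- function(DR) {
  stopifnot(DR >= 1)
  1 / DR
}

#' In-plume temperature after the first dilution stage
#'
#' T_P = T_A + (T_E - T_A)/DR.
#'
#' @param T_A ambient air temperature, K.
#' @param T_E exhaust gas temperature, K.
#' @param DR first-stage dilution ratio (>= 1).
#' @return plume temperature, K.
#' @export
initial_plume_temperature <- function(T_A, T_E, DR) {
  if (DR < 1) stop("DR must be >= 1")
  T_A + (T_E - T_A) / DR
}

#' Fraction of particles surviving coagulation during first-stage expansion
#'
#' Coagulation competes with the super-linear plume expansion during the
#' first second. The surviving number fraction (dilution excluded) is
#' obtained by integrating monodisperse Smoluchowski loss inside the
#' analytically expanding cross-section:
#' dn/dt = -1/2 K n^2 - (S'/S) n, fraction = n(t) S(t) / (n0 S0).
#' The kernel is the Fuchs Brownian kernel at the exhaust count-median
#' diameter times a polydisperse-enhancement factor.
#'
#' @param initial_PN particle number concentration at the stack exit, cm^-3
#'   (diluted-exhaust PN times DR).
#' @param stack a [stack_spec()].
#' @param event a `ship_event` (wind speed drives the expansion).
#' @param cmd_nm exhaust count-median diameter for the kernel, nm (default 40).
#' @param kernel_scale polydisperse enhancement of the monodisperse kernel
#'   (default 25).
#' @param t_end end of the first stage, s (default 1).
#' @param alpha turbulence constant (default 0.1).
#' @param temperature_K kernel temperature, K (default the event's T_A).
#' @return fraction in (0, 1].
#' @export
coagulation_fraction_remaining <- function(initial_PN, stack, event,
                                           cmd_nm = 40, kernel_scale = 25,
                                           t_end = 1, alpha = 0.1,
                                           temperature_K = NULL) {
  stopifnot(initial_PN >= 0)
  if (initial_PN == 0) return(1)
  Tk <- if (is.null(temperature_K)) event$air_temperature_K else temperature_K
  K <- kernel_scale * fuchs_kernel(cmd_nm, cmd_nm, Tk)   # cm^3 s^-1
  sw <- entrainment_velocity(event$wind_speed_ms, stack$Vs_ms, 0, alpha)
  S_of <- function(t) {
    pmax((sqrt(stack$S0_m2) + t * sw)^2 - (t * alpha * stack$Vs_ms)^2,
         stack$S0_m2)
  }
  # RK4 on n(t); fraction excludes dilution via n S / (n0 S0)
  dt <- 1e-3
  tt <- seq(0, t_end, by = dt)
  n <- initial_PN
  A <- sqrt(stack$S0_m2); B <- sw; C <- alpha * stack$Vs_ms
  dlogS <- function(t) {
    Sraw <- (A + B * t)^2 - (C * t)^2
    if (Sraw <= stack$S0_m2) return(0)  # floored regime: no expansion
    (2 * B * (A + B * t) - 2 * C^2 * t) / Sraw
  }
  f <- function(t, n) -0.5 * K * n^2 - dlogS(t) * n
  for (i in seq_len(length(tt) - 1)) {
    t0 <- tt[i]
    k1 <- f(t0, n)
    k2 <- f(t0 + dt / 2, n + dt / 2 * k1)
    k3 <- f(t0 + dt / 2, n + dt / 2 * k2)
    k4 <- f(t0 + dt, n + dt * k3)
    n <- n + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (n < 0) n <- 0
  }
  min(n * S_of(t_end) / (initial_PN * stack$S0_m2), 1)
}

#' Fit a power-law dilution curve
#'
#' Ordinary least squares of log(y) on log(x) for y(x) = a x^-b. Samples are
#' expected background-subtracted and ordered by increasing distance from
#' the concentration maximum; nonpositive concentrations (and points at
#' distance 0) are dropped with a warning.
#'
#' @param samples data.frame with columns `distance_m`, `concentration`
#'   (background already subtracted), or `background` column to subtract.
#' @return list with `a`, `b`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(samples) {
  y <- samples$concentration
  if (!is.null(samples$background)) y <- y - samples$background
  x <- samples$distance_m
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (any(!ok)) warning(sum(!ok), " nonpositive/invalid points dropped")
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 valid points for the power-law fit")
  fit <- stats::lm(log(y) ~ log(x))
  # summary.lm warns on exact fits; r^2 is still well defined
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(
    a = exp(unname(stats::coef(fit)[1])),
    b = -unname(stats::coef(fit)[2]),
    r_squared = r2,
    n_points = length(x)
  )
}

#' Stability-dependent vertical dispersion scale a'
#'
#' sigma_z = a' x^b with a' = 110.62, 86.49 or 61.14 (m per km^b) for
#' unstable, neutral and stable conditions.
#'
#' @param stability one of `"unstable"`, `"neutral"`, `"stable"`.
#' @return a' value.
#' @export
sigma_z_scale <- function(stability) {
  c(unstable = 110.62, neutral = 86.49, stable = 61.14)[[
    match.arg(stability, c("unstable", "neutral", "stable"))]]
}

#' Second-stage dilution parameters
#'
#' @param DR first-stage dilution ratio.
#' @param a power-law concentration scale.
#' @param b power-law dilution exponent (> 0).
#' @param H_P0 initial plume height after the first stage, m (default 5.5).
#' @param stability stability class selecting a' (default neutral).
#' @param t0 reference time at which the second stage starts, s (default 1).
#' @return object of class `dilution_params`.
#' @export
dilution_params <- function(DR = 8, a = 5000, b = 1.26, H_P0 = 5.5,
                            stability = "neutral", t0 = 1) {
  stopifnot(DR >= 1, b > 0, H_P0 > 0, t0 > 0)
  structure(
    list(DR = DR, a = a, b = b, H_P0 = H_P0,
         a_prime = sigma_z_scale(stability), stability = stability, t0 = t0),
    class = "dilution_params"
  )
}

#' Time-dependent plume height
#'
#' H_P(t) = sqrt(H_P0^2 + (a' (1e-3 U t)^b)^2); the downwind distance
#' enters in km.
#'
#' @param t time since release, s (>= 0).
#' @param U wind speed, m s^-1.
#' @param params a [dilution_params()].
#' @return plume height, m (monotone nondecreasing in t).
#' @export
plume_height <- function(t, U, params) {
  stopifnot(all(t >= 0), U >= 0)
  sqrt(params$H_P0^2 + (params$a_prime * (1e-3 * U * t)^params$b)^2)
}

#' Dilution tendency toward background
#'
#' dC/dt = -(b/t) (C - C_bg), applied identically to gas concentrations and
#' to every particle section/component.
#'
#' @param value in-plume concentration.
#' @param background_value background concentration.
#' @param b dilution exponent.
#' @param t time since release, s (> 0).
#' @return rate, concentration units per second.
#' @export
dilution_tendency <- function(value, background_value, b, t) {
  if (any(t <= 0)) stop("dilution tendency requires t > 0")
  -(b / t) * (value - background_value)
}

# Exact update factor for the dilution ODE over [t, t+dt]:
# C(t+dt) - C_bg = (C(t) - C_bg) * ((t+dt)/t)^-b. Never overshoots.
dilution_factor <- function(b, t, dt) ((t + dt) / t)^(-b)

#' Grid convergence index
#'
#' GCI_21 = F_s e_21 / (r_21^p - 1): discretization-error estimate of the
#' fine-grid solution from two grid refinements.
#'
#' @param e21 relative error between the two finest grids (>= 0).
#' @param r21 grid refinement ratio (> 1).
#' @param p observed order of convergence (> 0).
#' @param F_s safety factor (default 1.25).
#' @return dimensionless GCI.
#' @export
grid_convergence_index <- function(e21, r21, p, F_s = 1.25) {
  stopifnot(e21 >= 0, p > 0, F_s >= 1)
  if (r21 <= 1) stop("refinement ratio must exceed 1")
  F_s * e21 / (r21^p - 1)
}
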