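#' Fixed log-spaced diameter sections
#'
#' Builds the fixed sectional size grid on which all aerosol states live.
#' Sections are log-spaced in diameter between `d_min_nm` and `d_max_nm`;
#' section centers are the geometric means of the edges and never move
#' (growth transfers number and mass between sections).
#'
#' @param n_sections number of sections (default 120).
#' @param d_min_nm lower diameter bound, nm (default 1; must contain the
#'   ~1.5 nm freshly nucleated mode).
#' @param d_max_nm upper diameter bound, nm (default 1e4 = 10 um).
#' @return object of class `size_grid` with elements `edges_nm`,
#'   `centers_nm`, `volumes_cm3` (single-particle volume at the section
#'   center), `n_sections`.
#' @export
size_grid <- function(n_sections = 120, d_min_nm = 1, d_max_nm = 1e4) {
  stopifnot(n_sections >= 2, d_min_nm > 0, d_max_nm > d_min_nm)
  edges <- 10^seq(log10(d_min_nm), log10(d_max_nm), length.out = n_sections + 1)
  centers <- sqrt(edges[-1] * edges[-(n_sections + 1)])
  vol <- (pi / 6) * (centers * 1e-7)^3   # cm^3 (1 nm = 1e-7 cm)
  structure(
    list(
      n_sections = n_sections,
      edges_nm = edges,
      centers_nm = centers,
      volumes_cm3 = vol,
      edge_volumes_cm3 = (pi / 6) * (edges * 1e-7)^3
    ),
    class = "size_grid"
  )
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf(
    "<size_grid> %d log-spaced sections, %.3g-%.3g nm\n",
    x$n_sections, x$edges_nm[1], x$edges_nm[length(x$edges_nm)]
  ))
  invisible(x)
}

#' Multicomponent sectional aerosol state
#'
#' Per-section particle number concentration plus per-section, per-component
#' mass concentrations on a fixed [size_grid()].
#'
#' @param grid a [size_grid()].
#' @param number numeric vector of length `grid$n_sections`, cm^-3.
#' @param mass matrix (`n_sections` x components, columns named as in
#'   [aerosol_components()]), ug m^-3. Missing columns are filled with 0.
#' @param temperature_K air temperature, K.
#' @param rh relative humidity, percent.
#' @return object of class `aerosol_state`.
#' @export
aerosol_state <- function(grid, number = NULL, mass = NULL,
                          temperature_K = 288, rh = 70) {
  stopifnot(inherits(grid, "size_grid"))
  ns <- grid$n_sections
  comps <- aerosol_components()
  if (is.null(number)) number <- numeric(ns)
  stopifnot(length(number) == ns)
  m <- matrix(0, ns, length(comps), dimnames = list(NULL, comps))
  if (!is.null(mass)) {
    stopifnot(nrow(mass) == ns, !is.null(colnames(mass)))
    bad <- setdiff(colnames(mass), comps)
    if (length(bad)) stop("unknown components: ", paste(bad, collapse = ", "))
    m[, colnames(mass)] <- as.matrix(mass)
  }
  if (any(number < 0) || any(m < 0)) stop("negative number or mass concentration")
  structure(
    list(grid = grid, number = number, mass = m,
         temperature_K = temperature_K, rh = rh),
    class = "aerosol_state"
  )
}

#' @export
print.aerosol_state <- function(x, ...) {
  cat(sprintf(
    "<aerosol_state> total N = %.4g cm^-3, dry mass = %.4g ug m^-3 (%d sections)\n",
    total_number(x), sum(x$mass[, dry_components()]), x$grid$n_sections
  ))
  invisible(x)
}

#' Total particle number concentration
#'
#' @param state an [aerosol_state()].
#' @param d_min_nm,d_max_nm optional diameter window (section centers), nm.
#' @return cm^-3.
#' @export
total_number <- function(state, d_min_nm = -Inf, d_max_nm = Inf) {
  d <- state$grid$centers_nm
  sum(state$number[d >= d_min_nm & d < d_max_nm])
}

#' Total dry mass concentration per component in a diameter window
#'
#' @param state an [aerosol_state()].
#' @param d_min_nm,d_max_nm diameter window (section centers), nm.
#' @return named vector, ug m^-3, over [dry_components()].
#' @export
component_dry_mass <- function(state, d_min_nm = -Inf, d_max_nm = Inf) {
  d <- state$grid$centers_nm
  sel <- d >= d_min_nm & d < d_max_nm
  colSums(state$mass[sel, dry_components(), drop = FALSE])
}

#' Dry-mass fractions from component masses
#'
#' Normalizes a vector of component mass concentrations to fractions summing
#' to one. Used both for model diagnostics and for cross-checking printed
#' composition tables.
#'
#' @param mass named numeric vector of dry component masses (any unit).
#' @return named fractions summing to 1 (all zero if the total is 0).
#' @export
dry_mass_fractions <- function(mass) {
  tot <- sum(mass)
  if (tot <= 0) return(mass * 0)
  mass / tot
}

#' Number size distribution dN/dlogDp
#'
#' @param state an [aerosol_state()].
#' @return numeric vector, cm^-3 per decade of diameter.
#' @export
dNdlogDp <- function(state) {
  e <- state$grid$edges_nm
  state$number / diff(log10(e))
}

# Total particle volume per section from component masses, cm^3 cm^-3 air.
# mass ug m^-3 -> g cm^-3 = 1e-12; / density g cm^-3.
section_volume <- function(state, components = aerosol_components()) {
  rho <- .comp_density[components] * 1e-3      # g cm^-3
  as.numeric(state$mass[, components, drop = FALSE] %*% (1 / rho)) * 1e-12
}

# Mean single-particle volume per section, cm^3; falls back to the section
# center volume where a section is empty.
mean_particle_volume <- function(state, dry_only = TRUE) {
  comps <- if (dry_only) dry_components() else aerosol_components()
  v <- section_volume(state, comps)
  out <- state$grid$volumes_cm3
  nz <- state$number > 0 & v > 0
  out[nz] <- v[nz] / state$number[nz]
  out
}

#' Check number/mass consistency of a sectional state
#'
#' The per-section mean particle volume implied by the component masses must
#' stay within a tolerance factor of the section's center volume (fixed-grid
#' consistency). Empty sections are ignored.
#'
#' @param state an [aerosol_state()].
#' @param tol_factor allowed multiplicative drift (default 2).
#' @return logical; attributes carry the worst ratio.
#' @export
check_volume_consistency <- function(state, tol_factor = 2) {
  vbar <- mean_particle_volume(state)
  vc <- state$grid$volumes_cm3
  nz <- state$number > 0
  ratio <- vbar[nz] / vc[nz]
  ok <- length(ratio) == 0 || all(ratio < tol_factor & ratio > 1 / tol_factor)
  structure(ok, worst = if (length(ratio)) max(abs(log(ratio))) else 0)
}

#' Diagnose equilibrium water uptake on the sulfate fraction
#'
#' Water is not transported kinetically; it is diagnosed from a
#' single-parameter (kappa-type) equilibrium on the hygroscopic sulfate
#' volume: V_w = kappa * V_sulfate * aw/(1-aw), with water activity aw = RH/100
#' (clamped at 0.95). The water column of the state is replaced.
#'
#' @param state an [aerosol_state()].
#' @param kappa hygroscopicity of the sulfate component (default 0.9).
#' @return updated state.
#' @export
equilibrate_water <- function(state, kappa = 0.9) {
  aw <- min(max(state$rh, 0) / 100, 0.95)
  v_sulf <- state$mass[, "sulfate"] * 1e-12 / (.comp_density["sulfate"] * 1e-3)
  v_w <- kappa * v_sulf * aw / (1 - aw)
  state$mass[, "water"] <- v_w * (.comp_density["water"] * 1e-3) * 1e12
  state
}
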