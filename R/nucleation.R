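# Binary homogeneous H2SO4-H2O nucleation (BHN) via the published polynomial
# parameterization of the classical theory (mole fraction, rate, cluster
# content and radius as polynomial fits in temperature, RH and sulfuric-acid
# concentration), with its applicability extended to exhaust temperatures
# (up to 400 K). A heterogeneous variant (HET) augments the BHN rate with an
# organic-availability factor and adds the organic vapor to the cluster.

# Mole fraction of H2SO4 in the critical cluster.
bhn_mole_fraction <- function(T, rh_frac, na) {
  lna <- log(na); lrh <- log(rh_frac)
  0.740997 - 0.00266379 * T - 0.00349998 * lna + 0.0000504022 * T * lna +
    0.00201048 * lrh - 0.000183289 * T * lrh + 0.00157407 * lrh^2 -
    0.0000179059 * T * lrh^2 + 0.000184403 * lrh^3 - 1.50345e-6 * T * lrh^3
}

# Coefficient polynomials for ln(J). Each row: intercept, T, T^2, T^3, 1/x.
.bhn_J_coef <- matrix(c(
  0.14309,    2.21956,    -0.0273911,   0.0000722811,  5.91822,
  0.117489,   0.462532,   -0.0118059,   0.0000404196, 15.7963,
 -0.215554,  -0.0810269,   0.00143581, -4.7758e-6,    -2.91297,
 -3.58856,    0.049508,   -0.00021382,  3.10801e-7,   -0.0293333,
  1.14598,   -0.600796,    0.00864245, -0.0000228947, -8.44985,
  2.15855,    0.0808121,  -0.000407382,-4.01957e-7,    0.721326,
  1.6241,    -0.0160106,   0.0000377124,3.21794e-8,   -0.0113255,
  9.71682,   -0.115048,    0.000157098, 4.00914e-7,    0.71186,
 -1.05611,    0.00903378, -0.0000198417,2.46048e-8,   -0.0579087,
 -0.148712,   0.00283508, -9.24619e-6,  5.00427e-9,   -0.0127081
), nrow = 10, byrow = TRUE)

# Coefficient polynomials for ln(Ntot) (total molecules in the cluster).
.bhn_N_coef <- matrix(c(
 -0.00295413, -0.0976834,   0.00102485,  -2.18646e-6,  -0.101717,
 -0.00205064, -0.00758504,  0.000192654, -6.7043e-7,   -0.255774,
  0.00322308,  0.000852637,-0.0000154757, 5.66661e-8,   0.0338444,
  0.0474323,  -0.000625104, 2.65066e-6,  -3.67471e-9,  -0.000267251,
 -0.0125211,   0.00580655, -0.000101674,  2.88195e-7,   0.0942243,
 -0.038546,   -0.000672316, 2.60288e-6,   1.19416e-8,  -0.00851515,
 -0.0183749,   0.000172072,-3.71766e-7,  -5.14875e-10,  0.000268660,
 -0.0619974,   0.000906958,-9.11728e-7,  -5.36796e-9,  -0.00774234,
  0.0121827,  -0.00010665,  2.5346e-7,   -3.63519e-10,  0.000610065,
  0.000320184,-0.0000174762,6.06504e-8,  -1.4177e-11,   0.000135751
), nrow = 10, byrow = TRUE)

bhn_poly <- function(coef, T, x) {
  coef[, 1] + coef[, 2] * T + coef[, 3] * T^2 + coef[, 4] * T^3 + coef[, 5] / x
}

# ln of a polynomial expansion in (ln RH, ln Na) with 10 terms.
bhn_expand <- function(cf, lrh, lna) {
  cf[1] + cf[2] * lrh + cf[3] * lrh^2 + cf[4] * lrh^3 + cf[5] * lna +
    cf[6] * lrh * lna + cf[7] * lrh^2 * lna + cf[8] * lna^2 +
    cf[9] * lrh * lna^2 + cf[10] * lna^3
}

#' Binary homogeneous H2SO4-H2O nucleation rate
#'
#' Polynomial parameterization of classical BHN: returns the nucleation
#' rate, the critical-cluster diameter, the number of H2SO4 molecules in the
#' cluster and its H2SO4 mole fraction. Inputs are clamped to the fit's
#' stated domain (H2SO4 1e4-1e11 cm^-3, RH 0.01-100%); the rate is capped at
#' the validity ceiling 1e10 cm^-3 s^-1.
#'
#' @param T temperature, K (190-400; the high-temperature extension applies
#'   above ~305 K).
#' @param rh relative humidity, percent.
#' @param h2so4 sulfuric-acid concentration, molecules cm^-3.
#' @return list `J` (cm^-3 s^-1), `d_crit_nm`, `n_acid` (H2SO4 molecules per
#'   cluster), `x_acid` (mole fraction).
#' @export
bhn_rate <- function(T, rh, h2so4) {
  if (T < 190 || T > 400) stop("temperature outside 190-400 K")
  if (rh <= 0 || rh > 100) stop("RH must be in (0, 100]")
  if (h2so4 <= 0) return(list(J = 0, d_crit_nm = 1.5, n_acid = 0, x_acid = 0))
  Tc <- min(max(T, 190.15), 400)
  rhf <- min(max(rh / 100, 1e-4), 1)
  na <- min(max(h2so4, 1e4), 1e11)
  x <- bhn_mole_fraction(Tc, rhf, na)
  x <- min(max(x, 1e-3), 1)
  lrh <- log(rhf); lna <- log(na)
  lnJ <- bhn_expand(bhn_poly(.bhn_J_coef, Tc, x), lrh, lna)
  J <- min(exp(lnJ), 1e10)
  if (J < 1e-7) J <- 0
  ntot <- exp(bhn_expand(bhn_poly(.bhn_N_coef, Tc, x), lrh, lna))
  ntot <- max(ntot, 2)
  r_nm <- exp(-1.6524245 + 0.42316402 * x + 0.3346648 * log(ntot))
  list(J = J, d_crit_nm = max(2 * r_nm, 1.0), n_acid = x * ntot, x_acid = x)
}

#' Nucleation rate (BHN or organic-involving variant)
#'
#' `mechanism = "BHN"` evaluates [bhn_rate()]. `mechanism = "HET"` scales the
#' BHN rate by an organic-availability factor 1 + k_org * C_org and assigns
#' part of the cluster mass to the extremely low-volatility organic,
#' representing nucleation involving an organic vapor.
#'
#' @param T temperature, K.
#' @param rh relative humidity, percent.
#' @param h2so4 sulfuric-acid concentration, cm^-3.
#' @param mechanism `"BHN"` or `"HET"`.
#' @param organic organic-vapor (ELV) concentration, cm^-3 (HET only).
#' @param k_org organic enhancement coefficient, cm^3 (default 2e-13).
#' @return list `J`, `d_crit_nm`, `n_acid`, `n_org` (organic molecules per
#'   cluster, 0 for BHN), `x_acid`.
#' @export
nucleation_rate <- function(T, rh, h2so4, mechanism = c("BHN", "HET"),
                            organic = 0, k_org = 2e-13) {
  mechanism <- match.arg(mechanism)
  out <- bhn_rate(T, rh, h2so4)
  out$n_org <- 0
  if (mechanism == "HET" && out$J > 0 && organic > 0) {
    out$J <- min(out$J * (1 + k_org * organic), 1e10)
    out$n_org <- 1  # one organic molecule joins the critical cluster
  }
  out
}
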