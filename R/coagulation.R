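# Brownian coagulation on the fixed sectional grid. The kernel is the Fuchs
# transition-regime form evaluated at the section-center diameters. Each
# colliding pair (i, j) produces one particle of combined center volume,
# assigned to the two sections whose centers bracket it with a
# volume-conserving split; the component masses of both parents move with
# it, so every component's total mass is conserved to machine precision and
# total number strictly decreases. Per-section losses are damped with an
# exponential-integrator factor, keeping the state positive for any step.

#' Fuchs transition-regime Brownian coagulation kernel
#'
#' @param d1_nm,d2_nm particle diameters, nm (vectorized).
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param rho_p particle density for the particle mass entering the thermal
#'   speed, kg m^-3 (default 1400).
#' @return kernel, cm^3 s^-1.
#' @export
fuchs_kernel <- function(d1_nm, d2_nm, T = 288, P = .P0, rho_p = 1400) {
  mu <- air_viscosity(T)
  lam <- air_mean_free_path(T, P)
  kern1 <- function(d_nm) {
    d <- d_nm * 1e-9
    Kn <- 2 * lam / d
    Cc <- 1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn))
    D <- .kB * T * Cc / (3 * pi * mu * d)
    m <- rho_p * pi / 6 * d^3
    cbar <- sqrt(8 * .kB * T / (pi * m))
    lp <- 8 * D / (pi * cbar)
    gg <- ((d + lp)^3 - (d^2 + lp^2)^1.5) / (3 * d * lp) - d
    list(d = d, D = D, cbar = cbar, g = gg)
  }
  p1 <- kern1(d1_nm); p2 <- kern1(d2_nm)
  ds <- p1$d + p2$d
  K <- 2 * pi * (p1$D + p2$D) * ds /
    (ds / (ds + 2 * sqrt(p1$g^2 + p2$g^2)) +
       8 * (p1$D + p2$D) / (sqrt(p1$cbar^2 + p2$cbar^2) * ds))
  K * 1e6   # m^3 s^-1 -> cm^3 s^-1
}

# Precompute the pairwise structure for a grid: pair indices (i <= j), the
# split targets k/k+1 and split fraction for the combined center volume, and
# the kernel matrix at temperature T.
coagulation_tables <- function(grid, T = 288, kernel_override = NULL) {
  ns <- grid$n_sections
  vc <- grid$volumes_cm3
  pr <- which(upper.tri(matrix(0, ns, ns), diag = TRUE), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  Vij <- vc[i] + vc[j]
  k <- findInterval(Vij, vc)
  k <- pmin(k, ns)
  k2 <- pmin(k + 1, ns)
  f <- ifelse(k2 > k, (vc[k2] - Vij) / (vc[k2] - vc[k]), 1)
  f <- pmin(pmax(f, 0), 1)
  if (is.null(kernel_override)) {
    Kmat <- outer(grid$centers_nm, grid$centers_nm,
                  function(a, b) fuchs_kernel(a, b, T))
  } else if (is.function(kernel_override)) {
    Kmat <- outer(grid$centers_nm, grid$centers_nm, kernel_override)
  } else {
    Kmat <- matrix(kernel_override, ns, ns)
  }
  list(i = i, j = j, k = k, k2 = k2, f = f, K = Kmat[cbind(i, j)],
       Kmat = Kmat, ns = ns)
}

#' One Brownian coagulation step
#'
#' @param state an [aerosol_state()].
#' @param dt time step, s (<= 0.1 in the plume model; larger steps remain
#'   positive thanks to the loss damping, at reduced accuracy).
#' @param tables optional precomputed [coagulation_tables] (rebuilt from the
#'   state temperature if missing).
#' @param kernel_override a constant (cm^3 s^-1) or function(d1, d2) used in
#'   place of the Fuchs kernel, for closed-form verification.
#' @return updated [aerosol_state()].
#' @export
coagulation_step <- function(state, dt, tables = NULL, kernel_override = NULL) {
  n <- state$number
  if (all(n == 0)) return(state)
  g <- state$grid
  if (is.null(tables))
    tables <- coagulation_tables(g, state$temperature_K, kernel_override)
  i <- tables$i; j <- tables$j
  # pair collision rates (i < j: K n_i n_j; i = j: 1/2 K n_i^2)
  r <- tables$K * n[i] * n[j]
  r[i == j] <- r[i == j] / 2
  if (all(r == 0)) return(state)
  # exponential-integrator damping of each section's total loss
  lam <- as.numeric(tables$Kmat %*% n)            # collision frequency per particle
  s <- ifelse(lam > 0, (1 - exp(-dt * lam)) / (dt * lam), 1)
  gpair <- pmin(s[i], s[j])
  r <- r * gpair
  act <- which(r > 0)
  i <- i[act]; j <- j[act]; r <- r[act]
  k <- tables$k[act]; k2 <- tables$k2[act]; f <- tables$f[act]
  ns <- tables$ns
  dn_pair <- dt * r                                # particles produced per pair
  # number bookkeeping
  loss <- numeric(ns)
  self <- i == j
  loss_add <- function(idx, w) {
    tab <- rowsum(w, idx)
    out <- numeric(ns)
    out[as.integer(rownames(tab))] <- tab
    out
  }
  loss <- loss_add(i, dn_pair * ifelse(self, 2, 1)) + loss_add(j, dn_pair * !self)
  prod_n <- loss_add(k, f * dn_pair) + loss_add(k2, (1 - f) * dn_pair)
  new_n <- n - loss + prod_n
  # mass bookkeeping: each pair carries the per-particle mass of both parents
  m <- state$mass
  vc <- g$volumes_cm3
  Vij <- vc[i] + vc[j]
  wk <- f * vc[k] / Vij                            # volume share to section k
  new_m <- m
  for (q in seq_len(ncol(m))) {
    mpp <- ifelse(n > 0, m[, q] / n, 0)            # mass per particle
    mq_pair <- dn_pair * (mpp[i] + mpp[j])
    mloss <- loss_add(i, dn_pair * mpp[i] * ifelse(self, 2, 1)) +
      loss_add(j, dn_pair * mpp[j] * !self)
    mprod <- loss_add(k, wk * mq_pair) + loss_add(k2, (1 - wk) * mq_pair)
    new_m[, q] <- m[, q] - mloss + mprod
  }
  new_n[new_n < 0] <- 0
  new_m[new_m < 0] <- 0
  state$number <- new_n
  state$mass <- new_m
  state
}
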