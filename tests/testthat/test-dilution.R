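test_that("entrainment velocity follows the quadrature formula", {
  expect_equal(entrainment_velocity(0, 0, 0), 0)
  expect_equal(entrainment_velocity(5, 25, 0, alpha = 0.1),
               sqrt(0.25 + 6.25), tolerance = 1e-12)
  expect_equal(round(entrainment_velocity(5, 25, 0, alpha = 0.1), 4), 2.5495)
  expect_equal(entrainment_velocity(5, 25), entrainment_velocity(25, 5))
})

test_that("jet cross-section expands per the printed formula", {
  st <- stack_spec(S0_m2 = 1, Vs_ms = 25)
  expect_equal(plume_cross_section(st, 2.5, 0), 1)
  sw <- entrainment_velocity(5, 25, 0, 0.1)
  expect_equal(plume_cross_section(st, sw, 1), (1 + sw)^2 - 2.5^2,
               tolerance = 1e-12)
  expect_equal(round(plume_cross_section(st, sw, 1), 3), 6.349)
  expect_gt(plume_cross_section(st, 3, 1), plume_cross_section(st, 2.6, 1))
  expect_error(plume_cross_section(stack_spec(S0_m2 = 0.01, Vs_ms = 50), 0.05, 1),
               "nonpositive")
})

test_that("first-stage dilution ratio is ~8 for all events and monotone", {
  still <- list(wind_speed_ms = 0)
  expect_equal(
    first_stage_dilution_ratio(stack_spec(Vs_ms = 0), still), 1
  )
  st1 <- stack_spec(S0_m2 = 1, Vs_ms = 25)
  expect_equal(round(first_stage_dilution_ratio(st1, list(wind_speed_ms = 5)), 2),
               6.35)
  st <- stack_spec()
  drs <- vapply(ship_event_ids(),
                function(id) first_stage_dilution_ratio(st, make_event(id)),
                numeric(1))
  expect_true(all(drs >= 7 & drs <= 10))
  expect_equal(mean(drs), 8, tolerance = 0.1)
  # monotone in U and V_S over the physical range
  dr_u <- vapply(seq(0, 10, by = 1), function(u)
    first_stage_dilution_ratio(st, list(wind_speed_ms = u)), numeric(1))
  expect_true(all(diff(dr_u) >= 0))
  dr_v <- vapply(seq(10, 40, by = 5), function(v)
    first_stage_dilution_ratio(stack_spec(Vs_ms = v), list(wind_speed_ms = 5)),
    numeric(1))
  expect_true(all(diff(dr_v) >= 0))
  expect_true(all(dr_u >= 1) && all(dr_v >= 1))
})

test_that("plume temperature interpolates between exhaust and ambient", {
  expect_equal(initial_plume_temperature(280, 580, 8), 317.5)
  expect_equal(initial_plume_temperature(280, 280, 3), 280)
  expect_equal(initial_plume_temperature(280, 580, 1e9), 280, tolerance = 1e-6)
  expect_error(initial_plume_temperature(280, 580, 0.5))
  for (dr in c(1, 2, 8, 50)) {
    tp <- initial_plume_temperature(270, 600, dr)
    expect_true(tp >= 270 && tp <= 600)
  }
})

test_that("dilution alone leaves 1/DR of the stack concentration", {
  expect_equal(first_stage_fraction_remaining(8), 0.125)
  expect_equal(first_stage_fraction_remaining(1), 1)
})

test_that("coagulation during expansion removes a minor particle fraction", {
  st <- stack_spec()
  ev <- make_event("A_20110912")
  expect_equal(coagulation_fraction_remaining(0, st, ev), 1)
  # typical events: fraction remaining 0.77-0.93
  typical <- setdiff(ship_event_ids(), "K_20110802")
  fr <- vapply(typical, function(id) {
    e <- make_event(id)
    coagulation_fraction_remaining(e$pn_diluted_cm3 *
                                     first_stage_dilution_ratio(st, e), st, e)
  }, numeric(1))
  expect_true(all(fr > 0.77 & fr < 0.93))
  # weak-wind, high-PN event: markedly lower survival
  ew <- make_event("K_20110802")
  fw <- coagulation_fraction_remaining(
    ew$pn_diluted_cm3 * first_stage_dilution_ratio(st, ew), st, ew
  )
  expect_true(fw > 0.4 && fw < 0.7)
  expect_true(all(c(fr, fw) > 0 & c(fr, fw) <= 1))
})

test_that("power-law fitting is the inverse of the generator", {
  s <- make_dilution_samples(5000, 1.26, seq(40, 2000, by = 40))
  f <- fit_power_law(s)
  expect_equal(f$a, 5000, tolerance = 1e-6)
  expect_equal(f$b, 1.26, tolerance = 1e-6)
  const <- data.frame(distance_m = c(10, 100, 1000), concentration = 7)
  expect_equal(fit_power_law(const)$b, 0, tolerance = 1e-12)
  expect_error(fit_power_law(data.frame(distance_m = 1:2, concentration = 1:2)),
               "fewer than 3")
  withneg <- data.frame(distance_m = c(0, 10, 50, 100, 500),
                        concentration = c(5, 100, -1, 30, 10))
  expect_warning(f2 <- fit_power_law(withneg), "dropped")
  expect_equal(f2$n_points, 3)
})

test_that("noisy fit recovers the exponent within the stated band", {
  s <- make_dilution_samples(5000, 1.26, seq(40, 2000, length.out = 50),
                             noise_sd = 0.1, seed = 11)
  expect_lt(abs(fit_power_law(s)$b - 1.26), 0.05)
})

test_that("plume height grows from H_P0 with the sigma_z power law", {
  p <- dilution_params(b = 1.26, stability = "neutral")
  expect_equal(plume_height(0, 5, p), 5.5)
  expect_equal(round(plume_height(100, 5, p), 2), 36.53)
  expect_equal(plume_height(500, 0, p), 5.5)
  hp <- plume_height(seq(0, 900, by = 10), 4, p)
  expect_true(all(diff(hp) >= 0))
  expect_equal(sigma_z_scale("unstable"), 110.62)
  expect_equal(sigma_z_scale("stable"), 61.14)
})

test_that("dilution tendency relaxes toward background without overshoot", {
  expect_equal(dilution_tendency(50, 50, 1.3, 10), 0)
  expect_equal(dilution_tendency(1000, 0, 1, 10), -100)
  expect_error(dilution_tendency(1, 0, 1, 0))
  # RK4 integration of the tendency at dt = 0.1 matches the closed form
  # N(t) = N(t0) (t/t0)^-b within 1% at 900 s
  for (b in c(0.5, 1.26, 2)) {
    n <- 1000; t <- 1; dt <- 0.1
    nst <- 8990
    for (k in seq_len(nst)) {
      k1 <- dilution_tendency(n, 0, b, t)
      k2 <- dilution_tendency(n + dt / 2 * k1, 0, b, t + dt / 2)
      k3 <- dilution_tendency(n + dt / 2 * k2, 0, b, t + dt / 2)
      k4 <- dilution_tendency(n + dt * k3, 0, b, t + dt)
      n <- n + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + dt
    }
    expect_equal(n, 1000 * 900^-b, tolerance = 0.01)
  }
  # the package's step update never crosses the background for any b > 0
  g <- size_grid(10, 1, 100)
  bg <- aerosol_state(g, rep(50, 10),
                      matrix(1, 10, 1, dimnames = list(NULL, "soot")))
  st <- aerosol_state(g, rep(1000, 10),
                      matrix(5, 10, 1, dimnames = list(NULL, "soot")))
  for (b in c(0.5, 1.26, 5, 20)) {
    s <- st; t <- 1
    for (k in 1:50) {
      s <- background_mixing_step(s, bg, b, t, 0.1)
      t <- t + 0.1
      expect_true(all(s$number >= bg$number - 1e-9))
    }
  }
})

test_that("grid convergence index follows its definition", {
  expect_equal(grid_convergence_index(0, 2, 2), 0)
  expect_equal(round(grid_convergence_index(0.04, 2, 2), 6), 0.016667)
  expect_equal(grid_convergence_index(0.08, 2, 2),
               2 * grid_convergence_index(0.04, 2, 2))
  expect_error(grid_convergence_index(0.04, 1, 2), "refinement")
})
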