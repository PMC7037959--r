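test_that("lognormal discretization recovers the requested total number", {
  g <- size_grid()
  for (ps in list(c(1e6, 20, 1.5), c(5400, 60, 1.8), c(3.2e6, 5.5, 1.35))) {
    st <- make_exhaust_distribution(
      lognormal_mode(ps[1], ps[2], ps[3], c(soot = 1)), g
    )
    expect_equal(total_number(st), ps[1], tolerance = 0.005)
  }
})

test_that("mode validation rejects degenerate inputs", {
  expect_error(lognormal_mode(1e6, 20, 1.5, c(soot = 0.5)), "sum to 1")
  expect_error(lognormal_mode(1e6, 20, 0.9, c(soot = 1)))
  g <- size_grid(d_min_nm = 10, d_max_nm = 100)
  expect_error(
    make_exhaust_distribution(lognormal_mode(1e6, 5, 1.5, c(soot = 1)), g),
    "outside"
  )
})

test_that("default exhaust preset puts 29% of the number below 25 nm", {
  ex <- default_exhaust()
  expect_equal(total_number(ex, d_max_nm = 25) / total_number(ex), 0.29,
               tolerance = 0.02)
})

test_that("per-section dry-mass fractions close to one for any preset", {
  for (st in list(default_exhaust(),
                  make_background_distribution("helsinki", size_grid()))) {
    dm <- st$mass[, dry_components()]
    tot <- rowSums(dm)
    nz <- tot > 0
    expect_true(all(abs(rowSums(dm[nz, ] / tot[nz]) - 1) < 1e-9))
    expect_true(all(st$number >= 0) && all(st$mass >= 0))
  }
})

test_that("background presets give the stated totals", {
  g <- size_grid()
  expect_equal(total_number(make_background_distribution("helsinki", g)),
               5400, tolerance = 0.005)
  z <- make_background_distribution("zero", g)
  expect_true(all(z$number == 0) && all(z$mass == 0))
  expect_error(make_background_distribution("nowhere", g))
})

test_that("dilution samples follow the power law and are reproducible", {
  s <- make_dilution_samples(5000, 1.26, c(50, 100, 500, 1000))
  expect_equal(s$concentration, 5000 * s$distance_m^-1.26, tolerance = 1e-12)
  expect_equal(s$concentration[2], 5000 * 100^-1.26)
  expect_equal(round(s$concentration[2], 1), 15.1)
  a <- make_dilution_samples(5000, 1.26, 1:50 * 40, noise_sd = 0.2, seed = 7)
  b <- make_dilution_samples(5000, 1.26, 1:50 * 40, noise_sd = 0.2, seed = 7)
  expect_identical(a, b)
})

test_that("noisy generated samples are recovered by the power-law fit", {
  for (seed in 1:5) {
    s <- make_dilution_samples(5000, 1.26, seq(40, 2000, by = 40),
                               noise_sd = 0.1, seed = seed)
    f <- fit_power_law(s)
    expect_lt(abs(f$b - 1.26), 3 * 0.1)
    expect_lt(abs(log(f$a / 5000)), 3 * 0.1 * 2)
  }
})

test_that("ship events reproduce the recorded meteorology", {
  ev <- make_event("J_20100811")
  expect_equal(ev$air_temperature_K, 292)
  expect_equal(ev$wind_speed_ms, 4.6)
  expect_equal(ev$wind_direction_deg, 219)
  ev2 <- make_event("J_20110217")
  expect_equal(ev2$air_temperature_K, 258)
  expect_equal(ev2$wind_speed_ms, 2.4)
  expect_identical(ev2$stability, "stable")
  expect_error(make_event("X_19990101"), "unknown")
  expect_length(ship_event_ids(), 14)
  for (id in ship_event_ids()) {
    ev <- make_event(id)
    expect_true(ev$air_temperature_K > 200 && ev$air_temperature_K < 330)
    expect_true(ev$rh_pct >= 0 && ev$rh_pct <= 100)
    expect_true(ev$wind_speed_ms >= 0)
    expect_true(ev$wind_direction_deg >= 0 && ev$wind_direction_deg < 360)
    expect_true(ev$stability %in% c("unstable", "neutral", "stable"))
    expect_true(ev$pn_diluted_cm3 >= 1e6 && ev$pn_diluted_cm3 <= 1e7)
  }
})

test_that("population grids are nonnegative, exact-sum and reproducible", {
  z <- make_population_grid(2000, list(), seed = 1)
  expect_true(all(z$inhabitants == 0))
  h <- list(list(center = c(1000, 1200), total = 650, sd_m = 300))
  p1 <- make_population_grid(2000, h, seed = 3)
  p2 <- make_population_grid(2000, h, seed = 3)
  expect_identical(p1, p2)
  expect_equal(sum(p1$inhabitants), 650)
  expect_true(all(p1$inhabitants >= 0))
  expect_equal(p1$cell_size_m, 100)
})
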