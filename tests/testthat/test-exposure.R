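# Quarter-turn rotation of a raster indexed [x, y] (x east, y north),
# matching a +90 degree compass rotation of the wind direction.
rotate_quarter <- function(m) {
  out <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  out
}

# A tiny synthetic trajectory for field construction: constant wind, known
# UFP concentrations per snapshot.
toy_trajectory <- function(conc, U = 4, wd = 270, times = seq(1, 900, by = 1),
                           bg_cm3 = 5400) {
  g <- size_grid(10, 1, 100)   # all sections below 100 nm
  mk <- function(n_tot) {
    n <- numeric(10); n[5] <- n_tot
    aerosol_state(g, n)
  }
  conc <- rep_len(conc, length(times))
  bg <- mk(bg_cm3)
  structure(list(
    time_s = times, x_m = U * times, t0 = 1,
    states = lapply(conc, mk),
    event = list(wind_direction_deg = wd, wind_speed_ms = U),
    background = bg
  ), class = "plume_trajectory")
}

test_that("ring values are distance averages of the trajectory", {
  traj <- toy_trajectory(conc = 2e5)
  f <- build_plume_field(traj)
  expect_equal(f$centerline_deg, 90)
  # constant concentration: every reached ring holds it
  reached <- seq_len(floor(max(traj$x_m) / 40))
  expect_true(all(f$ring_cm3[reached] == 2e5))
  # rings beyond the trajectory (and beyond 3600 m) hold background
  expect_true(all(f$ring_cm3[-reached] == f$background_cm3))
  # brute-force check of the ring mean with a varying profile
  conc <- 5400 + 1e6 / seq(1, 900)
  traj2 <- toy_trajectory(conc = conc)
  f2 <- build_plume_field(traj2)
  ufp <- conc
  ring7 <- mean(ufp[traj2$x_m >= 240 & traj2$x_m < 280])
  expect_equal(f2$ring_cm3[7], ring7)
})

test_that("daily mean composes plume windows with background", {
  bg <- 5400
  expect_equal(daily_mean_concentration(8 * bg, numeric(0), 5, bg), bg)
  expect_equal(daily_mean_concentration(bg, c(300), 5, bg), bg)
  got <- daily_mean_concentration(10 * bg, c(60, 300, 600, 1200), 5, bg)
  expect_equal(got, bg * (1 + 9 * 20 / 1440))
  expect_warning(
    daily_mean_concentration(2 * bg, c(100, 102), 5, bg), "overlap"
  )
})

test_that("infiltration scales outdoor concentrations", {
  expect_equal(infiltrate(10000, 0.56), 5600)
  expect_equal(infiltrate(1234), 0.56 * 1234)
  expect_equal(infiltrate(777, 1), 777)
  expect_equal(infiltrate(0, 0.56), 0)
  expect_error(infiltrate(100, 1.2), "F_inf")
})

test_that("population exposure follows the weighted-concentration sum", {
  pop <- make_population_grid(100, list(), seed = 1)
  pop$inhabitants[1, 1] <- 100L
  daily <- matrix(10000, 1, 1)
  res <- population_exposure(daily, pop, time_at_home = 1, F_inf = 0.56,
                             background_cm3 = 5400)
  expect_equal(res$total, 0.56 * 10000 * 100)
  # zero population
  pop0 <- make_population_grid(100, list(), seed = 1)
  expect_equal(population_exposure(daily, pop0, 1, 0.56, 5400)$total, 0)
  # bilinear in concentration and population
  res2 <- population_exposure(2 * daily, pop, 1, 0.56, 5400)
  expect_equal(res2$total, 2 * res$total)
  pop2 <- pop; pop2$inhabitants <- pop$inhabitants * 2L
  expect_equal(population_exposure(daily, pop2, 1, 0.56, 5400)$total,
               2 * res$total)
  expect_error(population_exposure(matrix(1, 2, 2), pop, 1, 0.56, 5400),
               "misaligned")
})

test_that("uniform background exposure is exact and plumes only add", {
  traj <- toy_trajectory(conc = 4e4, U = 4, wd = 200)
  f <- build_plume_field(traj)
  pop <- make_population_grid(
    2000, list(list(center = c(700, 1300), total = 300, sd_m = 400)), seed = 5
  )
  conc <- field_to_raster(f, pop)
  daily <- daily_mean_concentration(conc, c(420, 1050), 5, f$background_cm3)
  res <- population_exposure(daily, pop, 0.6, 0.56, f$background_cm3)
  bg_only <- daily_mean_concentration(matrix(f$background_cm3, nrow(conc), ncol(conc)),
                                      c(420, 1050), 5, f$background_cm3)
  res_bg <- population_exposure(bg_only, pop, 0.6, 0.56, f$background_cm3)
  expect_equal(res_bg$total,
               0.56 * f$background_cm3 * sum(pop$inhabitants) * 0.6)
  expect_true(all(res$exposure >= res_bg$exposure - 1e-9))
  expect_true(res$max_excess_percent >= 0)
})

test_that("the exposure chain is invariant under 90-degree rotations", {
  pop <- make_population_grid(
    2000, list(list(center = c(600, 1400), total = 200, sd_m = 300)), seed = 2
  )
  base <- NULL
  for (k in 0:3) {
    wd <- (200 + 90 * k) %% 360
    traj <- toy_trajectory(conc = 4e4, U = 4, wd = wd)
    f <- build_plume_field(traj)
    pop_k <- pop
    # rotate the population grid by the same quarter turns
    m <- pop$inhabitants
    if (k > 0) for (r in seq_len(k)) m <- rotate_quarter(m)
    pop_k$inhabitants <- m
    conc <- field_to_raster(f, pop_k)
    daily <- daily_mean_concentration(conc, c(420), 5, f$background_cm3)
    tot <- population_exposure(daily, pop_k, 0.6, 0.56, f$background_cm3)$total
    if (is.null(base)) base <- tot else expect_equal(tot, base, tolerance = 1e-9)
  }
})

test_that("excess risk is linear at 4% per 6250 cm^-3", {
  expect_equal(excess_risk(6250), 4)
  expect_equal(excess_risk(0), 0)
  expect_equal(excess_risk(12500), 8)
  expect_error(excess_risk(-5))
})
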