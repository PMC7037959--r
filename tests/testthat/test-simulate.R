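test_that("a background-initialized plume with no emissions stays put", {
  g <- size_grid()
  ev <- make_event("A_20110111")
  bg <- make_background_distribution("helsinki", g, ev$air_temperature_K,
                                     ev$rh_pct)
  traj <- simulate_plume(
    ev, duration_s = 30, grid = g, exhaust = bg, background = bg,
    gases = background_gas_state(ev),
    processes = list(nucleation = FALSE, deposition = FALSE)
  )
  n_end <- total_number(traj$states[[length(traj$states)]])
  expect_equal(n_end, total_number(bg), tolerance = 0.01)
  m_end <- sum(component_dry_mass(traj$states[[length(traj$states)]]))
  expect_equal(m_end, sum(component_dry_mass(bg)), tolerance = 0.02)
})

test_that("with all microphysics off the trajectory is the dilution closed
           form", {
  g <- size_grid()
  ev <- make_event("A_20110111")
  zero <- make_background_distribution("zero", g)
  ex <- default_exhaust(g)
  traj <- simulate_plume(
    ev, duration_s = 900, grid = g, exhaust = ex, background = zero,
    processes = list(chemistry = FALSE, nucleation = FALSE,
                     condensation = FALSE, coagulation = FALSE,
                     deposition = FALSE)
  )
  tail_state <- traj$states[[length(traj$states)]]
  b <- traj$params$b
  t_end <- traj$time_s[length(traj$time_s)]
  expect_equal(total_number(tail_state) / total_number(ex), 900^-b,
               tolerance = 0.01)
  # the per-section profile scales uniformly with the exact factor
  nz <- ex$number > 1e-6
  expect_equal(tail_state$number[nz] / ex$number[nz],
               rep((t_end / traj$t0)^-b, sum(nz)), tolerance = 1e-6)
  # bookkeeping: x = U t and H_P follows the plume-height law
  expect_equal(traj$x_m, ev$wind_speed_ms * traj$time_s)
  expect_equal(traj$H_P_m,
               plume_height(traj$time_s, ev$wind_speed_ms, traj$params))
})

test_that("summaries report consistent diagnostics", {
  g <- size_grid()
  ev <- make_event("A_20110111")
  zero <- make_background_distribution("zero", g)
  traj <- simulate_plume(ev, duration_s = 2, grid = g, exhaust = zero,
                         background = zero,
                         processes = list(chemistry = FALSE, nucleation = FALSE,
                                          condensation = FALSE,
                                          coagulation = FALSE,
                                          deposition = FALSE))
  s <- summarize_plume(traj, 1)
  expect_equal(s$total_pn_cm3, 0)
  expect_equal(sum(s$ufp_dry_mass_ugm3), 0)
  expect_true(is.na(s$nuc1_mode_diameter_nm))
  # fractions close to one on a populated state
  ex <- default_exhaust(g)
  fr <- dry_mass_fractions(component_dry_mass(ex, d_max_nm = 100))
  expect_equal(sum(fr), 1, tolerance = 1e-9)
})

test_that("the Nuc_1 growth-rate estimator recovers constructed rates", {
  g <- size_grid(n_sections = 600)   # fine grid: quantization ~0.15%
  times <- seq(1, 901, by = 60)
  rate_nm_h <- 3
  mk <- function(d_peak) {
    n <- numeric(g$n_sections)
    n[which.min(abs(g$centers_nm - d_peak))] <- 1e4
    aerosol_state(g, n)
  }
  traj <- structure(list(
    time_s = times, t0 = 1,
    states = lapply(times, function(t) mk(1.5 + rate_nm_h * (t - 1) / 3600))
  ), class = "plume_trajectory")
  expect_equal(nuc1_growth_rate(traj, min_points = 5), 3, tolerance = 0.05)
  flat <- structure(list(
    time_s = times, t0 = 1,
    states = lapply(times, function(t) mk(1.5))
  ), class = "plume_trajectory")
  expect_equal(nuc1_growth_rate(flat), 0, tolerance = 1e-9)
  empty <- structure(list(
    time_s = times, t0 = 1,
    states = lapply(times, function(t) aerosol_state(g))
  ), class = "plume_trajectory")
  expect_warning(gr <- nuc1_growth_rate(empty), "no identifiable")
  expect_true(is.na(gr))
})
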