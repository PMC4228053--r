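test_that("zero-contrast stimulus yields baseline Poisson firing", {
  scr <- tiny_screen()
  st <- render_stimulus("full_field_flash", contrast = 0.3, screen = scr)
  st$patterns[] <- 0   # blank screen throughout
  u <- unit_spec(baseline_hz = 12, gain_hz = 60)
  ra <- simulate_unit(u, st, 100, seed = 5)
  expected <- 12 * st$duration * 100
  expect_lt(abs(nrow(ra) - expected), 4 * sqrt(expected))
})

test_that("simulated PSTH matches the closed-form LNP rate at reliability 1", {
  scr <- tiny_screen()
  st <- render_stimulus("full_field_flash", contrast = 0.58,
                        flash_duration = 0.05, onset = 0.25, duration = 1,
                        screen = scr)
  u <- unit_spec(rf_center_deg = c(0, 0), rf_width_hm_deg = 14,
                 surround_strength = 0, gain_hz = 200, baseline_hz = 2,
                 tau_s = 0.04, reliability = 1)
  ra <- simulate_unit(u, st, 300, seed = 9, dt_s = 0.002)
  ps <- build_psth(ra, 0.02)
  oracle <- flash_rate_oracle(ps$t, 0.25, 0.05, 0.58, 0, 200, 2, 0.04)
  expect_gt(stats::cor(ps$rate, oracle), 0.99)
  # mean rate agreement improves with trial count (~1/sqrt(n))
  ra40 <- simulate_unit(u, st, 40, seed = 10, dt_s = 0.002)
  e40 <- mean((build_psth(ra40, 0.02)$rate - oracle)^2)
  e300 <- mean((ps$rate - oracle)^2)
  expect_lt(e300, e40)
})

test_that("Poisson count dispersion is near 1 for constant-rate segments", {
  scr <- tiny_screen()
  st <- render_stimulus("full_field_flash", contrast = 0.3, screen = scr)
  st$patterns[] <- 0
  u <- unit_spec(baseline_hz = 20, reliability = 1)
  ra <- simulate_unit(u, st, 300, seed = 2)
  counts <- tabulate(ra$trial, nbins = 300)
  fano <- stats::var(counts) / mean(counts)
  # chi-square CI for the Fano factor at 300 trials
  expect_gt(fano, 0.75); expect_lt(fano, 1.3)
})

test_that("planted preferred SF follows the DoG Fourier peak", {
  scr <- screen_geometry()
  sf_grid <- c(0.0175, 0.035, 0.07, 0.14)
  width <- 8
  sigma <- width / (2 * sqrt(2 * log(2)))
  for (s in c(0, 0.8)) {
    u <- unit_spec(rf_center_deg = c(3, -2), rf_width_hm_deg = width,
                   surround_strength = s, gain_hz = 80, baseline_hz = 4,
                   reliability = 1)
    mods <- vapply(sf_grid, function(k) {
      m2 <- 0
      for (phv in c(0, pi / 2)) {
        st <- render_stimulus("inverting_grating", sf_cpd = k, tf_hz = 1,
                              orientation_deg = 0, contrast = 0.8,
                              duration = 3, phase = phv, screen = scr)
        ra <- simulate_unit(u, st, 40, seed = round(1000 * k) + s * 7 + 1,
                            dt_s = 0.01)
        m2 <- m2 + inversion_modulation(ra, st)^2
      }
      sqrt(m2)
    }, numeric(1))
    oracle <- abs(dog_fourier_oracle(sf_grid, sigma, s))
    got <- which.max(mods); want <- which.max(oracle)
    expect_lte(abs(got - want), 1)   # within one grid step
    if (s == 0) expect_equal(want, 1L)   # no surround -> lowest SF
    if (s == 0.8) expect_gt(want, 1L)    # strong surround -> interior peak
  }
})

test_that("direction selectivity is planted multiplicatively with TF tuning", {
  scr <- tiny_screen()
  u <- unit_spec(rf_center_deg = c(0, 0), ds_strength = 0.8, ds_pref_deg = 90,
                 ds_tf_peak_hz = 1, gain_hz = 60, baseline_hz = 3,
                 reliability = 1)
  rates <- vapply(c(90, 270), function(d) {
    st <- render_stimulus("drifting_grating", sf_cpd = 0.035, tf_hz = 1,
                          direction_deg = d, duration = 5, screen = scr)
    nrow(simulate_unit(u, st, 10, seed = d)) / (10 * 5)
  }, numeric(1))
  expect_gt(rates[1], 2 * rates[2])   # pref markedly above null
  # depth decays away from the TF peak
  expect_lt(ds_depth(u, 0.2, "x"), 0.2 * ds_depth(u, 1, "x"))
})

test_that("recovered reproducibility increases with planted reliability", {
  scr <- tiny_screen()
  st <- render_stimulus("movie", duration = 8, frame_rate = 10, seed = 21,
                        screen = scr, contrast_sd = 0.5)
  rs <- vapply(c(0.2, 0.5, 0.9), function(r) {
    u <- unit_spec(rf_center_deg = c(0, 0), rf_width_hm_deg = 12,
                   gain_hz = 70, baseline_hz = 4, reliability = r)
    ra <- simulate_unit(u, st, 60, seed = round(100 * r), dt_s = 0.01)
    trial_reproducibility(ra)$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("simulation is deterministic under a fixed seed", {
  scr <- tiny_screen()
  st <- render_stimulus("full_field_flash", contrast = 0.58, screen = scr)
  u <- unit_spec(reliability = 0.7)
  r1 <- simulate_unit(u, st, 20, seed = 77)
  r2 <- simulate_unit(u, st, 20, seed = 77)
  expect_identical(r1$spike_time_s, r2$spike_time_s)
  expect_error(simulate_unit(u, st, 0), "n_trials")
})
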