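mk_raster <- function(trial, t, n_trials, duration) {
  trial_raster(data.frame(trial = trial, spike_time_s = t),
               n_trials = n_trials, duration = duration)
}

test_that("PSTH arithmetic and spike-count conservation hold", {
  ra <- mk_raster(1L, 0.015, n_trials = 1, duration = 1)
  ps <- build_psth(ra, 0.01)
  expect_equal(ps$rate[2], 100)   # 1 spike / (1 trial x 10 ms)
  for (bw in c(0.005, 0.02, 0.05)) {
    ps2 <- build_psth(ra, bw)
    expect_equal(sum(ps2$rate) * bw * ps2$n_trials, 1)
  }
  set.seed(4)
  t <- stats::runif(500); tr <- sample.int(20, 500, replace = TRUE)
  ra2 <- mk_raster(tr, t, 20, 1)
  for (bw in c(0.01, 0.025, 0.1))
    expect_equal(sum(build_psth(ra2, bw)$rate) * bw * 20, 500)
  expect_warning(build_psth(mk_raster(integer(), numeric(), 5, 1), 0.01),
                 "empty")
})

test_that("homogeneous Poisson PSTH stays within sampling bounds", {
  set.seed(11)
  rate <- 20; ntr <- 200; dur <- 1
  n <- stats::rpois(1, rate * ntr * dur)
  ra <- mk_raster(sample.int(ntr, n, replace = TRUE),
                  stats::runif(n, 0, dur), ntr, dur)
  ps <- build_psth(ra, 0.02)
  se <- sqrt(rate / (0.02 * ntr))
  expect_true(all(abs(ps$rate - rate) < 5 * se))
})

test_that("flash amplitude is the baseline-subtracted window mean", {
  # deterministic raster: baseline 10 Hz everywhere, +15 Hz step in the
  # 200 ms response window
  ntr <- 10; dur <- 1; onset <- 0.25
  base_times <- seq(0.0005, dur - 0.0005, length.out = 10)          # 10 Hz
  resp_times <- seq(onset + 0.001, onset + 0.199, length.out = 3)   # +15 Hz over 0.2 s
  tr <- rep(seq_len(ntr), each = length(base_times) + length(resp_times))
  tt <- rep(c(base_times, resp_times), times = ntr)
  ra <- mk_raster(tr, tt, ntr, dur)
  ps <- build_psth(ra, 0.05, baseline_window_s = c(0, onset))
  amp <- flash_response_amplitude(ps, onset)
  # baseline window holds only the 10 Hz train; response window holds
  # 10 + 3/0.2 = 25 Hz
  expect_equal(amp, 15, tolerance = 1)
  ps0 <- ps; ps0$rate[] <- ps0$baseline_hz
  expect_equal(flash_response_amplitude(ps0, onset), 0)
})

test_that("latency is the smoothed post-onset peak", {
  ntr <- 50
  set.seed(2)
  tt <- c(stats::runif(200, 0, 1), stats::rnorm(400, 0.31, 0.004))
  tt <- tt[tt > 0 & tt < 1]
  ra <- mk_raster(sample.int(ntr, length(tt), TRUE), tt, ntr, 1)
  ps <- build_psth(ra, 0.01, c(0, 0.25))
  lat <- response_latency(ps, 0.25)
  expect_true(lat$responsive)
  expect_lt(abs(lat$latency_s - 0.06), 0.015)
  # no response -> undefined
  ra0 <- mk_raster(sample.int(ntr, 200, TRUE), stats::runif(200), ntr, 1)
  lat0 <- response_latency(build_psth(ra0, 0.01, c(0, 0.25)), 0.25)
  expect_false(lat0$responsive)
  expect_true(is.na(lat0$latency_s))
})

test_that("latency population comparison controls level and has power", {
  set.seed(5)
  la <- stats::rnorm(300, 0.08, 0.015)
  cmp_same <- latency_distribution_comparison(la, la + 1e-9)
  expect_true(cmp_same$comparable)
  expect_gt(cmp_same$p, 0.99)

  # planted 20 ms latency shift at 80 units per condition: among the runs
  # where both histogram fits clear the R2 gate, the F test should almost
  # always reject the shared Gaussian
  hits <- 0; attempted <- 0
  for (i in 1:100) {
    set.seed(200 + i)
    a <- stats::rnorm(80, 0.08, 0.015)
    b <- stats::rnorm(80, 0.10, 0.015)
    cmp <- latency_distribution_comparison(a, b)
    if (cmp$comparable) {
      attempted <- attempted + 1
      if (cmp$p < 0.05) hits <- hits + 1
    }
  }
  expect_gte(attempted, 40)
  expect_gte(hits, 0.9 * attempted)
})

test_that("trial reproducibility behaves at its extremes", {
  # identical, non-constant trials -> 1
  ntr <- 8
  tt <- rep(c(0.1, 0.11, 0.5), times = ntr)
  ra <- mk_raster(rep(seq_len(ntr), each = 3), tt, ntr, 1)
  expect_equal(trial_reproducibility(ra, 0.05)$r, 1)
  expect_error(trial_reproducibility(mk_raster(1L, 0.1, 3, 1)), "trials")

  # independent homogeneous Poisson -> population mean near 0
  set.seed(9)
  rs <- vapply(1:100, function(i) {
    n <- stats::rpois(1, 20 * 10)
    ra <- mk_raster(sample.int(10, n, TRUE), stats::runif(n), 10, 1)
    trial_reproducibility(ra)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / 10)
})

test_that("STA recovers a planted receptive field", {
  scr <- screen_geometry()
  st <- render_stimulus("bar_white_noise", axis = "vertical",
                        bar_width_deg = 5, n_frames = 10000, seed = 31,
                        screen = scr)
  u <- unit_spec(rf_center_deg = c(10, 0), rf_width_hm_deg = 14,
                 gain_hz = 400, baseline_hz = 8, tau_s = 0.04,
                 reliability = 1)
  ra <- simulate_unit(u, st, 1, seed = 6)
  rf <- sta_receptive_field(ra, st)
  expect_false(rf$low_confidence)
  expect_lt(abs(rf$center_deg - 10), 1)
  expect_lt(abs(rf$width_hm_deg - 14) / 14, 0.15)
  expect_gt(rf$r2, 0.5)

  # half-max width conversion: width = 2 sigma sqrt(2 ln 2)
  expect_equal(2 * sqrt(2 * log(2)) * hm_to_sd(14), 14)

  # untuned unit -> flat STA, poor fit
  u0 <- unit_spec(gain_hz = 0, baseline_hz = 30)
  ra0 <- simulate_unit(u0, st, 1, seed = 7)
  rf0 <- sta_receptive_field(ra0, st)
  expect_true(is.na(rf0$r2) || rf0$r2 < 0.5)
})

test_that("STA width estimate converges with frame count", {
  scr <- screen_geometry()
  u <- unit_spec(rf_center_deg = c(-5, 0), rf_width_hm_deg = 16,
                 gain_hz = 400, baseline_hz = 8, reliability = 1)
  errs <- vapply(c(1000, 4000, 16000), function(nf) {
    st <- render_stimulus("bar_white_noise", axis = "vertical",
                          bar_width_deg = 5, n_frames = nf, seed = 41,
                          screen = scr)
    ra <- simulate_unit(u, st, 1, seed = 8)
    abs(sta_receptive_field(ra, st)$width_hm_deg - 16)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / 16, 0.15)
})

test_that("DSI closed-form cases are exact", {
  mk <- function(rp, rn) {
    dirs <- seq(0, 315, by = 45)
    mu <- rep(1, 8); mu[1] <- rp; mu[5] <- rn
    data.frame(direction_deg = rep(dirs, each = 4),
               response = rep(mu, each = 4))
  }
  expect_equal(direction_selectivity(mk(10, 0), n_perm = 0)$dsi, 1)
  d0 <- direction_selectivity(
    data.frame(direction_deg = rep(seq(0, 315, 45), each = 4),
               response = rep(2, 32)), n_perm = 0)
  expect_equal(d0$dsi, 0)
  expect_equal(direction_selectivity(mk(7.5, 2.5), n_perm = 0)$dsi, 0.5)
  # undefined when pref + null responses are both zero
  dz <- direction_selectivity(
    data.frame(direction_deg = rep(seq(0, 315, 45), each = 2),
               response = rep(0, 16)), n_perm = 0)
  expect_true(is.na(dz$dsi))
  # vector-sum variant: single active direction -> index 1
  dv <- direction_selectivity(mk(10, 0), n_perm = 0, method = "vector_sum")
  expect_true(dv$dsi > 0 && dv$dsi <= 1)
})

test_that("permutation test flags genuine direction sensitivity", {
  set.seed(12)
  dirs <- rep(seq(0, 315, by = 45), each = 10)
  tuned <- data.frame(direction_deg = dirs,
                      response = stats::rpois(80, 5 * (1 + 0.8 *
                        cos(dirs * pi / 180))))
  flat <- data.frame(direction_deg = dirs,
                     response = stats::rpois(80, 5))
  expect_true(direction_selectivity(tuned, seed = 1)$direction_sensitive)
  ps <- vapply(1:20, function(i) {
    set.seed(i)
    flat$response <- stats::rpois(80, 5)
    direction_selectivity(flat, seed = i)$p_value
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 4)   # near-nominal false positive rate
})

test_that("tuning-curve helpers pick preferred values with lower-tie-break", {
  resp <- expand.grid(orientation_deg = c(0, 90),
                      sf_cpd = c(0.0175, 0.035, 0.07))
  resp$modulation_hz <- c(1, 1, 1, 8, 1, 1)   # only 0.035 at ori 90
  tc <- spatial_frequency_tuning(resp)
  expect_equal(tc$preferred, 0.035)
  expect_equal(tc$preferred_orientation_deg, 90)
  # exact tie within the preferred orientation -> lower SF
  resp$modulation_hz <- c(5, 1, 5, 1, 1, 1)
  expect_equal(spatial_frequency_tuning(resp)$preferred, 0.0175)

  tf <- data.frame(tf_hz = rep(c(0.2, 0.5, 1, 2), each = 2),
                   direction_deg = rep(c(0, 180), 4),
                   peak_hz = c(2, 1, 3, 2, 9, 4, 5, 2))
  tt <- temporal_frequency_tuning(tf)
  expect_equal(tt$preferred, 1)
  # uniform scaling leaves the normalised tuning shape unchanged
  tf2 <- tf; tf2$peak_hz <- tf2$peak_hz * 1.3
  tt2 <- temporal_frequency_tuning(tf2)
  expect_equal(tt2$response / max(tt2$response),
               tt$response / max(tt$response), tolerance = 1e-12)
})

test_that("signal correlation hits its closed-form extremes", {
  a <- c(1, 4, 2, 8, 3)
  expect_equal(signal_correlation(a, a), 1)
  expect_equal(signal_correlation(a, -a + 2 * mean(a)), -1)
  expect_true(is.na(signal_correlation(a, rep(2, 5))))
  expect_error(signal_correlation(a, a[1:3]))
})
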