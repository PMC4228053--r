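test_that("simulated ERG plants the Naka-Rushton b-wave amplitude exactly", {
  # zero contrast -> zero amplitude before noise
  tr0 <- simulate_erg(0, gain_uv = 40, noise_sd_uv = 0)
  expect_equal(attr(tr0, "amplitude_uv"), 0)
  expect_equal(extract_b_wave(tr0)$amplitude_uv, 0)

  # fully adapted, noiseless: trough-to-peak equals gain * c^n/(c^n + c50^n)
  tr <- simulate_erg(0.58, gain_uv = 40, c50 = 0.3, n_hill = 2,
                     noise_sd_uv = 0)
  want <- naka_rushton(0.58, 40, 0.3, 2)
  bw <- extract_b_wave(tr)
  expect_equal(bw$amplitude_uv, want, tolerance = 1e-9)
  expect_gt(bw$b_peak_time_s, bw$a_trough_time_s)
  expect_gt(bw$a_trough_time_s, attr(tr, "flash_onset_s"))

  # exponential approach: at t = 3 tau the deviation is exp(-3) of the step
  g1 <- 40; g0 <- 20; tau <- 180
  tr3 <- simulate_erg(1, gain_uv = g1, gain_from_uv = g0, tau_s = tau,
                      t_since_switch_s = 3 * tau, c50 = 0.3, n_hill = 2,
                      noise_sd_uv = 0)
  eff <- extract_b_wave(tr3)$amplitude_uv / naka_rushton(1, 1, 0.3, 2)
  expect_equal((g1 - eff) / (g1 - g0), exp(-3), tolerance = 1e-6)

  expect_error(simulate_erg(0.5, noise_sd_uv = -1), "noise")
  expect_error(simulate_erg(1.5), "contrast")
})

test_that("b-wave extraction is invariant to DC offset and time origin", {
  tr <- simulate_erg(0.5, gain_uv = 35, noise_sd_uv = 0)
  a0 <- extract_b_wave(tr)$amplitude_uv
  tr$uv <- tr$uv + 17.3
  expect_equal(extract_b_wave(tr)$amplitude_uv, a0, tolerance = 1e-9)
  tr2 <- simulate_erg(0.5, gain_uv = 35, noise_sd_uv = 0,
                      flash_onset_s = 0.15, duration_s = 0.45)
  expect_equal(extract_b_wave(tr2)$amplitude_uv, a0, tolerance = 1e-9)
  expect_error(extract_b_wave(tr, window_s = 2), "window")
})

test_that("adaptation time constant is recovered within 25%", {
  # the per-replicate estimate is unbiased but heavy-tailed (barely one
  # time constant of data), so the recovery claim is about the median over
  # replicates
  tau <- 180
  recov <- vapply(1:100, function(rep) {
    set.seed(rep)
    tt <- 0:179
    amp <- 40 - (40 - 20) * exp(-tt / tau) + stats::rnorm(180, 0, 4)
    adaptation_timecourse(tt, amp, bin_s = 20)$tau_s
  }, numeric(1))
  expect_lt(abs(stats::median(recov) - tau) / tau, 0.25)
})

test_that("flat series flags the time constant unidentifiable", {
  set.seed(3)
  tt <- 0:119
  amp <- rep(30, 120) + stats::rnorm(120, 0, 2)
  fit <- adaptation_timecourse(tt, amp, bin_s = 20)
  expect_false(fit$identifiable)
  expect_error(adaptation_timecourse(c(0, 1), c(1, 2), bin_s = 10), "bins")
})

test_that("adaptation reverses: recovery plateau matches the initial one", {
  tau <- 120; set.seed(8)
  seg <- function(from, to) {
    tt <- 0:599
    to + (from - to) * exp(-tt / tau) + stats::rnorm(600, 0, 2)
  }
  mellow1 <- seg(40, 40)          # steady mel-low
  daylight <- seg(40, 24)         # adapt down in daylight
  mellow2 <- seg(24, 40)          # recovery
  win <- 450:599
  p1 <- mean(mellow1[win]); p2 <- mean(mellow2[win])
  sem <- stats::sd(mellow1[win]) / sqrt(length(win))
  expect_lt(abs(p1 - p2), 4 * sem + 40 * exp(-450 / tau))
  expect_lt(mean(daylight[win]), p1 - 10)
})

test_that("Naka-Rushton fits recover parameters and compare conditions", {
  cgrid <- c(0.05, 0.1, 0.2, 0.35, 0.58, 0.9)
  noiseless <- data.frame(contrast = cgrid,
                          amplitude = naka_rushton(cgrid, 1, 0.3, 2))
  fit <- fit_contrast_response(noiseless, compare = FALSE)
  cf <- coef(fit)
  expect_equal(unname(cf[1, ]), c(1, 0.3, 2), tolerance = 1e-6)

  # fixed point: refitting the fit's own predictions returns the same curve
  pred <- data.frame(contrast = cgrid,
                     amplitude = predict(fit, cgrid, "all"))
  fit2 <- fit_contrast_response(pred, compare = FALSE)
  expect_equal(coef(fit2)[1, ], cf[1, ], tolerance = 1e-6)

  # fitted curves are non-decreasing in contrast
  cc <- seq(0, 1, by = 0.01)
  expect_true(all(diff(predict(fit, cc, "all")) >= -1e-12))

  # identical data in both conditions -> F ~ 0, p ~ 1
  set.seed(41)
  noisy <- noiseless
  noisy$amplitude <- noisy$amplitude + stats::rnorm(6, 0, 0.02)
  same <- rbind(cbind(noisy, condition = "a"),
                cbind(noisy, condition = "b"))
  fs <- fit_contrast_response(same)
  expect_lt(fs$f_test$F, 1e-6)
  expect_gt(fs$f_test$p, 0.99)

  expect_error(fit_contrast_response(noiseless[1:3, ]), "contrast levels")
})

test_that("the F test detects a 30% gain difference with high power", {
  cgrid <- c(0.05, 0.1, 0.2, 0.35, 0.58, 0.9)
  hits <- 0
  for (i in 1:100) {
    set.seed(i)
    d <- do.call(rbind, lapply(c(a = 1, b = 0.7), function(rmax) {
      data.frame(contrast = rep(cgrid, each = 6),
                 amplitude = naka_rushton(rep(cgrid, each = 6), rmax,
                                          0.3, 2) +
                   stats::rnorm(36, 0, 0.05))
    }))
    d$condition <- rep(c("a", "b"), each = 36)
    ft <- fit_contrast_response(d)$f_test
    if (!is.null(ft) && is.finite(ft$p) && ft$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
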