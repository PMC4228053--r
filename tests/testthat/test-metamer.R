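mouse4 <- function() mouse_templates()[c("SWS", "melanopsin", "rod",
                                         "LWS_human")]

test_that("receptor matrix entries equal per-cell oracle integrations", {
  tps <- mouse_templates()
  pr <- default_led_primaries()
  R <- receptor_matrix(pr, tps)
  for (r in names(tps)) for (p in names(pr$spds)) {
    oracle <- trapz_oracle(
      pr$wavelengths_nm,
      pr$spds[[p]]$photon_flux *
        stats::approx(tps[[r]]$wavelengths_nm, tps[[r]]$sensitivity,
                      pr$wavelengths_nm, rule = 2)$y)
    expect_equal(R[r, p], oracle, tolerance = 1e-9 * max(oracle, 1))
  }
  # doubling a primary's SPD doubles its column
  pr2 <- primary_set(c(pr$spds[1], list(bright = scale_spd(pr$spds[[2]], 2))))
  R2 <- receptor_matrix(pr2, tps)
  expect_equal(R2[, "bright"], 2 * R[, 2], tolerance = 1e-12)
})

test_that("solve_metamer recovers a known weight vector from exact fluxes", {
  tps <- mouse_templates()[c("SWS", "rod", "LWS_human")]
  pr <- default_led_primaries()
  R <- receptor_matrix(pr, tps)
  w0 <- c(0.31, 0.52, 0.18)
  target <- drop(R %*% w0)
  cons <- lapply(names(tps), function(r)
    design_constraint(r, "match_flux", 1, target[[r]]))
  sol <- solve_metamer(pr, tps, cons, n_spectra = 1)
  expect_true(sol$feasible)
  expect_equal(drop(sol$weights), w0, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rod+melanopsin silencing yields a nonzero cone modulation", {
  tps <- mouse4()
  pr <- default_led_primaries()
  R <- receptor_matrix(pr, tps)
  bg <- drop(R %*% c(0.3, 0.3, 0.3))
  cons <- c(
    lapply(names(tps), function(r)
      design_constraint(r, "match_flux", 1, bg[[r]], hard = FALSE)),
    list(design_constraint("melanopsin", "match_across_spectra", c(1, 2)),
         design_constraint("rod", "match_across_spectra", c(1, 2)),
         design_constraint("LWS_human", "contrast_target", c(1, 2), 0.2,
                           hard = TRUE, direction = -1)))
  sol <- solve_metamer(pr, tps, cons, n_spectra = 2)
  expect_true(sol$feasible)
  expect_gt(sum(abs(sol$weights[1, ] - sol$weights[2, ])), 1e-4)
  expect_lt(michelson_contrast(sol$fluxes[1, "melanopsin"],
                               sol$fluxes[2, "melanopsin"]), 1e-9)
  expect_lt(michelson_contrast(sol$fluxes[1, "rod"],
                               sol$fluxes[2, "rod"]), 1e-9)
})

test_that("out-of-gamut targets are flagged infeasible, not clipped", {
  tps <- mouse_templates()[c("SWS", "rod", "LWS_human")]
  pr <- default_led_primaries()
  R <- receptor_matrix(pr, tps)
  # ask for fluxes requiring drives far above the box
  target <- drop(R %*% c(5, 5, 5))
  cons <- lapply(names(tps), function(r)
    design_constraint(r, "match_flux", 1, target[[r]], hard = TRUE))
  sol <- solve_metamer(pr, tps, cons, n_spectra = 1)
  expect_false(sol$feasible)
  expect_true(any(sol$weights > 1))   # reported unclipped
})

test_that("solver matches a dense grid-search oracle on a 2x2 toy problem", {
  grid <- 300:780
  spds <- list(A = led_spd(430, 30, grid), B = led_spd(570, 30, grid))
  pr <- primary_set(spds)
  tps <- list(P1 = pigment_template(450, grid),
              P2 = pigment_template(550, grid))
  R <- receptor_matrix(pr, tps)
  target <- drop(R %*% c(0.43, 0.27)) * c(1.1, 0.8)
  cons <- list(design_constraint("P1", "match_flux", 1, target[[1]]),
               design_constraint("P2", "match_flux", 1, target[[2]]))
  sol <- solve_metamer(pr, tps, cons, n_spectra = 1)
  gridw <- seq(0, 1, by = 0.001)
  resid <- outer(gridw, gridw, function(w1, w2)
    (R[1, 1] * w1 + R[1, 2] * w2 - target[1])^2 +
      (R[2, 1] * w1 + R[2, 2] * w2 - target[2])^2)
  best <- min(resid) / sum(target^2)
  got <- sum((drop(R %*% drop(sol$weights)) - target)^2) / sum(target^2)
  expect_lt(got, best + 1e-6)
})

test_that("achieved fluxes round-trip through synthesized spectra", {
  tps <- mouse4()
  pr <- default_led_primaries()
  sol <- design_daylight_mellow(pr, tps, daylight_flux_profile(pr, tps))
  R <- receptor_matrix(pr, tps)
  direct <- sol$weights %*% t(R)
  expect_equal(unclass(sol$fluxes), unclass(direct), tolerance = 1e-10)
})

test_that("daylight/mel-low quartet meets its design constraints", {
  tps <- mouse4()
  pr <- default_led_primaries()
  prof <- daylight_flux_profile(pr, tps)

  # degenerate request: no contrast, no attenuation -> four identical spectra
  sol0 <- design_daylight_mellow(pr, tps, prof, cone_contrast = 0,
                                 mel_attenuation = 1)
  expect_true(sol0$feasible)
  expect_lt(max(abs(sweep(sol0$weights, 2, sol0$weights[1, ]))), 1e-8)

  sol <- design_daylight_mellow(pr, tps, prof)
  expect_true(sol$feasible)
  f <- sol$fluxes
  expect_equal(f["spectrum_1", "melanopsin"] / f["spectrum_3", "melanopsin"],
               10, tolerance = 0.01)
  for (cn in c("SWS", "LWS_human")) {
    expect_lt(michelson_contrast(f["spectrum_1", cn], f["spectrum_3", cn]),
              1e-6)
    expect_lt(michelson_contrast(f["spectrum_2", cn], f["spectrum_4", cn]),
              1e-6)
  }
  for (pair in list(1:2, 3:4)) for (rn in c("melanopsin", "rod")) {
    expect_lt(michelson_contrast(f[pair[1], rn], f[pair[2], rn]), 1e-6)
  }
  # the carrier cone realises the requested 58% step
  carrier <- sol$contrast_convention$cone
  expect_equal(unname(sol$cone_contrasts[carrier]), 0.58, tolerance = 1e-6)
})

test_that("gamut-feasible designs scale with the primaries' output", {
  tps <- mouse4()
  pr1 <- default_led_primaries(total_flux = 1e14)
  pr2 <- default_led_primaries(total_flux = 2e14)
  prof <- daylight_flux_profile(pr1, tps)
  s1 <- design_daylight_mellow(pr1, tps, prof)
  s2 <- design_daylight_mellow(pr2, tps, 2 * prof)
  expect_true(s1$feasible && s2$feasible)
  expect_equal(unclass(s2$fluxes), unclass(2 * s1$fluxes),
               tolerance = 1e-6)
})
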