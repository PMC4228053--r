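test_that("pigment template peaks at 1 at lambda_max and matches the A1 nomogram", {
  grid <- 300:780
  tp <- pigment_template(480, grid)
  expect_equal(tp$sensitivity[grid == 480], 1, tolerance = 1e-3)
  expect_true(all(tp$sensitivity >= 0))

  # independent evaluation of the published template constants
  rod <- pigment_template(498, grid)
  oracle <- gov_oracle(498, grid)
  oracle <- oracle / max(oracle)
  expect_equal(rod$sensitivity[grid == 560], oracle[grid == 560],
               tolerance = 1e-10)
  expect_equal(rod$sensitivity[grid == 560], 0.2639975, tolerance = 1e-6)

  # unimodal on the alpha band: no interior local minima between the
  # beta-band shoulder and lambda_max
  alpha_band <- grid >= 440 & grid <= 498
  s <- rod$sensitivity[alpha_band]
  expect_true(all(diff(s) > 0))

  expect_error(pigment_template(250), "lambda_max")
  expect_error(pigment_template(700), "lambda_max")
})

test_that("template peak normalisation holds across the lambda_max range", {
  for (lm in seq(340, 620, by = 40)) {
    tp <- pigment_template(lm, 300:780)
    expect_lt(abs(max(tp$sensitivity) - 1), 1e-3)
  }
})

test_that("effective photon flux integrates SPD x sensitivity", {
  grid <- 300:780
  rod <- pigment_template(498, grid)

  # narrow line at lambda_max with known trapezoid integral N -> flux N
  line <- rep(0, length(grid))
  line[grid %in% 497:499] <- c(0, 1e12, 0)
  s <- spd(grid, line)
  n_photons <- trapz_oracle(grid, line)
  expect_equal(effective_photon_flux(s, rod), n_photons, tolerance = 1e-3)

  # linearity
  s2 <- spd(grid, 2 * line)
  expect_equal(effective_photon_flux(s2, rod),
               2 * effective_photon_flux(s, rod), tolerance = 1e-12)

  # flat SPD over 400-700 nm vs brute-force trapezoid on the 1 nm grid
  flat <- ifelse(grid >= 400 & grid <= 700, 1e10, 0)
  sf <- spd(grid, flat)
  oracle <- trapz_oracle(grid, flat * rod$sensitivity)
  expect_equal(effective_photon_flux(sf, rod), oracle,
               tolerance = 1e-6 * oracle)

  # disjoint ranges error
  tp_uv <- pigment_template(360, 300:400)
  expect_error(effective_photon_flux(spd(600:700, rep(1, 101)), tp_uv),
               "disjoint")
})

test_that("effective flux is linear and non-negative for random SPDs", {
  grid <- seq(300, 780, by = 2)
  tp <- pigment_template(508, grid)
  set.seed(7)
  for (i in 1:20) {
    f1 <- stats::runif(length(grid), 0, 1e10)
    f2 <- stats::runif(length(grid), 0, 1e10)
    a <- stats::runif(1, 0, 3)
    fl <- function(v) effective_photon_flux(spd(grid, v), tp)
    expect_gte(fl(f1), 0)
    expect_equal(fl(a * f1 + f2), a * fl(f1) + fl(f2),
                 tolerance = 1e-9 * fl(f2))
  }
})

test_that("Michelson contrast follows (max-min)/(max+min)", {
  expect_equal(michelson_contrast(5e12, 5e12), 0)
  r <- 1.58 / 0.42   # solves (r-1)/(r+1) = 0.58
  expect_equal(michelson_contrast(r * 1e12, 1e12), 0.58, tolerance = 1e-12)
  expect_equal(michelson_contrast(3e10, 7e11),
               michelson_contrast(7e11, 3e10))
  expect_error(michelson_contrast(0, 0), "undefined")
  set.seed(1)
  for (i in 1:20) {
    a <- stats::runif(1, 0, 1e12); b <- stats::runif(1, 0, 1e12)
    m <- michelson_contrast(a, b)
    expect_true(m >= 0 && m <= 1)
    expect_equal(m, abs(a - b) / (a + b))
  }
})

test_that("receptor profile matches per-template fluxes and daylight pattern", {
  grid <- 300:780
  tps <- mouse_templates(grid)
  zero <- spd(grid, rep(0, length(grid)))
  expect_true(all(receptor_profile(zero, tps) == 0))

  bb <- blackbody_spd(6500, grid)
  prof <- receptor_profile(bb, tps)
  for (nm in names(tps))
    expect_identical(prof[[nm]], effective_photon_flux(bb, tps[[nm]]))
  # melanopsin and rod fluxes of a broadband daylight-like spectrum are
  # within 2-fold of each other
  ratio <- prof[["melanopsin"]] / prof[["rod"]]
  expect_true(ratio > 0.5 && ratio < 2)
})

test_that("SPD round-trips through CSV", {
  grid <- seq(350, 750, by = 5)
  s <- spd(grid, stats::runif(length(grid), 0, 1e12))
  path <- tempfile(fileext = ".csv")
  write_spd(s, path)
  s2 <- read_spd(path)
  expect_equal(s2$wavelengths_nm, s$wavelengths_nm)
  expect_equal(s2$photon_flux, s$photon_flux)
})
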