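#' Synthetic cohort configuration
#'
#' Assembles and validates the configuration of a full synthetic experiment:
#' a population of LNP model units recorded under the daylight and mel-low
#' spectral conditions across the standard stimulus battery (full-field
#' flashes, contrast-inverting gratings over a spatial-frequency grid,
#' drifting gratings over temporal frequencies and directions, a naturalistic
#' movie surrogate), plus flash ERG series over a contrast grid.
#'
#' The wild-type defaults plant the melanopsin-dependent effects under
#' study: in daylight, affected units acquire a strong inhibitory surround
#' (lower full-field flash response, preference for higher spatial
#' frequency), direction-selective units shift their deepest selectivity
#' from 0.2 Hz to 1 Hz, movie responses become more reliable, and the shared
#' drive between simultaneously recorded units weakens (lower signal
#' correlation); flash reliability is higher in mel-low, matched to the
#' amplitude effect. A knockout cohort (`knockout = TRUE`) draws both
#' conditions from identical parameters.
#'
#' @param ... overrides of the default fields (unknown names are an error).
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_units = 40L,              # flash / grating population
    n_responsive = NULL,        # planted flash-responsive count (default all)
    frac_flash_effect = 0.75,   # fraction with larger flash response in mel-low
    knockout = FALSE,
    conditions = c("daylight", "mel_low"),
    # planted condition-dependent parameters
    surround_daylight = 0.8,
    surround_mellow = 0,
    reliability_flash = c(daylight = 0.55, mel_low = 0.9),
    reliability_grating = c(daylight = 0.95, mel_low = 0.75),
    reliability_movie = c(daylight = 0.9, mel_low = 0.55),
    shared_drive_movie = c(daylight = 0.3, mel_low = 0.6),
    ds_fraction = 0.16,
    ds_strength = 0.8,
    ds_tf_peak = c(daylight = 1, mel_low = 0.2),
    # unit parameter ranges; widths are right-skewed over the observed
    # range (most dLGN centres are small), Beta(1.2, 4) over the range
    rf_width_range = c(5.6, 23),
    rf_width_beta = c(1.2, 4),
    gain_range = c(40, 80),
    baseline_range = c(2, 8),
    tau_s = 0.04,
    # movie sub-population grouped into animals (within-animal pairs)
    movie_units_per_animal = c(5L, 4L, 4L, 4L),
    # stimulus battery
    flash_contrast = 0.58, flash_duration = 0.05, flash_onset = 0.25,
    trial_duration_flash = 1,
    sf_grid = c(0.0175, 0.035, 0.07, 0.14, 0.28, 0.56),
    orientations = c(0, 45, 90, 135),
    grating_contrast = 0.8, grating_duration = 4,
    grating_phases = c(0, pi / 2),   # quadrature pair: phase-independent tuning
    inversions_per_cycle = 2, grating_tf = 1,
    tf_grid = c(0.2, 0.5, 1, 2),
    directions = seq(0, 315, by = 45),
    # drift duration covers one full cycle at the slowest TF (0.2 Hz), so
    # mean rates are direction-balanced for untuned units
    drift_sf = 0.035, drift_duration = 5, drift_contrast = 0.8,
    movie_duration = 30, movie_frame_rate = 10, movie_contrast_sd = 0.5,
    # trial counts
    n_flash_trials = 100L, n_grating_trials = 20L,
    n_drift_trials = 10L, n_movie_trials = 50L,
    # ERG
    erg_contrast_grid = c(0.04, 0.1, 0.2, 0.35, 0.58, 0.9),
    erg_gain = c(daylight = 28, mel_low = 40),
    erg_c50 = 0.3, erg_n = 2, erg_noise_sd = 2, n_erg_trials = 6L,
    # geometry / rendering
    px_deg = 1, screen_width = 100, screen_height = 60,
    dt_flash_s = 0.005, dt_s = 0.02, stim_seed = 99L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("cohort_config: unknown fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (is.null(cfg$n_responsive)) cfg$n_responsive <- cfg$n_units
  stopifnot(cfg$n_units >= 1, cfg$n_responsive <= cfg$n_units,
            cfg$frac_flash_effect >= 0, cfg$frac_flash_effect <= 1)
  structure(cfg, class = "cohort_config")
}

#' Pre-render the stimulus battery of a cohort
#'
#' The battery is a property of the experiment, not of the animal: it is
#' rendered once (seeded by `stim_seed`) and can be reused across cohorts.
#'
#' @param config a [cohort_config].
#' @return Named list of stimulus sets used by [make_cohort].
#' @export
cohort_stimuli <- function(config) {
  scr <- screen_geometry(config$screen_width, config$screen_height,
                         config$px_deg)
  flash <- render_stimulus("full_field_flash", contrast = config$flash_contrast,
                           flash_duration = config$flash_duration,
                           onset = config$flash_onset,
                           duration = config$trial_duration_flash,
                           screen = scr)
  sf <- list()
  for (ori in config$orientations)
    for (s in config$sf_grid)
      for (ip in seq_along(config$grating_phases))
        sf[[sprintf("ori%g_sf%g_ph%d", ori, s, ip)]] <-
          render_stimulus("inverting_grating", sf_cpd = s,
                          tf_hz = config$grating_tf,
                          orientation_deg = ori,
                          contrast = config$grating_contrast,
                          duration = config$grating_duration,
                          inversions_per_cycle = config$inversions_per_cycle,
                          phase = config$grating_phases[ip], screen = scr)
  drift <- list()
  for (tf in config$tf_grid)
    for (d in config$directions)
      drift[[sprintf("tf%g_dir%g", tf, d)]] <-
        render_stimulus("drifting_grating", sf_cpd = config$drift_sf,
                        tf_hz = tf, direction_deg = d,
                        contrast = config$drift_contrast,
                        duration = config$drift_duration, screen = scr)
  movie <- render_stimulus("movie", duration = config$movie_duration,
                           frame_rate = config$movie_frame_rate,
                           contrast_sd = config$movie_contrast_sd,
                           seed = config$stim_seed, screen = scr)
  list(screen = scr, flash = flash, sf = sf, drift = drift, movie = movie)
}

# draw the ground-truth unit population
draw_units <- function(config, seed) {
  set.seed(seed)
  n <- config$n_units
  ko <- isTRUE(config$knockout)
  resp <- seq_len(n) <= config$n_responsive
  n_eff <- floor(config$frac_flash_effect * config$n_responsive + 0.5)
  affected <- rep(FALSE, n)
  affected[sample(which(resp), n_eff)] <- TRUE
  nds <- floor(config$ds_fraction * n + 0.5)
  is_ds <- rep(FALSE, n); is_ds[sample.int(n, nds)] <- TRUE

  s_ml <- config$surround_mellow
  s_dl <- if (ko) s_ml else config$surround_daylight
  pk_ml <- unname(config$ds_tf_peak[["mel_low"]])
  pk_dl <- if (ko) pk_ml else unname(config$ds_tf_peak[["daylight"]])
  units <- vector("list", n)
  for (i in seq_len(n)) {
    units[[i]] <- unit_spec(
      id = sprintf("u%03d", i),
      rf_center_deg = c(stats::runif(1, -30, 30), stats::runif(1, -15, 15)),
      rf_width_hm_deg = config$rf_width_range[1] +
        diff(config$rf_width_range) *
        stats::rbeta(1, config$rf_width_beta[1], config$rf_width_beta[2]),
      surround_strength = if (affected[i])
        c(daylight = s_dl, mel_low = s_ml) else
          c(daylight = s_ml, mel_low = s_ml),
      gain_hz = if (resp[i])
        stats::runif(1, config$gain_range[1], config$gain_range[2]) else
          stats::runif(1, 0, 2),
      tau_s = config$tau_s,
      ds_pref_deg = sample(config$directions, 1),
      ds_strength = if (is_ds[i]) config$ds_strength else 0,
      ds_tf_peak_hz = c(daylight = pk_dl, mel_low = pk_ml),
      baseline_hz = stats::runif(1, config$baseline_range[1],
                                 config$baseline_range[2]))
  }
  list(units = units, affected = affected, responsive = resp, is_ds = is_ds)
}

# reliability vector for a block under (possibly knockout) config
block_reliability <- function(config, field) {
  r <- config[[field]]
  if (isTRUE(config$knockout)) {
    v <- mean(r); r[] <- v
  }
  r
}

# filtered linear drive of many units for one stimulus: returns nb x n_units
batch_drive <- function(stim, rfmat, tau_s, dt_s) {
  dp <- crossprod(stim$patterns, rfmat)          # npat x n_units
  tt <- seq(dt_s / 2, stim$duration, by = dt_s)
  fi <- stim$frame_idx[findInterval(tt, stim$times)]
  x <- dp[fi, , drop = FALSE]                    # nb x n_units
  a <- exp(-dt_s / tau_s)
  apply(x, 2, function(col)
    as.numeric(stats::filter(col * (1 - a), a, method = "recursive")))
}

# Simulate all trials of one unit for one stimulus. `reliability` sets the
# trial-shared fraction of drive variance: per trial the drive is
# sqrt(r) * y + sqrt(1-r) * sd(y) * xi, with xi fresh frame-held Gaussian
# noise, so r is the expected trial-to-trial drive correlation; the same r
# also sets the log-normal gain-noise variance (1 - r).
sim_unit_trials <- function(y, fidx, n_frames, base, gain_m, reliability,
                            n_trials, dt_s, t_centres, duration) {
  nb <- length(y)
  r <- min(max(reliability, 0), 1)
  if (r < 1) {
    sdy <- stats::sd(y)
    xi <- matrix(stats::rnorm(n_frames * n_trials), n_frames)
    Y <- sqrt(r) * y + sqrt(1 - r) * sdy * xi[fidx, , drop = FALSE]
  } else {
    Y <- matrix(y, nb, n_trials)
  }
  g <- exp(stats::rnorm(n_trials, 0, gain_noise_sigma(r)))
  lam <- (base + gain_m * pmax(Y, 0)) * rep(g * dt_s, each = nb)
  counts <- stats::rpois(nb * n_trials, lam)
  nz <- which(counts > 0L)
  cnz <- counts[nz]
  bin <- rep.int((nz - 1L) %% nb + 1L, cnz)
  trial <- rep.int((nz - 1L) %/% nb + 1L, cnz)
  st <- t_centres[bin] + stats::runif(length(bin), -dt_s / 2, dt_s / 2)
  st <- pmin(pmax(st, 0), duration - 1e-9)
  list(trial = trial, t = st)
}

#' Generate a full synthetic cohort
#'
#' Simulates every unit of the configured population through the stimulus
#' battery under both spectral conditions, plus the flash ERG contrast
#' series. All randomness derives from `seed` (unit draws) and fixed
#' per-block offsets; rerunning with the same config and seed is
#' bit-identical.
#'
#' @param config a [cohort_config].
#' @param seed integer RNG seed.
#' @param stimuli optional precomputed [cohort_stimuli] (the battery is
#'   config-determined, so it may be shared across cohorts).
#' @return An object of class `"cohort"`: list with `config`, `seed`,
#'   `units` (ground truth), `spikes` (data frame: block, unit_id,
#'   condition, stim, trial, spike_time_s), `stim_meta`, `erg`
#'   (b-wave measurements with planted parameters), `movie_animal`
#'   (animal id per movie unit).
#' @export
make_cohort <- function(config, seed = 1, stimuli = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(stimuli)) stimuli <- cohort_stimuli(config)
  scr <- stimuli$screen
  gt <- draw_units(config, seed)
  units <- gt$units
  n <- length(units)
  conds <- config$conditions

  n_groups <- (1L + length(stimuli$sf) + length(stimuli$drift)) *
    length(conds) * n +
    sum(config$movie_units_per_animal) * length(conds)
  acc <- list(trial = vector("list", n_groups),
              t = vector("list", n_groups))
  grp <- list(block = character(n_groups), unit = character(n_groups),
              cond = character(n_groups), stim = character(n_groups),
              n = integer(n_groups))
  k_grp <- 0L
  push <- function(block, unit, cond, stim, sp) {
    k <- k_grp + 1L; k_grp <<- k
    acc$trial[[k]] <<- sp$trial
    acc$t[[k]] <<- sp$t
    grp$block[k] <<- block; grp$unit[k] <<- unit
    grp$cond[k] <<- cond; grp$stim[k] <<- stim
    grp$n[k] <<- length(sp$trial)
  }

  dt <- config$dt_s   # default time step (flash block overrides)
  rf_mats <- lapply(conds, function(cn)
    vapply(units, function(u) rf_weights(u, scr, cn), numeric(scr$npix)))
  names(rf_mats) <- conds
  gains <- vapply(units, `[[`, numeric(1), "gain_hz")
  bases <- vapply(units, `[[`, numeric(1), "baseline_hz")

  run_block <- function(block, stim_list, n_trials, rel_field, block_seed,
                        ds_mod = FALSE, dt = config$dt_s) {
    rel <- block_reliability(config, rel_field)
    set.seed(block_seed)
    for (sn in names(stim_list)) {
      stim <- stim_list[[sn]]
      tt <- seq(dt / 2, stim$duration, by = dt)
      fnum <- findInterval(tt, stim$times)
      for (cn in conds) {
        y <- batch_drive(stim, rf_mats[[cn]], config$tau_s, dt)
        rr <- cond_val(rel, cn)
        for (i in seq_len(n)) {
          m <- 1
          if (ds_mod && stim$kind == "drifting_grating") {
            depth <- ds_depth(units[[i]], stim$params$tf_hz, cn)
            m <- 1 + depth * cos((stim$params$direction_deg -
                                    cond_val(units[[i]]$ds_pref_deg, cn)) *
                                   pi / 180)
          }
          sp <- sim_unit_trials(y[, i], fnum, length(stim$times), bases[i],
                                gains[i] * m, rr, n_trials, dt, tt,
                                stim$duration)
          push(block, units[[i]]$id, cn, sn, sp)
        }
      }
    }
  }

  run_block("flash", list(flash = stimuli$flash), config$n_flash_trials,
            "reliability_flash", derive_seed(seed, 1L),
            dt = config$dt_flash_s)
  run_block("sf", stimuli$sf, config$n_grating_trials,
            "reliability_grating", derive_seed(seed, 2L))
  run_block("tfds", stimuli$drift, config$n_drift_trials,
            "reliability_grating", derive_seed(seed, 3L), ds_mod = TRUE)

  # movie block: dedicated sub-population with a condition-dependent shared
  # drive (common input), grouped into animals for within-animal pairing
  mu_per_an <- config$movie_units_per_animal
  n_mv <- sum(mu_per_an)
  movie_animal <- rep(seq_along(mu_per_an), mu_per_an)
  mv_idx <- rep_len(which(gt$responsive), n_mv)  # reuse responsive RF geometry
  stim <- stimuli$movie
  tt <- seq(dt / 2, stim$duration, by = dt)
  relm <- block_reliability(config, "reliability_movie")
  sharedw <- config$shared_drive_movie
  if (isTRUE(config$knockout)) sharedw[] <- mean(sharedw)
  set.seed(derive_seed(seed, 4L))
  # shared drive: filtered drive of a reference receptive field at screen
  # centre — spectrally matched to the units' own drives, so the mixing
  # weight moves pairwise correlations without changing per-unit
  # signal-to-noise
  ref <- unit_spec(id = "shared", rf_center_deg = c(0, 0),
                   rf_width_hm_deg = mean(config$rf_width_range),
                   surround_strength = 0, tau_s = config$tau_s)
  zsh <- batch_drive(stim, matrix(rf_weights(ref, scr, "mel_low"), ncol = 1),
                     config$tau_s, dt)[, 1]
  zsh <- (zsh - mean(zsh)) / stats::sd(zsh)
  fnum <- findInterval(tt, stim$times)
  # movie units keep condition-independent spatial parameters (mel-low RF):
  # the movie block plants reliability and shared-drive effects, spatial
  # retuning is probed by the grating blocks
  y_mv <- batch_drive(stim, rf_mats[["mel_low"]][, mv_idx, drop = FALSE],
                      config$tau_s, dt)
  for (cn in conds) {
    w <- cond_val(sharedw, cn)
    rr <- cond_val(relm, cn)
    for (j in seq_len(n_mv)) {
      i <- mv_idx[j]
      sdy <- stats::sd(y_mv[, j])
      z <- (y_mv[, j] - mean(y_mv[, j])) / sdy
      # orthogonalise the private drive against the shared one: 1/f movies
      # are dominated by global luminance structure that correlates every
      # RF drive, which would swamp the planted shared-drive weight
      z <- z - zsh * stats::cor(z, zsh)
      z <- z / stats::sd(z)
      mix <- sdy * (sqrt(1 - w^2) * z + w * zsh)
      sp <- sim_unit_trials(mix, fnum, length(stim$times), bases[i],
                            gains[i], rr, config$n_movie_trials, dt, tt,
                            stim$duration)
      push("movie", sprintf("m%02d", j), cn, "movie", sp)
    }
  }

  trial_all <- unlist(acc$trial, use.names = FALSE)
  spikes <- structure(
    list(block = rep.int(grp$block, grp$n),
         unit_id = rep.int(grp$unit, grp$n),
         condition = rep.int(grp$cond, grp$n),
         stim = rep.int(grp$stim, grp$n),
         trial = trial_all,
         spike_time_s = unlist(acc$t, use.names = FALSE)),
    class = "data.frame", row.names = .set_row_names(length(trial_all)))
  groups <- data.frame(block = grp$block, unit_id = grp$unit,
                       condition = grp$cond, stim = grp$stim,
                       end = cumsum(grp$n))
  groups$start <- groups$end - grp$n + 1L

  stim_meta <- rbind(
    data.frame(block = "flash", stim = "flash",
               duration = stimuli$flash$duration,
               n_trials = config$n_flash_trials),
    data.frame(block = "sf", stim = names(stimuli$sf),
               duration = config$grating_duration,
               n_trials = config$n_grating_trials),
    data.frame(block = "tfds", stim = names(stimuli$drift),
               duration = config$drift_duration,
               n_trials = config$n_drift_trials),
    data.frame(block = "movie", stim = "movie",
               duration = config$movie_duration,
               n_trials = config$n_movie_trials))

  # flash ERG contrast series, fully adapted in each condition
  eg <- config$erg_gain
  if (isTRUE(config$knockout)) eg[] <- mean(eg)
  erg <- expand.grid(condition = conds, contrast = config$erg_contrast_grid,
                     trial = seq_len(config$n_erg_trials),
                     stringsAsFactors = FALSE)
  erg$amplitude_uv <- NA_real_
  for (k in seq_len(nrow(erg))) {
    tr <- simulate_erg(erg$contrast[k],
                       gain_uv = cond_val(eg, erg$condition[k]),
                       c50 = config$erg_c50, n_hill = config$erg_n,
                       noise_sd_uv = config$erg_noise_sd,
                       seed = derive_seed(seed, 100L + k),
                       condition = erg$condition[k], trial = erg$trial[k])
    erg$amplitude_uv[k] <- extract_b_wave(tr)$amplitude_uv
  }

  structure(list(config = config, seed = seed, units = gt,
                 spikes = spikes, groups = groups, stim_meta = stim_meta,
                 erg = erg, movie_animal = movie_animal, stimuli = stimuli),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d units (%s), %d spikes over %d stimulus conditions, seed %d\n",
    x$config$n_units,
    if (isTRUE(x$config$knockout)) "knockout" else "wild-type",
    nrow(x$spikes), nrow(x$stim_meta), x$seed))
  invisible(x)
}

#' Extract one trial raster from a cohort
#'
#' @param cohort a [make_cohort] result.
#' @param block,unit_id,condition,stim selectors.
#' @return A [trial_raster].
#' @export
cohort_raster <- function(cohort, block, unit_id, condition, stim = NULL) {
  s <- cohort$spikes
  sel <- s$block == block & s$unit_id == unit_id & s$condition == condition
  if (!is.null(stim)) sel <- sel & s$stim == stim
  meta <- cohort$stim_meta[cohort$stim_meta$block == block &
                             (is.null(stim) | cohort$stim_meta$stim ==
                                (stim %||% cohort$stim_meta$stim)), ][1, ]
  trial_raster(data.frame(trial = s$trial[sel],
                          spike_time_s = s$spike_time_s[sel]),
               n_trials = meta$n_trials, duration = meta$duration,
               unit_id = unit_id, condition = condition)
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + k * 12345) %% 2147483647L)
}

# recompute the contiguous group index of a spikes table (used after
# round-tripping a cohort through CSV)
rebuild_groups <- function(spikes) {
  key <- paste(spikes$block, spikes$unit_id, spikes$condition, spikes$stim,
               sep = "\1")
  rl <- rle(key)
  ends <- cumsum(rl$lengths)
  parts <- strsplit(rl$values, "\1", fixed = TRUE)
  data.frame(block = vapply(parts, `[[`, "", 1),
             unit_id = vapply(parts, `[[`, "", 2),
             condition = vapply(parts, `[[`, "", 3),
             stim = vapply(parts, `[[`, "", 4),
             end = ends, start = ends - rl$lengths + 1L)
}
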