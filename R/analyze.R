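#' Run the full analysis battery on a cohort
#'
#' Computes, per unit and condition: full-field flash amplitude, latency and
#' trial-to-trial reproducibility; spatial-frequency tuning and preferred SF
#' from inversion-locked grating modulation; temporal-frequency tuning, DS
#' index and direction-sensitivity flag per temporal frequency; movie
#' autocorrelation and within-animal pairwise signal correlations; and the
#' ERG contrast-response fit comparing conditions.
#'
#' @param cohort a [make_cohort] result.
#' @param n_perm permutations for the direction-sensitivity test.
#' @param responsiveness_sd responsiveness criterion (baseline SDs).
#' @param high_corr_threshold threshold for the high-correlation pair
#'   sub-analysis.
#' @return An object of class `"cohort_analysis"`: list of data frames
#'   (`flash`, `sf`, `tfds`, `movie`, `pairs`) and the `erg_fit`.
#' @export
analyze_cohort <- function(cohort, n_perm = 1000, responsiveness_sd = 2,
                           high_corr_threshold = 0.25) {
  cfg <- cohort$config
  conds <- cfg$conditions
  tvec <- cohort$spikes$spike_time_s
  trvec <- cohort$spikes$trial
  gr <- cohort$groups
  if (is.null(gr)) gr <- rebuild_groups(cohort$spikes)
  genv <- new.env(hash = TRUE, size = nrow(gr) * 2L)
  for (k in seq_len(nrow(gr)))
    assign(paste(gr$block[k], gr$unit_id[k], gr$condition[k], gr$stim[k],
                 sep = "\1"), c(gr$start[k], gr$end[k]), envir = genv)
  get_tt <- function(block, unit, cond, stim) {
    se <- genv[[paste(block, unit, cond, stim, sep = "\1")]]
    if (is.null(se) || se[2] < se[1])
      return(list(t = numeric(), trial = integer()))
    i <- se[1]:se[2]
    list(t = tvec[i], trial = trvec[i])
  }
  fast_raster <- function(sp, n_trials, duration, unit, cond) {
    structure(data.frame(trial = sp$trial, spike_time_s = sp$t),
              n_trials = as.integer(n_trials), duration = duration,
              unit_id = unit, condition = cond,
              class = c("trial_raster", "data.frame"))
  }

  unit_ids <- vapply(cohort$units$units, `[[`, character(1), "id")
  onset <- cfg$flash_onset

  ## ---- flash block ----
  flash <- expand.grid(unit_id = unit_ids, condition = conds,
                       stringsAsFactors = FALSE)
  flash$amplitude_hz <- flash$latency_s <- flash$reliability_r <- NA_real_
  flash$responsive <- FALSE
  for (k in seq_len(nrow(flash))) {
    sp <- get_tt("flash", flash$unit_id[k], flash$condition[k], "flash")
    ra <- fast_raster(sp, cfg$n_flash_trials, cfg$trial_duration_flash,
                      flash$unit_id[k], flash$condition[k])
    ps <- suppressWarnings(build_psth(ra, 0.01, c(0, onset)))
    flash$amplitude_hz[k] <- flash_response_amplitude(ps, onset)
    lat <- response_latency(ps, onset, min_sd = responsiveness_sd)
    flash$latency_s[k] <- lat$latency_s
    flash$responsive[k] <- lat$responsive
    flash$reliability_r[k] <- suppressWarnings(
      trial_reproducibility(ra, 0.025)$r)
  }

  ## ---- spatial frequency block (quadrature phases combined by RMS) ----
  sf_stim1 <- cohort$stimuli$sf[[1]]
  period <- sf_stim1$params$inversion_interval
  events <- sf_stim1$params$inversion_times
  events <- events[events >= period]
  nph <- length(cfg$grating_phases)
  sf_rows <- vector("list", length(unit_ids) * length(conds))
  ri <- 0L
  for (u in unit_ids) for (cn in conds) {
    resp <- expand.grid(orientation_deg = cfg$orientations,
                        sf_cpd = cfg$sf_grid)
    resp$modulation_hz <- NA_real_
    for (k in seq_len(nrow(resp))) {
      m2 <- 0
      for (ip in seq_len(nph)) {
        sn <- sprintf("ori%g_sf%g_ph%d", resp$orientation_deg[k],
                      resp$sf_cpd[k], ip)
        sp <- get_tt("sf", u, cn, sn)
        m2 <- m2 + core_inversion_mod(sp$t, cfg$n_grating_trials, period,
                                      events, trials = sp$trial)^2
      }
      resp$modulation_hz[k] <- sqrt(m2)
    }
    tc <- spatial_frequency_tuning(resp)
    ri <- ri + 1L
    sf_rows[[ri]] <- data.frame(
      unit_id = u, condition = cn, preferred_sf_cpd = tc$preferred,
      preferred_orientation_deg = tc$preferred_orientation_deg,
      max_modulation_hz = max(tc$response))
  }
  sf <- do.call(rbind, sf_rows); rownames(sf) <- NULL

  ## ---- temporal frequency / direction block ----
  base_tbl <- stats::setNames(
    vapply(cohort$units$units, `[[`, numeric(1), "baseline_hz"), unit_ids)
  nb_drift <- floor(cfg$drift_duration / 0.05)
  tf_rows <- vector("list", length(unit_ids) * length(conds) *
                      length(cfg$tf_grid))
  ri <- 0L
  for (u in unit_ids) for (cn in conds) for (tf in cfg$tf_grid) {
    peak <- -Inf
    dir_lab <- rep(cfg$directions, each = cfg$n_drift_trials)
    trial_resp <- numeric(length(dir_lab))
    pos <- 0L
    for (d in cfg$directions) {
      sp <- get_tt("tfds", u, cn, sprintf("tf%g_dir%g", tf, d))
      rate <- tabulate(floor(sp$t / 0.05) + 1L, nbins = nb_drift) /
        (cfg$n_drift_trials * 0.05)
      peak <- max(peak, max(rate) - base_tbl[[u]])
      cnt <- tabulate(sp$trial, nbins = cfg$n_drift_trials)
      trial_resp[pos + seq_len(cfg$n_drift_trials)] <-
        cnt / cfg$drift_duration - base_tbl[[u]]
      pos <- pos + cfg$n_drift_trials
    }
    dsr <- direction_selectivity(
      data.frame(direction_deg = dir_lab, response = trial_resp),
      n_perm = n_perm, seed = derive_seed(cohort$seed, 1000L + ri))
    ri <- ri + 1L
    tf_rows[[ri]] <- data.frame(
      unit_id = u, condition = cn, tf_hz = tf, peak_hz = peak,
      dsi = dsr$dsi, ds_p = dsr$p_value,
      direction_sensitive = dsr$direction_sensitive,
      preferred_direction_deg = dsr$preferred_deg)
  }
  tfds <- do.call(rbind, tf_rows); rownames(tfds) <- NULL

  ## ---- movie block ----
  n_mv <- sum(cfg$movie_units_per_animal)
  mv_ids <- sprintf("m%02d", seq_len(n_mv))
  movie <- expand.grid(unit_id = mv_ids, condition = conds,
                       stringsAsFactors = FALSE)
  movie$animal <- rep(cohort$movie_animal, times = length(conds))
  movie$autocorrelation_r <- NA_real_
  mresp <- list()
  for (k in seq_len(nrow(movie))) {
    sp <- get_tt("movie", movie$unit_id[k], movie$condition[k], "movie")
    ra <- fast_raster(sp, cfg$n_movie_trials, cfg$movie_duration,
                      movie$unit_id[k], movie$condition[k])
    movie$autocorrelation_r[k] <- suppressWarnings(
      trial_reproducibility(ra, 0.025)$r)
    mresp[[paste(movie$unit_id[k], movie$condition[k])]] <-
      mean_response(ra, 0.025)
  }
  pair_rows <- list()
  for (an in unique(cohort$movie_animal)) {
    ids <- mv_ids[cohort$movie_animal == an]
    if (length(ids) < 2) next
    cmb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cmb))) for (cn in conds) {
      r <- signal_correlation(mresp[[paste(cmb[1, j], cn)]],
                              mresp[[paste(cmb[2, j], cn)]])
      pair_rows[[paste(an, j, cn)]] <- data.frame(
        animal = an, unit_a = cmb[1, j], unit_b = cmb[2, j],
        condition = cn, signal_r = r)
    }
  }
  pairs <- do.call(rbind, pair_rows); rownames(pairs) <- NULL
  wide <- stats::reshape(pairs, direction = "wide", timevar = "condition",
                         idvar = c("animal", "unit_a", "unit_b"))
  hc <- apply(wide[, grep("^signal_r", names(wide)), drop = FALSE], 1,
              function(z) any(z > high_corr_threshold, na.rm = TRUE))
  key2 <- paste(pairs$animal, pairs$unit_a, pairs$unit_b)
  wkey <- paste(wide$animal, wide$unit_a, wide$unit_b)
  pairs$high_correlation <- hc[match(key2, wkey)]

  ## ---- ERG ----
  ed <- data.frame(contrast = cohort$erg$contrast,
                   amplitude = cohort$erg$amplitude_uv,
                   condition = cohort$erg$condition)
  erg_fit <- fit_contrast_response(ed, normalize = FALSE, compare = TRUE)

  structure(list(flash = flash, sf = sf, tfds = tfds, movie = movie,
                 pairs = pairs, erg_fit = erg_fit,
                 config = cfg, seed = cohort$seed),
            class = "cohort_analysis")
}

#' Cross-condition comparison report
#'
#' The five headline comparisons between daylight and mel-low: full-field
#' flash amplitude (paired t), preferred spatial frequency (paired Wilcoxon
#' signed rank on log SF), direction-selectivity temporal-frequency
#' preference (paired t on the per-unit DSI difference between the highest
#' and lowest TF, over units direction-sensitive in either condition),
#' movie autocorrelation (paired t), and pairwise signal correlation
#' (paired t over pairs). P values are Bonferroni-adjusted across the five
#' tests; `significant` refers to the adjusted values at alpha = 0.05.
#'
#' Also reports the preferred-SF change classification
#' (higher-in-daylight / higher-in-mel-low / unchanged), the
#' direction-sensitivity prevalence by temporal frequency and condition,
#' the fraction of responsive units with larger flash responses in mel-low,
#' the amplitude-reliability correlation of the flash effect, and the ERG
#' F test.
#'
#' @param analysis a [analyze_cohort] result.
#' @param alpha significance level applied to adjusted p values.
#' @return An object of class `"condition_report"`; element `tests` is a
#'   data frame with one row per comparison.
#' @export
compare_conditions <- function(analysis, alpha = 0.05) {
  fl <- analysis$flash
  dl <- fl[fl$condition == "daylight", ]
  ml <- fl[fl$condition == "mel_low", ]
  dl <- dl[match(ml$unit_id, dl$unit_id), ]
  use <- dl$responsive | ml$responsive

  tests <- list()
  add <- function(name, stat, p, direction, n) {
    tests[[name]] <<- data.frame(comparison = name, statistic = stat,
                                 p_raw = p, direction = direction, n = n)
  }
  safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  # 1. flash amplitude
  d_amp <- dl$amplitude_hz[use] - ml$amplitude_hz[use]
  p1 <- safe_p(stats::t.test(d_amp)$p.value)
  add("flash_amplitude", mean(d_amp), p1,
      if (mean(d_amp) < 0) "lower in daylight" else "higher in daylight",
      sum(use))

  # 2. preferred spatial frequency
  sf <- analysis$sf
  sdl <- sf[sf$condition == "daylight", ]
  sml <- sf[sf$condition == "mel_low", ]
  sdl <- sdl[match(sml$unit_id, sdl$unit_id), ]
  keep <- sdl$unit_id %in% ml$unit_id[use]
  d_sf <- log2(sdl$preferred_sf_cpd[keep]) - log2(sml$preferred_sf_cpd[keep])
  p2 <- safe_p(suppressWarnings(
    stats::wilcox.test(d_sf, exact = FALSE)$p.value))
  add("preferred_sf", mean(d_sf), p2,
      if (mean(d_sf) > 0) "higher in daylight" else "lower in daylight",
      sum(keep))
  sf_class <- table(factor(
    ifelse(d_sf > 0, "higher_in_daylight",
           ifelse(d_sf < 0, "higher_in_mel_low", "unchanged")),
    levels = c("higher_in_daylight", "higher_in_mel_low", "unchanged")))

  # 3. DS temporal-frequency preference
  td <- analysis$tfds
  tf_lo <- min(td$tf_hz); tf_hi <- max(td$tf_hz[td$tf_hz <= 1])
  ds_units <- unique(td$unit_id[td$direction_sensitive])
  d_ds <- NULL
  for (u in ds_units) {
    g <- function(cn, tf) td$dsi[td$unit_id == u & td$condition == cn &
                                   td$tf_hz == tf]
    d_ds <- c(d_ds, (g("daylight", tf_hi) - g("daylight", tf_lo)) -
                (g("mel_low", tf_hi) - g("mel_low", tf_lo)))
  }
  p3 <- if (length(d_ds) >= 3) safe_p(stats::t.test(d_ds)$p.value) else
    NA_real_
  add("ds_tf_preference", mean(d_ds %||% NA_real_), p3,
      if (isTRUE(mean(d_ds) > 0)) "faster in daylight" else
        "slower in daylight", length(d_ds))
  prevalence <- stats::aggregate(direction_sensitive ~ tf_hz + condition,
                                 data = td, FUN = sum)

  # 4. movie autocorrelation
  mv <- analysis$movie
  mdl <- mv[mv$condition == "daylight", ]
  mml <- mv[mv$condition == "mel_low", ]
  mdl <- mdl[match(mml$unit_id, mdl$unit_id), ]
  d_ac <- mdl$autocorrelation_r - mml$autocorrelation_r
  p4 <- safe_p(stats::t.test(d_ac)$p.value)
  add("movie_autocorrelation", mean(d_ac, na.rm = TRUE), p4,
      if (mean(d_ac, na.rm = TRUE) > 0) "higher in daylight" else
        "lower in daylight", sum(is.finite(d_ac)))

  # 5. signal correlation
  pr <- analysis$pairs
  pdl <- pr[pr$condition == "daylight", ]
  pml <- pr[pr$condition == "mel_low", ]
  kk <- paste(pml$animal, pml$unit_a, pml$unit_b)
  pdl <- pdl[match(kk, paste(pdl$animal, pdl$unit_a, pdl$unit_b)), ]
  d_sc <- pdl$signal_r - pml$signal_r
  p5 <- safe_p(stats::t.test(d_sc)$p.value)
  add("signal_correlation", mean(d_sc, na.rm = TRUE), p5,
      if (mean(d_sc, na.rm = TRUE) < 0) "lower in daylight" else
        "higher in daylight", sum(is.finite(d_sc)))
  d_sc_high <- d_sc[pml$high_correlation]
  p5h <- if (sum(is.finite(d_sc_high)) >= 3)
    safe_p(stats::t.test(d_sc_high)$p.value) else NA_real_

  tests <- do.call(rbind, tests); rownames(tests) <- NULL
  tests$p_adj <- pmin(1, tests$p_raw * nrow(tests))
  tests$significant <- !is.na(tests$p_adj) & tests$p_adj < alpha

  # auxiliary descriptive results
  frac_ml_larger <- mean((ml$amplitude_hz - dl$amplitude_hz)[use] > 0)
  d_rel <- dl$reliability_r[use] - ml$reliability_r[use]
  amp_rel_cor <- safe_p(stats::cor(d_amp, d_rel,
                                   use = "complete.obs"))

  structure(list(
    tests = tests, alpha = alpha,
    sf_classification = sf_class,
    ds_prevalence = prevalence,
    frac_larger_in_mellow = frac_ml_larger,
    amplitude_reliability_cor = amp_rel_cor,
    signal_correlation_high_p = p5h,
    erg_f_test = analysis$erg_fit$f_test,
    knockout = isTRUE(analysis$config$knockout)),
    class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> daylight vs mel-low (%s cohort)\n",
              if (x$knockout) "knockout" else "wild-type"))
  df <- x$tests
  df$p_raw <- signif(df$p_raw, 3); df$p_adj <- signif(df$p_adj, 3)
  df$statistic <- signif(df$statistic, 3)
  print(df, row.names = FALSE)
  cat(sprintf("fraction of units with larger flash response in mel-low: %.2f\n",
              x$frac_larger_in_mellow))
  cat("preferred-SF classification:\n"); print(x$sf_classification)
  cat("direction-sensitive units by TF:\n")
  print(x$ds_prevalence, row.names = FALSE)
  if (!is.null(x$erg_f_test))
    cat(sprintf("ERG contrast-response shared-vs-separate: F = %.3g, p = %.3g\n",
                x$erg_f_test$F, x$erg_f_test$p))
  invisible(x)
}
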