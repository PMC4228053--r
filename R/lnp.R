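#' Synthetic dLGN unit specification
#'
#' Ground-truth parameters for one linear-nonlinear-Poisson (LNP) model unit
#' with a difference-of-Gaussians (DoG) receptive field. Any parameter may be
#' a scalar (condition-independent) or a named vector keyed by condition
#' (e.g. `c(daylight = 0.8, mel_low = 0.2)`).
#'
#' @param id unit identifier.
#' @param rf_center_deg receptive-field centre, `c(azimuth, elevation)` in
#'   degrees.
#' @param rf_width_hm_deg half-maximum width of the RF centre Gaussian
#'   (degrees); the underlying SD is `width / (2 sqrt(2 log 2))`.
#' @param surround_strength relative surround weight in `[0, 1)`; the
#'   full-field gain of the DoG is `1 - surround_strength`.
#' @param surround_width_factor surround SD as a multiple of the centre SD.
#' @param gain_hz evoked firing gain (spikes/s per unit rectified drive).
#' @param tau_s exponential temporal-kernel time constant (s).
#' @param ds_pref_deg preferred motion direction (degrees).
#' @param ds_strength direction-selectivity depth in `[0, 1]`;
#'   0 = untuned.
#' @param ds_tf_peak_hz temporal frequency (Hz) at which direction
#'   selectivity is deepest; the depth falls off as a log-frequency
#'   Gaussian of SD `ds_tf_bw_oct` octaves around this peak.
#' @param ds_tf_bw_oct direction-selectivity TF bandwidth (octaves).
#' @param reliability trial-to-trial reliability in `[0, 1]`: per-trial
#'   multiplicative gain noise is log-normal with unit median and variance
#'   `1 - reliability` (0 noise at reliability 1).
#' @param baseline_hz spontaneous firing rate (spikes/s).
#' @return An object of class `"unit_spec"`.
#' @export
unit_spec <- function(id = "u1", rf_center_deg = c(0, 0),
                      rf_width_hm_deg = 14, surround_strength = 0,
                      surround_width_factor = 2, gain_hz = 60, tau_s = 0.04,
                      ds_pref_deg = 0, ds_strength = 0, ds_tf_peak_hz = 1,
                      ds_tf_bw_oct = 0.5, reliability = 1, baseline_hz = 4) {
  stopifnot(all(rf_width_hm_deg > 0), all(reliability >= 0 & reliability <= 1),
            all(baseline_hz >= 0), all(gain_hz >= 0),
            all(surround_strength >= 0 & surround_strength < 1))
  structure(list(id = id, rf_center_deg = rf_center_deg,
                 rf_width_hm_deg = rf_width_hm_deg,
                 surround_strength = surround_strength,
                 surround_width_factor = surround_width_factor,
                 gain_hz = gain_hz, tau_s = tau_s, ds_pref_deg = ds_pref_deg,
                 ds_strength = ds_strength, ds_tf_peak_hz = ds_tf_peak_hz,
                 ds_tf_bw_oct = ds_tf_bw_oct, reliability = reliability,
                 baseline_hz = baseline_hz),
            class = "unit_spec")
}

# condition-dependent parameter lookup: scalars pass through, named vectors
# are indexed by condition
cond_val <- function(x, condition) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && condition %in% names(x)) return(unname(x[[condition]]))
  unname(x[[1]])
}

hm_to_sd <- function(width_hm) width_hm / (2 * sqrt(2 * log(2)))

#' Difference-of-Gaussians receptive field weights
#'
#' Pixel weight vector of a DoG receptive field on a screen grid. The centre
#' Gaussian is normalised to unit sum, the surround likewise and scaled by
#' the surround strength, so a full-field stimulus of contrast c drives the
#' unit by `c * (1 - surround_strength)`.
#'
#' @param unit a [unit_spec].
#' @param screen a [screen_geometry].
#' @param condition condition label used to resolve per-condition
#'   parameters.
#' @return Numeric weight vector of length `screen$npix`.
#' @export
rf_weights <- function(unit, screen, condition = "daylight") {
  ctr <- unit$rf_center_deg
  sdc <- hm_to_sd(cond_val(unit$rf_width_hm_deg, condition))
  s <- cond_val(unit$surround_strength, condition)
  sds <- sdc * cond_val(unit$surround_width_factor, condition)
  d2 <- (screen$xs - ctr[1])^2 + (screen$ys - ctr[2])^2
  gc <- exp(-d2 / (2 * sdc^2)); gc <- gc / sum(gc)
  gs <- exp(-d2 / (2 * sds^2)); gs <- gs / sum(gs)
  gc - s * gs
}

# log-normal gain-noise SD (of log gain) such that Var(gain) = 1 - reliability
# with unit median: Var = exp(s^2)(exp(s^2)-1) = v  =>  exp(s^2) solves
# quadratic x(x-1) = v
gain_noise_sigma <- function(reliability) {
  v <- 1 - reliability
  if (v <= 0) return(0)
  sqrt(log((1 + sqrt(1 + 4 * v)) / 2))
}

#' Deterministic LNP firing rate of a unit for a stimulus
#'
#' Linear stage: DoG receptive field applied per frame, filtered in time by
#' a single-exponential kernel; static rectifying nonlinearity; a
#' multiplicative cosine direction modulation is applied for drifting
#' gratings. This is the noise-free intensity of the inhomogeneous Poisson
#' process that [simulate_unit] samples.
#'
#' @inheritParams rf_weights
#' @param stim a `stimulus_sequence` from [render_stimulus].
#' @param dt_s simulation time step (s).
#' @param drive_pat optional precomputed per-pattern drive (internal reuse).
#' @return List with `t` (bin centres) and `rate` (spikes/s).
#' @export
lnp_rate <- function(unit, stim, condition = "daylight", dt_s = 0.005,
                     drive_pat = NULL) {
  d <- lnp_drive(unit, stim, condition, dt_s, drive_pat)
  base <- cond_val(unit$baseline_hz, condition)
  g <- cond_val(unit$gain_hz, condition)
  list(t = d$t, rate = base + g * d$dsmod * pmax(d$y, 0), dt_s = dt_s)
}

# filtered linear drive and DS modulation factor of one unit
lnp_drive <- function(unit, stim, condition, dt_s, drive_pat = NULL) {
  if (is.null(drive_pat)) {
    rf <- rf_weights(unit, stim$screen, condition)
    drive_pat <- drop(crossprod(stim$patterns, rf))
  }
  tt <- seq(dt_s / 2, stim$duration, by = dt_s)
  x <- drive_pat[stim$frame_idx[findInterval(tt, stim$times)]]
  tau <- cond_val(unit$tau_s, condition)
  a <- exp(-dt_s / tau)
  y <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  dsmod <- 1
  if (stim$kind == "drifting_grating") {
    depth <- ds_depth(unit, stim$params$tf_hz, condition)
    dsmod <- 1 + depth *
      cos((stim$params$direction_deg - cond_val(unit$ds_pref_deg, condition)) *
            pi / 180)
  }
  list(t = tt, y = y, dsmod = dsmod)
}

# TF-dependent direction-selectivity depth (log2-frequency Gaussian)
ds_depth <- function(unit, tf_hz, condition) {
  d0 <- cond_val(unit$ds_strength, condition)
  if (d0 <= 0) return(0)
  pk <- cond_val(unit$ds_tf_peak_hz, condition)
  bw <- cond_val(unit$ds_tf_bw_oct, condition)
  d0 * exp(-((log2(tf_hz) - log2(pk))^2) / (2 * bw^2))
}

#' Simulate spike trains of an LNP unit
#'
#' Draws `n_trials` spike trains from an inhomogeneous Poisson process. The
#' unit's `reliability` r sets the trial-shared fraction of drive variance
#' (per trial the filtered drive is `sqrt(r) y + sqrt(1-r) sd(y) xi` with
#' fresh frame-held Gaussian noise xi, so r is the expected trial-to-trial
#' drive correlation) and, jointly, the variance `1 - r` of a log-normal
#' per-trial multiplicative gain (unit median), which couples response
#' amplitude to reliability.
#'
#' @inheritParams lnp_rate
#' @param n_trials number of trials (>= 1).
#' @param seed RNG seed.
#' @return A [trial_raster].
#' @export
simulate_unit <- function(unit, stim, n_trials, condition = "daylight",
                          seed = 1, dt_s = 0.005) {
  if (n_trials < 1) stop("simulate_unit: n_trials must be >= 1")
  d <- lnp_drive(unit, stim, condition, dt_s)
  base <- cond_val(unit$baseline_hz, condition)
  g0 <- cond_val(unit$gain_hz, condition) * d$dsmod
  y <- d$y
  r <- cond_val(unit$reliability, condition)

  set.seed(seed)
  tt <- d$t
  nb <- length(y)
  fnum <- findInterval(tt, stim$times)
  if (r < 1) {
    sdy <- stats::sd(y)
    xi <- matrix(stats::rnorm(length(stim$times) * n_trials),
                 length(stim$times))
    Y <- sqrt(r) * y + sqrt(1 - r) * sdy * xi[fnum, , drop = FALSE]
  } else {
    Y <- matrix(y, nb, n_trials)
  }
  g <- exp(stats::rnorm(n_trials, 0, gain_noise_sigma(r)))
  lam <- (base + g0 * pmax(Y, 0)) * rep(g * dt_s, each = nb)
  counts <- matrix(stats::rpois(nb * n_trials, lam), nrow = nb)
  tot <- colSums(counts)
  trial <- rep(seq_len(n_trials), tot)
  bin <- unlist(lapply(seq_len(n_trials), function(i)
    rep.int(seq_len(nb), counts[, i])), use.names = FALSE)
  st <- tt[bin] + stats::runif(length(bin), -dt_s / 2, dt_s / 2)
  st <- pmin(pmax(st, 0), stim$duration - 1e-9)
  o <- order(trial, st)
  trial_raster(data.frame(trial = trial[o], spike_time_s = st[o]),
               n_trials = n_trials, duration = stim$duration,
               unit_id = unit$id, condition = condition)
}

#' Trial-structured spike raster
#'
#' @param spikes data frame with columns `trial` (1-based index) and
#'   `spike_time_s` in `[0, duration)`.
#' @param n_trials total number of trials (trials without spikes allowed).
#' @param duration trial duration (s); trials are aligned to stimulus onset
#'   at t = 0.
#' @param unit_id,condition labels.
#' @return An object of class `"trial_raster"` (a data frame with
#'   attributes).
#' @export
trial_raster <- function(spikes, n_trials, duration, unit_id = "u1",
                         condition = "none") {
  stopifnot(is.data.frame(spikes), all(c("trial", "spike_time_s") %in%
                                         names(spikes)))
  if (nrow(spikes) &&
      (min(spikes$spike_time_s) < 0 || max(spikes$spike_time_s) >= duration))
    stop("trial_raster: spike times must lie in [0, duration)")
  if (nrow(spikes) && max(spikes$trial) > n_trials)
    stop("trial_raster: trial index exceeds n_trials")
  structure(spikes, n_trials = as.integer(n_trials), duration = duration,
            unit_id = unit_id, condition = condition,
            class = c("trial_raster", "data.frame"))
}

#' @export
print.trial_raster <- function(x, ...) {
  cat(sprintf("<trial_raster> unit %s [%s]: %d spikes, %d trials x %.3g s\n",
              attr(x, "unit_id"), attr(x, "condition"), nrow(x),
              attr(x, "n_trials"), attr(x, "duration")))
  invisible(x)
}
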