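#' Peri-stimulus time histogram
#'
#' Bins spike times across trials into half-open bins `[t, t + dt)` from
#' trial onset, as trate in spikes/s. The baseline rate is the mean rate
#' within a stated pre-stimulus window.
#'
#' @param raster a [trial_raster].
#' @param bin_width_s bin width (s).
#' @param baseline_window_s length-2 window `[t0, t1)` used for the
#'   baseline rate, or `NULL`.
#' @return An object of class `"psth"`: list with `edges`, `t` (bin
#'   centres), `rate` (spikes/s), `n_trials`, `baseline_hz`.
#' @export
build_psth <- function(raster, bin_width_s = 0.01, baseline_window_s = NULL) {
  if (bin_width_s <= 0) stop("bin_width_s must be positive")
  dur <- attr(raster, "duration"); ntr <- attr(raster, "n_trials")
  nb <- ceiling(dur / bin_width_s - 1e-9)
  edges <- seq(0, by = bin_width_s, length.out = nb + 1)
  if (nrow(raster) == 0) {
    warning("build_psth: empty raster")
    counts <- rep(0, nb)
  } else {
    counts <- tabulate(findInterval(raster$spike_time_s, edges,
                                    rightmost.closed = FALSE), nbins = nb)
  }
  rate <- counts / (ntr * bin_width_s)
  baseline <- NA_real_
  if (!is.null(baseline_window_s)) {
    tt <- edges[-length(edges)] + bin_width_s / 2
    sel <- tt >= baseline_window_s[1] & tt < baseline_window_s[2]
    baseline <- mean(rate[sel])
  }
  structure(list(edges = edges, t = edges[-length(edges)] + bin_width_s / 2,
                 rate = rate, bin_width_s = bin_width_s, n_trials = ntr,
                 baseline_hz = baseline,
                 condition = attr(raster, "condition"),
                 unit_id = attr(raster, "unit_id")),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins x %g s, %d trials, peak %.3g Hz, baseline %.3g Hz\n",
              length(x$rate), x$bin_width_s, x$n_trials, max(x$rate),
              x$baseline_hz))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  graphics::plot(x$t, x$rate, type = "s", xlab = "time (s)",
                 ylab = "rate (spikes/s)", ...)
  if (is.finite(x$baseline_hz))
    graphics::abline(h = x$baseline_hz, lty = 2, col = "grey50")
  invisible(x)
}

#' Flash response amplitude
#'
#' Mean baseline-subtracted firing rate over a post-onset window
#' (200 ms by convention).
#'
#' @param psth a [build_psth] result with a baseline.
#' @param onset_s flash onset time within the trial (s).
#' @param window_s response window length after onset (s).
#' @return Amplitude in spikes/s (positive = excitation).
#' @export
flash_response_amplitude <- function(psth, onset_s, window_s = 0.2) {
  sel <- psth$t >= onset_s & psth$t < onset_s + window_s
  if (!any(sel)) stop("response window not covered by PSTH")
  if (!is.finite(psth$baseline_hz))
    stop("flash_response_amplitude: PSTH has no baseline")
  mean(psth$rate[sel]) - psth$baseline_hz
}

#' Response latency from a PSTH
#'
#' Time of the peak bin after light smoothing (moving average), relative to
#' stimulus onset. Undefined when the response amplitude criterion fails
#' (peak below `min_sd` baseline SDs above baseline).
#'
#' @param psth a [build_psth] result.
#' @param onset_s stimulus onset (s).
#' @param smooth_bins moving-average width (bins).
#' @param min_sd responsiveness criterion in baseline SD units.
#' @return List with `latency_s` (NA when undefined) and `responsive`.
#' @export
response_latency <- function(psth, onset_s, smooth_bins = 3, min_sd = 2) {
  k <- rep(1 / smooth_bins, smooth_bins)
  sm <- stats::filter(psth$rate, k, sides = 2)
  sm[is.na(sm)] <- psth$rate[is.na(sm)]
  base_sel <- psth$t < onset_s
  bsd <- stats::sd(psth$rate[base_sel])
  bmu <- mean(psth$rate[base_sel])
  post <- which(psth$t >= onset_s)
  pk <- post[which.max(sm[post])]
  responsive <- is.finite(bsd) && sm[pk] > bmu + min_sd * max(bsd, 1e-9)
  list(latency_s = if (responsive) psth$t[pk] - onset_s else NA_real_,
       responsive = responsive, peak_rate_hz = psth$rate[pk])
}

#' Compare two population latency distributions via Gaussian fits
#'
#' Histograms of the two latency samples on shared breaks are each fitted
#' with a Gaussian curve, and with one shared Gaussian; an
#' extra-sum-of-squares F test asks whether separate curves explain the
#' histograms significantly better. The comparison is only attempted when
#' both per-condition fits have R-squared above `min_r2`.
#'
#' @param latency_a,latency_b latency samples (s).
#' @param bin_s histogram bin width (s).
#' @param min_r2 minimum per-fit R-squared to attempt the comparison.
#' @return List with per-condition fits (`mean`, `sd`, `r2`), `F`, `p`,
#'   `comparable`.
#' @export
latency_distribution_comparison <- function(latency_a, latency_b,
                                            bin_s = 0.01, min_r2 = 0.8) {
  all_l <- c(latency_a, latency_b)
  breaks <- seq(floor(min(all_l) / bin_s) * bin_s,
                ceiling(max(all_l) / bin_s + 1) * bin_s, by = bin_s)
  hg <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(t = h$mids, count = h$counts)
  }
  da <- hg(latency_a); db <- hg(latency_b)
  gfit <- function(d) {
    fit <- tryCatch(minpack.lm::nlsLM(
      count ~ a * exp(-((t - m)^2) / (2 * s^2)), data = d,
      start = list(a = max(d$count), m = d$t[which.max(d$count)],
                   s = max(bin_s, stats::sd(rep(d$t, d$count)))),
      lower = c(0, min(d$t), bin_s / 10),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    rss <- sum(stats::resid(fit)^2)
    r2 <- 1 - rss / sum((d$count - mean(d$count))^2)
    list(coef = stats::coef(fit), rss = rss, r2 = r2)
  }
  fa <- gfit(da); fb <- gfit(db)
  out <- list(fit_a = fa, fit_b = fb, comparable = FALSE,
              F = NA_real_, p = NA_real_)
  if (is.null(fa) || is.null(fb) || fa$r2 < min_r2 || fb$r2 < min_r2)
    return(out)
  both <- rbind(da, db)
  fsh <- gfit(both)
  if (is.null(fsh)) return(out)
  rss_sep <- fa$rss + fb$rss
  df_sep <- nrow(both) - 6; df_sh <- nrow(both) - 3
  Fstat <- max(0, ((fsh$rss - rss_sep) / (df_sh - df_sep)) /
                 (rss_sep / df_sep))
  out$comparable <- TRUE
  out$F <- Fstat
  out$p <- stats::pf(Fstat, df_sh - df_sep, df_sep, lower.tail = FALSE)
  out
}

# trials x bins count matrix for one raster
trial_bin_matrix <- function(raster, bin_width_s, window_s = NULL) {
  dur <- attr(raster, "duration"); ntr <- attr(raster, "n_trials")
  if (is.null(window_s)) window_s <- c(0, dur)
  nb <- floor((window_s[2] - window_s[1]) / bin_width_s + 1e-9)
  sel <- raster$spike_time_s >= window_s[1] &
    raster$spike_time_s < window_s[1] + nb * bin_width_s
  b <- floor((raster$spike_time_s[sel] - window_s[1]) / bin_width_s) + 1
  idx <- (raster$trial[sel] - 1L) * nb + b
  matrix(tabulate(idx, nbins = ntr * nb), nrow = ntr, byrow = TRUE)
}

#' Trial-to-trial response reproducibility
#'
#' Leave-one-out estimator: each trial's binned response is correlated
#' (Pearson) with the mean of all other trials, and the correlations are
#' averaged. Zero-variance trials are excluded; with fewer than 2 usable
#' trials the result is flagged undefined.
#'
#' @param raster a [trial_raster] (>= 4 trials).
#' @param bin_width_s bin width (s), 25 ms by default.
#' @param window_s optional analysis window `[t0, t1)`.
#' @return List with `r` (mean leave-one-out Pearson r, NA if undefined),
#'   `n_used` trials.
#' @export
trial_reproducibility <- function(raster, bin_width_s = 0.025,
                                  window_s = NULL) {
  if (attr(raster, "n_trials") < 4)
    stop("trial_reproducibility: need >= 4 trials")
  m <- trial_bin_matrix(raster, bin_width_s, window_s)
  rm_ <- rowMeans(m)
  v <- (rowSums(m^2) - ncol(m) * rm_^2) / (ncol(m) - 1)
  keep <- which(v > 0)
  if (length(keep) < 2) return(list(r = NA_real_, n_used = length(keep)))
  m <- m[keep, , drop = FALSE]
  tot <- colSums(m)
  rs <- vapply(seq_len(nrow(m)), function(i) {
    rest <- (tot - m[i, ]) / (nrow(m) - 1)
    if (stats::sd(rest) == 0) return(NA_real_)
    stats::cor(m[i, ], rest)
  }, numeric(1))
  list(r = mean(rs, na.rm = TRUE), n_used = nrow(m))
}

#' Spike-triggered-average receptive field from flickering bars
#'
#' Averages the signed bar stimulus over a lag window preceding each spike,
#' giving a one-dimensional RF profile over bar positions, then fits a
#' Gaussian (with offset). RF diameter is reported as the half-maximum
#' width `2 sqrt(2 ln 2) sigma`.
#'
#' @param raster a [trial_raster] recorded during `stim`.
#' @param stim a `bar_white_noise` stimulus from [render_stimulus].
#' @param lag_window_s STA lag window before each spike (s).
#' @return An object of class `"receptive_field"`: `positions_deg`,
#'   `sta`, Gaussian fit (`center_deg`, `width_hm_deg`, `amplitude`,
#'   `offset`, `r2`), `n_spikes`, `low_confidence` (TRUE below 100 spikes),
#'   `axis`.
#' @export
sta_receptive_field <- function(raster, stim, lag_window_s = c(0.02, 0.16)) {
  if (stim$kind != "bar_white_noise")
    stop("sta_receptive_field expects a bar_white_noise stimulus")
  fr <- stim$params$frame_rate
  pos <- stim$params$position_idx
  col <- stim$params$color
  npos <- length(stim$params$positions_deg)
  nf <- length(pos)
  lag_frames <- max(1L, floor(lag_window_s[1] * fr)):
    max(1L, ceiling(lag_window_s[2] * fr) - 1L)
  spike_frame <- floor(raster$spike_time_s * fr) + 1L
  acc <- numeric(npos); nacc <- 0
  for (o in lag_frames) {
    fidx <- spike_frame - o
    ok <- fidx >= 1 & fidx <= nf
    if (!any(ok)) next
    acc <- acc + vapply(seq_len(npos), function(p)
      sum(col[fidx[ok]][pos[fidx[ok]] == p]), numeric(1))
    nacc <- nacc + sum(ok)
  }
  sta <- if (nacc > 0) acc / nacc else acc
  n_spikes <- nrow(raster)

  d <- data.frame(x = stim$params$positions_deg, y = sta)
  pk <- which.max(abs(d$y - stats::median(d$y)))
  amp0 <- d$y[pk] - stats::median(d$y)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ a * exp(-((x - m)^2) / (2 * s^2)) + o, data = d,
    start = list(a = amp0, m = d$x[pk], s = 2 * stim$params$bar_width_deg,
                 o = stats::median(d$y)),
    lower = c(-Inf, min(d$x) - 20, stim$params$bar_width_deg / 10, -Inf),
    upper = c(Inf, max(d$x) + 20, diff(range(d$x)) * 2, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  center <- width <- amp <- off <- r2 <- NA_real_
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    center <- cf[["m"]]; amp <- cf[["a"]]; off <- cf[["o"]]
    width <- 2 * sqrt(2 * log(2)) * cf[["s"]]
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((d$y - mean(d$y))^2)
  }
  structure(list(positions_deg = d$x, sta = d$y, center_deg = center,
                 width_hm_deg = width, amplitude = amp, offset = off,
                 r2 = r2, n_spikes = n_spikes,
                 low_confidence = n_spikes < 100,
                 axis = stim$params$axis),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf(
    "<receptive_field> %s axis: center %.2f deg, half-max width %.2f deg (R2 %.2f, %d spikes%s)\n",
    x$axis, x$center_deg, x$width_hm_deg, x$r2, x$n_spikes,
    if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Modulation of firing locked to grating inversion events
#'
#' Builds an event-locked PSTH over the inversion interval and returns its
#' modulation amplitude (spikes/s) — the response measure for
#' contrast-inverting gratings. The raw peak-to-trough range of a PSTH is
#' biased upward by Poisson counting noise (more so for weak responses), so
#' the modulation is estimated from the debiased PSTH variance: the
#' expected Poisson contribution `mean rate / (bin width x events x
#' trials)` is subtracted from the across-bin variance, and the remainder
#' is scaled to a peak-to-trough-equivalent amplitude
#' (`2 sqrt(2 var_signal)`, exact for a sinusoidal profile).
#'
#' @param raster a [trial_raster].
#' @param stim the `inverting_grating` stimulus shown.
#' @param bin_width_s event-locked PSTH bin width (s).
#' @return Modulation amplitude (spikes/s, >= 0).
#' @export
inversion_modulation <- function(raster, stim, bin_width_s = 0.05) {
  if (stim$kind != "inverting_grating")
    stop("inversion_modulation expects an inverting_grating stimulus")
  period <- stim$params$inversion_interval
  events <- stim$params$inversion_times
  # skip the first inversion so the event-locked response is in steady state
  events <- events[events >= period]
  core_inversion_mod(raster$spike_time_s, attr(raster, "n_trials"),
                     period, events, bin_width_s, trials = raster$trial)
}

core_inversion_mod <- function(spike_times, n_trials, period, events,
                               bin_width_s = 0.05, trials = NULL) {
  # event-locked phase of each spike relative to the most recent inversion
  idx <- findInterval(spike_times, events)
  ok <- idx >= 1L
  ph <- spike_times[ok] - events[idx[ok]]
  keep <- ph < period
  ph <- ph[keep]
  nb <- max(2L, floor(period / bin_width_s))
  width <- period / nb
  bins <- floor(ph / width) + 1L
  if (is.null(trials) || n_trials < 2) {
    # single-sample fallback: across-bin variance debiased by the expected
    # Poisson contribution
    nrep <- n_trials * length(events)
    rate <- tabulate(bins, nbins = nb) / (nrep * width)
    v <- stats::var(rate) * (nb - 1) / nb
    noise_v <- mean(rate) / (width * nrep)
    return(2 * sqrt(2 * max(v - noise_v, 0)))
  }
  # trial-resolved signal variance: across-bin variance of the mean PSTH,
  # minus the trial-to-trial variance contribution /n. Noise is independent
  # across trials, so this estimates the stimulus-locked signal variance
  # without the rate-dependent upward bias of a raw peak-to-trough range.
  tr <- trials[ok][keep]
  nev <- length(events)
  cnt <- matrix(tabulate((tr - 1L) * nb + bins, nbins = n_trials * nb),
                nrow = nb)
  rate_tb <- cnt / (nev * width)
  mu <- rowMeans(rate_tb)
  v_between <- sum((mu - mean(mu))^2) / nb
  v_within <- mean((rowSums(rate_tb^2) - n_trials * mu^2) / (n_trials - 1))
  sig_v <- v_between - v_within / n_trials
  2 * sqrt(2 * max(sig_v, 0))
}

#' Spatial frequency tuning from inverting-grating responses
#'
#' Given inversion-locked modulation amplitudes on a (spatial frequency x
#' orientation) grid, selects the preferred orientation (the orientation of
#' the overall maximal response) and returns the modulation-vs-SF tuning
#' curve at that orientation. Preferred SF is the grid argmax; ties break
#' toward the lower frequency.
#'
#' @param responses data frame with columns `sf_cpd`, `orientation_deg`,
#'   `modulation_hz` (one row per grid point, e.g. from
#'   [inversion_modulation]).
#' @return An object of class `"tuning_curve"` with `parameter = "sf_cpd"`,
#'   `grid`, `response`, `preferred`, `preferred_orientation_deg`.
#' @export
spatial_frequency_tuning <- function(responses) {
  stopifnot(all(c("sf_cpd", "orientation_deg", "modulation_hz") %in%
                  names(responses)))
  if (length(unique(responses$sf_cpd)) < 3)
    stop("need >= 3 spatial frequencies")
  if (length(unique(responses$orientation_deg)) < 2)
    stop("need >= 2 orientations")
  best <- responses[which.max(responses$modulation_hz), ]
  sel <- responses[responses$orientation_deg == best$orientation_deg, ]
  sel <- sel[order(sel$sf_cpd), ]
  pref <- sel$sf_cpd[which.max(sel$modulation_hz)]  # which.max: lowest on tie
  structure(list(parameter = "sf_cpd", grid = sel$sf_cpd,
                 response = sel$modulation_hz, preferred = pref,
                 preferred_orientation_deg = best$orientation_deg),
            class = "tuning_curve")
}

#' Temporal frequency tuning from drifting-grating responses
#'
#' Per temporal frequency, the response is the peak firing rate (maximum
#' over directions of the baseline-subtracted PSTH peak).
#'
#' @param responses data frame with columns `tf_hz`, `direction_deg`,
#'   `peak_hz`.
#' @return A `"tuning_curve"` with `parameter = "tf_hz"`.
#' @export
temporal_frequency_tuning <- function(responses) {
  stopifnot(all(c("tf_hz", "direction_deg", "peak_hz") %in% names(responses)))
  agg <- stats::aggregate(peak_hz ~ tf_hz, data = responses, FUN = max)
  agg <- agg[order(agg$tf_hz), ]
  structure(list(parameter = "tf_hz", grid = agg$tf_hz,
                 response = agg$peak_hz,
                 preferred = agg$tf_hz[which.max(agg$peak_hz)]),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s: preferred %.4g\n", x$parameter,
              x$preferred))
  print(stats::setNames(round(x$response, 3), signif(x$grid, 3)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$grid, x$response, type = "b", log = "x",
                 xlab = x$parameter, ylab = "response", ...)
  graphics::abline(v = x$preferred, lty = 2, col = "grey50")
  invisible(x)
}

#' Direction selectivity of drifting-grating responses
#'
#' DS index `(R_pref - R_null) / (R_pref + R_null)`, with `R_null` the
#' response 180 degrees from the preferred direction (responses floored at
#' zero). Significance of direction sensitivity is assessed by a
#' permutation test shuffling direction labels across trials; a vector-sum
#' index `|sum R_k exp(i theta_k)| / sum R_k` is available as an
#' alternative.
#'
#' @param trial_responses data frame with columns `direction_deg` and
#'   `response` (one row per trial, e.g. trial spike rates).
#' @param n_perm permutation count.
#' @param alpha significance level for the `direction_sensitive` flag.
#' @param method `"pref_null"` (default) or `"vector_sum"`.
#' @param seed RNG seed for the permutations.
#' @return An object of class `"ds_result"`: `preferred_deg`, `dsi`,
#'   `p_value`, `direction_sensitive`, `mean_by_direction`.
#' @export
direction_selectivity <- function(trial_responses, n_perm = 1000,
                                  alpha = 0.05,
                                  method = c("pref_null", "vector_sum"),
                                  seed = 1) {
  method <- match.arg(method)
  if (!all(c("direction_deg", "response") %in% names(trial_responses)))
    stop("trial_responses needs columns direction_deg and response")
  dirs <- sort(unique(trial_responses$direction_deg))
  if (length(dirs) < 8) stop("direction_selectivity: need >= 8 directions")

  g <- match(trial_responses$direction_deg, dirs)
  r <- trial_responses$response
  n <- length(r)
  gsize <- tabulate(g, nbins = length(dirs))
  # opposite-direction index per direction (nearest to 180 deg away)
  opp <- vapply(dirs, function(d)
    which.min(abs(((dirs - (d + 180)) %% 360 + 180) %% 360 - 180)),
    integer(1))

  # columns of `resp` are response vectors (observed or permuted); returns
  # DSI and preferred direction per column, fully vectorised
  dsi_cols <- function(resp) {
    mu <- rowsum(resp, g) / gsize
    mu <- pmax(mu, 0)
    if (method == "vector_sum") {
      z <- colSums(mu * exp(1i * dirs * pi / 180))
      tot <- colSums(mu)
      dsi <- ifelse(tot == 0, NA_real_, Mod(z) / tot)
      return(list(dsi = dsi, pref = (Arg(z) * 180 / pi) %% 360))
    }
    ip <- max.col(t(mu), ties.method = "first")
    cols <- seq_len(ncol(mu))
    rp <- mu[cbind(ip, cols)]; rn <- mu[cbind(opp[ip], cols)]
    list(dsi = ifelse(rp + rn == 0, NA_real_, (rp - rn) / (rp + rn)),
         pref = dirs[ip])
  }

  obs_l <- dsi_cols(matrix(r, ncol = 1))
  obs <- c(obs_l$dsi, obs_l$pref)
  p <- NA_real_
  if (is.finite(obs[1]) && n_perm > 0) {
    set.seed(seed)
    # sequential sampling: once the permutation p value is clearly above
    # alpha (>= 15% exceedances after 200 shuffles), the remaining
    # shuffles cannot change the classification and are skipped
    done <- 0L; exceed <- 0L
    while (done < n_perm) {
      m <- if (done == 0L) min(200L, n_perm) else n_perm - done
      idx <- vapply(seq_len(m), function(i) sample.int(n), integer(n))
      perm <- dsi_cols(matrix(r[idx], nrow = n))$dsi
      exceed <- exceed + sum(perm >= obs[1], na.rm = TRUE)
      done <- done + m
      if (exceed >= 0.15 * done && done >= 200L) break
    }
    p <- (1 + exceed) / (1 + done)
  }
  mu <- drop(rowsum(r, g)) / gsize
  structure(list(preferred_deg = obs[2], dsi = obs[1], p_value = p,
                 direction_sensitive = is.finite(p) && p < alpha,
                 mean_by_direction = stats::setNames(mu, dirs),
                 method = method),
            class = "ds_result")
}

#' @export
print.ds_result <- function(x, ...) {
  cat(sprintf("<ds_result> DSI %.3f at %g deg (p = %.3g%s)\n", x$dsi,
              x$preferred_deg, x$p_value,
              if (x$direction_sensitive) ", direction sensitive" else ""))
  invisible(x)
}

#' Trial-averaged binned response of a unit
#'
#' @param raster a [trial_raster].
#' @param bin_width_s bin width (s).
#' @return Numeric vector of mean rates (spikes/s) per bin.
#' @export
mean_response <- function(raster, bin_width_s = 0.025) {
  m <- trial_bin_matrix(raster, bin_width_s)
  colMeans(m) / bin_width_s
}

#' Signal correlation between two units
#'
#' Pearson correlation between the two units' trial-averaged binned
#' responses to the same stimulus. Pairs with a constant mean response are
#' excluded (NA).
#'
#' @param resp_a,resp_b mean binned responses (same length), e.g. from
#'   [mean_response].
#' @return Pearson r, or NA when either response is constant.
#' @export
signal_correlation <- function(resp_a, resp_b) {
  stopifnot(length(resp_a) == length(resp_b))
  if (stats::sd(resp_a) == 0 || stats::sd(resp_b) == 0) return(NA_real_)
  stats::cor(resp_a, resp_b)
}
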