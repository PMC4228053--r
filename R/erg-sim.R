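#' Naka-Rushton contrast-response function
#'
#' `R(c) = Rmax c^n / (c^n + c50^n)`.
#'
#' @param contrast stimulus contrast(s) in `[0, 1]`.
#' @param rmax saturating response amplitude.
#' @param c50 semisaturation contrast in `(0, 1]`.
#' @param n hill exponent (> 0).
#' @return Response on the scale of `rmax`.
#' @export
naka_rushton <- function(contrast, rmax, c50, n) {
  rmax * contrast^n / (contrast^n + c50^n)
}

# Stereotyped flash ERG waveform: negative a-wave lobe then positive b-wave
# lobe, normalised so the a-trough to b-peak span is exactly 1.
erg_waveform <- function(t_rel) {
  a <- -0.25 * exp(-((t_rel - 0.015) / 0.004)^2 / 2)
  b <- 0.75 * exp(-((t_rel - 0.060) / 0.012)^2 / 2)
  w <- ifelse(t_rel >= 0, a + b, 0)
  w / (max(w) - min(w))
}

#' Simulate a flash electroretinogram trace
#'
#' The b-wave amplitude follows a Naka-Rushton function of flash contrast,
#' scaled by a response gain that relaxes exponentially (time constant
#' `tau_s`) from the previous condition's gain toward the current
#' condition's asymptotic gain — the minutes-scale melanopsin-dependent
#' adaptation. Gaussian noise is added per sample.
#'
#' @param contrast flash cone contrast in `[0, 1]`.
#' @param gain_uv asymptotic b-wave gain of the current condition (microvolts;
#'   the saturating amplitude at full contrast).
#' @param c50,n_hill Naka-Rushton parameters.
#' @param tau_s adaptation time constant (s).
#' @param t_since_switch_s time elapsed since the condition switch (s);
#'   `Inf` for fully adapted.
#' @param gain_from_uv gain at the moment of the switch (defaults to
#'   `gain_uv`, i.e. no transient).
#' @param noise_sd_uv additive Gaussian noise SD (microvolts, >= 0).
#' @param seed RNG seed.
#' @param fs_hz sampling rate (Hz).
#' @param duration_s trace length (s).
#' @param flash_onset_s flash time within the trace (s).
#' @param condition,trial labels carried on the trace.
#' @return An object of class `"erg_trace"`: data frame with `time_s`, `uv`
#'   and attributes `flash_onset_s`, `condition`, `trial`, plus the planted
#'   noise-free amplitude as attribute `amplitude_uv`.
#' @export
simulate_erg <- function(contrast, gain_uv = 40, c50 = 0.3, n_hill = 2,
                         tau_s = 180, t_since_switch_s = Inf,
                         gain_from_uv = gain_uv, noise_sd_uv = 0, seed = 1,
                         fs_hz = 1000, duration_s = 0.4,
                         flash_onset_s = 0.1, condition = "daylight",
                         trial = 1L) {
  if (contrast < 0 || contrast > 1) stop("contrast must lie in [0, 1]")
  if (gain_uv <= 0) stop("gain_uv must be positive")
  if (noise_sd_uv < 0) stop("noise_sd_uv must be non-negative")
  g <- gain_uv + (gain_from_uv - gain_uv) * exp(-t_since_switch_s / tau_s)
  amp <- naka_rushton(contrast, g, c50, n_hill)
  tt <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)
  v <- amp * erg_waveform(tt - flash_onset_s)
  if (noise_sd_uv > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd_uv)
  }
  structure(data.frame(time_s = tt, uv = v),
            flash_onset_s = flash_onset_s, fs_hz = fs_hz,
            condition = condition, trial = as.integer(trial),
            amplitude_uv = amp,
            class = c("erg_trace", "data.frame"))
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf("<erg_trace> [%s] trial %d: %d samples @ %g Hz, flash at %g s\n",
              attr(x, "condition"), attr(x, "trial"), nrow(x),
              attr(x, "fs_hz"), attr(x, "flash_onset_s")))
  invisible(x)
}
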