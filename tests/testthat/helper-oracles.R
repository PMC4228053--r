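# Independent oracles used to freeze expected values.

# A1 visual-pigment template, evaluated directly from the published
# constants (alpha band + beta band), peak-normalised on the grid.
gov_oracle <- function(lambda_max, lambda) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  beta <- 0.26 * exp(-((lambda - (189 + 0.315 * lambda_max)) /
                         (-40.5 + 0.195 * lambda_max))^2)
  alpha + beta
}

# plain trapezoid quadrature written out by hand
trapz_oracle <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# Fourier amplitude of a difference-of-Gaussians receptive field
# (unit-sum centre minus s x unit-sum surround of f-fold SD)
dog_fourier_oracle <- function(k_cpd, sigma_deg, surround_strength,
                               surround_factor = 2) {
  exp(-2 * pi^2 * sigma_deg^2 * k_cpd^2) -
    surround_strength *
    exp(-2 * pi^2 * (surround_factor * sigma_deg)^2 * k_cpd^2)
}

# closed-form LNP rate for a full-field flash through an exponential
# kernel: drive steps to c*(1 - s) at onset and back to 0 at offset
flash_rate_oracle <- function(t, onset, dur, contrast, surround, gain,
                              baseline, tau) {
  amp <- contrast * (1 - surround)
  y <- ifelse(t < onset, 0,
              ifelse(t < onset + dur,
                     amp * (1 - exp(-(t - onset) / tau)),
                     amp * (1 - exp(-dur / tau)) *
                       exp(-(t - onset - dur) / tau)))
  baseline + gain * pmax(y, 0)
}

tiny_screen <- function() screen_geometry(60, 40, 1)
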