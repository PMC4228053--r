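#' Visual pigment spectral sensitivity template
#'
#' Builds a photopigment's relative quantal spectral sensitivity from its peak
#' wavelength using the Govardovskii et al. (2000) A1 nomogram (alpha plus
#' beta band), normalised to peak 1 on the supplied grid. A tabulated
#' sensitivity curve can be supplied instead of the nomogram via `sensitivity`.
#'
#' @param lambda_max_nm peak wavelength (nm), between 300 and 650.
#' @param wavelengths_nm wavelength grid (nm), within 300-780.
#' @param name template label (e.g. `"melanopsin"`).
#' @param sensitivity optional tabulated relative sensitivity on
#'   `wavelengths_nm`; overrides the nomogram (it is renormalised to peak 1).
#' @return An object of class `"photoreceptor_template"`: list with `name`,
#'   `lambda_max_nm`, `wavelengths_nm`, `sensitivity`.
#' @examples
#' mel <- pigment_template(480, name = "melanopsin")
#' @export
pigment_template <- function(lambda_max_nm,
                             wavelengths_nm = seq(300, 780, by = 1),
                             name = sprintf("pigment_%g", lambda_max_nm),
                             sensitivity = NULL) {
  if (lambda_max_nm < 300 || lambda_max_nm > 650)
    stop("pigment_template: lambda_max_nm must lie in [300, 650] nm")
  if (min(wavelengths_nm) < 300 || max(wavelengths_nm) > 780)
    stop("pigment_template: wavelength grid must lie within 300-780 nm")
  if (is.null(sensitivity)) {
    s <- govardovskii_a1(lambda_max_nm, wavelengths_nm)
  } else {
    if (length(sensitivity) != length(wavelengths_nm))
      stop("pigment_template: tabulated sensitivity length mismatch")
    if (any(sensitivity < 0)) stop("pigment_template: sensitivity must be >= 0")
    s <- as.numeric(sensitivity)
  }
  s <- s / max(s)
  structure(list(name = name, lambda_max_nm = lambda_max_nm,
                 wavelengths_nm = as.numeric(wavelengths_nm), sensitivity = s),
            class = "photoreceptor_template")
}

# Govardovskii et al. (2000) A1 pigment nomogram: alpha band (their eq. for
# S(x) with x = lambda_max / lambda) plus beta band Gaussian.
govardovskii_a1 <- function(lambda_max, lambda) {
  x <- lambda_max / lambda
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  lam_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - lam_beta) / b_beta)^2)
  alpha + beta
}

#' @export
print.photoreceptor_template <- function(x, ...) {
  cat(sprintf("<photoreceptor_template> %s, lambda_max %g nm (%d grid points)\n",
              x$name, x$lambda_max_nm, length(x$wavelengths_nm)))
  invisible(x)
}

#' Default photopigment set
#'
#' Nomogram templates for the pigments of the red-cone knock-in
#' (Opn1mw^R) mouse used in melanopsin-contrast experiments: SWS cone opsin
#' (360 nm), melanopsin (480 nm), rod opsin (498 nm), and the knocked-in human
#' LWS cone opsin (556 nm). The native mouse MWS opsin (508 nm) is included
#' for wild-type modelling.
#'
#' @param wavelengths_nm wavelength grid (nm).
#' @param lambda_max named numeric vector of peak wavelengths; defaults to
#'   standard literature values.
#' @return Named list of [pigment_template] objects.
#' @export
mouse_templates <- function(wavelengths_nm = seq(300, 780, by = 1),
                            lambda_max = c(SWS = 360, melanopsin = 480,
                                           rod = 498, MWS = 508,
                                           LWS_human = 556)) {
  out <- lapply(names(lambda_max), function(nm)
    pigment_template(lambda_max[[nm]], wavelengths_nm, name = nm))
  names(out) <- names(lambda_max)
  out
}

#' Effective (alpha-opic) photon flux
#'
#' Weights a spectral power distribution by a pigment's relative quantal
#' sensitivity and integrates over wavelength (trapezoid rule on the SPD grid;
#' the template is linearly interpolated onto that grid). An optional
#' pre-receptoral transmission curve (e.g. lens) multiplies the integrand.
#'
#' @param spd an [spd].
#' @param template a [pigment_template].
#' @param prereceptoral optional function of wavelength (nm) returning a
#'   transmission factor in `[0, 1]`; default none.
#' @return Effective corneal photon flux (photons cm^-2 s^-1).
#' @export
effective_photon_flux <- function(spd, template, prereceptoral = NULL) {
  wl <- spd$wavelengths_nm
  twl <- range(template$wavelengths_nm)
  if (max(wl) < twl[1] || min(wl) > twl[2])
    stop("effective_photon_flux: SPD and template wavelength ranges are disjoint")
  s <- stats::approx(template$wavelengths_nm, template$sensitivity,
                     xout = wl, rule = 2)$y
  integrand <- spd$photon_flux * s
  if (!is.null(prereceptoral)) integrand <- integrand * prereceptoral(wl)
  pracma::trapz(wl, integrand)
}

#' Michelson contrast between two photon fluxes
#'
#' `(max - min) / (max + min)`; symmetric in its arguments and in `[0, 1]`.
#'
#' @param flux_a,flux_b non-negative fluxes, not both zero.
#' @return Dimensionless contrast.
#' @export
michelson_contrast <- function(flux_a, flux_b) {
  if (flux_a < 0 || flux_b < 0)
    stop("michelson_contrast: fluxes must be non-negative")
  if (flux_a + flux_b == 0)
    stop("michelson_contrast: undefined for two zero fluxes")
  abs(flux_a - flux_b) / (flux_a + flux_b)
}

#' Per-receptor flux profile of a spectrum
#'
#' Applies [effective_photon_flux] for each template, giving the
#' receptor-space representation of an environmental or stimulus spectrum
#' (e.g. the daylight profile at a given solar angle).
#'
#' @param spd an [spd].
#' @param templates named list of [pigment_template] objects.
#' @param prereceptoral passed to [effective_photon_flux].
#' @return Named numeric vector of effective photon fluxes
#'   (photons cm^-2 s^-1), one per template.
#' @export
receptor_profile <- function(spd, templates, prereceptoral = NULL) {
  vapply(templates, function(tp) effective_photon_flux(spd, tp, prereceptoral),
         numeric(1))
}
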