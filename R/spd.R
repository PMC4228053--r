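#' Spectral power distribution
#'
#' Container for a wavelength-sampled photon flux spectrum, the common currency
#' of the metamer-design machinery. Fluxes are spectral photon irradiances at
#' the cornea (photons cm^-2 s^-1 nm^-1).
#'
#' @param wavelengths_nm strictly increasing numeric grid of wavelengths (nm),
#'   length >= 2.
#' @param photon_flux non-negative spectral photon flux at each grid point.
#' @return An object of class `"spd"`: a list with elements `wavelengths_nm`
#'   and `photon_flux`.
#' @examples
#' s <- spd(380:780, rep(1e12, 401))
#' @export
spd <- function(wavelengths_nm, photon_flux) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  photon_flux <- as.numeric(photon_flux)
  if (length(wavelengths_nm) < 2L)
    stop("spd: wavelength grid must have at least 2 points")
  if (length(photon_flux) != length(wavelengths_nm))
    stop("spd: wavelengths_nm and photon_flux lengths differ")
  if (any(diff(wavelengths_nm) <= 0))
    stop("spd: wavelength grid must be strictly increasing")
  if (any(!is.finite(photon_flux)) || any(photon_flux < 0))
    stop("spd: photon_flux must be finite and non-negative")
  structure(list(wavelengths_nm = wavelengths_nm, photon_flux = photon_flux),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf("<spd> %d samples, %g-%g nm, total %.4g photons/cm2/s\n",
              length(x$wavelengths_nm), rng[1], rng[2],
              pracma::trapz(x$wavelengths_nm, x$photon_flux)))
  invisible(x)
}

#' Arithmetic helpers used by the metamer synthesis
#' @noRd
scale_spd <- function(x, k) spd(x$wavelengths_nm, x$photon_flux * k)

#' @noRd
add_spds <- function(spds, weights) {
  wl <- spds[[1]]$wavelengths_nm
  for (s in spds)
    if (!isTRUE(all.equal(s$wavelengths_nm, wl)))
      stop("add_spds: SPDs must share a common wavelength grid")
  flux <- Reduce(`+`, Map(function(s, w) s$photon_flux * w, spds, as.list(weights)))
  spd(wl, pmax(flux, 0))
}

#' Read / write a spectral power distribution
#'
#' Two-column CSV with a one-line header (`wavelength_nm,photon_flux`).
#'
#' @param path file path.
#' @return `read_spd()` returns an [spd]; `write_spd()` returns `path`
#'   invisibly.
#' @export
read_spd <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("read_spd: expected two columns")
  spd(d[[1]], d[[2]])
}

#' @param x an [spd] object.
#' @rdname read_spd
#' @export
write_spd <- function(x, path) {
  utils::write.csv(
    data.frame(wavelength_nm = x$wavelengths_nm, photon_flux = x$photon_flux),
    path, row.names = FALSE)
  invisible(path)
}

#' Blackbody photon spectrum
#'
#' Planck spectral radiance converted to relative photon flux, usable as a
#' stand-in daylight spectrum (a ~6500 K blackbody approximates the daylight
#' locus well enough for receptor-ratio work).
#'
#' @param temperature_K blackbody temperature in kelvin.
#' @param wavelengths_nm wavelength grid (nm).
#' @param peak_flux photon flux at the spectral peak
#'   (photons cm^-2 s^-1 nm^-1); the curve is scaled to this value.
#' @return An [spd].
#' @export
blackbody_spd <- function(temperature_K = 6500,
                          wavelengths_nm = seq(300, 780, by = 1),
                          peak_flux = 1e13) {
  h <- 6.62607015e-34; c <- 2.99792458e8; kB <- 1.380649e-23
  lam <- wavelengths_nm * 1e-9
  # photon radiance ~ spectral radiance / photon energy
  e <- (2 * h * c^2 / lam^5) / (exp(h * c / (lam * kB * temperature_K)) - 1)
  photons <- e * lam / (h * c)
  spd(wavelengths_nm, photons / max(photons) * peak_flux)
}

#' Gaussian LED emission spectrum
#'
#' Idealised LED primary: Gaussian spectral shape parameterised by peak
#' wavelength and full width at half maximum.
#'
#' @param peak_nm peak emission wavelength (nm).
#' @param fwhm_nm full width at half maximum (nm).
#' @param wavelengths_nm wavelength grid (nm).
#' @param total_flux integrated photon flux at unit drive
#'   (photons cm^-2 s^-1).
#' @return An [spd] whose integral equals `total_flux`.
#' @export
led_spd <- function(peak_nm, fwhm_nm = 20,
                    wavelengths_nm = seq(300, 780, by = 1),
                    total_flux = 1e14) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  f <- exp(-0.5 * ((wavelengths_nm - peak_nm) / sigma)^2)
  area <- pracma::trapz(wavelengths_nm, f)
  spd(wavelengths_nm, f / area * total_flux)
}
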