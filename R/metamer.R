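#' Multi-primary light source model
#'
#' A set of independently drivable primaries (e.g. LEDs), each described by
#' its spectral power distribution at unit drive, plus per-primary drive
#' bounds. All primary SPDs must share one wavelength grid.
#'
#' @param spds named list of [spd] objects (one per primary, unit drive).
#' @param max_drive upper drive bound per primary (recycled); drives are
#'   dimensionless in `[0, max_drive]`.
#' @return An object of class `"primary_set"`.
#' @export
primary_set <- function(spds, max_drive = 1) {
  if (length(spds) < 2) stop("primary_set: need at least 2 primaries")
  wl <- spds[[1]]$wavelengths_nm
  for (s in spds)
    if (!isTRUE(all.equal(s$wavelengths_nm, wl)))
      stop("primary_set: all primaries must share a common wavelength grid")
  if (is.null(names(spds))) names(spds) <- sprintf("P%d", seq_along(spds))
  max_drive <- rep_len(as.numeric(max_drive), length(spds))
  if (any(max_drive <= 0)) stop("primary_set: max_drive must be positive")
  structure(list(spds = spds, max_drive = max_drive,
                 wavelengths_nm = wl), class = "primary_set")
}

#' Three-LED mouse stimulator model
#'
#' Gaussian-spectrum primaries at the peak wavelengths of the three-LED
#' source used for melanopsin-contrast work (365, 460, 600 nm).
#'
#' @param peaks_nm LED peak wavelengths (nm).
#' @param fwhm_nm spectral FWHM per LED (nm, recycled).
#' @param total_flux integrated photon flux per LED at unit drive.
#' @param wavelengths_nm wavelength grid.
#' @param max_drive drive bound per primary.
#' @return A [primary_set].
#' @export
default_led_primaries <- function(peaks_nm = c(365, 460, 600), fwhm_nm = 20,
                                  total_flux = 1e14,
                                  wavelengths_nm = seq(300, 780, by = 1),
                                  max_drive = 1) {
  fwhm_nm <- rep_len(fwhm_nm, length(peaks_nm))
  total_flux <- rep_len(total_flux, length(peaks_nm))
  spds <- Map(function(p, f, tf) led_spd(p, f, wavelengths_nm, tf),
              peaks_nm, fwhm_nm, total_flux)
  names(spds) <- sprintf("LED%g", peaks_nm)
  primary_set(spds, max_drive)
}

#' Receptor excitation matrix of a primary set
#'
#' Entry `(r, p)` is the effective photon flux delivered to receptor `r` by
#' primary `p` at unit drive — the linearisation on which silent substitution
#' rests.
#'
#' @param primaries a [primary_set].
#' @param templates named list of [pigment_template] objects.
#' @return Matrix (receptors x primaries) of photons cm^-2 s^-1 per unit
#'   drive, with dimnames from the template and primary names.
#' @export
receptor_matrix <- function(primaries, templates) {
  M <- vapply(primaries$spds,
              function(s) receptor_profile(s, templates),
              numeric(length(templates)))
  M <- matrix(M, nrow = length(templates),
              dimnames = list(names(templates), names(primaries$spds)))
  M
}

#' Metamer design constraint
#'
#' One linear(isable) requirement on the per-receptor fluxes of the designed
#' spectra.
#'
#' Kinds:
#' \describe{
#'   \item{`match_flux`}{flux of `receptor` in spectrum `spectra[1]` equals
#'     `value` (photons cm^-2 s^-1).}
#'   \item{`match_across_spectra`}{fluxes in `spectra[1]` and `spectra[2]`
#'     are equal (silent substitution / isoluminance).}
#'   \item{`contrast_target`}{Michelson contrast `value` between
#'     `spectra[1]` (background) and `spectra[2]` (flash), linearised as
#'     `f2 = k f1` with `k = (1 + value) / (1 - value)` for an increment
#'     (`direction = 1`) or `f2 = f1 / k` for a decrement
#'     (`direction = -1`); Michelson contrast is unsigned, so both realise
#'     the same contrast.}
#'   \item{`ratio_target`}{`f1 = value * f2`.}
#' }
#'
#' @param receptor template name the constraint binds.
#' @param kind one of the four kinds above.
#' @param spectra integer index (length 1 for `match_flux`, else 2) of the
#'   designed spectra the constraint applies to.
#' @param value target flux, contrast in `[0, 1)`, or ratio; ignored for
#'   `match_across_spectra`.
#' @param hard logical: hard constraints are satisfied exactly (null-space
#'   solve); soft ones enter a weighted least-squares objective. Defaults:
#'   isoluminance and contrast targets hard, flux and ratio targets soft.
#' @param weight least-squares weight for soft constraints.
#' @param direction for `contrast_target`: `1` increment, `-1` decrement.
#' @return An object of class `"design_constraint"`.
#' @export
design_constraint <- function(receptor,
                              kind = c("match_flux", "match_across_spectra",
                                       "contrast_target", "ratio_target"),
                              spectra, value = NULL,
                              hard = NULL, weight = 1, direction = 1) {
  kind <- match.arg(kind)
  if (kind == "match_flux") {
    if (length(spectra) != 1) stop("match_flux binds exactly one spectrum")
  } else if (length(spectra) != 2) {
    stop(sprintf("%s binds exactly two spectra", kind))
  }
  if (kind %in% c("match_flux", "contrast_target", "ratio_target")) {
    if (is.null(value) || value < 0)
      stop(sprintf("%s requires a non-negative value", kind))
    if (kind == "contrast_target" && value >= 1)
      stop("contrast_target value must lie in [0, 1)")
  }
  if (is.null(hard))
    hard <- kind %in% c("match_across_spectra", "contrast_target")
  if (!direction %in% c(1, -1)) stop("direction must be 1 or -1")
  structure(list(receptor = receptor, kind = kind,
                 spectra = as.integer(spectra), value = value,
                 hard = isTRUE(hard), weight = weight, direction = direction),
            class = "design_constraint")
}

# One constraint -> (row of A over the stacked weight vector, rhs b)
constraint_row <- function(con, R, n_spectra) {
  P <- ncol(R)
  row <- numeric(n_spectra * P)
  blk <- function(i) ((i - 1) * P + 1):(i * P)
  if (!con$receptor %in% rownames(R))
    stop(sprintf("constraint receptor '%s' not in template set", con$receptor))
  r <- R[con$receptor, ]
  if (any(con$spectra < 1 | con$spectra > n_spectra))
    stop("constraint spectra index out of range")
  b <- 0
  switch(con$kind,
    match_flux = { row[blk(con$spectra[1])] <- r; b <- con$value },
    match_across_spectra = {
      row[blk(con$spectra[1])] <- r
      row[blk(con$spectra[2])] <- row[blk(con$spectra[2])] - r
    },
    contrast_target = {
      k <- ((1 + con$value) / (1 - con$value))^con$direction
      row[blk(con$spectra[1])] <- k * r
      row[blk(con$spectra[2])] <- row[blk(con$spectra[2])] - r
    },
    ratio_target = {
      row[blk(con$spectra[1])] <- r
      row[blk(con$spectra[2])] <- row[blk(con$spectra[2])] - con$value * r
    })
  list(row = row, b = b)
}

#' Solve a silent-substitution design
#'
#' Finds per-spectrum primary drive weights satisfying a set of
#' [design_constraint]s. Hard constraints are solved exactly: the weight
#' vector is restricted to the affine solution set (minimum-norm particular
#' solution plus SVD null-space basis), and soft constraints are then
#' resolved by weighted least squares inside that set. Drives must lie in
#' `[0, max_drive]`; if the unconstrained optimum violates the box, a bounded
#' refinement (L-BFGS-B on the full weighted objective) is attempted and the
#' solution is flagged infeasible if hard residuals remain above tolerance —
#' weights are never silently clipped.
#'
#' @param primaries a [primary_set].
#' @param templates named list of [pigment_template]s.
#' @param constraints list of [design_constraint]s.
#' @param n_spectra number of spectra designed jointly.
#' @param tol relative residual below which a hard constraint counts as
#'   satisfied.
#' @return An object of class `"metamer_solution"`: list with `weights`
#'   (n_spectra x primaries), `spds` (synthesised [spd] per spectrum),
#'   `fluxes` (n_spectra x receptors, recomputed from the synthesised SPDs),
#'   `residuals` (per-constraint data frame), `feasible`, `null_dim`.
#' @export
solve_metamer <- function(primaries, templates, constraints, n_spectra,
                          tol = 1e-6) {
  R <- receptor_matrix(primaries, templates)
  P <- ncol(R)
  nv <- n_spectra * P
  rows <- lapply(constraints, constraint_row, R = R, n_spectra = n_spectra)
  A <- do.call(rbind, lapply(rows, `[[`, "row"))
  b <- vapply(rows, `[[`, numeric(1), "b")
  hard <- vapply(constraints, `[[`, logical(1), "hard")
  wts <- vapply(constraints, `[[`, numeric(1), "weight")

  # typical flux magnitude, used to scale rows into comparable units
  fscale <- max(abs(R))
  As <- A / fscale; bs <- b / fscale

  w <- numeric(nv)
  null_dim <- nv
  if (any(hard)) {
    Ah <- As[hard, , drop = FALSE]; bh <- bs[hard]
    sv <- svd(Ah, nu = nrow(Ah), nv = nv)
    rk <- sum(sv$d > max(dim(Ah)) * max(sv$d, 0) * 1e-12)
    # minimum-norm particular solution
    dinv <- c(1 / sv$d[seq_len(rk)], rep(0, length(sv$d) - rk))
    w <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
      (dinv * crossprod(sv$u[, seq_along(sv$d), drop = FALSE], bh))
    w <- drop(w)
    N <- if (rk < nv) sv$v[, (rk + 1):nv, drop = FALSE] else
      matrix(0, nv, 0)
    null_dim <- ncol(N)
  } else {
    N <- diag(nv)
  }
  ub <- rep(primaries$max_drive, times = n_spectra)
  btol <- 1e-8 * max(ub)
  w0 <- w
  if (any(!hard) && null_dim > 0) {
    Asoft <- As[!hard, , drop = FALSE]; bsoft <- bs[!hard]
    sw <- sqrt(wts[!hard])
    M <- (Asoft %*% N) * sw
    rhs <- drop((bsoft - Asoft %*% w0) * sw)
    t_hat <- qr.coef(qr(M), rhs)
    t_hat[is.na(t_hat)] <- 0
    w <- w0 + drop(N %*% t_hat)
    if (any(w < -btol) || any(w > ub + btol)) {
      # bounded refinement inside the null space: hinge penalty on the drive
      # box keeps the hard constraints machine-exact while pushing the soft
      # optimum to the nearest in-gamut point
      for (mu in 10^seq(2, 10, by = 2)) {
        obj <- function(t) {
          x <- w0 + drop(N %*% t)
          sum((M %*% t - rhs)^2) +
            mu * sum(pmin(x, 0)^2) + mu * sum(pmax(x - ub, 0)^2)
        }
        t_hat <- stats::optim(t_hat, obj, method = "BFGS",
                              control = list(maxit = 1000,
                                             reltol = 1e-14))$par
      }
      w <- w0 + drop(N %*% t_hat)
    }
  }
  in_box <- all(w >= -btol) && all(w <= ub + btol)
  if (in_box) w <- pmin(pmax(w, 0), ub)  # clean sub-tolerance spill only;
  # genuinely out-of-box solutions are returned unclipped with feasible=FALSE

  W <- matrix(w, nrow = n_spectra, byrow = TRUE,
              dimnames = list(sprintf("spectrum_%d", seq_len(n_spectra)),
                              colnames(R)))
  if (in_box) {
    # round trip: synthesise each spectrum and re-integrate through the
    # templates, rather than trusting R %*% w
    spds <- lapply(seq_len(n_spectra), function(i)
      add_spds(primaries$spds, W[i, ]))
    names(spds) <- rownames(W)
    fluxes <- t(vapply(spds, function(s) receptor_profile(s, templates),
                       numeric(length(templates))))
  } else {
    spds <- NULL
    fluxes <- W %*% t(R)
    dimnames(fluxes) <- list(rownames(W), rownames(R))
  }

  resid <- drop(A %*% w - b)
  mag <- drop(abs(A) %*% abs(w))
  rel <- abs(resid) / pmax(mag, abs(b), fscale * 1e-12)
  residuals <- data.frame(
    receptor = vapply(constraints, `[[`, character(1), "receptor"),
    kind = vapply(constraints, `[[`, character(1), "kind"),
    hard = hard, residual = resid, relative = rel)
  feasible <- in_box && all(rel[hard] < tol)

  structure(list(weights = W, spds = spds, fluxes = fluxes,
                 residuals = residuals, feasible = feasible,
                 null_dim = null_dim, receptor_matrix = R, tol = tol),
            class = "metamer_solution")
}

#' @export
print.metamer_solution <- function(x, ...) {
  cat(sprintf("<metamer_solution> %d spectra x %d primaries, feasible: %s\n",
              nrow(x$weights), ncol(x$weights), x$feasible))
  cat("log10 effective photon fluxes:\n")
  print(round(log10(pmax(x$fluxes, .Machine$double.xmin)), 3))
  bad <- x$residuals[x$residuals$hard & x$residuals$relative >= x$tol, ]
  if (nrow(bad)) {
    cat("unsatisfied hard constraints:\n"); print(bad)
  }
  invisible(x)
}

#' Design the daylight / mel-low stimulus quartet
#'
#' Constructs the four-spectrum set used to probe melanopsin-driven
#' adaptation: spectrum 1 (daylight background), 2 (daylight flash),
#' 3 (mel-low background), 4 (mel-low flash). Hard constraints: both cone
#' opsins isoluminant across the pairs (1 vs 3 and 2 vs 4); rod and
#' melanopsin isoluminant within each background/flash pair; a cone
#' Michelson contrast of `cone_contrast` within each pair; and the
#' melanopsin flux of spectrum 1 equal to `mel_attenuation` times that of
#' spectrum 3. Soft targets: the rod flux attenuated by the same factor
#' (best effort — with three primaries rod attenuation cannot be pinned
#' independently of melanopsin), and spectrum 1 matching `daylight_profile`.
#'
#' Because rod and melanopsin silencing confine the within-pair modulation
#' to a single spectral-exchange direction, along which the two cone opsins
#' necessarily move with opposite sign, the requested contrast is carried
#' exactly by one reference cone opsin; the other opsin sees the contrast
#' implied by the exchange geometry (reported in `cone_contrasts`). By
#' default each cone and both step polarities are tried and the first
#' in-gamut design wins.
#'
#' @param primaries a [primary_set].
#' @param templates named list of [pigment_template]s containing entries for
#'   `cones`, `rod_name` and `mel_name`.
#' @param daylight_profile named receptor flux vector for the background, as
#'   from [receptor_profile] on an environmental spectrum (see
#'   [daylight_flux_profile]).
#' @param cone_contrast within-pair cone Michelson contrast in `[0, 1)`.
#' @param mel_attenuation factor (>= 1) by which melanopsin flux is reduced
#'   from daylight to mel-low.
#' @param cones,rod_name,mel_name template names of the cone opsins, rod
#'   opsin and melanopsin.
#' @param contrast_cone cone opsins to try as the contrast carrier, in order
#'   of preference.
#' @param tol hard-constraint tolerance, passed to [solve_metamer].
#' @return A [solve_metamer] solution with four spectra, plus elements
#'   `contrast_convention` (carrier opsin and polarity) and
#'   `cone_contrasts` (achieved within-pair Michelson contrast per cone).
#' @export
design_daylight_mellow <- function(primaries, templates, daylight_profile,
                                   cone_contrast = 0.58, mel_attenuation = 10,
                                   cones = c("SWS", "LWS_human"),
                                   rod_name = "rod", mel_name = "melanopsin",
                                   contrast_cone = cones, tol = 1e-6) {
  if (cone_contrast < 0 || cone_contrast >= 1)
    stop("cone_contrast must lie in [0, 1)")
  if (mel_attenuation < 1) stop("mel_attenuation must be >= 1")
  need <- c(cones, rod_name, mel_name)
  if (!all(need %in% names(templates)))
    stop("templates must include: ", paste(need, collapse = ", "))

  base_cons <- list()
  for (cn in cones) {
    base_cons <- c(base_cons, list(
      design_constraint(cn, "match_across_spectra", c(1, 3)),
      design_constraint(cn, "match_across_spectra", c(2, 4))))
  }
  for (pair in list(c(1, 2), c(3, 4))) {
    base_cons <- c(base_cons, list(
      design_constraint(mel_name, "match_across_spectra", pair),
      design_constraint(rod_name, "match_across_spectra", pair)))
  }
  base_cons <- c(base_cons, list(
    design_constraint(mel_name, "ratio_target", c(1, 3), mel_attenuation,
                      hard = TRUE),
    design_constraint(rod_name, "ratio_target", c(1, 3), mel_attenuation,
                      hard = FALSE)))
  for (rn in names(daylight_profile)) {
    if (!rn %in% names(templates)) next
    base_cons <- c(base_cons, list(
      design_constraint(rn, "match_flux", 1, daylight_profile[[rn]],
                        hard = FALSE)))
  }

  candidates <- expand.grid(cone = contrast_cone, dir = c(-1, 1),
                            stringsAsFactors = FALSE)
  best <- NULL; best_conv <- NULL
  for (i in seq_len(nrow(candidates))) {
    cn <- candidates$cone[i]; dir <- candidates$dir[i]
    cons <- c(base_cons, list(
      design_constraint(cn, "contrast_target", c(1, 2), cone_contrast,
                        direction = dir),
      design_constraint(cn, "contrast_target", c(3, 4), cone_contrast,
                        direction = dir)))
    sol <- solve_metamer(primaries, templates, cons, n_spectra = 4, tol = tol)
    if (is.null(best) || (sol$feasible && !best$feasible)) {
      best <- sol
      best_conv <- list(cone = cn, direction = dir)
    }
    if (sol$feasible && cone_contrast > 0) break
  }
  best$contrast_convention <- best_conv
  cc_ach <- vapply(cones, function(cn)
    michelson_contrast(best$fluxes["spectrum_1", cn],
                       best$fluxes["spectrum_2", cn]), numeric(1))
  best$cone_contrasts <- cc_ach
  best
}

#' Built-in daylight receptor profile
#'
#' Receptor flux profile of a low-sun daylight spectrum (6500 K blackbody
#' photon spectrum as a daylight-locus stand-in), scaled so that the
#' best-fitting primary drives use a stated fraction of the gamut. The
#' resulting profile shares the signature of natural daylight for the mouse:
#' melanopsin, rod and long-wavelength cone fluxes roughly equivalent and
#' roughly an order of magnitude above the SWS cone flux.
#'
#' @param primaries a [primary_set] defining the gamut.
#' @param templates named list of [pigment_template]s.
#' @param gamut_fraction target peak drive as a fraction of `max_drive`.
#' @return Named flux vector (photons cm^-2 s^-1).
#' @export
daylight_flux_profile <- function(primaries, templates,
                                  gamut_fraction = 0.25) {
  env <- blackbody_spd(6500, primaries$wavelengths_nm)
  prof <- receptor_profile(env, templates)
  R <- receptor_matrix(primaries, templates)
  w <- qr.coef(qr(R), prof)
  w[is.na(w)] <- 0
  k <- gamut_fraction / max(abs(w) / primaries$max_drive)
  prof * k
}
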