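#' Screen geometry in degrees of visual angle
#'
#' @param width_deg,height_deg screen extent (degrees of visual angle).
#' @param px_deg pixel size (degrees).
#' @return List with pixel-center coordinate vectors `xs`, `ys` (length
#'   `npix`, row-major over a `nx` x `ny` grid), counts and extents.
#' @export
screen_geometry <- function(width_deg = 100, height_deg = 60, px_deg = 1) {
  nx <- round(width_deg / px_deg); ny <- round(height_deg / px_deg)
  x <- seq(-width_deg / 2 + px_deg / 2, width_deg / 2 - px_deg / 2,
           length.out = nx)
  y <- seq(-height_deg / 2 + px_deg / 2, height_deg / 2 - px_deg / 2,
           length.out = ny)
  list(width_deg = width_deg, height_deg = height_deg, px_deg = px_deg,
       nx = nx, ny = ny,
       xs = rep(x, times = ny), ys = rep(y, each = nx), npix = nx * ny)
}

#' Grating geometry helpers
#'
#' `grating_half_cycle_deg()` gives the visual angle subtended by one
#' half-cycle (one bar) of a grating; `grating_speed_deg_s()` the drift
#' speed of a grating moving at a given temporal frequency.
#'
#' @param sf_cpd spatial frequency (cycles per degree).
#' @param tf_hz temporal frequency (Hz).
#' @return Degrees, or degrees per second.
#' @examples
#' grating_half_cycle_deg(0.035)      # ~14 degrees
#' grating_speed_deg_s(0.2, 0.035)    # ~6 deg/s
#' grating_speed_deg_s(1, 0.035)      # ~29 deg/s
#' @export
grating_half_cycle_deg <- function(sf_cpd) 1 / (2 * sf_cpd)

#' @rdname grating_half_cycle_deg
#' @export
grating_speed_deg_s <- function(tf_hz, sf_cpd) tf_hz / sf_cpd

new_stimulus <- function(kind, times, frame_idx, patterns, screen, params,
                         duration) {
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(kind = kind, times = times, frame_idx = as.integer(frame_idx),
                 patterns = patterns, screen = screen, params = params,
                 duration = duration),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> %s: %.3g s, %d frames, %d patterns, %dx%d deg\n",
              x$kind, x$duration, length(x$times), ncol(x$patterns),
              x$screen$width_deg, x$screen$height_deg))
  invisible(x)
}

grating_pattern <- function(screen, sf_cpd, direction_deg, phase,
                            contrast) {
  th <- direction_deg * pi / 180
  u <- screen$xs * cos(th) + screen$ys * sin(th)
  contrast * sin(2 * pi * sf_cpd * u + phase)
}

#' Render a visual stimulus sequence
#'
#' Builds the frame timeline and spatial patterns for the stimulus classes
#' used in the melanopsin-contrast experiments. Patterns are stored once and
#' referenced per frame, in contrast units around the mean grey (0), on a
#' degrees-of-visual-angle pixel grid.
#'
#' Supported kinds and their parameters (all durations in seconds):
#' \describe{
#'   \item{`full_field_flash`}{`contrast`, `flash_duration` (default 0.05),
#'     `period` (default 1, i.e. 1 Hz flashes), `duration`.}
#'   \item{`inverting_grating`}{`sf_cpd`, `tf_hz` (nominal label),
#'     `orientation_deg`, `contrast`, `duration`,
#'     `inversions_per_cycle` (default 2: a "1 Hz" grating inverts phase
#'     every 0.5 s).}
#'   \item{`drifting_grating`}{`sf_cpd`, `tf_hz`, `direction_deg`,
#'     `contrast`, `duration`, `frame_rate` (default 20 Hz); drift speed is
#'     `tf_hz / sf_cpd` degrees/s.}
#'   \item{`bar_white_noise`}{`axis` ("vertical" bars map azimuth,
#'     "horizontal" bars map elevation), `bar_width_deg` (default 5),
#'     `contrast`, `n_frames`, `frame_rate` (default 25 Hz), `seed`; each
#'     frame shows one black or white bar at a uniformly drawn position on
#'     grey.}
#'   \item{`movie`}{seeded 1/f spatiotemporal noise: `duration`,
#'     `frame_rate` (default 10 Hz), `contrast_sd` (default 0.35), `seed`.}
#' }
#'
#' @param kind stimulus class, see Details.
#' @param ... kind-specific parameters.
#' @param screen a [screen_geometry].
#' @return A `"stimulus_sequence"` object with elements `times` (frame onset
#'   times), `frame_idx` (pattern index per frame), `patterns`
#'   (`npix` x n_patterns matrix), `screen`, `params`, `duration`.
#' @export
render_stimulus <- function(kind = c("full_field_flash", "inverting_grating",
                                     "drifting_grating", "bar_white_noise",
                                     "movie"),
                            ..., screen = screen_geometry()) {
  kind <- match.arg(kind)
  p <- list(...)
  chk_contrast <- function(con) {
    if (con < 0 || con > 1) stop("contrast must lie in [0, 1]")
    con
  }
  switch(kind,
    full_field_flash = {
      # one trial = one flash cycle; flash onset partway through the trial
      # leaves a pre-stimulus baseline window
      con <- chk_contrast(p$contrast %||% 0.58)
      fd <- p$flash_duration %||% 0.05
      onset <- p$onset %||% 0.25
      duration <- p$duration %||% 1
      if (fd <= 0 || onset + fd >= duration)
        stop("flash must fall inside the trial")
      times <- c(0, onset, onset + fd)
      pat <- cbind(rep(0, screen$npix), rep(con, screen$npix))
      new_stimulus(kind, times, c(1L, 2L, 1L), pat, screen,
                   list(contrast = con, flash_duration = fd, onset = onset),
                   duration)
    },
    inverting_grating = {
      con <- chk_contrast(p$contrast %||% 0.8)
      sf <- p$sf_cpd %||% 0.035
      tf <- p$tf_hz %||% 1
      ori <- (p$orientation_deg %||% 0) %% 360
      duration <- p$duration %||% 4
      ipc <- p$inversions_per_cycle %||% 2
      dt_inv <- 1 / (tf * ipc)
      times <- seq(0, duration - 1e-9, by = dt_inv)
      idx <- rep_len(c(1L, 2L), length(times))
      g <- grating_pattern(screen, sf, ori, p$phase %||% (pi / 4), con)
      new_stimulus(kind, times, idx, cbind(g, -g), screen,
                   list(sf_cpd = sf, tf_hz = tf, orientation_deg = ori,
                        contrast = con, inversion_interval = dt_inv,
                        inversion_times = times[-1]), duration)
    },
    drifting_grating = {
      con <- chk_contrast(p$contrast %||% 0.8)
      sf <- p$sf_cpd %||% 0.035
      tf <- p$tf_hz %||% 1
      dir <- (p$direction_deg %||% 0) %% 360
      duration <- p$duration %||% 5
      fr <- p$frame_rate %||% 20
      npat <- max(4L, round(fr / tf))
      pats <- vapply(seq_len(npat) - 1L, function(k)
        grating_pattern(screen, sf, dir, -2 * pi * k / npat, con),
        numeric(screen$npix))
      times <- seq(0, duration - 1e-9, by = 1 / fr)
      idx <- (seq_along(times) - 1L) %% npat + 1L
      new_stimulus(kind, times, idx, pats, screen,
                   list(sf_cpd = sf, tf_hz = tf, direction_deg = dir,
                        contrast = con, frame_rate = fr,
                        speed_deg_s = grating_speed_deg_s(tf, sf)), duration)
    },
    bar_white_noise = {
      con <- chk_contrast(p$contrast %||% 1)
      axis <- match.arg(p$axis %||% "vertical", c("vertical", "horizontal"))
      bw <- p$bar_width_deg %||% 5
      nf <- p$n_frames %||% 5000
      fr <- p$frame_rate %||% 25
      seed <- p$seed %||% 1
      coord <- if (axis == "vertical") screen$xs else screen$ys
      extent <- if (axis == "vertical") screen$width_deg else screen$height_deg
      npos <- floor(extent / bw)
      edges <- -extent / 2 + bw * (seq_len(npos) - 1)
      centers <- edges + bw / 2
      pats <- matrix(0, screen$npix, npos * 2L)
      for (i in seq_len(npos)) {
        inbar <- coord >= edges[i] & coord < edges[i] + bw
        pats[inbar, 2 * i - 1] <- con    # white bar
        pats[inbar, 2 * i] <- -con       # black bar
      }
      rs <- local({ set.seed(seed)
        list(pos = sample.int(npos, nf, replace = TRUE),
             col = sample.int(2L, nf, replace = TRUE)) })
      idx <- 2L * (rs$pos - 1L) + rs$col
      times <- seq(0, by = 1 / fr, length.out = nf)
      new_stimulus(kind, times, idx, pats, screen,
                   list(axis = axis, bar_width_deg = bw, contrast = con,
                        frame_rate = fr, positions_deg = centers,
                        position_idx = rs$pos, color = c(1, -1)[rs$col],
                        seed = seed), nf / fr)
    },
    movie = {
      duration <- p$duration %||% 30
      fr <- p$frame_rate %||% 10
      seed <- p$seed %||% 1
      csd <- p$contrast_sd %||% 0.35
      nf <- round(duration * fr)
      pats <- onef_movie(screen, nf, seed, csd)
      times <- seq(0, by = 1 / fr, length.out = nf)
      new_stimulus(kind, times, seq_len(nf), pats, screen,
                   list(frame_rate = fr, seed = seed, contrast_sd = csd),
                   duration)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded 1/f spatiotemporal noise surrogate for natural footage
onef_movie <- function(screen, nf, seed, contrast_sd) {
  set.seed(seed)
  nx <- screen$nx; ny <- screen$ny
  arr <- array(stats::rnorm(nx * ny * nf), dim = c(nx, ny, nf))
  fx <- stats::fft(arr)
  kx <- c(seq(0, floor(nx / 2)), seq(-ceiling(nx / 2) + 1, -1)) / nx
  ky <- c(seq(0, floor(ny / 2)), seq(-ceiling(ny / 2) + 1, -1)) / ny
  kt <- c(seq(0, floor(nf / 2)), seq(-ceiling(nf / 2) + 1, -1)) / nf
  ks <- sqrt(outer(kx^2, ky^2, `+`))
  amp_s <- 1 / (ks + min(1 / nx, 1 / ny))
  amp_t <- 1 / (abs(kt) + 1 / nf)
  fl <- sweep(array(rep(amp_s, nf), dim = c(nx, ny, nf)), 3, amp_t, `*`)
  sm <- Re(stats::fft(fx * fl, inverse = TRUE)) / (nx * ny * nf)
  sm <- sm / stats::sd(sm) * contrast_sd
  sm <- pmin(pmax(sm, -1), 1)
  dim(sm) <- c(nx * ny, nf)   # pixel order: x fastest, matching screen$xs
  sm
}
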