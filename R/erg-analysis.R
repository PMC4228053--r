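#' Extract the b-wave amplitude from an ERG trace
#'
#' Standard trough-to-peak convention: the mean voltage over the 50 ms
#' before the flash is subtracted (drift robustness), the a-wave trough is
#' the minimum within the search window after flash onset, and the b-wave
#' peak the maximum after the trough; amplitude is peak minus trough.
#'
#' @param trace an `erg_trace` (or data frame with `time_s`, `uv` columns
#'   and a `flash_onset_s` attribute or argument).
#' @param window_s search window after flash onset (s).
#' @param flash_onset_s flash time; defaults to the trace attribute.
#' @return An object of class `"b_wave"`: list with `amplitude_uv`,
#'   `a_trough_time_s`, `b_peak_time_s`, `condition`, `trial`.
#' @export
extract_b_wave <- function(trace, window_s = 0.2,
                           flash_onset_s = attr(trace, "flash_onset_s")) {
  if (is.null(flash_onset_s)) stop("flash onset time unknown")
  tt <- trace$time_s; v <- trace$uv
  if (flash_onset_s + window_s > max(tt) + 1e-9)
    stop("extract_b_wave: window extends beyond the trace")
  pre <- v[tt >= flash_onset_s - 0.05 & tt < flash_onset_s]
  if (length(pre)) v <- v - mean(pre)
  inwin <- which(tt >= flash_onset_s & tt <= flash_onset_s + window_s)
  ia <- inwin[which.min(v[inwin])]
  post <- inwin[inwin >= ia]
  ib <- post[which.max(v[post])]
  structure(list(amplitude_uv = v[ib] - v[ia],
                 a_trough_time_s = tt[ia], b_peak_time_s = tt[ib],
                 condition = attr(trace, "condition") %||% NA_character_,
                 trial = attr(trace, "trial") %||% NA_integer_),
            class = "b_wave")
}

#' Adaptation time course of b-wave amplitudes
#'
#' Bins a time-stamped series of b-wave amplitudes following a condition
#' switch, and fits a single-exponential approach
#' `A(t) = A_inf + (A_0 - A_inf) exp(-t / tau)` to the raw series. The time
#' constant is flagged unidentifiable when the fitted amplitude change is
#' smaller than twice the residual noise, or when the fit fails.
#'
#' @param time_s time of each measurement since the condition switch (s).
#' @param amplitude_uv b-wave amplitude per measurement.
#' @param bin_s bin width for the displayed time course (s).
#' @return List with `timecourse` (data frame: `t`, `mean`, `sem`, `n`),
#'   `tau_s`, `a0`, `a_inf`, `identifiable`.
#' @export
adaptation_timecourse <- function(time_s, amplitude_uv, bin_s = 30) {
  stopifnot(length(time_s) == length(amplitude_uv))
  bins <- floor(time_s / bin_s)
  if (length(unique(bins)) < 3)
    stop("adaptation_timecourse: need at least 3 time bins")
  tc <- do.call(rbind, lapply(split(seq_along(bins), bins), function(i)
    data.frame(t = (bins[i[1]] + 0.5) * bin_s, mean = mean(amplitude_uv[i]),
               sem = stats::sd(amplitude_uv[i]) / sqrt(length(i)),
               n = length(i))))
  rownames(tc) <- NULL

  a0 <- mean(amplitude_uv[time_s <= min(time_s) + bin_s])
  ainf <- mean(amplitude_uv[time_s >= max(time_s) - bin_s])
  out <- list(timecourse = tc, tau_s = NA_real_, a0 = a0, a_inf = ainf,
              identifiable = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      amplitude_uv ~ ainf_ + (a0_ - ainf_) * exp(-time_s / tau_),
      start = list(a0_ = a0, ainf_ = ainf,
                   tau_ = max(diff(range(time_s)) / 3, bin_s)),
      lower = c(-Inf, -Inf, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    resid_sd <- stats::sd(stats::resid(fit))
    span <- abs(cf[["a0_"]] - cf[["ainf_"]])
    out$tau_s <- cf[["tau_"]]; out$a0 <- cf[["a0_"]]; out$a_inf <- cf[["ainf_"]]
    out$identifiable <- span > 2 * resid_sd &&
      cf[["tau_"]] < 10 * diff(range(time_s))
  }
  out
}

#' Fit Naka-Rushton contrast-response functions and compare conditions
#'
#' Least-squares fit of `R(c) = Rmax c^n / (c^n + c50^n)` to amplitudes
#' measured over a contrast series, per condition and (optionally) shared
#' across conditions, with an extra-sum-of-squares F test of whether
#' separate per-condition curves explain significantly more variance than
#' one shared curve.
#'
#' @param data data frame with columns `contrast`, `amplitude` and
#'   (optionally) `condition`.
#' @param normalize if `TRUE`, amplitudes are divided by the maximum
#'   recorded amplitude (per `group` column if present — "1 = maximum
#'   recorded for that animal") before fitting.
#' @param compare if `TRUE` and >= 2 conditions present, perform the
#'   shared-vs-separate F test.
#' @return An object of class `"crf_fit"`: per-condition parameter list
#'   (`rmax`, `c50`, `n`, `rss`), shared fit, and `f_test` (`F`, `df1`,
#'   `df2`, `p`).
#' @export
fit_contrast_response <- function(data, normalize = FALSE, compare = TRUE) {
  stopifnot(all(c("contrast", "amplitude") %in% names(data)))
  if (length(unique(data$contrast)) < 4)
    stop("fit_contrast_response: need >= 4 contrast levels")
  if (is.null(data$condition)) data$condition <- "all"
  if (normalize) {
    grp <- if (!is.null(data$group)) data$group else rep(1, nrow(data))
    mx <- stats::ave(data$amplitude, grp, FUN = max)
    data$amplitude <- data$amplitude / mx
  }

  fit1 <- function(d) {
    rmax0 <- max(d$amplitude)
    half <- rmax0 / 2
    ord <- order(d$contrast)
    c50_0 <- tryCatch(
      stats::approx(d$amplitude[ord], d$contrast[ord], xout = half,
                    ties = mean)$y, error = function(e) NA_real_)
    if (!is.finite(c50_0) || c50_0 <= 0) c50_0 <- 0.3
    fit <- tryCatch(minpack.lm::nlsLM(
      amplitude ~ naka_rushton(contrast, rmax, c50, n), data = d,
      start = list(rmax = rmax0, c50 = c50_0, n = 2),
      lower = c(1e-9, 1e-6, 1e-3), upper = c(Inf, 1, 50),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit))
      return(list(rmax = NA_real_, c50 = NA_real_, n = NA_real_,
                  rss = NA_real_, converged = FALSE))
    cf <- stats::coef(fit)
    list(rmax = cf[["rmax"]], c50 = cf[["c50"]], n = cf[["n"]],
         rss = sum(stats::resid(fit)^2), converged = TRUE)
  }

  conds <- unique(data$condition)
  per <- lapply(conds, function(cn) fit1(data[data$condition == cn, ]))
  names(per) <- conds
  shared <- fit1(data)

  f_test <- NULL
  if (compare && length(conds) >= 2 &&
      all(vapply(per, `[[`, logical(1), "converged")) && shared$converged) {
    rss_sep <- sum(vapply(per, `[[`, numeric(1), "rss"))
    df_sep <- nrow(data) - 3 * length(conds)
    df_sh <- nrow(data) - 3
    extra <- shared$rss - rss_sep
    if (extra <= 1e-12 * max(shared$rss, .Machine$double.eps)) {
      Fstat <- 0   # separate curves explain nothing extra (e.g. identical data)
    } else {
      Fstat <- max(0, (extra / (df_sh - df_sep)) / (rss_sep / df_sep))
    }
    f_test <- list(F = Fstat, df1 = df_sh - df_sep, df2 = df_sep,
                   p = stats::pf(Fstat, df_sh - df_sep, df_sep,
                                 lower.tail = FALSE))
  }
  structure(list(per_condition = per, shared = shared, f_test = f_test,
                 normalized = normalize, n_obs = nrow(data)),
            class = "crf_fit")
}

#' @export
print.crf_fit <- function(x, ...) {
  cat("<crf_fit> Naka-Rushton contrast-response fit\n")
  for (cn in names(x$per_condition)) {
    p <- x$per_condition[[cn]]
    cat(sprintf("  %-12s Rmax %.4g  c50 %.4g  n %.4g  (rss %.3g)%s\n", cn,
                p$rmax, p$c50, p$n, p$rss,
                if (!p$converged) "  [NOT CONVERGED]" else ""))
  }
  if (!is.null(x$f_test))
    cat(sprintf("  shared vs separate: F(%d,%d) = %.3g, p = %.3g\n",
                x$f_test$df1, x$f_test$df2, x$f_test$F, x$f_test$p))
  invisible(x)
}

#' @export
coef.crf_fit <- function(object, ...) {
  t(vapply(object$per_condition,
           function(p) c(rmax = p$rmax, c50 = p$c50, n = p$n), numeric(3)))
}

#' @export
predict.crf_fit <- function(object, contrast, condition = NULL, ...) {
  p <- if (is.null(condition)) object$shared else
    object$per_condition[[condition]]
  naka_rushton(contrast, p$rmax, p$c50, p$n)
}
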