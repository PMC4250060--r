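#' Normalized autocorrelation of a collective variable
#'
#' Mean-removed, variance-normalized autocorrelation function of a CV series
#' after discarding an initial equilibration stretch. Computed to a maximum
#' lag of 10% of the (retained) series length; long lags are noise-dominated
#' and excluded by construction.
#'
#' @param series a `CVSeries` (or plain numeric vector).
#' @param skip initial stretch to discard, in ps (default 10 ns = 1e4 ps).
#'   Ignored for plain vectors without times.
#' @param max_lag_frac maximum lag as a fraction of series length
#'   (default 0.1).
#' @return list with `lag` (in frames), `lag_time` (ps, when times known),
#'   `acf` (normalized, acf\[1\] = 1 at lag 0), `dt` (ps or NA), `n` (frames
#'   used).
#' @export
cv_autocorrelation <- function(series, skip = 10000, max_lag_frac = 0.1) {
  if (inherits(series, "CVSeries")) {
    keep <- series$times >= series$times[1] + skip
    x <- series$values[keep]
    dt <- if (length(series$times) > 1) diff(series$times[1:2]) else NA_real_
  } else {
    x <- as.numeric(series)
    dt <- NA_real_
  }
  n <- length(x)
  if (n < 10) stop("too few frames after skipping the transient")
  if (var(x) == 0) stop("constant CV series: autocorrelation undefined")
  max_lag <- max(1L, floor(n * max_lag_frac))
  ac <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lag <- seq_along(ac) - 1L
  list(lag = lag, lag_time = if (is.na(dt)) NULL else lag * dt,
       acf = as.numeric(ac), dt = dt, n = n)
}

#' Decorrelation time from an exponential ACF fit
#'
#' Single-exponential least-squares fit acf(k) ~ exp(-k/tau) (no additive
#' offset) over lags 1 .. first lag where the ACF drops below e^-2; beyond
#' that point the ACF is noise-dominated. A residual diagnostic flags fits
#' on nonmonotone or oscillating ACFs.
#'
#' @param ac result of [cv_autocorrelation()].
#' @param poor_fit_rms RMS-residual level above which the fit is flagged
#'   (default 0.05).
#' @return list with `tau` (ps if the ACF carries times, else frames),
#'   `tau_frames`, `rms_residual`, `poor_fit` (logical), `n_lags_fit`.
#' @export
fit_correlation_time <- function(ac, poor_fit_rms = 0.05) {
  a <- ac$acf
  below <- which(a < exp(-2))
  if (length(below) == 0) {
    if (min(a) > 0.9) stop("ACF never decays; cannot fit a correlation time")
    end <- length(a)
  } else {
    end <- below[1]
  }
  k <- ac$lag[2:end]
  y <- a[2:end]
  if (length(k) < 2) { k <- ac$lag[2:min(4, length(a))]; y <- a[2:min(4, length(a))] }
  sse <- function(tau) sum((y - exp(-k / tau))^2)
  opt <- optimize(sse, interval = c(1e-3, max(k) * 50))
  tau_frames <- opt$minimum
  rms <- sqrt(opt$objective / length(k))
  dt <- if (is.null(ac$dt) || is.na(ac$dt)) 1 else ac$dt
  list(tau = tau_frames * dt, tau_frames = tau_frames,
       rms_residual = rms, poor_fit = rms > poor_fit_rms,
       n_lags_fit = length(k))
}

#' Internal diffusion coefficient of a collective variable
#'
#' Harmonic-approximation estimate D = <delta xi^2> / tau_xi: the stationary
#' variance of the CV (after discarding the initial transient) divided by its
#' decorrelation time from the exponential ACF fit. Adding a constant to the
#' CV leaves D unchanged; scaling the CV by c scales D by c^2.
#'
#' @param series a `CVSeries`.
#' @param skip initial stretch to discard (ps), default 10 ns.
#' @return an object of class `DiffusionEstimate`: list with `cv` (name),
#'   `fluctuation` (<delta xi^2>, CV-units^2), `tau` (ns), `D`
#'   (CV-units^2/ns), `skip_ns`, `fit` (diagnostics from
#'   [fit_correlation_time()]).
#' @export
diffusion_coefficient <- function(series, skip = 10000) {
  if (!inherits(series, "CVSeries")) stop("series must be a CVSeries")
  keep <- series$times >= series$times[1] + skip
  x <- series$values[keep]
  if (length(x) < 10) stop("too few frames after skipping the transient")
  fluct <- mean((x - mean(x))^2)
  if (fluct == 0) stop("constant CV series: diffusion undefined")
  ac <- cv_autocorrelation(series, skip = skip)
  ft <- fit_correlation_time(ac)
  tau_ns <- ft$tau / 1000   # tau in ps -> ns
  structure(
    list(cv = series$name, fluctuation = fluct, tau = tau_ns,
         D = fluct / tau_ns, skip_ns = skip / 1000, fit = ft),
    class = "DiffusionEstimate"
  )
}

#' @export
print.DiffusionEstimate <- function(x, ...) {
  cat(sprintf(
    "<DiffusionEstimate '%s'> <dxi^2> = %.4g, tau = %.4g ns, D = %.4g /ns%s\n",
    x$cv, x$fluctuation, x$tau, x$D,
    if (isTRUE(x$fit$poor_fit)) "  [poor ACF fit]" else ""))
  invisible(x)
}
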