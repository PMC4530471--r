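#' Melt curves and binding series
#'
#' @param temperatures strictly increasing temperatures in Celsius
#'   (at least 10 points).
#' @param fluorescence reporter-dye fluorescence, same length.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperatures, fluorescence) {
  if (length(temperatures) != length(fluorescence))
    stop("temperatures and fluorescence must have equal length")
  if (length(temperatures) < 10L) stop("at least 10 points required")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (!all(is.finite(temperatures)) || !all(is.finite(fluorescence)))
    stop("non-finite values")
  structure(list(temperatures = temperatures, fluorescence = fluorescence),
            class = "melt_curve")
}

#' Melting temperatures from a dye-reported thermal melt
#'
#' The curve is min-max normalised, smoothed with a Savitzky-Golay
#' local polynomial, and differentiated by central differences.
#' Unfolding exposes hydrophobic surface and increases reporter-dye
#' fluorescence, so each transition appears as a maximum of +dF/dT.
#' Peak detection is restricted to temperatures before the global
#' fluorescence maximum, which excludes the post-aggregation decay, and
#' keeps peaks whose prominence is at least `min_prominence` of the
#' derivative range in that region.
#'
#' @param curve a [melt_curve()].
#' @param smooth_window odd Savitzky-Golay window length (default 7).
#' @param min_prominence fraction of the derivative range a peak must
#'   rise above its surroundings (default 0.1).
#' @return An object of class `melt_result`: list with `tms` (sorted
#'   Celsius), `n_transitions`, and `derivative_curve` (data frame
#'   temperature, dFdT).
#' @export
melting_temperatures <- function(curve, smooth_window = 7L,
                                 min_prominence = 0.1) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temperatures)
  if (smooth_window %% 2L == 0L || smooth_window < 3L || smooth_window >= n)
    stop("smooth_window must be odd, >= 3 and smaller than the curve")
  f <- curve$fluorescence
  rng <- range(f)
  if (diff(rng) == 0) {
    return(structure(list(tms = numeric(0), n_transitions = 0L,
                          derivative_curve = data.frame(
                            temperature = curve$temperatures,
                            dFdT = rep(0, n))),
                     class = "melt_result"))
  }
  fn <- (f - rng[1]) / diff(rng)
  fs <- signal::sgolayfilt(fn, p = 2, n = smooth_window)
  tt <- curve$temperatures
  dfdt <- numeric(n)
  dfdt[2:(n - 1)] <- (fs[3:n] - fs[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  dfdt[1] <- dfdt[2]; dfdt[n] <- dfdt[n - 1]
  # search window: before the global fluorescence maximum
  i_max <- which.max(fs)
  win <- seq_len(max(i_max, 3L))
  dwin <- dfdt[win]
  peaks <- find_peaks_prominence(dwin)
  if (nrow(peaks) > 0) {
    thresh <- min_prominence * diff(range(dwin))
    peaks <- peaks[peaks$prominence >= thresh & dwin[peaks$index] > 0, ,
                   drop = FALSE]
  }
  tms <- sort(tt[win][peaks$index])
  structure(list(tms = tms, n_transitions = length(tms),
                 derivative_curve = data.frame(temperature = tt, dFdT = dfdt)),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  if (x$n_transitions == 0L) cat("melt_result: no transitions detected\n")
  else cat(sprintf("melt_result: %d transition(s), Tm = %s degC\n",
                   x$n_transitions,
                   paste(sprintf("%.1f", x$tms), collapse = ", ")))
  invisible(x)
}

# Interior local maxima with topographic prominence: for each peak,
# walk out on both sides to the nearest higher peak (or the end) and
# take the higher of the two valley minima encountered; prominence is
# peak height minus that reference level.
find_peaks_prominence <- function(y) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(0), prominence = numeric(0)))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(idx) == 0L) return(data.frame(index = integer(0),
                                           prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[1:i]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l)) min(y[max(higher_l):i]) else min(left)
    right <- y[i:n]
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r)) min(y[i:(i + min(higher_r) - 1)]) else min(right)
    h - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Binding series container
#'
#' @param x concentrations (saturation mode) or times (dissociation
#'   mode); non-negative, strictly increasing for time series.
#' @param signal measured signal, same length.
#' @param mode "saturation" or "dissociation".
#' @return An object of class `binding_series`.
#' @export
binding_series <- function(x, signal, mode = c("saturation", "dissociation")) {
  mode <- match.arg(mode)
  if (length(x) != length(signal)) stop("x and signal must match in length")
  if (any(x < 0)) stop("x must be non-negative")
  if (mode == "dissociation" && any(diff(x) <= 0))
    stop("time series must be strictly increasing")
  structure(list(x = x, signal = signal, mode = mode, fitted = NULL),
            class = "binding_series")
}

#' One-site saturation binding fit
#'
#' Least-squares fit of `signal = bmax * c / (kd + c) + baseline` with
#' a deterministic initialisation (baseline from the signal minimum,
#' bmax from the span, kd from the half-rise concentration by linear
#' interpolation).  Standard errors come from the residual-based
#' covariance of the nonlinear fit.
#'
#' @param series a [binding_series()] in saturation mode with at least
#'   5 concentrations.
#' @return The series with a `fitted` list: kd, bmax, baseline, their
#'   standard errors, and `ill_conditioned` flag.
#' @export
fit_saturation <- function(series) {
  stopifnot(inherits(series, "binding_series"))
  if (series$mode != "saturation") stop("series is not in saturation mode")
  x <- series$x; y <- series$signal
  if (length(x) < 5L) stop("at least 5 concentration points required")
  base0 <- min(y)
  span0 <- max(y) - base0
  if (span0 <= 0) stop("signal has no dynamic range")
  half <- base0 + span0 / 2
  above <- which(y >= half)
  kd0 <- if (length(above)) max(x[min(above)], min(x[x > 0])) else stats::median(x)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bmax * x / (kd + x) + baseline, data = dat,
      start = list(bmax = span0, kd = kd0, baseline = base0),
      lower = c(bmax = 0, kd = .Machine$double.eps, baseline = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # curvature-free data: nlsLM cannot build a model (singular
    # gradient); fall back to the raw Levenberg-Marquardt estimates
    # with infinite standard errors
    lm_fit <- suppressWarnings(minpack.lm::nls.lm(
      par = c(bmax = span0, kd = kd0, baseline = base0),
      fn = function(p) y - (p[1] * x / (p[2] + x) + p[3])))
    warning("saturation fit ill-conditioned: no clear curvature")
    series$fitted <- list(
      kd = unname(lm_fit$par[2]), bmax = unname(lm_fit$par[1]),
      baseline = unname(lm_fit$par[3]),
      se = c(kd = Inf, bmax = Inf, baseline = Inf),
      ill_conditioned = TRUE)
    return(series)
  }
  cf <- summary(fit)$coefficients
  ill <- any(!is.finite(cf[, "Std. Error"])) ||
    cf["kd", "Std. Error"] > abs(cf["kd", "Estimate"])
  if (ill) warning("saturation fit ill-conditioned: no clear curvature")
  series$fitted <- list(
    kd = cf["kd", "Estimate"], bmax = cf["bmax", "Estimate"],
    baseline = cf["baseline", "Estimate"],
    se = c(kd = cf["kd", "Std. Error"], bmax = cf["bmax", "Std. Error"],
           baseline = cf["baseline", "Std. Error"]),
    ill_conditioned = ill)
  series
}

#' Single-exponential dissociation fit
#'
#' Least-squares fit of `signal = A * exp(-t / tau) + baseline`;
#' `koff = 1 / tau`.  Initialised from a log-linear regression on
#' baseline-subtracted data, refined with Levenberg-Marquardt.
#'
#' @param series a [binding_series()] in dissociation mode with at
#'   least 6 time points and an overall decreasing signal.
#' @return The series with a `fitted` list: koff, tau, amplitude,
#'   baseline, standard errors.
#' @export
fit_dissociation <- function(series) {
  stopifnot(inherits(series, "binding_series"))
  if (series$mode != "dissociation") stop("series is not in dissociation mode")
  t <- series$x; y <- series$signal
  if (length(t) < 6L) stop("at least 6 time points required")
  if (y[length(y)] >= y[1]) stop("fit failure: signal does not decay")
  base0 <- min(y) - 0.05 * (max(y) - min(y))
  pos <- y - base0 > 0
  lf <- stats::lm(log(y[pos] - base0) ~ t[pos])
  tau0 <- unname(max(-1 / stats::coef(lf)[2], diff(range(t)) / 20))
  a0 <- unname(exp(stats::coef(lf)[1]))
  dat <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-t / tau) + baseline, data = dat,
    start = list(A = a0, tau = tau0, baseline = max(base0, 0)),
    lower = c(A = 0, tau = .Machine$double.eps, baseline = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  tau <- cf["tau", "Estimate"]
  series$fitted <- list(
    koff = 1 / tau, tau = tau,
    amplitude = cf["A", "Estimate"], baseline = cf["baseline", "Estimate"],
    se = c(tau = cf["tau", "Std. Error"], A = cf["A", "Std. Error"],
           baseline = cf["baseline", "Std. Error"]),
    ill_conditioned = FALSE)
  series
}
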