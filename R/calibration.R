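#' A recorded PID trace
#'
#' @param t Sample times, s (strictly increasing).
#' @param signal PID signal, volts.
#' @param valve_open_t,valve_close_t Valve opening and closing times, s,
#'   with `valve_open_t < valve_close_t` and both inside the record.
#' @return An object of class `"pid_trace"`.
#' @export
pid_trace <- function(t, signal, valve_open_t, valve_close_t) {
  t <- as.numeric(t); signal <- as.numeric(signal)
  if (length(t) != length(signal) || length(t) < 2L) {
    stop("'t' and 'signal' must be equal-length vectors (>= 2 samples)",
         call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing", call. = FALSE)
  if (!(valve_open_t < valve_close_t)) {
    stop("'valve_open_t' must precede 'valve_close_t'", call. = FALSE)
  }
  if (valve_open_t < t[1L] || valve_close_t > t[length(t)]) {
    stop("valve times must lie within the recorded time range", call. = FALSE)
  }
  structure(list(t = t, signal = signal,
                 valve_open_t = valve_open_t, valve_close_t = valve_close_t),
            class = "pid_trace")
}

#' @export
print.pid_trace <- function(x, ...) {
  cat(sprintf(
    "<pid_trace> %d samples over [%.4g, %.4g] s; valve open [%.4g, %.4g] s\n",
    length(x$t), x$t[1L], x$t[length(x$t)], x$valve_open_t, x$valve_close_t))
  invisible(x)
}

#' Read a PID trace CSV (`t_s,signal_v`) plus valve times
#'
#' @param path CSV path with columns `t_s` and `signal_v`.
#' @param valve_open_t,valve_close_t Valve times, s.
#' @return A [pid_trace()].
#' @export
read_pid_trace <- function(path, valve_open_t, valve_close_t) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "signal_v") %in% names(df))) {
    stop("PID trace CSV must have columns 't_s' and 'signal_v'",
         call. = FALSE)
  }
  pid_trace(df$t_s, df$signal_v, valve_open_t, valve_close_t)
}

#' Baseline-subtracted plateau intensity of a PID trace
#'
#' Plateau response = mean signal over the `window` seconds before valve
#' closing, minus the mean clean-air baseline over the `window` seconds
#' before valve opening. Windows that extend beyond the available record
#' are shrunk with a warning.
#'
#' @param trace A [pid_trace()].
#' @param window Averaging window, s (default 30).
#' @return Plateau intensity, volts.
#' @export
extract_plateau <- function(trace, window = 30) {
  stopifnot(inherits(trace, "pid_trace"), window > 0)
  # half-open on the right so the window excludes the transition sample
  win_mean <- function(from, to, what) {
    idx <- trace$t >= from & trace$t < to
    if (!any(idx)) {
      stop(sprintf("no samples in the %s window [%.4g, %.4g) s", what,
                   from, to), call. = FALSE)
    }
    mean(trace$signal[idx])
  }
  b0 <- trace$valve_open_t - window
  if (b0 < trace$t[1L]) {
    warning("baseline window shrunk to the available pre-opening record")
    b0 <- trace$t[1L]
  }
  p0 <- trace$valve_close_t - window
  if (p0 < trace$valve_open_t) {
    warning("plateau window shrunk to the open-valve period")
    p0 <- trace$valve_open_t
  }
  win_mean(p0, trace$valve_close_t, "plateau") -
    win_mean(b0, trace$valve_open_t, "baseline")
}

#' PID calibration curve on log-log scale
#'
#' Fits `log(response) ~ log(concentration)` by ordinary least squares over
#' calibration points spanning at least one order of magnitude in
#' concentration.
#'
#' @param concentration Known headspace concentrations, mol/m^3 (> 0).
#' @param response Measured PID responses, volts (> 0).
#' @return An object of class `"pid_calibration_curve"` with the fitted
#'   log-log slope and intercept.
#' @export
pid_calibration_curve <- function(concentration, response) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) < 2L ||
      length(concentration) != length(response)) {
    stop("need >= 2 matched calibration points", call. = FALSE)
  }
  if (any(concentration <= 0) || any(response <= 0)) {
    stop("calibration concentrations and responses must be positive",
         call. = FALSE)
  }
  if (max(concentration) / min(concentration) < 10) {
    stop("calibration points must span at least one order of magnitude",
         call. = FALSE)
  }
  fit <- stats::lm(log(response) ~ log(concentration))
  structure(list(points = data.frame(concentration = concentration,
                                     response = response),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 fit = fit),
            class = "pid_calibration_curve")
}

#' @export
print.pid_calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<pid_calibration_curve> %d points; log(V) = %.4g + %.4g log(C)\n",
    nrow(x$points), x$intercept, x$slope))
  invisible(x)
}

#' Convert a PID response to a concentration via a calibration curve
#'
#' Inverts the fitted log-log line. Responses more than a factor of 10
#' outside the calibrated response range are flagged with a warning
#' (extrapolation).
#'
#' @param response PID response, volts (> 0).
#' @param curve A [pid_calibration_curve()].
#' @return Concentration, mol/m^3.
#' @export
apply_pid_calibration <- function(response, curve) {
  stopifnot(inherits(curve, "pid_calibration_curve"))
  if (any(response <= 0)) {
    stop("'response' must be strictly positive", call. = FALSE)
  }
  rng <- range(curve$points$response)
  if (any(response < rng[1L] / 10) || any(response > rng[2L] * 10)) {
    warning("response more than 10x outside the calibrated range; ",
            "extrapolating the log-log fit")
  }
  exp((log(response) - curve$intercept) / curve$slope)
}

#' Flow-dilution correction of PID measurements
#'
#' At the source outlet the PID pump (750 mL/min) draws more air than the
#' source delivers (200 mL/min), so the sample is diluted with the clean
#' make-up air and the measured concentration is multiplied by 750/200. At
#' the Teflon-tube or glass-tube outlets the delivered flow exceeds the
#' pump flow and no correction applies.
#'
#' @param c_measured Measured concentration, mol/m^3.
#' @param location One of `"source_outlet"`, `"teflon_outlet"`,
#'   `"glass_tube_outlet"`.
#' @param pid_flow,source_flow Pump and source airflows in any common unit
#'   (defaults 750 and 200 mL/min).
#' @return Corrected concentration, mol/m^3.
#' @export
flow_correction <- function(c_measured,
                            location = c("source_outlet", "teflon_outlet",
                                         "glass_tube_outlet"),
                            pid_flow = 750, source_flow = 200) {
  location <- match.arg(location)
  if (location == "source_outlet") {
    c_measured * pid_flow / source_flow
  } else {
    c_measured
  }
}

#' Express a measured concentration as a fraction of the equilibrium headspace
#'
#' @param c_corrected Flow-corrected concentration, mol/m^3.
#' @param c_h0 Initial (equilibrium) headspace concentration, mol/m^3 (> 0).
#' @return Dimensionless observed plateau concentration.
#' @export
to_dimensionless <- function(c_corrected, c_h0) {
  if (!is.finite(c_h0) || c_h0 <= 0) {
    stop("'c_h0' must be strictly positive", call. = FALSE)
  }
  c_corrected / c_h0
}

#' Assemble plateau observations for calibration
#'
#' @param compound Compound names.
#' @param khl Partition coefficients (> 0).
#' @param y_psr_obs Observed dimensionless plateau concentrations, in
#'   `(0, 1.2]` (a small overshoot is tolerated for noisy data).
#' @param location Measurement location (recycled).
#' @return A data frame of class `"plateau_observations"`.
#' @export
plateau_observations <- function(compound, khl, y_psr_obs,
                                 location = "source_outlet") {
  if (any(khl <= 0)) stop("'khl' must be positive", call. = FALSE)
  if (any(y_psr_obs <= 0) || any(y_psr_obs > 1.2)) {
    stop("'y_psr_obs' must lie in (0, 1.2]", call. = FALSE)
  }
  df <- data.frame(compound = as.character(compound), khl = khl,
                   y_psr_obs = y_psr_obs, location = location,
                   stringsAsFactors = FALSE)
  class(df) <- c("plateau_observations", "data.frame")
  df
}

#' Read plateau observations from CSV (`compound,khl,y_psr_obs,location`)
#'
#' @param path CSV path.
#' @return A [plateau_observations()] data frame.
#' @export
read_plateau_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "khl", "y_psr_obs")
  if (!all(need %in% names(df))) {
    stop("observations CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  plateau_observations(df$compound, df$khl, df$y_psr_obs,
                       if ("location" %in% names(df)) df$location
                       else "source_outlet")
}

#' Calibrate transfer coefficients from observed plateau concentrations
#'
#' Fits the pseudo-stationary relationship
#' `Y ~ A / (A + exp(B) + exp(C) * Khl)` with `B = log(Q_s/k_h)` and
#' `C = log(Q_s/k_l)` to observed dimensionless plateau concentrations by
#' nonlinear least squares on the untransformed `Y`. The log
#' parametrisation yields back-transformed estimates `k_h = Q_s/exp(B)`,
#' `k_l = Q_s/exp(C)` with Wald 95% confidence intervals that are
#' symmetrical on a logarithmic scale. Identifiability of `k_l` requires
#' observations on the declining (high-`Khl`) part of the curve.
#'
#' @param obs A [plateau_observations()] data frame (or any data frame with
#'   columns `khl` and `y_psr_obs`).
#' @param device The [device_geometry()] on which the observations were
#'   made (supplies `A` and `Q_s`).
#' @param n_starts Multi-start grid resolution per parameter (default 5).
#' @param conf_level Confidence level for the intervals.
#' @param variance Error-variance model: `"constant"` (default; ordinary
#'   unweighted least squares) or `"relative"` (error standard deviation
#'   proportional to the plateau level, fitted by `1/yhat^2`-weighted least
#'   squares). Use `"relative"` when the measurement error is known to be
#'   multiplicative, as for detector signals spanning decades; the
#'   intervals are then calibrated against that noise structure.
#' @return An object of class `"calibration_fit"` with elements `b_param`,
#'   `c_param`, `k_h`, `k_l`, `ci_h`, `ci_l`, `rss`, `n`, and the underlying
#'   `nls` fit.
#' @examples
#' dev <- reference_device()
#' k_true <- reference_transfer()
#' obs <- gen_plateau_observations(k_true, dev,
#'                                 khl_list = 10^seq(-7, -2, length.out = 9),
#'                                 sigma = 0, seed = 1)
#' fit <- fit_transfer_coefficients(obs, dev)
#' fit
#' @export
fit_transfer_coefficients <- function(obs, device, n_starts = 5L,
                                      conf_level = 0.95,
                                      variance = c("constant", "relative")) {
  stopifnot(inherits(device, "device_geometry"))
  variance <- match.arg(variance)
  if (!all(c("khl", "y_psr_obs") %in% names(obs))) {
    stop("'obs' must have columns 'khl' and 'y_psr_obs'", call. = FALSE)
  }
  khl <- obs$khl; y <- obs$y_psr_obs
  n <- length(khl)
  if (n < 3L) {
    stop("identifiability failure: need >= 3 observations to fit (B, C)",
         call. = FALSE)
  }
  a <- device$area; qs <- device$q_s

  # Heuristic starts: B from the low-khl plateau level, C from the highest
  # khl observation.
  low <- khl <= stats::quantile(khl, 1 / 3)
  y_low <- mean(y[low])
  y_low <- min(max(y_low, 1e-6), 0.999)
  b0 <- log(a * (1 - y_low) / y_low)
  i_hi <- which.max(khl)
  y_hi <- min(max(y[i_hi], 1e-6), 0.999)
  ec <- (a * (1 - y_hi) / y_hi - exp(b0)) / khl[i_hi]
  c0 <- if (is.finite(ec) && ec > 0) log(ec) else b0 - log(khl[i_hi])

  grid <- expand.grid(B = b0 + seq(-2, 2, length.out = n_starts),
                      C = c0 + seq(-2, 2, length.out = n_starts))
  starts <- rbind(data.frame(B = b0, C = c0), grid)

  df <- data.frame(khl = khl, y = y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (a + exp(B) + exp(C) * khl), data = df,
                        start = list(B = starts$B[i], C = starts$C[i]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "nonlinear fit did not converge from any of %d start points (B0 = %.3g, C0 = %.3g)",
      nrow(starts), b0, c0), call. = FALSE)
  }
  fit <- best$fit
  if (variance == "relative") {
    # iteratively reweighted least squares from the unweighted optimum,
    # with weights 1/yhat^2 (constant relative error)
    for (iter in 1:2) {
      df$w <- 1 / stats::fitted(fit)^2
      refit <- tryCatch(
        minpack.lm::nlsLM(y ~ a / (a + exp(B) + exp(C) * khl), data = df,
                          start = as.list(stats::coef(fit)), weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(refit)) break
      fit <- refit
    }
    best$rss <- sum((df$y - stats::fitted(fit))^2)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(B = NA_real_, C = NA_real_))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2L)
  # k = Qs/exp(param): the interval is symmetric in log space
  back <- function(param) qs / exp(param)
  ci_from <- function(param, s) {
    if (!is.finite(s)) return(c(NA_real_, NA_real_))
    c(back(param + tq * s), back(param - tq * s))
  }
  k_l_hat <- back(cf[["C"]])
  # Degenerate design: all khl on the flat part of the curve leaves C
  # (hence k_l) unidentifiable.
  if (exp(cf[["C"]]) * max(khl) < 0.05 * (a + exp(cf[["B"]])) ||
      (is.finite(se[["C"]]) && se[["C"]] > 5)) {
    warning("k_l is poorly identified: no observations on the declining ",
            "(high-Khl) part of the curve")
  }
  structure(
    list(b_param = unname(cf[["B"]]), c_param = unname(cf[["C"]]),
         k_h = back(cf[["B"]]), k_l = k_l_hat,
         ci_h = ci_from(cf[["B"]], se[["B"]]),
         ci_l = ci_from(cf[["C"]], se[["C"]]),
         rss = best$rss, n = n, conf_level = conf_level,
         variance = variance, device = device, fit = fit),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  cat(sprintf("  k_h = %.3g m/s (%.0f%% CI %.3g-%.3g)\n",
              x$k_h, 100 * x$conf_level, x$ci_h[1], x$ci_h[2]))
  cat(sprintf("  k_l = %.3g m/s (%.0f%% CI %.3g-%.3g)\n",
              x$k_l, 100 * x$conf_level, x$ci_l[1], x$ci_l[2]))
  cat(sprintf("  RSS = %.4g on %d observations\n", x$rss, x$n))
  invisible(x)
}

#' Predict plateau concentrations from a calibration fit
#'
#' @param object A `"calibration_fit"`.
#' @param khl Partition coefficients at which to predict.
#' @param ... Unused.
#' @return Predicted dimensionless plateau concentrations.
#' @export
predict.calibration_fit <- function(object, khl, ...) {
  a <- object$device$area
  a / (a + exp(object$b_param) + exp(object$c_param) * khl)
}
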