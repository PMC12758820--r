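# Multiplicative lognormal noise: positive signals spanning decades.
# sigma is the standard deviation of log-noise; sigma = 0 is exact.
mult_noise <- function(n, sigma) {
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (sigma == 0) rep(1, n) else exp(stats::rnorm(n, sd = sigma))
}

#' Generate synthetic plateau observations
#'
#' The exact forward model of [fit_transfer_coefficients()]: dimensionless
#' plateau concentrations computed from [psr()] under known transfer
#' coefficients, degraded by multiplicative lognormal noise. Deterministic
#' under a fixed seed.
#'
#' @param k_true Generating [transfer_coefficients()].
#' @param device A [device_geometry()].
#' @param khl_list Partition coefficients of the emulated compound panel.
#' @param sigma Standard deviation of the log-noise (0 = noise-free).
#' @param seed Mandatory integer seed.
#' @return A [plateau_observations()] data frame.
#' @export
gen_plateau_observations <- function(k_true, device, khl_list, sigma, seed) {
  stopifnot(length(khl_list) >= 1L, is.numeric(seed))
  y <- psr(device, k_true, khl_list)
  noisy <- withr::with_seed(as.integer(seed),
                            y * mult_noise(length(y), sigma))
  plateau_observations(
    compound = sprintf("synthetic_%02d", seq_along(khl_list)),
    khl = khl_list, y_psr_obs = pmin(noisy, 1.2),
    location = "source_outlet")
}

#' Generate a synthetic PID trace
#'
#' Simulates the device, scales the outlet concentration by a detector
#' gain, optionally applies a first-order low-pass filter with time
#' constant `tau_pid` (emulating the PID's slow response to low-volatility
#' compounds), and adds noise on top of a constant baseline.
#'
#' @inheritParams simulate_device
#' @param gain Detector gain, volts per dimensionless concentration unit.
#' @param sigma Additive Gaussian noise standard deviation, volts.
#' @param seed Mandatory integer seed.
#' @param tau_pid Detector low-pass time constant, s (0 = ideal detector).
#' @param baseline Constant clean-air baseline, volts.
#' @param which Trajectory the detector samples: `"y_h"` (source outlet)
#'   or `"y_c"` (tube outlet).
#' @return A [pid_trace()]; valve times are taken from the protocol.
#' @export
gen_pid_trace <- function(device, k, khl, protocol, gain, sigma, seed,
                          tau_pid = 0, baseline = 0.05,
                          which = c("y_h", "y_c")) {
  which <- match.arg(which)
  stopifnot(is.numeric(seed), gain > 0, tau_pid >= 0)
  tc <- simulate_device(device, k, khl, protocol)
  y <- tc[[which]]
  if (which == "y_h") {
    # at the source outlet the detector samples delivered air: the
    # headspace concentration while the valve is open, clean air otherwise
    y <- y * as.numeric(tc$valve_open)
  }
  if (tau_pid > 0) {
    # exact discrete first-order low-pass on the (uniform) sample grid
    dt <- diff(tc$t)
    out <- numeric(length(y))
    out[1L] <- y[1L]
    for (i in seq_along(dt)) {
      a <- exp(-dt[i] / tau_pid)
      out[i + 1L] <- a * out[i] + (1 - a) * y[i + 1L]
    }
    y <- out
  }
  signal <- baseline + gain * y
  signal <- withr::with_seed(as.integer(seed), {
    if (sigma > 0) signal + stats::rnorm(length(signal), sd = sigma)
    else signal
  })
  open_idx <- which(tc$valve_open)
  if (!length(open_idx)) {
    stop("protocol contains no open-valve segment", call. = FALSE)
  }
  pid_trace(tc$t, signal,
            valve_open_t = tc$t[open_idx[1L]],
            valve_close_t = tc$t[open_idx[length(open_idx)]])
}

#' Generate a synthetic PRV series
#'
#' Forward model of [prv_fit()]: liquid aliquots between `v_min` and
#' `v_max` in a 20-mL vial give areas `p1 / (beta + 1/Khl)`, with
#' multiplicative lognormal noise.
#'
#' @param khl_true Generating partition coefficient.
#' @param n_vials Number of vials (default 15).
#' @param sigma Log-noise standard deviation.
#' @param seed Mandatory integer seed.
#' @param v_vial Vial volume, m^3 (default 20 mL).
#' @param v_min,v_max Aliquot range, m^3 (defaults 30 uL to 1 mL).
#' @param p1 Detector/response gain (arbitrary units).
#' @return A [prv_series()].
#' @export
gen_prv_series <- function(khl_true, n_vials = 15L, sigma = 0, seed,
                           v_vial = 20e-6, v_min = 30e-9, v_max = 1e-6,
                           p1 = 1e6) {
  stopifnot(khl_true > 0, n_vials >= 3L, is.numeric(seed))
  v_liquid <- exp(seq(log(v_min), log(v_max), length.out = n_vials))
  beta <- (v_vial - v_liquid) / v_liquid
  area <- p1 / (beta + 1 / khl_true)
  area <- withr::with_seed(as.integer(seed),
                           area * mult_noise(n_vials, sigma))
  prv_series(v_liquid, area, v_vial = v_vial)
}

#' Generate a synthetic liquid-calibration series
#'
#' Forward model of [lc_fit()]: a power-law FID (`area =
#' gain * amount^exponent`) calibrated over known injected amounts, and
#' headspace observations at Henry equilibrium (`c_head = Khl * c_liquid`)
#' converted through the same detector. Optional per-series gain offsets
#' emulate day effects across independent series.
#'
#' @param khl_true Generating partition coefficient.
#' @param detector_gain FID gain (area per mol^exponent).
#' @param sigma Log-noise standard deviation.
#' @param seed Mandatory integer seed.
#' @param exponent Detector power-law exponent (1 = linear FID).
#' @param c_liquid Liquid concentrations, mol/m^3 (default 4 levels,
#'   3 replicates each).
#' @param n_replicates Replicates per concentration.
#' @param amounts Calibration amounts, mol; by default 4 log-spaced levels
#'   bracketing the emulated headspace injection amounts.
#' @param series_gain Named or unnamed vector of per-series multiplicative
#'   gain offsets; length gives the number of series.
#' @param v_injection Injected headspace volume, m^3.
#' @return An [lc_series()].
#' @export
gen_lc_series <- function(khl_true, detector_gain = 1e9, sigma = 0, seed,
                          exponent = 1, c_liquid = c(5, 15, 50, 150),
                          n_replicates = 3L, amounts = NULL,
                          series_gain = 1, v_injection = 2e-6) {
  stopifnot(khl_true > 0, is.numeric(seed), detector_gain > 0, exponent > 0)
  if (is.null(amounts)) {
    # bracket the headspace amounts so the calibration spans the responses
    rng <- range(khl_true * c_liquid * v_injection)
    amounts <- 10^seq(log10(rng[1] / 3), log10(rng[2] * 3), length.out = 4L)
  }
  cal_amount <- rep(amounts, each = n_replicates)
  obs_c <- rep(rep(c_liquid, each = n_replicates), times = length(series_gain))
  series_id <- rep(seq_along(series_gain),
                   each = length(c_liquid) * n_replicates)
  withr::with_seed(as.integer(seed), {
    cal_area <- detector_gain * cal_amount^exponent *
      mult_noise(length(cal_amount), sigma)
    amount_inj <- khl_true * obs_c * v_injection
    obs_area <- series_gain[series_id] * detector_gain *
      amount_inj^exponent * mult_noise(length(obs_c), sigma)
    lc_series(
      fid_calibration = data.frame(amount_injected = cal_amount,
                                   peak_area = cal_area),
      headspace_obs = data.frame(c_liquid = obs_c, peak_area = obs_area,
                                 series_id = series_id),
      v_injection = v_injection)
  })
}
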