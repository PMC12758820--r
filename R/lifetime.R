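#' Source lifetime by full ODE simulation
#'
#' The lifetime of an odor source is the time after valve opening at which
#' the headspace concentration first drops below 95% of the pseudo-stationary
#' value (computed from the closed form with `Y_l = 1`), i.e. when liquid
#' depletion starts to erode the delivered plateau. It is independent of the
#' amount of odorant loaded. Located by solver event detection in two
#' phases: the trajectory must first come within 1% of the plateau (to avoid
#' triggering on the initial equilibration transient), then the downward
#' crossing of `0.95 * Y_h,psr` is found.
#'
#' @inheritParams psr
#' @param horizon Maximum simulated time, s (default 30 days). If the
#'   threshold is not crossed, the result is censored at the horizon.
#' @param rtol,atol Solver tolerances.
#' @return A list of class `"lifetime_result"` with `lifetime` (s),
#'   `y_psr_used`, `method = "ode"` and logical `censored`.
#' @examples
#' dev <- reference_device()
#' k <- reference_transfer()
#' source_lifetime(dev, k, 1.14e-2)  # isoprene: well under a minute
#' @export
source_lifetime <- function(device, k, khl, horizon = 30 * 86400,
                            rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(device, "device_geometry"),
            inherits(k, "transfer_coefficients"))
  khl_num <- as_khl(khl)
  if (!is.finite(khl_num) || khl_num <= 0) {
    stop("'khl' must be strictly positive", call. = FALSE)
  }
  y_psr <- psr(device, k, khl_num)
  kg <- kglob(k, khl_num)
  pars <- c(device, list(kg = kg, khl = khl_num, open = TRUE))
  state <- c(yl = 1, yh = 1, yc1 = 0)
  # log-spaced reporting grid; roots are located by the solver, the grid
  # only bounds the step size near the start
  grid <- function(from, to) {
    unique(c(from, from + 10^seq(log10(max(from * 1e-3, 1e-4)),
                                 log10(to - from), length.out = 300L), to))
  }
  run_to_root <- function(state, t0, t1, threshold) {
    times <- grid(t0, t1)
    sol <- deSolve::ode(y = state, times = times, func = model_rhs,
                        parms = pars, method = "lsodar",
                        rootfunc = function(t, y, p) y[2L] - threshold,
                        rtol = rtol, atol = atol)
    troot <- attr(sol, "troot")
    list(t = if (length(troot)) troot[1L] else NA_real_,
         state = unlist(as.data.frame(sol)[nrow(sol), -1L]))
  }
  arm_level <- 1.01 * y_psr
  t_arm <- 0
  st <- state
  if (st[["yh"]] > arm_level) {
    ph1 <- run_to_root(st, 0, horizon, arm_level)
    if (is.na(ph1$t)) {
      return(structure(list(lifetime = horizon, y_psr_used = y_psr,
                            method = "ode", censored = TRUE),
                       class = "lifetime_result"))
    }
    t_arm <- ph1$t
    st <- ph1$state
  }
  ph2 <- run_to_root(st, t_arm, horizon, 0.95 * y_psr)
  if (is.na(ph2$t)) {
    return(structure(list(lifetime = horizon, y_psr_used = y_psr,
                          method = "ode", censored = TRUE),
                     class = "lifetime_result"))
  }
  structure(list(lifetime = ph2$t, y_psr_used = y_psr,
                 method = "ode", censored = FALSE),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  lt <- x$lifetime
  human <- if (lt < 120) sprintf("%.3g s", lt)
    else if (lt < 7200) sprintf("%.3g min", lt / 60)
    else if (lt < 2 * 86400) sprintf("%.3g h", lt / 3600)
    else sprintf("%.3g days", lt / 86400)
  cat(sprintf("<lifetime_result> %s%s (method = %s, Y_h,psr = %.3g)\n",
              if (x$censored) ">= " else "", human, x$method, x$y_psr_used))
  invisible(x)
}

#' Source lifetime by the quasi-steady approximation
#'
#' When headspace equilibration is much faster than liquid depletion, the
#' headspace tracks `Y_h ~ Y_h,psr * Y_l` and the liquid decays
#' exponentially at rate
#' `lambda = (A * kglob * Khl / V_l) * (1 - Y_h,psr)`, so the 95% threshold
#' is crossed at `ln(1/0.95) / lambda`. Refuses to answer when the
#' timescale separation (depletion time over headspace equilibration time)
#' is below `min_separation`, where the approximation degrades.
#'
#' @inheritParams source_lifetime
#' @param min_separation Required ratio of depletion to equilibration
#'   timescales (default 100).
#' @return Lifetime in seconds.
#' @export
lifetime_quasi_steady <- function(device, k, khl, min_separation = 100) {
  stopifnot(inherits(device, "device_geometry"),
            inherits(k, "transfer_coefficients"))
  khl_num <- as_khl(khl)
  if (!is.finite(khl_num) || khl_num <= 0) {
    stop("'khl' must be strictly positive", call. = FALSE)
  }
  kg <- kglob(k, khl_num)
  y_psr <- psr(device, k, khl_num)
  lambda <- (device$area * kg * khl_num / device$v_l) * (1 - y_psr)
  tau_h <- device$v_h / (device$area * kg + device$q_s)
  sep <- 1 / (lambda * tau_h)
  if (sep < min_separation) {
    stop(sprintf(
      paste0("quasi-steady approximation invalid: depletion/equilibration ",
             "timescale ratio is %.3g (< %g); use source_lifetime()"),
      sep, min_separation), call. = FALSE)
  }
  log(1 / 0.95) / lambda
}

#' Sweep delivered plateau and lifetime over a design grid
#'
#' For each (diameter, airflow) cell, predicts the headspace transfer
#' coefficient from the Sherwood correlation, composes it with a fixed
#' liquid-side coefficient and partition coefficient into the
#' pseudo-stationary plateau, and computes the source lifetime. Compartment
#' volumes follow a geometric-similarity policy by default: headspace
#' volume `v_h_coef * d^3` and liquid volume `v_h / liquid_fraction_inv`.
#'
#' @param d_grid Source diameters, m.
#' @param q_grid Source airflows, m^3/s.
#' @param khl Partition coefficient of the probe compound.
#' @param k_l Liquid-side transfer coefficient, m/s.
#' @param v_h_coef Headspace volume coefficient: `v_h = v_h_coef * d^3`
#'   (default 0.8, covering 0.8 mL at d = 10 mm up to ~22 L at 300 mm).
#' @param liquid_fraction_inv `v_l = v_h / liquid_fraction_inv` (default 3).
#' @param q_c_ratio Carrier over source airflow (default 8).
#' @param method `"quasi_steady"` (fast, default) or `"ode"` for the
#'   lifetime; quasi-steady cells that fail the timescale check fall back
#'   to the ODE.
#' @param diffusion_d,air,regime,sc Passed to [kh_from_correlation()].
#' @return A tidy data frame `d_m, q_s_m3s, k_h, y_h_psr, lifetime_s`.
#' @export
design_sweep <- function(d_grid, q_grid, khl, k_l,
                         v_h_coef = 0.8, liquid_fraction_inv = 3,
                         q_c_ratio = 8,
                         method = c("quasi_steady", "ode"),
                         diffusion_d = NULL, air = air_properties(),
                         regime = "auto", sc = NULL) {
  method <- match.arg(method)
  stopifnot(all(d_grid > 0), all(q_grid > 0), khl > 0, k_l > 0)
  grid <- expand.grid(d_m = d_grid, q_s_m3s = q_grid,
                      KEEP.OUT.ATTRS = FALSE)
  one_cell <- function(d, q) {
    kh <- kh_from_correlation(q, d, diffusion_d, air, regime, sc)
    v_h <- v_h_coef * d^3
    dev <- device_geometry(d = d, v_l = v_h / liquid_fraction_inv,
                           v_h = v_h, v_c = v_h, q_s = q,
                           q_c = q * q_c_ratio)
    kk <- transfer_coefficients(k_h = kh, k_l = k_l)
    y <- psr(dev, kk, khl)
    lt <- if (method == "quasi_steady") {
      tryCatch(lifetime_quasi_steady(dev, kk, khl),
               error = function(e) source_lifetime(dev, kk, khl)$lifetime)
    } else {
      source_lifetime(dev, kk, khl)$lifetime
    }
    c(k_h = kh, y_h_psr = y, lifetime_s = lt)
  }
  res <- t(mapply(one_cell, grid$d_m, grid$q_s_m3s))
  cbind(grid, as.data.frame(res))
}
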