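#' Global two-film mass-transfer coefficient
#'
#' Transfer from bulk liquid to bulk headspace decomposes into a liquid-side
#' and a headspace-side resistance in series:
#' `1/kglob = 1/k_h + Khl/k_l`. For small `Khl` the headspace side dominates
#' (`kglob -> k_h`); for large `Khl` the coefficient becomes inversely
#' proportional to `Khl` (`kglob -> k_l/Khl`). The transition sits at
#' `Khl = k_l/k_h`.
#'
#' @param k A [transfer_coefficients()] object.
#' @param khl Dimensionless air-solvent partition coefficient (>= 0), or a
#'   [compound()]. Vectorised over numeric `khl`.
#' @return Global transfer coefficient, m/s.
#' @export
kglob <- function(k, khl) {
  stopifnot(inherits(k, "transfer_coefficients"))
  khl <- as_khl(khl)
  if (any(!is.finite(khl)) || any(khl < 0)) {
    stop("'khl' must be non-negative", call. = FALSE)
  }
  1 / (1 / k$k_h + khl / k$k_l)
}

#' Interfacial mass flux from liquid to headspace
#'
#' The flux is proportional to the deviation from Henry equilibrium:
#' `J = (Khl * c_l - c_h) * kg`. It vanishes exactly at equilibrium and is
#' positive when the headspace is depleted below it.
#'
#' @param c_l,c_h Liquid and headspace concentrations, mol/m^3 (>= 0).
#' @param khl Dimensionless partition coefficient or a [compound()].
#' @param kg Global transfer coefficient, m/s (see [kglob()]).
#' @return Flux in mol/(m^2 s); positive towards the headspace.
#' @export
flux_l_to_h <- function(c_l, c_h, khl, kg) {
  khl <- as_khl(khl)
  if (any(c_l < 0) || any(c_h < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  (khl * c_l - c_h) * kg
}

#' Headspace concentration at the dynamic pseudo-stationary regime
#'
#' While liquid depletion is negligible (`Y_l ~ 1`), dilution of the source
#' headspace by the airflow balances interfacial transfer at
#' `Y_h,psr = A / (A + Q_s/kglob)`, a fraction of the initial equilibrium
#' headspace concentration that depends only on source area, airflow and the
#' global transfer coefficient.
#'
#' @param device A [device_geometry()].
#' @param k A [transfer_coefficients()].
#' @param khl Dimensionless partition coefficient (>= 0), a [compound()],
#'   or a numeric vector.
#' @return Dimensionless plateau concentration(s) in `(0, 1]`.
#' @examples
#' dev <- reference_device()
#' k <- reference_transfer()
#' psr(dev, k, 1.14e-2)  # most volatile: ~0.04
#' psr(dev, k, 1e-5)     # low-volatility regime: ~0.3
#' @export
psr <- function(device, k, khl) {
  stopifnot(inherits(device, "device_geometry"))
  kg <- kglob(k, khl)
  device$area / (device$area + device$q_s / kg)
}

#' Dimensional delivered concentrations at pseudo-stationary regime
#'
#' @inheritParams psr
#' @param c_l0 Initial liquid concentration, mol/m^3 (>= 0).
#' @return A list with `c_h_psr` (source headspace, mol/m^3) and `c_c_psr`
#'   (transport-tube outlet, mol/m^3, i.e. after the `q_s/q_c` carrier
#'   dilution).
#' @export
delivered_plateau <- function(device, k, khl, c_l0) {
  khl_num <- as_khl(khl)
  if (any(c_l0 < 0)) stop("'c_l0' must be non-negative", call. = FALSE)
  y <- psr(device, k, khl)
  c_h_psr <- y * khl_num * c_l0
  list(c_h_psr = c_h_psr, c_c_psr = c_h_psr * device$q_s / device$q_c)
}

# Right-hand side of the dimensionless compartment model. Y_c is normalised
# by Ch0, so its open-valve plateau is Yh,psr * Q_s/Q_c. Transport tube may
# be chained into n well-mixed cells (state yc1..ycn), default 1.
model_rhs <- function(t, y, p) {
  yl <- y[1L]; yh <- y[2L]; yc <- y[-(1:2)]
  qs <- if (p$open) p$q_s else 0
  dyl <- -(p$area * p$kg * p$khl / p$v_l) * (yl - yh)
  dyh <- (p$area * p$kg / p$v_h) * (yl - yh) - qs / p$v_h * yh
  n <- length(yc)
  vcell <- p$v_c / n
  inflow <- c(qs * yh, p$q_c * yc[-n])
  dyc <- (inflow - p$q_c * yc) / vcell
  list(c(dyl, dyh, dyc))
}

#' Simulate the concentration time course in all compartments
#'
#' Integrates the dimensionless three-compartment system
#' \deqn{dY_l/dt = -(A k_g K_{hl}/V_l)(Y_l - Y_h)}
#' \deqn{dY_h/dt = (A k_g/V_h)(Y_l - Y_h) - (Q_s/V_h) Y_h}
#' \deqn{dY_c/dt = (Q_s/V_c) Y_h - (Q_c/V_c) Y_c}
#' with `Q_s = 0` while the valve is closed, from the equilibrated initial
#' state `Y_l = Y_h = 1, Y_c = 0`. Trajectories are dimensionless (fractions
#' of `Cl0` and `Ch0`) and therefore independent of the source loading.
#' Integration uses a stiff-capable adaptive solver and restarts at each
#' valve transition so the flow steps are exact.
#'
#' @inheritParams psr
#' @param protocol A [stimulus_protocol()] giving the valve schedule.
#' @param c_l0 Optional initial liquid concentration (mol/m^3) used only to
#'   attach dimensional scale factors to the result.
#' @param n_cells Number of well-mixed cells chained to represent the
#'   transport compartment (default 1; larger values emulate reduced axial
#'   mixing). The reported `y_c` is the last cell.
#' @param rtol,atol Solver tolerances.
#' @return A `"time_course"` object: sample grid `t` (s), trajectories
#'   `y_l`, `y_h`, `y_c`, valve state, scale factors `c_l0`, `c_h0`, and the
#'   device. Convert with [as.data.frame.time_course()].
#' @examples
#' tc <- simulate_device(reference_device(), reference_transfer(), 2.71e-5,
#'                       stimulus_protocol(c(5, 60), c(FALSE, TRUE)))
#' head(as.data.frame(tc))
#' @export
simulate_device <- function(device, k, khl, protocol,
                            c_l0 = NULL, n_cells = 1L,
                            rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(device, "device_geometry"),
            inherits(k, "transfer_coefficients"),
            inherits(protocol, "stimulus_protocol"))
  khl_num <- as_khl(khl)
  if (!is.finite(khl_num) || khl_num < 0) {
    stop("'khl' must be non-negative", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 1L)
  kg <- kglob(k, khl_num)
  pars <- c(device, list(kg = kg, khl = khl_num))

  state <- c(yl = 1, yh = 1, stats::setNames(rep(0, n_cells),
                                      paste0("yc", seq_len(n_cells))))
  t0 <- 0
  rows <- list()
  dt <- protocol$sampling_dt
  for (i in seq_along(protocol$durations)) {
    dur <- protocol$durations[i]
    pars$open <- protocol$valve_open[i]
    times <- unique(c(seq(0, dur, by = dt), dur))
    sol <- deSolve::ode(y = state, times = times, func = model_rhs,
                        parms = pars, method = "bdf",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf(
        "ODE solver failed (khl = %.3g, kg = %.3g, segment %d): try looser tolerances",
        khl_num, kg, i), call. = FALSE)
    }
    sol <- as.data.frame(sol)
    state <- unlist(sol[nrow(sol), -1L])
    sol$time <- sol$time + t0
    sol$open <- pars$open
    # drop the duplicated boundary sample except for the first segment
    if (i > 1L) sol <- sol[-1L, , drop = FALSE]
    rows[[i]] <- sol
    t0 <- t0 + dur
  }
  out <- do.call(rbind, rows)
  c_h0 <- if (is.null(c_l0)) NULL else khl_num * c_l0
  structure(
    list(t = out$time, y_l = out$yl, y_h = out$yh,
         y_c = out[[paste0("yc", n_cells)]],
         valve_open = out$open,
         c_l0 = c_l0, c_h0 = c_h0, khl = khl_num,
         device = device, protocol = protocol),
    class = "time_course"
  )
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %d samples over %.4g s (Khl = %.3g)\n",
              length(x$t), max(x$t), x$khl))
  cat(sprintf("  final: Y_l = %.4g, Y_h = %.4g, Y_c = %.4g\n",
              x$y_l[length(x$y_l)], x$y_h[length(x$y_h)],
              x$y_c[length(x$y_c)]))
  if (!is.null(x$c_h0)) {
    cat(sprintf("  scale: Cl0 = %.3g, Ch0 = %.3g mol/m^3\n", x$c_l0, x$c_h0))
  }
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  df <- data.frame(t_s = x$t, y_l = x$y_l, y_h = x$y_h, y_c = x$y_c,
                   valve_open = x$valve_open)
  if (!is.null(x$c_l0)) {
    df$c_l <- x$y_l * x$c_l0
    df$c_h <- x$y_h * x$c_h0
    df$c_c <- x$y_c * x$c_h0
  }
  df
}

#' Write a simulated time course to CSV
#'
#' @param tc A `"time_course"` from [simulate_device()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' Peak and plateau of a simulated stimulus
#'
#' Summarises the headspace (or outlet) trajectory over the first open-valve
#' segment: the initial peak (evacuation of the equilibrated headspace), the
#' plateau (mean over the last half of the segment) and their ratio. The
#' peak-to-plateau ratio grows with `Khl`: highly volatile compounds give a
#' peaked stimulus, low-volatility ones a near-square pulse.
#'
#' @param tc A `"time_course"` from [simulate_device()].
#' @param which Trajectory to summarise: `"y_h"` (source outlet, default)
#'   or `"y_c"` (transport-tube outlet).
#' @return A list with `peak`, `plateau` and `peak_to_plateau_ratio`.
#' @export
stimulus_shape_summary <- function(tc, which = c("y_h", "y_c")) {
  stopifnot(inherits(tc, "time_course"))
  which <- match.arg(which)
  idx <- which(tc$valve_open)
  if (!length(idx)) {
    stop("time course contains no open-valve segment", call. = FALSE)
  }
  # first contiguous open run
  brk <- which(diff(idx) > 1L)
  if (length(brk)) idx <- idx[seq_len(brk[1L])]
  if (length(idx) < 4L) {
    stop("open-valve segment has fewer than 4 samples", call. = FALSE)
  }
  y <- tc[[which]][idx]
  peak <- max(y)
  tail_idx <- idx[seq.int(ceiling(length(idx) / 2), length(idx))]
  plateau <- mean(tc[[which]][tail_idx])
  list(peak = peak, plateau = plateau,
       peak_to_plateau_ratio = peak / plateau)
}

#' The vial stimulator used in the package's worked examples
#'
#' A 4-mL vial of 13.2 mm inner diameter holding 1 mL of odorant solution
#' under 3 mL of headspace (measured interface area 1.38 cm^2), flushed at
#' 200 mL/min during stimulation, feeding a 200 mm x 9 mm glass tube
#' carrying 1600 mL/min total airflow (8 parallel lines).
#'
#' @return A [device_geometry()].
#' @export
reference_device <- function() {
  device_geometry(
    d = 13.2e-3, area = 1.38e-4,
    v_l = 1e-6, v_h = 3e-6,
    v_c = pi / 4 * 0.009^2 * 0.2,
    q_s = ml_min_to_m3_s(200), q_c = ml_min_to_m3_s(1600)
  )
}

#' Transfer coefficients calibrated for the reference device
#'
#' Point estimates (with 95% CIs) of the headspace- and liquid-side
#' transfer coefficients obtained by fitting plateau observations for a
#' panel of volatile plant compounds on the reference device.
#'
#' @return A [transfer_coefficients()].
#' @export
reference_transfer <- function() {
  transfer_coefficients(k_h = 1.15e-2, k_l = 1.24e-5,
                        ci_h = c(0.92e-2, 1.44e-2),
                        ci_l = c(0.66e-5, 2.36e-5))
}
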