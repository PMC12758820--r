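#' Geometry and airflows of an odor delivery device
#'
#' Describes a vial-based odor source (liquid and headspace compartments
#' separated by the liquid surface) connected to a transport tube. All
#' quantities in SI units; see [ml_to_m3()] and friends for bench units.
#'
#' @param d Source inner diameter, m.
#' @param v_l Liquid volume, m^3.
#' @param v_h Source headspace volume, m^3.
#' @param v_c Transport compartment (glass tube) volume, m^3.
#' @param q_s Airflow through the source during stimulation, m^3/s.
#' @param q_c Total carrier airflow through the transport tube, m^3/s
#'   (must be >= `q_s`).
#' @param area Air-liquid interface area, m^2. Defaults to the disc area
#'   `pi * d^2 / 4`; give it explicitly to match a measured value.
#' @return An object of class `"device_geometry"`.
#' @examples
#' dev <- device_geometry(d = 13.2e-3, v_l = 1e-6, v_h = 3e-6,
#'                        v_c = 12.7e-6, q_s = ml_min_to_m3_s(200),
#'                        q_c = ml_min_to_m3_s(1600), area = 1.38e-4)
#' dev
#' @export
device_geometry <- function(d, v_l, v_h, v_c, q_s, q_c, area = NULL) {
  if (is.null(area)) area <- pi * d^2 / 4
  vals <- c(d = d, area = area, v_l = v_l, v_h = v_h, v_c = v_c,
            q_s = q_s, q_c = q_c)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all device dimensions and airflows must be strictly positive",
         call. = FALSE)
  }
  if (q_c < q_s) {
    stop("carrier airflow 'q_c' must be at least the source airflow 'q_s'",
         call. = FALSE)
  }
  structure(as.list(vals), class = "device_geometry")
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("<device_geometry>\n")
  cat(sprintf("  d = %.3g mm, A = %.3g cm^2\n", x$d * 1e3, x$area * 1e4))
  cat(sprintf("  V_l = %.3g mL, V_h = %.3g mL, V_c = %.3g mL\n",
              x$v_l * 1e6, x$v_h * 1e6, x$v_c * 1e6))
  cat(sprintf("  Q_s = %.3g mL/min, Q_c = %.3g mL/min\n",
              x$q_s * 6e7, x$q_c * 6e7))
  invisible(x)
}

#' Two-film mass-transfer coefficients
#'
#' `k_h` is the transfer coefficient from interface to bulk headspace,
#' `k_l` from bulk liquid to the interface, both in m/s.
#'
#' @param k_h Headspace-side transfer coefficient, m/s.
#' @param k_l Liquid-side transfer coefficient, m/s.
#' @param ci_h,ci_l Optional length-2 `c(low, high)` 95% confidence
#'   intervals.
#' @return An object of class `"transfer_coefficients"`.
#' @export
transfer_coefficients <- function(k_h, k_l, ci_h = NULL, ci_l = NULL) {
  if (!is.finite(k_h) || k_h <= 0 || !is.finite(k_l) || k_l <= 0) {
    stop("'k_h' and 'k_l' must be strictly positive", call. = FALSE)
  }
  chk_ci <- function(ci, est, what) {
    if (is.null(ci)) return(NULL)
    ci <- as.numeric(ci)
    if (length(ci) != 2L || any(ci <= 0) || ci[1] > est || ci[2] < est) {
      stop(sprintf("'%s' must be c(low, high) bracketing the estimate", what),
           call. = FALSE)
    }
    ci
  }
  structure(list(k_h = k_h, k_l = k_l,
                 ci_h = chk_ci(ci_h, k_h, "ci_h"),
                 ci_l = chk_ci(ci_l, k_l, "ci_l")),
            class = "transfer_coefficients")
}

#' @export
print.transfer_coefficients <- function(x, ...) {
  fmt <- function(est, ci) {
    s <- sprintf("%.3g m/s", est)
    if (!is.null(ci)) s <- sprintf("%s (95%% CI %.3g-%.3g)", s, ci[1], ci[2])
    s
  }
  cat("<transfer_coefficients>\n")
  cat("  k_h:", fmt(x$k_h, x$ci_h), "\n")
  cat("  k_l:", fmt(x$k_l, x$ci_l), "\n")
  invisible(x)
}

#' Valve schedule of a stimulation protocol
#'
#' An ordered list of segments during which the source valve is open
#' (airflow `q_s` through the source) or closed (no airflow through the
#' source; the carrier flow keeps running).
#'
#' @param durations Segment durations in s (all > 0).
#' @param valve_open Logical vector, one entry per segment.
#' @param sampling_dt Output sampling interval in s.
#' @return An object of class `"stimulus_protocol"`.
#' @examples
#' stimulus_protocol(c(10, 60, 30), c(FALSE, TRUE, FALSE))
#' @export
stimulus_protocol <- function(durations, valve_open, sampling_dt = 0.1) {
  durations <- as.numeric(durations)
  valve_open <- as.logical(valve_open)
  if (length(durations) < 1L || length(durations) != length(valve_open)) {
    stop("need at least one segment; 'durations' and 'valve_open' must match",
         call. = FALSE)
  }
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("segment durations must be strictly positive", call. = FALSE)
  }
  if (!is.finite(sampling_dt) || sampling_dt <= 0) {
    stop("'sampling_dt' must be strictly positive", call. = FALSE)
  }
  structure(list(durations = durations, valve_open = valve_open,
                 sampling_dt = sampling_dt),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>\n")
  state <- ifelse(x$valve_open, "open", "closed")
  cat(sprintf("  %s for %g s\n", state, x$durations), sep = "")
  cat(sprintf("  sampling_dt = %g s\n", x$sampling_dt))
  invisible(x)
}

#' Read a device description from a YAML config file
#'
#' The file must contain a `device` section with bench-unit fields
#' `d_mm, v_l_ml, v_h_ml, v_c_ml, q_s_ml_min, q_c_ml_min` and optionally
#' `area_cm2`, and may contain a `transfer` section with `k_h` and `k_l`
#' (m/s). A fixture describing the 8-valve vial stimulator used in the
#' package's worked examples ships as `reference_device.yaml`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `device` ([device_geometry()]) and,
#'   when present in the file, `transfer` ([transfer_coefficients()]).
#' @examples
#' cfg <- read_device_config(odorcal_example("reference_device.yaml"))
#' cfg$device
#' @export
read_device_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$device)) {
    stop("config has no 'device' section", call. = FALSE)
  }
  dv <- cfg$device
  need <- c("d_mm", "v_l_ml", "v_h_ml", "v_c_ml", "q_s_ml_min", "q_c_ml_min")
  missing_f <- need[!vapply(need, function(f) !is.null(dv[[f]]), logical(1))]
  if (length(missing_f)) {
    stop("device config is missing field(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  device <- device_geometry(
    d = mm_to_m(dv$d_mm),
    v_l = ml_to_m3(dv$v_l_ml), v_h = ml_to_m3(dv$v_h_ml),
    v_c = ml_to_m3(dv$v_c_ml),
    q_s = ml_min_to_m3_s(dv$q_s_ml_min), q_c = ml_min_to_m3_s(dv$q_c_ml_min),
    area = if (!is.null(dv$area_cm2)) cm2_to_m2(dv$area_cm2) else NULL
  )
  out <- list(device = device)
  if (!is.null(cfg$transfer)) {
    tr <- cfg$transfer
    if (is.null(tr$k_h) || is.null(tr$k_l)) {
      stop("'transfer' section must give both 'k_h' and 'k_l'", call. = FALSE)
    }
    out$transfer <- transfer_coefficients(tr$k_h, tr$k_l)
  }
  out
}
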