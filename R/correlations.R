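#' Flow regime coefficients for the Sherwood correlation
#'
#' The Sherwood-number correlation `Sh = a * Re^b * Sc^0.33` takes fixed
#' coefficient pairs per regime: laminar (1.86, 0.33), intermediate
#' (0.664, 0.5) and turbulent (0.04, 0.75).
#'
#' @param name One of `"laminar"`, `"intermediate"`, `"turbulent"`.
#' @param a,b Optional overrides of the regime coefficients.
#' @return An object of class `"flow_regime"`.
#' @export
flow_regime <- function(name = c("laminar", "intermediate", "turbulent"),
                        a = NULL, b = NULL) {
  name <- match.arg(name)
  defaults <- list(laminar = c(1.86, 0.33),
                   intermediate = c(0.664, 0.5),
                   turbulent = c(0.04, 0.75))
  ab <- defaults[[name]]
  if (!is.null(a)) ab[1] <- a
  if (!is.null(b)) ab[2] <- b
  stopifnot(ab[1] > 0, ab[2] > 0)
  structure(list(name = name, a = ab[1], b = ab[2]), class = "flow_regime")
}

#' @export
print.flow_regime <- function(x, ...) {
  cat(sprintf("<flow_regime> %s (a = %g, b = %g)\n", x$name, x$a, x$b))
  invisible(x)
}

#' Reynolds number of the airflow through the source headspace
#'
#' Pipe-flow formula with the air speed expressed as airflow over pipe
#' cross-section: `Re = rho * 4 * Q_s / (mu * pi * d)`.
#'
#' @param q_s Airflow, m^3/s (>= 0).
#' @param d Source diameter, m (> 0).
#' @param air An [air_properties()].
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds(ml_min_to_m3_s(200), 13.2e-3)  # ~21: deeply laminar
#' @export
reynolds <- function(q_s, d, air = air_properties()) {
  stopifnot(inherits(air, "air_properties"))
  if (any(d <= 0)) stop("'d' must be strictly positive", call. = FALSE)
  if (any(q_s < 0)) stop("'q_s' must be non-negative", call. = FALSE)
  air$rho * 4 * q_s / (air$mu * pi * d)
}

#' Schmidt number of an odorant in air
#'
#' `Sc = mu / (rho * D)`: the ratio of momentum to mass diffusivity.
#'
#' @param diffusion_d Gas-phase diffusion coefficient, m^2/s (> 0).
#' @param air An [air_properties()].
#' @return Dimensionless Schmidt number.
#' @export
schmidt <- function(diffusion_d, air = air_properties()) {
  stopifnot(inherits(air, "air_properties"))
  if (any(diffusion_d <= 0)) {
    stop("'diffusion_d' must be strictly positive", call. = FALSE)
  }
  air$mu / (air$rho * diffusion_d)
}

# Default panel-average Schmidt number used when no per-compound diffusion
# coefficient is supplied (range over the panel: 1.23-2.75).
SC_PANEL_DEFAULT <- 1.9

# Standard pipe-flow bounds; a Re exactly at a threshold resolves to the
# lower regime.
select_regime <- function(re) {
  if (re <= 2100) flow_regime("laminar")
  else if (re <= 10000) flow_regime("intermediate")
  else flow_regime("turbulent")
}

#' Predict the headspace transfer coefficient from the Sherwood correlation
#'
#' `k_h = D * a * Re^b * Sc^0.33 / d`. When no diffusion coefficient is
#' given, the compound-panel averages are used (`D = 8.54e-6` m^2/s,
#' `Sc = 1.9`). The prediction is reliable for broad trends only; direct
#' calibration is required for quantitative work (narrow vial inlets raise
#' turbulence above the straight-pipe estimate).
#'
#' @param q_s Airflow through the source, m^3/s (>= 0; zero gives `k_h = 0`:
#'   no convective transfer).
#' @param d Source diameter, m.
#' @param diffusion_d Diffusion coefficient, m^2/s; default panel average.
#' @param air An [air_properties()].
#' @param regime A [flow_regime()], or `"auto"` to select from `Re`
#'   (laminar below 2100, intermediate to 10000, turbulent above).
#' @param sc Schmidt number override; defaults to `schmidt(diffusion_d)`
#'   when `diffusion_d` is supplied, else the panel average 1.9.
#' @return Predicted headspace transfer coefficient, m/s.
#' @examples
#' kh_from_correlation(ml_min_to_m3_s(200), 13.2e-3)  # ~4e-3 m/s (laminar)
#' @export
kh_from_correlation <- function(q_s, d, diffusion_d = NULL,
                                air = air_properties(), regime = "auto",
                                sc = NULL) {
  if (is.null(sc)) {
    sc <- if (is.null(diffusion_d)) SC_PANEL_DEFAULT
          else schmidt(diffusion_d, air)
  }
  if (is.null(diffusion_d)) diffusion_d <- 8.54e-6
  re <- reynolds(q_s, d, air)
  if (identical(regime, "auto")) {
    regime <- select_regime(re)
  }
  stopifnot(inherits(regime, "flow_regime"))
  diffusion_d * regime$a * re^regime$b * sc^0.33 / d
}

#' Pseudo-stationary concentration surface over a design grid
#'
#' Composes [kh_from_correlation()], [kglob()] and [psr()] over grids of
#' source diameter, airflow and partition coefficient, predicting how the
#' delivered plateau fraction varies with device design. Larger sources and
#' slower airflows raise the plateau and widen the `Khl` range over which it
#' is compound-independent.
#'
#' @param d_grid Source diameters, m.
#' @param q_grid Source airflows, m^3/s.
#' @param k_l Liquid-side transfer coefficient, m/s (assumed independent of
#'   geometry).
#' @param khl_grid Partition coefficients.
#' @param diffusion_d,air,regime,sc Passed to [kh_from_correlation()].
#' @return A data frame with columns `d_m, q_s_m3s, khl, k_h, y_h_psr`.
#' @export
predicted_psr_surface <- function(d_grid, q_grid, k_l, khl_grid,
                                  diffusion_d = NULL,
                                  air = air_properties(),
                                  regime = "auto", sc = NULL) {
  stopifnot(length(d_grid) >= 1, length(q_grid) >= 1, length(khl_grid) >= 1,
            all(d_grid > 0), all(q_grid > 0), all(khl_grid >= 0), k_l > 0)
  grid <- expand.grid(d_m = d_grid, q_s_m3s = q_grid, khl = khl_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$k_h <- mapply(function(d, q) {
    kh_from_correlation(q, d, diffusion_d, air, regime, sc)
  }, grid$d_m, grid$q_s_m3s)
  grid$y_h_psr <- mapply(function(d, q, khl, kh) {
    a <- pi * d^2 / 4
    kg <- 1 / (1 / kh + khl / k_l)
    a / (a + q / kg)
  }, grid$d_m, grid$q_s_m3s, grid$khl, grid$k_h)
  grid
}
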