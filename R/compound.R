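#' Define an odorant compound
#'
#' A compound is identified by its dimensionless air-solvent partition
#' coefficient `khl` (Henry volatility: equilibrium ratio of gas-phase to
#' liquid-phase molar concentration), optionally accompanied by the physical
#' constants needed for unit conversions and transport predictions.
#'
#' @param name Compound name.
#' @param khl Dimensionless air-solvent partition coefficient (> 0).
#' @param khl_ci Optional length-2 numeric `c(low, high)` 95% confidence
#'   interval for `khl`; must bracket `khl` and be strictly positive.
#' @param mw Molecular weight in g/mol (optional).
#' @param density Liquid density in g/mL (optional).
#' @param diffusion_d Gas-phase diffusion coefficient in m^2/s. Defaults to
#'   `8.54e-6`, the mean over a panel of common volatile plant compounds.
#'
#' @return An object of class `"compound"`.
#' @examples
#' z3ha <- compound("Z3HA", khl = 2.71e-5, mw = 142.2, density = 0.897)
#' z3ha
#' @export
compound <- function(name, khl, khl_ci = NULL, mw = NULL, density = NULL,
                     diffusion_d = 8.54e-6) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(khl) || length(khl) != 1L || !is.finite(khl) || khl <= 0) {
    stop("'khl' must be a single positive number", call. = FALSE)
  }
  if (!is.null(khl_ci)) {
    khl_ci <- as.numeric(khl_ci)
    if (length(khl_ci) != 2L || any(!is.finite(khl_ci)) || khl_ci[1] <= 0 ||
        khl_ci[1] > khl || khl_ci[2] < khl) {
      stop("'khl_ci' must be c(low, high) with 0 < low <= khl <= high",
           call. = FALSE)
    }
  }
  check_pos <- function(x, what) {
    if (!is.null(x)) {
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
        stop(sprintf("'%s' must be a single positive number", what),
             call. = FALSE)
      }
    }
    x
  }
  structure(
    list(name = name, khl = khl, khl_ci = khl_ci,
         mw = check_pos(mw, "mw"), density = check_pos(density, "density"),
         diffusion_d = check_pos(diffusion_d, "diffusion_d")),
    class = "compound"
  )
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s\n", x$name))
  cat(sprintf("  Khl: %.3g", x$khl))
  if (!is.null(x$khl_ci)) {
    cat(sprintf("  (95%% CI %.3g-%.3g)", x$khl_ci[1], x$khl_ci[2]))
  }
  cat("\n")
  if (!is.null(x$mw)) cat(sprintf("  MW: %.4g g/mol\n", x$mw))
  if (!is.null(x$density)) cat(sprintf("  density: %.4g g/mL\n", x$density))
  cat(sprintf("  D: %.3g m^2/s\n", x$diffusion_d))
  invisible(x)
}

#' Physical properties of the carrier air
#'
#' Defaults correspond to dry air at the operating temperature of 22 degC
#' and atmospheric pressure.
#'
#' @param rho Air density, kg/m^3.
#' @param mu Dynamic viscosity of air, kg/(m s).
#' @param temperature Temperature in K.
#' @param pressure Pressure in Pa.
#' @return An object of class `"air_properties"`.
#' @export
air_properties <- function(rho = 1.20, mu = 1.81e-5,
                           temperature = 295.15, pressure = 101325) {
  vals <- c(rho = rho, mu = mu, temperature = temperature, pressure = pressure)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all air properties must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "air_properties")
}

#' @export
print.air_properties <- function(x, ...) {
  cat(sprintf(
    "<air_properties> rho = %.3g kg/m^3, mu = %.3g kg/(m s), T = %.2f K, P = %.0f Pa\n",
    x$rho, x$mu, x$temperature, x$pressure))
  invisible(x)
}

#' Read a compound table from CSV
#'
#' Expects columns `name,khl,khl_lo,khl_hi,mw,density,diffusion_d`; optional
#' cells may be empty. A fixture with measured air-mineral oil partition
#' coefficients for a panel of 11 volatile plant compounds ships with the
#' package (see [odorcal_example()]).
#'
#' @param path Path to a CSV file.
#' @return A named list of [compound()] objects.
#' @examples
#' panel <- read_compound_table(odorcal_example("vpc_panel.csv"))
#' names(panel)
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "khl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("compound table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  get_opt <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- row[[col]]
    if (is.null(v) || is.na(v)) NULL else as.numeric(v)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    lo <- get_opt(row, "khl_lo")
    hi <- get_opt(row, "khl_hi")
    ci <- if (!is.null(lo) && !is.null(hi)) c(lo, hi) else NULL
    d <- get_opt(row, "diffusion_d")
    compound(row$name, khl = as.numeric(row$khl), khl_ci = ci,
             mw = get_opt(row, "mw"), density = get_opt(row, "density"),
             diffusion_d = if (is.null(d)) 8.54e-6 else d)
  })
  names(out) <- df$name
  out
}

#' Path to a packaged example file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
odorcal_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "odorcal"))
  } else {
    path <- system.file("extdata", file, package = "odorcal", mustWork = FALSE)
    if (!nzchar(path)) stop("no packaged example file '", file, "'", call. = FALSE)
    path
  }
}
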