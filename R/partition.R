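#' A phase-ratio-variation (PRV) headspace series
#'
#' The same odorant solution is dispatched in varying aliquots across
#' sealed vials; after equilibration the FID peak area of a headspace
#' injection varies with the phase ratio
#' `beta = (v_vial - v_liquid) / v_liquid` (headspace over liquid volume).
#'
#' @param v_liquid Liquid aliquot volumes, m^3 (0 < v_liquid < v_vial).
#' @param peak_area FID peak areas (> 0), arbitrary units.
#' @param v_vial Vial volume, m^3 (default 20 mL).
#' @return An object of class `"prv_series"`.
#' @export
prv_series <- function(v_liquid, peak_area, v_vial = 20e-6) {
  v_liquid <- as.numeric(v_liquid); peak_area <- as.numeric(peak_area)
  if (length(v_liquid) != length(peak_area)) {
    stop("'v_liquid' and 'peak_area' must have equal length", call. = FALSE)
  }
  if (any(v_liquid <= 0) || any(v_liquid >= v_vial)) {
    stop("liquid volumes must satisfy 0 < v_liquid < v_vial", call. = FALSE)
  }
  if (any(peak_area <= 0)) {
    stop("peak areas must be strictly positive", call. = FALSE)
  }
  beta <- (v_vial - v_liquid) / v_liquid
  if (length(unique(signif(beta, 10))) < 3L) {
    stop("need >= 3 distinct phase ratios", call. = FALSE)
  }
  structure(list(v_liquid = v_liquid, peak_area = peak_area,
                 v_vial = v_vial, beta = beta),
            class = "prv_series")
}

#' Read a PRV series CSV (`v_liquid_ul,peak_area`)
#'
#' @param path CSV path.
#' @param v_vial Vial volume, m^3 (default 20 mL).
#' @return A [prv_series()].
#' @export
read_prv_series <- function(path, v_vial = 20e-6) {
  df <- utils::read.csv(path)
  if (!all(c("v_liquid_ul", "peak_area") %in% names(df))) {
    stop("PRV CSV must have columns 'v_liquid_ul' and 'peak_area'",
         call. = FALSE)
  }
  prv_series(df$v_liquid_ul * 1e-9, df$peak_area, v_vial = v_vial)
}

#' Estimate a partition coefficient by phase ratio variation
#'
#' Fits the PRV response `area = p1 / (beta + 1/Khl)` by nonlinear least
#' squares with log-parametrised `(p1, Khl)`, giving a 95% confidence
#' interval symmetric on the log scale. At the optimum this is equivalent to
#' the classical linearised rule: `Khl` = slope/intercept of the regression
#' of `1/area` on `beta`. The method is calibration-free but only
#' identifies relatively volatile compounds (roughly `Khl > 1e-4`): below
#' that the response barely varies with the phase ratio and the interval
#' blows up, which is reported as a warning.
#'
#' @param series A [prv_series()].
#' @param conf_level Confidence level.
#' @return A list of class `"partition_fit"` with `khl`, `ci`, `method`,
#'   the nuisance gain `p1` and the linearised estimate `khl_linear`.
#' @examples
#' s <- gen_prv_series(khl_true = 1.14e-2, sigma = 0, seed = 1)
#' prv_fit(s)
#' @export
prv_fit <- function(series, conf_level = 0.95) {
  stopifnot(inherits(series, "prv_series"))
  beta <- series$beta; area <- series$peak_area
  if (max(beta) / min(beta) < 5) {
    warning("phase ratios span less than a factor of 5; ",
            "the PRV design is weak")
  }
  # Linearised OLS start (and diagnostic): 1/area = beta/p1 + 1/(p1*Khl)
  lin <- stats::lm(I(1 / area) ~ beta)
  slope <- unname(stats::coef(lin)[2L])
  intercept <- unname(stats::coef(lin)[1L])
  khl_lin <- if (intercept > 0 && slope > 0) slope / intercept else NA_real_
  lp1_0 <- if (slope > 0) -log(slope) else log(max(area) * max(beta))
  lk_starts <- unique(c(if (is.finite(khl_lin)) log(khl_lin),
                        log(c(1e-5, 1e-3, 1e-1, 10))))

  df <- data.frame(beta = beta, area = area)
  # p1 enters linearly, so for any lk the optimal lp1 has a closed form;
  # profiling gives both a consistent start and a fallback optimiser for
  # near-flat (weakly identified) series
  lp1_given <- function(lk) {
    g <- 1 / (beta + exp(-lk))
    log(sum(area * g) / sum(g^2))
  }
  prof_rss <- function(lk) {
    g <- exp(lp1_given(lk)) / (beta + exp(-lk))
    sum((area - g)^2)
  }
  fit <- NULL
  for (lk_0 in lk_starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(area ~ exp(lp1) / (beta + exp(-lk)), data = df,
                        start = list(lp1 = lp1_given(lk_0), lk = lk_0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) ||
         sum(stats::residuals(cand)^2) < sum(stats::residuals(fit)^2))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    opt <- stats::optimize(prof_rss, lower = log(1e-9), upper = log(1e4))
    fit <- tryCatch(
      minpack.lm::nlsLM(area ~ exp(lp1) / (beta + exp(-lk)), data = df,
                        start = list(lp1 = lp1_given(opt$minimum),
                                     lk = opt$minimum),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2,
                  df = length(area) - 2L)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    lk_hat <- cf[["lk"]]
    lp1_hat <- cf[["lp1"]]
    se_lk <- tryCatch(summary(fit)$coefficients["lk", "Std. Error"],
                      error = function(e) NA_real_)
  } else {
    # degenerate (near-flat) series: report the profiled optimum with a
    # standard error from the numerical curvature of the profile RSS
    opt <- stats::optimize(prof_rss, lower = log(1e-9), upper = log(1e4))
    lk_hat <- opt$minimum
    lp1_hat <- lp1_given(lk_hat)
    h <- 1e-3
    curv <- (prof_rss(lk_hat + h) - 2 * opt$objective +
               prof_rss(lk_hat - h)) / h^2
    sigma2 <- opt$objective / (length(area) - 2L)
    se_lk <- if (is.finite(curv) && curv > 0) sqrt(2 * sigma2 / curv)
             else NA_real_
  }
  khl_hat <- exp(lk_hat)
  ci <- if (is.finite(se_lk)) {
    exp(lk_hat + c(-1, 1) * tq * se_lk)
  } else {
    c(NA_real_, NA_real_)
  }
  if (any(!is.finite(ci)) || ci[2] / ci[1] > 100) {
    warning("Khl is poorly identified by this PRV series ",
            "(confidence interval spans more than 2 orders of magnitude); ",
            "consider the liquid calibration method")
  }
  structure(list(khl = unname(khl_hat), ci = unname(ci),
                 p1 = exp(unname(lp1_hat)), khl_linear = khl_lin,
                 conf_level = conf_level, method = "prv", fit = fit),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("<partition_fit> method = %s\n", x$method))
  cat(sprintf("  Khl = %.3g (%.0f%% CI %.3g-%.3g)\n",
              x$khl, 100 * x$conf_level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' A liquid-calibration (LC) measurement series
#'
#' @param fid_calibration Data frame with columns `amount_injected` (mol)
#'   and `peak_area`, from direct liquid injections of known amounts.
#' @param headspace_obs Data frame with columns `c_liquid` (mol/m^3),
#'   `peak_area` and optionally `series_id` (measurement series label).
#' @param v_injection Headspace volume injected on the GC, m^3 (default
#'   2 mL).
#' @return An object of class `"lc_series"`.
#' @export
lc_series <- function(fid_calibration, headspace_obs, v_injection = 2e-6) {
  need_cal <- c("amount_injected", "peak_area")
  need_obs <- c("c_liquid", "peak_area")
  if (!all(need_cal %in% names(fid_calibration))) {
    stop("'fid_calibration' needs columns: ",
         paste(need_cal, collapse = ", "), call. = FALSE)
  }
  if (!all(need_obs %in% names(headspace_obs))) {
    stop("'headspace_obs' needs columns: ",
         paste(need_obs, collapse = ", "), call. = FALSE)
  }
  if (nrow(fid_calibration) < 2L) {
    stop("need >= 2 FID calibration points", call. = FALSE)
  }
  if (length(unique(headspace_obs$c_liquid)) < 2L) {
    stop("need >= 2 distinct liquid concentrations", call. = FALSE)
  }
  if (any(fid_calibration$amount_injected <= 0) ||
      any(fid_calibration$peak_area <= 0) ||
      any(headspace_obs$c_liquid <= 0) || any(headspace_obs$peak_area <= 0)) {
    stop("amounts, concentrations and areas must be strictly positive",
         call. = FALSE)
  }
  if (is.null(headspace_obs$series_id)) headspace_obs$series_id <- 1L
  structure(list(fid_calibration = fid_calibration,
                 headspace_obs = headspace_obs,
                 v_injection = v_injection),
            class = "lc_series")
}

#' Estimate a partition coefficient by liquid calibration
#'
#' Used when PRV fails (`Khl` below ~1e-4). (i) The FID is calibrated by
#' linear regression on log-transformed amount and area; (ii) headspace
#' peak areas are converted to headspace concentrations through the
#' inverted calibration and the injected headspace volume; (iii) `Khl` is
#' the slope of the zero-intercept regression of headspace on liquid
#' concentration. With several independent series, the pooled slope is
#' reported with a cluster-robust standard error (series as clusters).
#'
#' @param series An [lc_series()].
#' @param conf_level Confidence level.
#' @return A list of class `"partition_fit"` with `khl`, `ci`, the FID
#'   calibration fit, and the per-observation headspace concentrations.
#' @examples
#' s <- gen_lc_series(khl_true = 2.71e-5, sigma = 0, seed = 1)
#' lc_fit(s)
#' @export
lc_fit <- function(series, conf_level = 0.95) {
  stopifnot(inherits(series, "lc_series"))
  cal <- series$fid_calibration
  obs <- series$headspace_obs
  cal_fit <- stats::lm(log(peak_area) ~ log(amount_injected), data = cal)
  a0 <- unname(stats::coef(cal_fit)[1L])
  a1 <- unname(stats::coef(cal_fit)[2L])
  amount <- exp((log(obs$peak_area) - a0) / a1)
  rng <- range(cal$peak_area)
  if (any(obs$peak_area < rng[1L] / 10) || any(obs$peak_area > rng[2L] * 10)) {
    warning("headspace responses fall more than 10x outside the FID ",
            "calibration range; extrapolating")
  }
  c_head <- amount / series$v_injection
  slope_fit <- stats::lm(c_head ~ 0 + c_liquid,
                         data = data.frame(c_head = c_head,
                                           c_liquid = obs$c_liquid))
  khl_hat <- unname(stats::coef(slope_fit)[1L])
  if (!is.finite(khl_hat) || khl_hat <= 0) {
    stop("liquid calibration produced a non-positive slope: ",
         "check the input series", call. = FALSE)
  }
  n_series <- length(unique(obs$series_id))
  # suppressWarnings: summary.lm warns on numerically perfect fits
  vc <- suppressWarnings(
    if (n_series > 1L) {
      sandwich::vcovCL(slope_fit, cluster = obs$series_id)
    } else {
      stats::vcov(slope_fit)
    })
  se <- sqrt(vc[1L, 1L])
  dfree <- if (n_series > 1L) n_series - 1L else nrow(obs) - 1L
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = dfree)
  ci <- khl_hat + c(-1, 1) * tq * se
  structure(list(khl = khl_hat, ci = ci, conf_level = conf_level,
                 method = "lc", calibration = cal_fit,
                 c_headspace = c_head, fit = slope_fit),
            class = "partition_fit")
}

#' Read the two CSVs of a liquid-calibration series
#'
#' Calibration CSV: `amount_ng,peak_area`; headspace CSV:
#' `c_liquid_mol_m3,peak_area,series_id` (series_id optional).
#'
#' @param calibration_path,headspace_path CSV paths.
#' @param mw Molecular weight, g/mol (to convert ng to mol).
#' @param v_injection Injected headspace volume, m^3.
#' @return An [lc_series()].
#' @export
read_lc_series <- function(calibration_path, headspace_path, mw,
                           v_injection = 2e-6) {
  cal <- utils::read.csv(calibration_path)
  if (!all(c("amount_ng", "peak_area") %in% names(cal))) {
    stop("calibration CSV must have columns 'amount_ng' and 'peak_area'",
         call. = FALSE)
  }
  obs <- utils::read.csv(headspace_path)
  if (!all(c("c_liquid_mol_m3", "peak_area") %in% names(obs))) {
    stop("headspace CSV must have columns 'c_liquid_mol_m3' and 'peak_area'",
         call. = FALSE)
  }
  lc_series(
    fid_calibration = data.frame(
      amount_injected = cal$amount_ng * 1e-9 / mw,
      peak_area = cal$peak_area),
    headspace_obs = data.frame(
      c_liquid = obs$c_liquid_mol_m3, peak_area = obs$peak_area,
      series_id = if ("series_id" %in% names(obs)) obs$series_id else 1L),
    v_injection = v_injection
  )
}
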