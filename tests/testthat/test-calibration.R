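make_step_trace <- function(baseline = 0.1, height = 1.3,
                            t_open = 40, t_close = 100, t_end = 120,
                            dt = 0.1, tau = 0) {
  t <- seq(0, t_end, by = dt)
  sig <- rep(baseline, length(t))
  open <- t >= t_open & t <= t_close
  if (tau == 0) {
    sig[open] <- baseline + height
  } else {
    sig[open] <- baseline + height * (1 - exp(-(t[open] - t_open) / tau))
  }
  pid_trace(t, sig, t_open, t_close)
}

test_that("plateau extraction subtracts the pre-opening baseline", {
  flat <- pid_trace(seq(0, 120, 0.1), rep(0.7, 1201), 40, 100)
  expect_equal(extract_plateau(flat), 0)
  step <- make_step_trace(height = 1.3)
  expect_equal(extract_plateau(step), 1.3)
  # exponential approach, tau = 2 s: the 30-s tail mean sits within 0.1%
  expo <- make_step_trace(height = 2.0, tau = 2)
  expect_equal(extract_plateau(expo), 2.0, tolerance = 1e-3)
})

test_that("short records shrink the averaging windows with a warning", {
  short <- make_step_trace(t_open = 10, t_close = 100)  # only 10 s baseline
  expect_warning(v <- extract_plateau(short), "baseline window")
  expect_equal(v, 1.3, tolerance = 1e-6)
  brief <- make_step_trace(t_open = 40, t_close = 60)   # 20 s open
  expect_warning(v2 <- extract_plateau(brief), "plateau window")
  expect_equal(v2, 1.3, tolerance = 1e-6)
})

test_that("PID calibration inverts a power-law detector", {
  conc <- 10^seq(-6, -3, length.out = 4)
  resp <- 0.8 * conc^0.9          # nonlinear detector
  curve <- pid_calibration_curve(conc, resp)
  # noise-free round trip at and between the calibration points
  expect_equal(apply_pid_calibration(resp, curve), conc, tolerance = 1e-6)
  mid <- 0.8 * (3e-5)^0.9
  expect_equal(apply_pid_calibration(mid, curve), 3e-5, tolerance = 1e-6)
  expect_warning(apply_pid_calibration(max(resp) * 100, curve),
                 "extrapolat")
  expect_error(apply_pid_calibration(-1, curve), "positive")
  expect_error(pid_calibration_curve(c(1e-5, 2e-5), c(1, 2)),
               "order of magnitude")
})

test_that("flow correction applies only at the source outlet", {
  expect_equal(flow_correction(1.0, "source_outlet"), 3.75)
  expect_equal(flow_correction(1.0, "glass_tube_outlet"), 1.0)
  expect_equal(flow_correction(1.0, "teflon_outlet"), 1.0)
  expect_equal(flow_correction(0, "source_outlet"), 0)
  expect_error(flow_correction(1.0, "antenna"), "arg")
})

test_that("dimensionless conversion divides by the equilibrium headspace", {
  expect_equal(to_dimensionless(0, 2), 0)
  expect_equal(to_dimensionless(1.7, 1.7), 1)
  expect_equal(to_dimensionless(1, 0.5), 2 * to_dimensionless(1, 1))
  expect_error(to_dimensionless(1, 0), "positive")
})

test_that("transfer-coefficient fit recovers generating values exactly at zero noise", {
  khl_grid <- unname(panel_khl_obs)
  for (k_true in list(ref_k,
                      transfer_coefficients(3e-3, 1e-4),
                      transfer_coefficients(5e-2, 2e-6))) {
    obs <- gen_plateau_observations(k_true, ref_dev, khl_grid,
                                    sigma = 0, seed = 11)
    fit <- fit_transfer_coefficients(obs, ref_dev)
    expect_equal(fit$k_h, k_true$k_h, tolerance = 1e-6)
    expect_equal(fit$k_l, k_true$k_l, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
  # the relative-error variance model leaves noise-free recovery exact
  obs <- gen_plateau_observations(ref_k, ref_dev, khl_grid,
                                  sigma = 0, seed = 11)
  fit_w <- fit_transfer_coefficients(obs, ref_dev, variance = "relative")
  expect_equal(fit_w$k_h, ref_k$k_h, tolerance = 1e-6)
  expect_equal(fit_w$k_l, ref_k$k_l, tolerance = 1e-6)
})

test_that("confidence intervals are symmetric on the log scale", {
  obs <- gen_plateau_observations(ref_k, ref_dev, unname(panel_khl_obs),
                                  sigma = 0.05, seed = 42)
  fit <- fit_transfer_coefficients(obs, ref_dev)
  expect_equal(fit$ci_h[1] * fit$ci_h[2], fit$k_h^2, tolerance = 1e-9)
  expect_equal(fit$ci_l[1] * fit$ci_l[2], fit$k_l^2, tolerance = 1e-9)
  expect_true(fit$ci_h[1] < fit$k_h && fit$k_h < fit$ci_h[2])
})

test_that("underdetermined or degenerate designs are refused or flagged", {
  one <- plateau_observations("x", 1e-4, 0.3)
  expect_error(fit_transfer_coefficients(one, ref_dev), "identifiability")
  # all khl far below the transition: k_l cannot be identified
  low <- gen_plateau_observations(ref_k, ref_dev,
                                  10^seq(-8, -6, length.out = 6),
                                  sigma = 0, seed = 3)
  expect_warning(fit_transfer_coefficients(low, ref_dev),
                 "poorly identified")
})

test_that("fitted coefficients are invariant to consistent unit rescaling", {
  # expressing A and Q_s in another length/volume unit (both scaled by c)
  # must leave the back-transformed k_h, k_l unchanged
  obs <- gen_plateau_observations(ref_k, ref_dev, unname(panel_khl_obs),
                                  sigma = 0.03, seed = 7)
  scaled <- ref_dev
  scaled$area <- ref_dev$area * 1e4   # cm^2
  scaled$q_s <- ref_dev$q_s * 1e4
  fit_si <- fit_transfer_coefficients(obs, ref_dev)
  fit_sc <- fit_transfer_coefficients(obs, scaled)
  expect_equal(fit_sc$k_h, fit_si$k_h, tolerance = 1e-6)
  expect_equal(fit_sc$k_l, fit_si$k_l, tolerance = 1e-6)
})

test_that("CI width shrinks roughly as 1/sqrt(n) with replication", {
  # average the log-width over seeds: a single n = 9 fit estimates its own
  # residual scale too noisily for a sharp ratio check
  mean_width <- function(rep_factor) {
    mean(vapply(1:8, function(s) {
      khl <- rep(unname(panel_khl_obs), rep_factor)
      obs <- gen_plateau_observations(ref_k, ref_dev, khl,
                                      sigma = 0.05, seed = 100 * rep_factor + s)
      fit <- fit_transfer_coefficients(obs, ref_dev, n_starts = 1L)
      log(fit$ci_h[2] / fit$ci_h[1])
    }, numeric(1)))
  }
  widths <- vapply(c(1L, 4L, 16L), mean_width, numeric(1))
  expect_true(all(diff(widths) < 0))
  # quadrupling n should roughly halve the width
  expect_equal(widths[2] / widths[1], 0.5, tolerance = 0.25)
  expect_equal(widths[3] / widths[2], 0.5, tolerance = 0.25)
})

test_that("fit predictions reproduce the psr curve", {
  obs <- gen_plateau_observations(ref_k, ref_dev, unname(panel_khl_obs),
                                  sigma = 0, seed = 5)
  fit <- fit_transfer_coefficients(obs, ref_dev)
  khl_grid <- 10^seq(-7, -2, length.out = 20)
  expect_equal(predict(fit, khl_grid), psr(ref_dev, ref_k, khl_grid),
               tolerance = 1e-6)
})
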