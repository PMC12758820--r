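test_that("kglob composes the two film resistances", {
  expect_equal(kglob(ref_k, 0), ref_k$k_h)
  # isoprene: 1 / (1/1.15e-2 + 1.14e-2/1.24e-5)
  expect_equal(kglob(ref_k, 1.14e-2), 9.937e-4, tolerance = 1e-3)
  # large-Khl asymptote: kglob ~ k_l/Khl
  big <- 1e3
  expect_equal(kglob(ref_k, big) * big, ref_k$k_l, tolerance = 1e-4)
  # monotone non-increasing in khl
  grid <- 10^seq(-8, 0, length.out = 30)
  expect_true(all(diff(kglob(ref_k, grid)) < 0))
})

test_that("interfacial flux vanishes at equilibrium and is linear in kg", {
  expect_equal(flux_l_to_h(2, 2 * 3e-5, khl = 3e-5, kg = 1e-3), 0)
  expect_gt(flux_l_to_h(2, 1e-6, khl = 3e-5, kg = 1e-3), 0)
  expect_equal(flux_l_to_h(2, 1e-6, khl = 3e-5, kg = 2e-3),
               2 * flux_l_to_h(2, 1e-6, khl = 3e-5, kg = 1e-3))
})

test_that("closed valve at equilibrium is a fixed point", {
  proto <- stimulus_protocol(100, FALSE, sampling_dt = 1)
  tc <- simulate_device(ref_dev, ref_k, 1e-3, proto)
  expect_equal(tc$y_l, rep(1, length(tc$t)), tolerance = 1e-9)
  expect_equal(tc$y_h, rep(1, length(tc$t)), tolerance = 1e-9)
  expect_equal(tc$y_c, rep(0, length(tc$t)), tolerance = 1e-12)
})

test_that("closed system conserves mass to 1e-9 after an off-equilibrium start", {
  # deplete the headspace with a 10-s puff, then close for 1e4 s
  proto <- stimulus_protocol(c(10, 1e4), c(TRUE, FALSE), sampling_dt = 10)
  khl <- 1e-3
  tc <- simulate_device(ref_dev, ref_k, khl, proto)
  closed <- !tc$valve_open
  # total moles (per Cl0): V_l*Y_l + V_h*Khl*Y_h
  total <- ref_dev$v_l * tc$y_l[closed] + ref_dev$v_h * khl * tc$y_h[closed]
  expect_lt(max(abs(total - total[1])) / total[1], 1e-9)
  # and the headspace relaxes back towards equilibrium with the liquid
  expect_lt(abs(tc$y_h[length(tc$t)] - tc$y_l[length(tc$t)]), 1e-4)
})

test_that("open-valve plateau matches the pseudo-stationary closed form", {
  for (khl in c(1.92e-7, 1e-5, 6.25e-4)) {
    tc <- simulate_device(ref_dev, ref_k, khl,
                          stimulus_protocol(60, TRUE, sampling_dt = 0.05))
    n <- length(tc$t)
    # liquid depletion scales the quasi-plateau by Y_l; where depletion over
    # the window is negligible the raw closed form holds directly
    expect_equal(tc$y_h[n], psr(ref_dev, ref_k, khl) * tc$y_l[n],
                 tolerance = 1e-2)
    if (1 - tc$y_l[n] < 1e-3) {
      expect_equal(tc$y_h[n], psr(ref_dev, ref_k, khl), tolerance = 1e-2)
    }
  }
})

test_that("headspace dynamics follow the frozen-liquid closed form", {
  # with Y_l ~ 1, Y_h(t) = Ypsr + (1 - Ypsr) exp(-(A kg + Qs) t / V_h)
  for (khl in c(1e-7, 1e-6, 1e-5)) {
    kg <- kglob(ref_k, khl)
    tau <- ref_dev$v_h / (ref_dev$area * kg + ref_dev$q_s)
    y_psr <- psr(ref_dev, ref_k, khl)
    tc <- simulate_device(ref_dev, ref_k, khl,
                          stimulus_protocol(5 * tau, TRUE,
                                            sampling_dt = tau / 20))
    expected <- y_psr + (1 - y_psr) * exp(-tc$t / tau)
    expect_lt(max(abs(tc$y_h - expected) / expected), 1e-3)
  }
})

test_that("tube plateau is the headspace plateau diluted by Qs/Qc", {
  tc <- simulate_device(ref_dev, ref_k, 1e-5,
                        stimulus_protocol(120, TRUE, sampling_dt = 0.1))
  n <- length(tc$t)
  expect_equal(tc$y_c[n], tc$y_h[n] * ref_dev$q_s / ref_dev$q_c,
               tolerance = 1e-2)
})

test_that("dimensionless trajectories do not depend on the source loading", {
  proto <- stimulus_protocol(c(5, 30), c(FALSE, TRUE), sampling_dt = 0.1)
  a <- simulate_device(ref_dev, ref_k, 2.71e-5, proto, c_l0 = 6.31)
  b <- simulate_device(ref_dev, ref_k, 2.71e-5, proto, c_l0 = 631)
  expect_identical(a$y_h, b$y_h)
  expect_identical(a$y_c, b$y_c)
  # dimensional outputs scale exactly with the loading
  expect_equal(as.data.frame(b)$c_h, 100 * as.data.frame(a)$c_h)
})

test_that("trajectories stay in [0, 1] and the liquid never regains mass while open", {
  tc <- simulate_device(ref_dev, ref_k, 6.98e-3,
                        stimulus_protocol(120, TRUE, sampling_dt = 0.1))
  eps <- 1e-9
  for (y in list(tc$y_l, tc$y_h, tc$y_c)) {
    expect_true(all(y >= -eps & y <= 1 + eps))
  }
  expect_true(all(diff(tc$y_l) <= eps))
})

test_that("psr is monotone in khl, area and airflow", {
  khl_grid <- 10^seq(-8, -1, length.out = 25)
  expect_true(all(diff(psr(ref_dev, ref_k, khl_grid)) < 0))
  areas <- seq(0.5, 4, length.out = 10) * ref_dev$area
  y_a <- vapply(areas, function(a) {
    d <- ref_dev; d$area <- a
    psr(d, ref_k, 1e-4)
  }, numeric(1))
  expect_true(all(diff(y_a) > 0))
  flows <- seq(0.25, 4, length.out = 10) * ref_dev$q_s
  y_q <- vapply(flows, function(q) {
    d <- ref_dev; d$q_s <- q
    psr(d, ref_k, 1e-4)
  }, numeric(1))
  expect_true(all(diff(y_q) < 0))
  expect_true(all(psr(ref_dev, ref_k, khl_grid) > 0 &
                    psr(ref_dev, ref_k, khl_grid) <= 1))
})

test_that("delivered plateau applies Henry, psr and carrier dilution in order", {
  out <- delivered_plateau(ref_dev, ref_k, z3ha_compound, c_l0 = 6.31)
  expect_equal(out$c_h_psr,
               psr(ref_dev, ref_k, 2.71e-5) * 2.71e-5 * 6.31)
  # this device runs an 8-fold carrier dilution
  expect_equal(out$c_c_psr, out$c_h_psr / 8)
  zero <- delivered_plateau(ref_dev, ref_k, z3ha_compound, c_l0 = 0)
  expect_equal(unlist(zero), c(c_h_psr = 0, c_c_psr = 0))
})

test_that("stimulus shape is peaked for volatile compounds, square for heavy ones", {
  proto <- stimulus_protocol(c(2, 60), c(FALSE, TRUE), sampling_dt = 0.02)
  shape_iso <- stimulus_shape_summary(
    simulate_device(ref_dev, ref_k, panel_khl[["isoprene"]], proto))
  shape_lin <- stimulus_shape_summary(
    simulate_device(ref_dev, ref_k, panel_khl[["linalool"]], proto))
  expect_gt(shape_iso$peak_to_plateau_ratio, shape_lin$peak_to_plateau_ratio)
  expect_gte(shape_lin$peak_to_plateau_ratio, 1)
  # low-khl: ratio approaches 1/Y_h,psr ~ 3.2
  expect_equal(shape_lin$peak_to_plateau_ratio,
               1 / psr(ref_dev, ref_k, panel_khl[["linalool"]]),
               tolerance = 0.05)
  closed_only <- simulate_device(ref_dev, ref_k, 1e-4,
                                 stimulus_protocol(10, FALSE))
  expect_error(stimulus_shape_summary(closed_only), "open")
})

test_that("device and protocol validation rejects inconsistent inputs", {
  expect_error(device_geometry(d = 0.01, v_l = 1e-6, v_h = 3e-6, v_c = 1e-5,
                               q_s = 2e-6, q_c = 1e-6), "q_c")
  expect_error(device_geometry(d = -0.01, v_l = 1e-6, v_h = 3e-6, v_c = 1e-5,
                               q_s = 1e-6, q_c = 1e-5), "positive")
  expect_error(stimulus_protocol(numeric(0), logical(0)), "segment")
  expect_error(stimulus_protocol(c(10, -5), c(TRUE, FALSE)), "positive")
  # default area is the disc of diameter d
  d <- device_geometry(d = 13.2e-3, v_l = 1e-6, v_h = 3e-6, v_c = 1e-5,
                       q_s = 1e-6, q_c = 1e-5)
  expect_equal(d$area, pi * 13.2e-3^2 / 4)
  expect_equal(d$area, 1.368e-4, tolerance = 1e-3)
})

test_that("device config round-trips through YAML", {
  cfg <- read_device_config(odorcal_example("reference_device.yaml"))
  expect_equal(cfg$device$area, 1.38e-4)
  expect_equal(cfg$device$q_s, ml_min_to_m3_s(200))
  expect_equal(cfg$device$q_c / cfg$device$q_s, 8)
  expect_equal(cfg$transfer$k_h, 1.15e-2)
  expect_equal(cfg$transfer$k_l, 1.24e-5)
  bad <- tempfile(fileext = ".yaml")
  writeLines("device:\n  d_mm: 13.2\n  v_l_ml: 1", bad)
  expect_error(read_device_config(bad), "v_h_ml")
})

test_that("a chained transport compartment keeps the same plateau", {
  proto <- stimulus_protocol(120, TRUE, sampling_dt = 0.1)
  one <- simulate_device(ref_dev, ref_k, 1e-5, proto, n_cells = 1L)
  five <- simulate_device(ref_dev, ref_k, 1e-5, proto, n_cells = 5L)
  n <- length(one$t)
  expect_equal(five$y_c[n], one$y_c[n], tolerance = 1e-3)
  # more cells sharpen the front: well before one tube residence time
  # (V_c/Q_c ~ 0.5 s) the 5-cell outlet lags the single-cell one
  i_early <- which(one$t >= 0.1)[1L]
  expect_lt(five$y_c[i_early], one$y_c[i_early])
})
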