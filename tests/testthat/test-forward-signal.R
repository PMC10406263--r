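test_that("frequency shift matches scalar arithmetic for both agents", {
  expect_equal(frequency_shift(1, 0, 0), 0)
  expect_equal(frequency_shift(0.6, 0, 0), 33.9183433, tolerance = 1e-6)
  expect_equal(frequency_shift(1, 0, 1), 20.8777681, tolerance = 1e-6)
  # hyperoxic overshoot clips to zero with a warning
  expect_warning(fs <- frequency_shift(0.98, 0.05, 0), "clipped")
  expect_equal(fs, 0)
})

test_that("extravascular relaxation sums pcbv-weighted coefficients", {
  cap <- voxel_model(tibble::tibble(kind = "capillary", pcbv = 1,
                                    y0 = 0.775,
                                    vessel_class = "capillary_5um"), "GM")
  expect_equal(ees_relaxation(cap, 19.08), 0.738396, tolerance = 1e-6)
  expect_equal(ees_relaxation(cap, 0), 0)
  # doubling every pcbv doubles the rate
  vox <- voxel_tissue(4, "GM")
  vox2 <- voxel_tissue(8, "GM")
  shifts <- frequency_shift(vox$y0, -0.1, 0)
  expect_equal(ees_relaxation(vox2, shifts), 2 * ees_relaxation(vox, shifts),
               tolerance = 1e-12)
  expect_error(ees_relaxation(vox, c(1, 2)), "per compartment")
})

test_that("intravascular relaxation is quadratic in effective deoxygenation", {
  expect_equal(ivs_relaxation(1, 0, 0), 0)
  expect_equal(ivs_relaxation(0.6, 0, 0), 28.96, tolerance = 1e-9)
  expect_equal(ivs_relaxation(0.98, -0.23, 0), 11.3125, tolerance = 1e-9)
  # gadolinium enters through the pseudo-oxygenation equivalent
  expect_equal(ivs_relaxation(1, 0, 1),
               181 * (0.026 / (0.264 * 0.4))^2, tolerance = 1e-9)
})

test_that("voxel signal combines one EES and per-compartment IVS exponentials", {
  expect_equal(voxel_signal(voxel_arterial(100, y0 = 1)), 0.6610010,
               tolerance = 1e-6)
  expect_equal(voxel_signal(voxel_csf()), 0.5327516, tolerance = 1e-6)
  # baseline signal ordering: artery above vein (baseline deoxygenation)
  expect_gt(voxel_signal(voxel_arterial()), voxel_signal(voxel_venous()))
  # adding contrast never increases signal
  vox <- voxel_tissue(4, "GM")
  s0 <- voxel_signal(vox)
  for (dy in c(-0.05, -0.1, -0.2)) expect_lte(voxel_signal(vox, dy = dy), s0)
  for (gd in c(0.5, 1, 2)) expect_lte(voxel_signal(vox, gd = gd), s0)
})

test_that("signal is pointwise monotone in contrast amplitude", {
  vox <- voxel_venous()
  dys <- seq(0, -0.3, by = -0.02)
  s <- vapply(dys, function(d) voxel_signal(vox, dy = d), numeric(1))
  expect_true(all(diff(s) <= 1e-14))
  gds <- seq(0, 4, by = 0.25)
  s2 <- vapply(gds, function(g) voxel_signal(vox, gd = g), numeric(1))
  expect_true(all(diff(s2) <= 1e-14))
})

test_that("a pure-blood voxel's relaxation curve equals its intravascular rate change", {
  # single-exponential identity: round trip through the log-ratio conversion
  g <- time_grid(120)
  inlet <- gamma_variate_bolus(g, onset = 10)
  s <- simulate_signal_timecourse(inlet, voxel_arterial(100, y0 = 1),
                                  tr = NULL)
  dr <- signal_to_relaxation(s)$dr2s
  expected <- ivs_relaxation(1, 0, inlet$value) - ivs_relaxation(1, 0, 0)
  expect_equal(dr, expected, tolerance = 1e-9)
})

test_that("tissue peak relaxation is linear in CBV but large vessels are not", {
  inlets <- fig2_inlets()
  cbvs <- 1:5
  pk <- vapply(cbvs, function(v) peak_dr2s(inlets$dohb, voxel_tissue(v, "GM")),
               numeric(1))
  fit <- summary(lm(pk ~ cbvs))
  expect_gt(fit$r.squared, 0.99)
  # arterial dOHb response has an interior maximum in CBV
  sweep_cbv <- seq(10, 100, by = 10)
  pa <- vapply(sweep_cbv, function(v) peak_dr2s(inlets$dohb, voxel_arterial(v)),
               numeric(1))
  imax <- which.max(pa)
  expect_gt(imax, 1)
  expect_lt(imax, length(pa))
  # venous response saturates: < 5% relative change from CBV 90 to 100
  pv90 <- peak_dr2s(inlets$dohb, voxel_venous(90))
  pv100 <- peak_dr2s(inlets$dohb, voxel_venous(100))
  expect_lt(abs(pv100 - pv90) / pv90, 0.05)
})

test_that("simulated time course is flat at baseline for a zero bolus", {
  g <- time_grid(60)
  z <- gamma_variate_bolus(g, a = 0, onset = 10)
  s <- simulate_signal_timecourse(z, voxel_tissue(4, "GM"), tr = 1.5)
  expect_true(all(abs(s$signal - attr(s, "S0")) < 1e-14))
  expect_equal(attr(s, "TR"), 1.5)
})
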