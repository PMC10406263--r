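make_signal <- function(values, tr = 1.5, te = 0.03, s0 = NULL,
                        bw = seq_len(min(10, length(values)))) {
  signal_timecourse(time = (seq_along(values) - 1) * tr, signal = values,
                    tr = tr, te = te, s0 = s0, baseline_window = bw)
}

test_that("relaxation conversion inverts the exponential and ignores scaling", {
  s <- make_signal(rep(100, 30), s0 = 100)
  expect_true(all(signal_to_relaxation(s)$dr2s == 0))
  s2 <- make_signal(c(rep(100, 10), 100 * exp(-0.3), rep(100, 10)), s0 = 100)
  expect_equal(signal_to_relaxation(s2)$dr2s[11], 10, tolerance = 1e-12)
  # invariant under global scaling (S0 re-estimated from the baseline)
  v <- c(rep(1, 12), exp(-seq(0.1, 0.5, 0.1)), rep(1, 10))
  a <- signal_to_relaxation(make_signal(v))
  b <- signal_to_relaxation(make_signal(7.3 * v))
  expect_equal(a$dr2s, b$dr2s, tolerance = 1e-12)
  bad <- make_signal(c(rep(1, 10), -0.1, rep(1, 5)))
  expect_error(signal_to_relaxation(bad), "index 11")
})

test_that("percentage signal change and SNR follow their definitions", {
  s <- make_signal(c(rep(100, 12), 60, rep(100, 10)), s0 = 100)
  expect_equal(delta_s(s), 40)
  expect_equal(delta_s(make_signal(rep(5, 20), s0 = 5)), 0)
  # noiseless baseline flags infinite SNR
  sn <- snr(s)
  expect_true(is.infinite(sn))
  expect_true(attr(sn, "noiseless"))
  # known ratio: dS 40%, eps_t 2% -> 20
  set.seed(1)
  noisy <- c(rep(100, 10), 60, rep(100, 9))
  noisy[1:10] <- 100 + c(-2, 2, -2, 2, -2, 2, -2, 2, -2, 2) * 0.9486833
  s3 <- make_signal(noisy, s0 = NULL, bw = 1:10)
  expect_equal(as.numeric(snr(s3)), delta_s(s3) / attr(snr(s3), "eps_t"))
  # a pure-blood voxel's dS matches the closed form from its peak dR2*
  g <- time_grid(120)
  inlet <- gamma_variate_bolus(g, onset = 10)
  sart <- simulate_signal_timecourse(inlet, voxel_arterial(100, y0 = 1),
                                     tr = NULL)
  dr_max <- max(signal_to_relaxation(sart)$dr2s)
  expect_equal(delta_s(sart), 100 * (1 - exp(-0.03 * dr_max)),
               tolerance = 1e-9)
})

test_that("temporal noise estimate recovers a known sigma", {
  set.seed(42)
  sigma <- 2
  eps <- replicate(30, {
    v <- c(100 + rnorm(10, sd = sigma), 60, 100 + rnorm(9, sd = sigma))
    attr(snr(make_signal(v, bw = c(1:10, 12:20))), "eps_t")
  })
  # single-series estimates land within 30% most of the time at n = 20 ...
  expect_gt(mean(abs(eps - 2) / 2 < 0.3), 0.75)
  # ... and the mean estimate is close to the true percent noise level
  expect_equal(mean(eps), 100 * sigma / 100, tolerance = 0.1)
})

test_that("the 5-tap Gaussian filter is unit-sum and variance-reducing", {
  s <- make_signal(rep(3, 20))
  expect_equal(temporal_gaussian_filter(s)$signal, rep(3, 20),
               tolerance = 1e-12)
  imp <- make_signal(c(rep(0, 10) + 1e-9, 1, rep(0, 9) + 1e-9))
  sm <- temporal_gaussian_filter(imp)$signal
  expect_equal(sum(sm), 1, tolerance = 1e-6) # interior impulse mass conserved
  expect_equal(sum(sm > 1e-6), 5)
  set.seed(3)
  wn <- make_signal(10 + rnorm(200))
  expect_lt(var(temporal_gaussian_filter(wn)$signal), var(wn$signal))
})

test_that("bolus-window truncation keeps the rise and crops all series alike", {
  tr <- 1.5
  n <- 60
  t <- (seq_len(n) - 1) * tr
  aif <- relaxation_timecourse(t, ifelse(t >= 15 & t <= 30, 10, 0), tr)
  vof <- relaxation_timecourse(t, ifelse(t >= 18 & t <= 40, 8, 0), tr)
  tis <- relaxation_timecourse(t, ifelse(t >= 16 & t <= 35, 1, 0), tr)
  win <- truncate_to_bolus_window(tis, aif, vof)
  expect_equal(nrow(win$tissue), nrow(win$aif))
  expect_equal(nrow(win$tissue), nrow(win$vof))
  # starts one sample before the AIF onset, ends at the VOF return
  expect_equal(min(win$aif$time), 15 - tr)
  expect_equal(max(win$vof$time), 39.0) # last sample inside the VOF bolus
  # window always contains the AIF peak
  expect_true(max(win$aif$dr2s) == max(aif$dr2s))
  # detected onset within one TR of the true arrival (noiseless simulation)
  g <- time_grid(120)
  inlet <- gamma_variate_bolus(g, onset = 30)
  sa <- simulate_signal_timecourse(inlet, voxel_arterial(), tr = tr)
  ra <- signal_to_relaxation(sa)
  w2 <- truncate_to_bolus_window(ra, ra, NULL)
  expect_lte(abs(min(w2$aif$time) - 30), 1.5)
  flat <- relaxation_timecourse(t, rep(0, n), tr)
  expect_error(truncate_to_bolus_window(flat, flat), "no detectable bolus")
})

test_that("rCBV applies the agent's hematocrit correction to the area ratio", {
  expect_equal(kappa_factor("Gd", 0.4), 0.8287293, tolerance = 1e-6)
  expect_equal(kappa_factor("dOHb", 0.4), 1 / 0.69, tolerance = 1e-12)
  expect_equal(kappa_factor("dOHb", 0.25), kappa_factor("dOHb", 0.55))
  t <- seq(0, 60, 1.5)
  ref <- relaxation_timecourse(t, sin(pmax(0, pmin(t - 10, 20)) / 20 * pi), 1.5)
  tis <- relaxation_timecourse(t, 0.04 * ref$dr2s, 1.5)
  expect_equal(as.numeric(rcbv(tis, ref, "dOHb")), 4 / 0.69,
               tolerance = 1e-9)
  neg <- relaxation_timecourse(t, -ref$dr2s, 1.5)
  flagged <- rcbv(tis, neg, "Gd")
  expect_true(is.na(flagged))
  expect_equal(attr(flagged, "flagged"), "nonpositive_reference_area")
})

test_that("negative-rCBV voxels are excluded with a reason and a report", {
  est <- tibble::tibble(label = c("GM", "GM", "WM", "CSF"),
                        rcbv = c(4, -1, 2, NA))
  out <- exclude_voxels(est)
  expect_equal(out$excluded, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$reason[2], "negative_rcbv")
  rep <- attr(out, "report")
  expect_equal(sum(rep$n_excluded), 2)
})
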