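# Brute-force oracle: build the rectangle-rule convolution matrix directly
# and generate tissue curves as A %*% b_true.
conv_matrix <- function(aif, tr) {
  n <- length(aif)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(j)) A[j, k] <- tr * aif[j - k + 1]
  A
}

test_that("threshold-0 deconvolution inverts a consistent discrete system exactly", {
  tr <- 1.5
  t <- seq(0, 45, tr)
  aif <- gamma_variate_bolus(t, onset = -1)$value # nonzero from t = 0
  b_true <- 0.0135 * residue_value(biexponential_residue(), t)
  ct <- drop(conv_matrix(aif, tr) %*% b_true)
  res <- svd_deconvolve(relaxation_timecourse(t, ct, tr),
                        relaxation_timecourse(t, aif, tr), threshold = 0)
  expect_equal(res$residue, b_true, tolerance = 1e-6)
})

test_that("deconvolving a curve by itself yields a residue peaking at the first sample", {
  tr <- 1.5
  t <- seq(0, 90, tr)
  aif <- gamma_variate_bolus(t, onset = -1)$value
  res <- svd_deconvolve(relaxation_timecourse(t, aif, tr),
                        relaxation_timecourse(t, aif, tr), threshold = 0)
  expect_equal(which.max(res$residue), 1L)
  expect_equal(res$residue[1], 1 / tr, tolerance = 1e-6)
})

test_that("raising the threshold never increases the residue maximum", {
  md <- bolus_duration_mtt_experiment(durations = 30,
                                      thresholds = c(0, 0.05, 0.1, 0.2))
  for (ag in c("Gd", "dOHb")) {
    sub <- md[md$agent == ag, ]
    expect_true(all(diff(sub$cbf_recovered) <= 1e-9))
    # standard thresholding versus none: MTT is overestimated
    expect_gte(sub$mtt[sub$threshold == 0.2], sub$mtt[sub$threshold == 0])
  }
})

test_that("noiseless recovery: rCBF within 10% and the MTT consistency identity", {
  md <- bolus_duration_mtt_experiment(durations = 30, thresholds = 0)
  gd <- md[md$agent == "Gd", ]
  expect_equal(gd$cbf_recovered, gd$cbf_true, tolerance = 0.1)
  # full perfusion chain: MTT = rCBV/rCBF * 60 equals area-over-max of the
  # recovered residue when both use the same deconvolution inputs
  g <- time_grid(180)
  inlet <- gamma_variate_bolus(g, onset = 30)
  art <- simulate_signal_timecourse(inlet, voxel_arterial(), tr = 1.5)
  tis <- simulate_signal_timecourse(inlet, voxel_tissue(4, "GM"), tr = 1.5)
  fit <- perfusion_quantify(tis, art, vof = NULL, agent = "Gd",
                            threshold = 0.2)
  rt <- signal_to_relaxation(tis); ra <- signal_to_relaxation(art)
  win <- truncate_to_bolus_window(rt, ra)
  area_ratio <- pracma::trapz(win$tissue$time, win$tissue$dr2s) /
    pracma::trapz(win$aif$time, win$aif$dr2s)
  res <- svd_deconvolve(win$tissue, win$aif, 0.2)
  expect_equal(fit$mtt,
               area_ratio * 100 * kappa_factor("Gd") /
                 (kappa_factor("Gd") * max(res$residue) * 100 * 60) * 60,
               tolerance = 1e-9)
})

test_that("thresholding lowers rCBF and raises MTT relative to no threshold", {
  md <- bolus_duration_mtt_experiment(durations = c(30, 10),
                                      thresholds = c(0, 0.2))
  wide <- tidyr::pivot_wider(md, id_cols = c("agent", "bolus_duration"),
                             names_from = "threshold",
                             values_from = c("mtt", "cbf_recovered"))
  expect_true(all(wide$`cbf_recovered_0.2` <= wide$cbf_recovered_0 + 1e-9))
  expect_true(all(wide$`mtt_0.2` >= wide$mtt_0 - 1e-9))
})

test_that("tidy and glance summarize a perfusion fit", {
  g <- time_grid(180)
  inlet <- gamma_variate_bolus(g, onset = 30)
  art <- simulate_signal_timecourse(inlet, voxel_arterial(), tr = 1.5)
  ven <- simulate_signal_timecourse(inlet, voxel_venous(), tr = 1.5)
  tis <- simulate_signal_timecourse(inlet, voxel_tissue(4, "GM"), tr = 1.5)
  fit <- perfusion_quantify(tis, art, ven, agent = "Gd")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("rcbv_arterial", "rcbv_venous", "rcbf", "mtt",
                             "mtt_residue"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$agent, "Gd")
  expect_equal(gl$threshold, 0.2)
})
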