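test_that("phantom rendering is deterministic and regionally uniform when noiseless", {
  sp <- phantom_spec(noise_sigma = 0)
  r1 <- build_phantom(sp, "gd_standard")
  r2 <- build_phantom(sp, "gd_standard")
  expect_identical(r1$signal, r2$signal)
  # all noiseless GM voxels share one time course
  gm_idx <- which(r1$labels == "GM")
  nt <- dim(r1$signal)[4]
  S <- matrix(r1$signal, ncol = nt)
  expect_equal(max(apply(S[gm_idx, ], 2, function(x) diff(range(x)))), 0)
  # with a seed, noisy rendering is reproducible too
  spn <- phantom_spec(noise_sigma = 0.01, seed = 11)
  expect_identical(build_phantom(spn, "gd_standard")$signal,
                   build_phantom(spn, "gd_standard")$signal)
})

test_that("phantom analysis recovers the GM/WM blood-volume ratio and truth ordering", {
  maps <- analyze_dsc(build_phantom(phantom_spec(), "gd_standard"))
  vx <- maps$voxels
  gm <- mean(vx$rcbv[vx$label == "GM"])
  wm <- mean(vx$rcbv[vx$label == "WM"])
  expect_equal(gm / wm, 2, tolerance = 0.05) # CBV 4% vs 2%
  expect_gt(gm, 0)
  # CSF receives no contrast: zero rCBV, undefined MTT
  expect_equal(max(abs(vx$rcbv[vx$label == "CSF"])), 0)
  expect_true(all(is.na(vx$mtt[vx$label == "CSF"])))
  # rCBV ordering across paradigms survives the full image pipeline
  sp <- phantom_spec()
  rcbv_gm <- vapply(c("dohb_98_90", "dohb_98_75"), function(p) {
    m <- analyze_dsc(build_phantom(sp, p))
    mean(m$voxels$rcbv[m$voxels$label == "GM"])
  }, numeric(1))
  expect_gt(rcbv_gm[1], rcbv_gm[2])
})

test_that("threshold segmentation recovers ground truth on the noiseless phantom", {
  run <- build_phantom(phantom_spec(), "gd_standard")
  maps <- analyze_dsc(run)
  seg <- threshold_segmentation(maps$delta_s, maps$eps_t, maps$mtt)
  expect_gt(dice_coefficient(seg$gm, run$labels == "GM"), 0.95)
  expect_gt(dice_coefficient(seg$wm, run$labels == "WM"), 0.95)
  # raising the noise cutoff never shrinks the mask
  set.seed(5)
  noise_map <- array(runif(length(maps$delta_s)), dim = dim(maps$delta_s))
  masks <- lapply(c(0.1, 0.5, 0.9), function(f) {
    threshold_segmentation(maps$delta_s, noise_map, maps$mtt,
                           noise_frac = f)$valid
  })
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))
})

test_that("exclusion fraction grows with the phantom noise level", {
  frac <- vapply(c(0.01, 0.04, 0.08), function(sg) {
    m <- analyze_dsc(build_phantom(phantom_spec(noise_sigma = sg, seed = 7,
                                                vessel_noise_multiplier = 1),
                                   "gd_standard"))
    mean(m$voxels$excluded)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("signal-change ratio maps reproduce the regional ordering", {
  sp <- phantom_spec(artery_cbv = 90, vein_cbv = 90)
  gd6 <- build_phantom(sp, "gd_standard", peak_mM = 6)
  d84 <- build_phantom(sp, "dohb_98_84")
  rat <- delta_s_ratio_maps(gd6, d84)
  s <- setNames(rat$summary$mean_ratio, rat$summary$label)
  expect_gt(s[["venous"]], s[["GM"]])   # vein ratio above tissue
  expect_lt(s[["arterial"]], s[["venous"]]) # artery below vein at CBV 90
  # identical runs give a ratio of one everywhere it is defined
  self <- delta_s_ratio_maps(gd6, gd6$signal)
  vals <- self$ratio[!is.na(self$ratio)]
  expect_equal(unname(range(vals)), c(1, 1), tolerance = 1e-12)
})

test_that("map regression recovers slopes and benefits from smoothing", {
  set.seed(9)
  a <- array(runif(32 * 32 * 4, 1, 5), dim = c(32, 32, 4))
  fit0 <- suppressWarnings(map_regression(a, 2 * a)) # lm warns on exact fits
  expect_equal(fit0$slope, 2, tolerance = 1e-9)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-9)
  noisy1 <- a + array(rnorm(length(a), sd = 1), dim = dim(a))
  fit <- map_regression(a, noisy1)
  expect_equal(fit$slope, 1, tolerance = 0.15)
  expect_lt(fit$r_squared, 1)
  # smoothing spatially uncorrelated noise raises the smooth-map R^2
  base <- array(0, dim = c(32, 32, 4))
  for (i in 1:32) base[i, , ] <- i # smooth spatial gradient
  noisy <- base + array(rnorm(length(base), sd = 2), dim = dim(base))
  r2_raw <- map_regression(base, noisy)$r_squared
  r2_sm <- map_regression(base, noisy, smoothing = TRUE)$r_squared
  expect_gt(r2_sm, r2_raw)
  expect_error(map_regression(a[1:2, 1:1, 1, drop = FALSE],
                              a[1:2, 1:1, 1, drop = FALSE] * 2,
                              mask = array(c(TRUE, FALSE),
                                           dim = c(2, 1, 1))), ">= 3")
  # voxel-wise mean utility
  m <- map_mean(list(a, 3 * a))
  expect_equal(m, 2 * a, tolerance = 1e-12)
})
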