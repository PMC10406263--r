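#' Digital perfusion phantom specification
#'
#' A small labeled 3D geometry whose voxels carry the standard voxel
#' models: a CSF rim, a cortical GM ribbon, a WM core, and single-column
#' artery and vein embedded in the core. Small by design so the full
#' simulate-analyze loop runs in seconds.
#'
#' @param dim Grid dimensions (3 integers, default `c(32, 32, 8)`).
#' @param csf_width,gm_width Widths (voxels) of the CSF rim and GM ribbon.
#' @param artery_cbv,vein_cbv CBV (%) of the dedicated vessel columns.
#' @param gm_cbv,wm_cbv Total CBV (%) of the tissue voxels.
#' @param noise_sigma Temporal noise standard deviation as a fraction of
#'   the voxel's baseline signal (0 = noiseless).
#' @param vessel_noise_multiplier Noise multiplier for vessel voxels
#'   (emulating the elevated physiological noise of large vessels).
#' @param seed Integer seed; a fixed seed makes the rendered data
#'   reproducible to the byte.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(32, 32, 8), csf_width = 2, gm_width = 3,
                         artery_cbv = 100, vein_cbv = 100,
                         gm_cbv = 4, wm_cbv = 2,
                         noise_sigma = 0, vessel_noise_multiplier = 3,
                         seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 4),
            all(dim[1:2] > 2 * (csf_width + gm_width)))
  structure(list(dim = dim, csf_width = csf_width, gm_width = gm_width,
                 artery_cbv = artery_cbv, vein_cbv = vein_cbv,
                 gm_cbv = gm_cbv, wm_cbv = wm_cbv,
                 noise_sigma = noise_sigma,
                 vessel_noise_multiplier = vessel_noise_multiplier,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_labels <- function(spec) {
  d <- spec$dim
  lab <- array("CSF", dim = d)
  in_band <- function(i, n, w0, w1) i > w0 & i <= n - w0 & (i <= w0 + w1 | i > n - w0 - w1)
  interior0 <- spec$csf_width
  interior1 <- spec$csf_width + spec$gm_width
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  for (z in seq_len(d[3])) {
    inx <- xs > interior0 & xs <= d[1] - interior0
    iny <- ys > interior0 & ys <= d[2] - interior0
    core_x <- xs > interior1 & xs <= d[1] - interior1
    core_y <- ys > interior1 & ys <= d[2] - interior1
    lab[inx, iny, z] <- "GM"
    lab[core_x, core_y, z] <- "WM"
  }
  ax <- floor(d[1] / 2); ay <- floor(d[2] / 2)
  lab[ax, ay, ] <- "arterial"
  lab[ax + 1, ay + 1, ] <- "venous"
  lab
}

#' Render a 4D phantom dataset for a paradigm
#'
#' Simulates the per-region signal time courses for the given paradigm
#' (arterial voxels carry the inlet, tissue and venous voxels their
#' transported boluses), samples them at TR, broadcasts them over the
#' labeled geometry, and adds optional Gaussian temporal noise. Ground
#' truth CBV/MTT/label maps accompany the data. Deterministic under the
#' spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param paradigm A paradigm name from [dsc_paradigms()] or a one-row
#'   paradigm tibble.
#' @param tr Repetition time (s).
#' @param duration Scan duration (s).
#' @param onset Bolus arrival time (s).
#' @param constants A [physics_constants()] list.
#' @param peak_mM Optional gadolinium peak override (mM).
#' @return A `phantom_run` list: `signal` (4D array x,y,z,t), `labels`
#'   (3D), `truth` (tibble of per-region CBV and MTT), `aif`, `vof`
#'   (voxel indices, 1-based), `tr`, `te`, `agent`, `times`.
#' @export
build_phantom <- function(spec, paradigm = "gd_standard", tr = 1.5,
                          duration = 180, onset = 30,
                          constants = physics_constants(), peak_mM = NULL) {
  labels <- phantom_labels(spec)
  grid <- time_grid(duration)
  inlet <- paradigm_inlet(paradigm, grid, onset = onset, peak_mM = peak_mM)
  agent <- bolus_agent(inlet)
  voxels <- list(
    arterial = voxel_arterial(spec$artery_cbv),
    venous = voxel_venous(spec$vein_cbv),
    GM = voxel_tissue(spec$gm_cbv, "GM"),
    WM = voxel_tissue(spec$wm_cbv, "WM"),
    CSF = voxel_csf()
  )
  courses <- lapply(voxels, function(v) {
    simulate_signal_timecourse(inlet, v, tr = tr, constants = constants)
  })
  times <- courses[[1]]$time
  nt <- length(times)
  d <- spec$dim
  sig <- array(0, dim = c(d, nt))
  for (lb in names(courses)) {
    idx <- which(labels == lb)
    s <- courses[[lb]]$signal
    for (k in seq_len(nt)) {
      plane <- sig[, , , k]
      plane[idx] <- s[k]
      sig[, , , k] <- plane
    }
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    s0 <- vapply(courses, function(x) attr(x, "S0"), numeric(1))
    sd_map <- array(0, dim = d)
    for (lb in names(courses)) {
      mult <- if (lb %in% c("arterial", "venous")) {
        spec$vessel_noise_multiplier
      } else 1
      sd_map[labels == lb] <- spec$noise_sigma * s0[[lb]] * mult
    }
    noise <- array(stats::rnorm(prod(d) * nt), dim = c(d, nt)) *
      array(sd_map, dim = c(d, nt))
    sig <- sig + noise
  }
  truth <- tibble::tibble(
    label = names(voxels),
    cbv = c(spec$artery_cbv, spec$vein_cbv, spec$gm_cbv, spec$wm_cbv, 0),
    mtt = c(0, residue_mtt(monoexponential_residue(4)),
            residue_mtt(biexponential_residue()),
            residue_mtt(biexponential_residue()), NA)
  )
  ax <- floor(d[1] / 2); ay <- floor(d[2] / 2)
  structure(list(signal = sig, labels = labels, truth = truth,
                 aif = c(ax, ay, 1), vof = c(ax + 1, ay + 1, 1),
                 tr = tr, te = constants$TE, agent = agent, times = times,
                 spec = spec, paradigm = paradigm),
            class = "phantom_run")
}

#' @export
print.phantom_run <- function(x, ...) {
  cat("<phantom_run>", paste(dim(x$signal), collapse = "x"),
      " agent:", x$agent, " TR:", x$tr, "s\n")
  invisible(x)
}

#' Analyze a 4D DSC dataset voxel-wise
#'
#' Applies the full inversion pipeline to every voxel of a 4D dataset:
#' relaxation conversion, bolus-window truncation from the supplied AIF and
#' VOF voxels, kappa-corrected rCBV (arterial or venous normalization),
#' truncated-SVD deconvolution (the SVD is factored once from the AIF and
#' applied to all voxels), rCBF and central-volume MTT, plus per-voxel
#' percentage signal change and temporal noise. Voxels with negative rCBV
#' are flagged excluded.
#'
#' @param data A `phantom_run`, a 4D array (x, y, z, t), or a path to a 4D
#'   NIfTI file.
#' @param aif,vof Voxel indices (1-based x, y, z) of the arterial input and
#'   venous output voxels; defaults taken from the phantom run.
#' @param agent `"Gd"` or `"dOHb"`.
#' @param tr,te Acquisition timing (s); defaults from the phantom run.
#' @param threshold Singular-value threshold (default 0.2).
#' @param normalization `"arterial"` or `"venous"` reference for rCBV.
#' @param Hct Hematocrit fraction.
#' @param onset_frac Bolus-onset criterion for the analysis window.
#' @param baseline_n Number of leading samples used for S0 and noise.
#' @return A `dsc_maps` list of 3D arrays (`rcbv`, `rcbf`, `mtt`,
#'   `delta_s`, `eps_t`, `excluded`) plus `voxels`, a tibble with one row
#'   per voxel.
#' @export
analyze_dsc <- function(data, aif = NULL, vof = NULL,
                        agent = NULL, tr = NULL, te = NULL,
                        threshold = 0.2,
                        normalization = c("arterial", "venous"),
                        Hct = 0.4, onset_frac = 0.1, baseline_n = 10) {
  normalization <- match.arg(normalization)
  labels <- NULL
  if (inherits(data, "phantom_run")) {
    if (is.null(aif)) aif <- data$aif
    if (is.null(vof)) vof <- data$vof
    if (is.null(agent)) agent <- data$agent
    if (is.null(tr)) tr <- data$tr
    if (is.null(te)) te <- data$te
    labels <- data$labels
    arr <- data$signal
  } else if (is.character(data)) {
    arr <- as.array(RNifti::readNifti(data))
  } else {
    arr <- data
  }
  stopifnot(length(dim(arr)) == 4, !is.null(aif), !is.null(agent),
            !is.null(tr), !is.null(te))
  d <- dim(arr)[1:3]
  nt <- dim(arr)[4]
  nvox <- prod(d)
  S <- matrix(arr, nrow = nvox, ncol = nt) # voxels x time
  bw <- seq_len(min(baseline_n, nt))
  s0 <- rowMeans(S[, bw, drop = FALSE])
  eps_t <- 100 * apply(S[, bw, drop = FALSE], 1, stats::sd) / s0
  ds <- 100 * (s0 - apply(S, 1, min)) / s0
  # relaxation conversion (voxels with non-positive signal are dropped)
  ok <- s0 > 0 & apply(S > 0, 1, all)
  C <- matrix(NA_real_, nvox, nt)
  C[ok, ] <- -(1 / te) * log(S[ok, , drop = FALSE] / s0[ok])

  vidx <- function(ij) ij[1] + d[1] * (ij[2] - 1) + d[1] * d[2] * (ij[3] - 1)
  times <- (seq_len(nt) - 1) * tr
  aif_rt <- relaxation_timecourse(times, C[vidx(aif), ], tr)
  vof_rt <- if (!is.null(vof)) relaxation_timecourse(times, C[vidx(vof), ], tr)
  win <- truncate_to_bolus_window(aif_rt, aif_rt, vof_rt,
                                  onset_frac = onset_frac)$window
  Cw <- C[, win, drop = FALSE]
  tw <- times[win]
  a <- C[vidx(aif), win]
  v <- if (!is.null(vof)) C[vidx(vof), win]
  kap <- kappa_factor(agent, Hct)
  area <- function(x) pracma::trapz(tw, x)
  area_vec <- apply(Cw, 1, function(x) pracma::trapz(tw, x))
  ref_area <- if (normalization == "arterial") area(a) else area(v)
  rcbv_map <- kap * area_vec / ref_area * 100

  # one SVD of the AIF matrix, applied to every voxel curve
  n <- length(win)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j, 1:j] <- tr * a[j:1]
  sv <- svd(A)
  keep <- sv$d >= threshold * max(sv$d) & sv$d > 0
  dinv <- ifelse(keep, 1 / sv$d, 0)
  B <- sv$v %*% (dinv * (t(sv$u) %*% t(Cw))) # n x nvox
  bmax <- apply(B, 2, max)
  rcbf_map <- kap * bmax * 100 * 60
  mtt_map <- ifelse(bmax > 1e-10, rcbv_map / rcbf_map * 60, NA_real_)

  est <- tibble::tibble(
    voxel = seq_len(nvox),
    label = if (is.null(labels)) NA_character_ else as.vector(labels),
    rcbv = rcbv_map, rcbf = rcbf_map, mtt = mtt_map,
    delta_s = ds, eps_t = eps_t
  )
  est <- exclude_voxels(est)
  to_arr <- function(x) array(x, dim = d)
  structure(list(
    rcbv = to_arr(ifelse(est$excluded, NA, est$rcbv)),
    rcbf = to_arr(ifelse(est$excluded, NA, est$rcbf)),
    mtt = to_arr(ifelse(est$excluded, NA, est$mtt)),
    delta_s = to_arr(ds), eps_t = to_arr(eps_t),
    excluded = to_arr(est$excluded),
    voxels = est, window = win, agent = agent,
    normalization = normalization, threshold = threshold,
    report = attr(est, "report")
  ), class = "dsc_maps")
}

#' Write analysis maps to NIfTI
#'
#' @param maps A `dsc_maps` object from [analyze_dsc()].
#' @param dir Output directory.
#' @param which Map names to write.
#' @return Invisibly, the written file paths.
#' @export
write_dsc_maps <- function(maps, dir,
                           which = c("rcbv", "rcbf", "mtt", "delta_s",
                                     "eps_t")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(which, function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]]), p)
    p
  }, character(1))
  invisible(paths)
}
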