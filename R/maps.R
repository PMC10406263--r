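delta_s_map_from_signal <- function(arr, baseline_n = 10) {
  d <- dim(arr)[1:3]
  nt <- dim(arr)[4]
  S <- matrix(arr, nrow = prod(d), ncol = nt)
  bw <- seq_len(min(baseline_n, nt))
  s0 <- rowMeans(S[, bw, drop = FALSE])
  array(100 * (s0 - apply(S, 1, min)) / s0, dim = d)
}

#' Voxel-wise ratio of hypoxia to gadolinium signal changes
#'
#' Divides the percentage maximal signal change of a deoxyhemoglobin run by
#' that of a gadolinium run, voxel by voxel, and summarizes the ratio per
#' region. Voxels where the gadolinium signal change is (near) zero are
#' masked.
#'
#' @param gd_run,dohb_run `phantom_run`s on the same grid (or 4D arrays).
#' @param labels Optional 3D label array (taken from `gd_run` when absent).
#' @param baseline_n Leading samples used for S0.
#' @param min_gd_ds Mask threshold on the gadolinium signal change
#'   (percent).
#' @return A list: `ratio` (3D array), `summary` (tibble of per-region mean
#'   ratios), `delta_s_gd`, `delta_s_dohb`.
#' @export
delta_s_ratio_maps <- function(gd_run, dohb_run, labels = NULL,
                               baseline_n = 10, min_gd_ds = 1e-6) {
  arr_g <- if (inherits(gd_run, "phantom_run")) gd_run$signal else gd_run
  arr_d <- if (inherits(dohb_run, "phantom_run")) dohb_run$signal else dohb_run
  stopifnot(all(dim(arr_g)[1:3] == dim(arr_d)[1:3]))
  if (is.null(labels) && inherits(gd_run, "phantom_run")) {
    labels <- gd_run$labels
  }
  ds_g <- delta_s_map_from_signal(arr_g, baseline_n)
  ds_d <- delta_s_map_from_signal(arr_d, baseline_n)
  ratio <- ifelse(abs(ds_g) > min_gd_ds, ds_d / ds_g, NA_real_)
  summary <- if (!is.null(labels)) {
    tibble::tibble(label = as.vector(labels), ratio = as.vector(ratio)) |>
      dplyr::filter(!is.na(.data$ratio)) |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(mean_ratio = mean(.data$ratio), n = dplyr::n(),
                       .groups = "drop")
  }
  list(ratio = ratio, summary = summary, delta_s_gd = ds_g,
       delta_s_dohb = ds_d)
}

robust_range <- function(x, probs = c(0.02, 0.98)) {
  stats::quantile(x, probs, na.rm = TRUE, names = FALSE)
}

#' Threshold-based gray/white matter segmentation
#'
#' Segments a percentage-signal-change map into GM and WM masks by
#' thresholding, the registration-free segmentation used in place of
#' anatomical tissue maps. Voxels first pass a validity mask: finite MTT
#' within the lowest `mtt_frac` of the MTT robust range (removing CSF, where
#' no contrast arrives and MTT is undefined or extreme) and temporal noise
#' within the lowest `noise_frac` of the noise robust range (removing noisy
#' and large-vessel voxels; a constant noise map keeps everything). Among
#' valid voxels, WM is the lowest `wm_frac` of the signal-change robust
#' range and GM is everything above the `gm_quantile` quantile of the
#' valid values. Robust ranges are 2nd-98th percentile ranges.
#'
#' @param delta_s_map 3D array of percentage signal changes (gadolinium).
#' @param noise_map Optional 3D array of temporal noise levels.
#' @param mtt_map Optional 3D array of MTT values (s).
#' @param wm_frac WM cut as a fraction of the signal-change robust range
#'   (default 0.175, the middle of the 15-20% window).
#' @param gm_quantile Quantile of valid signal-change values above which a
#'   voxel is GM (default 0.25, i.e. the highest 75% of values).
#' @param noise_frac Fraction of the noise robust range kept (default 0.10).
#' @param mtt_frac Fraction of the MTT robust range kept (default 0.70).
#' @return A list of logical 3D arrays `gm`, `wm`, `valid`.
#' @export
threshold_segmentation <- function(delta_s_map, noise_map = NULL,
                                   mtt_map = NULL, wm_frac = 0.175,
                                   gm_quantile = 0.25, noise_frac = 0.10,
                                   mtt_frac = 0.70) {
  # Range-fraction cut floored at the median: a "keep the lowest x% of the
  # robust range" rule must never discard the central mass of the map, which
  # a literal range fraction can do when the distribution is tightly
  # clustered (as deconvolution bias makes phantom MTT maps).
  lower_cut <- function(x, frac) {
    rr <- robust_range(x)
    max(rr[1] + frac * (rr[2] - rr[1]), stats::median(x, na.rm = TRUE))
  }
  valid <- !is.na(delta_s_map)
  if (!is.null(mtt_map)) {
    valid <- valid & !is.na(mtt_map) &
      mtt_map <= lower_cut(mtt_map, mtt_frac)
  }
  if (!is.null(noise_map)) {
    rr <- robust_range(noise_map)
    if (diff(rr) > 0) {
      valid <- valid & !is.na(noise_map) &
        noise_map <= lower_cut(noise_map, noise_frac)
    }
  }
  vals <- delta_s_map[valid]
  if (length(vals) == 0) {
    warning("validity mask is empty", call. = FALSE)
    empty <- array(FALSE, dim = dim(delta_s_map))
    return(list(gm = empty, wm = empty, valid = valid))
  }
  rr <- robust_range(vals)
  wm_cut <- rr[1] + wm_frac * (rr[2] - rr[1])
  gm_cut <- stats::quantile(vals, gm_quantile, names = FALSE)
  wm <- valid & delta_s_map <= wm_cut
  gm <- valid & delta_s_map > gm_cut
  if (!any(wm) || !any(gm)) warning("empty tissue mask", call. = FALSE)
  list(gm = gm, wm = wm, valid = valid)
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b Logical arrays of equal dimension.
#' @return `2|A and B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# 3x3 unit-sum Gaussian smoothing applied slice by slice,
# kernel renormalized at the edges.
smooth_slices_3x3 <- function(arr, sigma = 0.85) {
  off <- -1:1
  ker <- outer(exp(-off^2 / (2 * sigma^2)), exp(-off^2 / (2 * sigma^2)))
  ker <- ker / sum(ker)
  d <- dim(arr)
  out <- arr
  for (z in seq_len(d[3])) {
    sl <- arr[, , z]
    num <- matrix(0, d[1], d[2])
    den <- matrix(0, d[1], d[2])
    for (i in off) for (j in off) {
      xs <- pmin(pmax(seq_len(d[1]) + i, 1), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + j, 1), d[2])
      w <- ker[i + 2, j + 2]
      v <- sl[xs, ys]
      ok <- !is.na(v)
      num[ok] <- num[ok] + w * v[ok]
      den[ok] <- den[ok] + w
    }
    out[, , z] <- ifelse(den > 0, num / den, NA)
  }
  out
}

#' Voxel-wise regression between two parameter maps
#'
#' Ordinary least-squares fit of `map_b` on `map_a` over the in-mask
#' voxels, optionally after per-slice 3x3 Gaussian spatial smoothing of
#' both maps. Used to compare perfusion maps across paradigms.
#'
#' @param map_a,map_b 3D arrays on the same grid.
#' @param mask Optional logical array restricting the fit.
#' @param smoothing Apply 3x3 Gaussian smoothing first?
#' @return A tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
map_regression <- function(map_a, map_b, mask = NULL, smoothing = FALSE) {
  stopifnot(all(dim(map_a) == dim(map_b)))
  if (smoothing) {
    map_a <- smooth_slices_3x3(map_a)
    map_b <- smooth_slices_3x3(map_b)
  }
  keep <- !is.na(map_a) & !is.na(map_b)
  if (!is.null(mask)) keep <- keep & mask
  x <- map_a[keep]; y <- map_b[keep]
  if (length(x) < 3) stop("need >= 3 in-mask voxels", call. = FALSE)
  fit <- stats::lm(y ~ x)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = length(x))
}

#' Voxel-wise mean of several maps
#'
#' Utility for "average paradigm" maps: the voxel-wise mean of a list of
#' equally shaped arrays (NA-aware).
#'
#' @param maps List of 3D arrays.
#' @return A 3D array.
#' @export
map_mean <- function(maps) {
  stopifnot(length(maps) >= 1)
  acc <- array(0, dim = dim(maps[[1]]))
  cnt <- array(0, dim = dim(maps[[1]]))
  for (m in maps) {
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  ifelse(cnt > 0, acc / cnt, NA)
}
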