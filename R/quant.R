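baseline_s0 <- function(s) {
  s0 <- attr(s, "S0")
  if (!is.null(s0)) return(s0)
  w <- attr(s, "baseline_window")
  if (is.null(w) || length(w) == 0) {
    stop("signal time course has no baseline window", call. = FALSE)
  }
  mean(s$signal[w])
}

#' Convert a signal time course to a relaxation-rate time course
#'
#' `dR2*(t) = -(1/TE) * log(S(t) / S0)`, with the baseline signal `S0`
#' taken from the time course's known baseline (simulations) or the mean
#' over its baseline window. Invariant under global signal scaling.
#'
#' @param s A [signal_timecourse()].
#' @return A `relaxation_timecourse` tibble (`time`, `dr2s` in 1/s) with
#'   attribute `TR`.
#' @export
signal_to_relaxation <- function(s) {
  bad <- which(s$signal <= 0)
  if (length(bad)) {
    stop("non-positive signal at sample index ", bad[1], call. = FALSE)
  }
  s0 <- baseline_s0(s)
  te <- attr(s, "TE")
  relaxation_timecourse(s$time, -(1 / te) * log(s$signal / s0),
                        tr = attr(s, "TR"), agent = attr(s, "agent"),
                        label = attr(s, "label"))
}

#' @rdname signal_to_relaxation
#' @param time Sample times (s).
#' @param dr2s Relaxation-rate changes (1/s).
#' @param tr Repetition time (s).
#' @param agent,label Optional provenance labels.
#' @export
relaxation_timecourse <- function(time, dr2s, tr, agent = NA, label = NA) {
  out <- tibble::tibble(time = time, dr2s = dr2s)
  attr(out, "TR") <- tr
  attr(out, "agent") <- agent
  attr(out, "label") <- label
  class(out) <- c("relaxation_timecourse", class(out))
  out
}

#' Percentage maximal signal change
#'
#' `dS = 100 * (S0 - min(S)) / S0`: the depth of the bolus-induced signal
#' drop as a percentage of baseline.
#'
#' @param s A [signal_timecourse()].
#' @return Percent signal change (scalar).
#' @export
delta_s <- function(s) {
  s0 <- baseline_s0(s)
  100 * (s0 - min(s$signal)) / s0
}

#' Bolus signal-to-noise ratio
#'
#' `SNR = dS / eps_t` where `eps_t = 100 * sd(baseline samples) / S0` is the
#' temporal noise level in percent of baseline. A noiseless series returns
#' `Inf` with attribute `noiseless = TRUE`.
#'
#' @param s A [signal_timecourse()].
#' @return SNR (unitless scalar); attribute `eps_t` carries the noise level.
#' @export
snr <- function(s) {
  w <- attr(s, "baseline_window")
  if (length(w) < 2) stop("baseline window needs >= 2 samples", call. = FALSE)
  s0 <- baseline_s0(s)
  eps_t <- 100 * stats::sd(s$signal[w]) / s0
  out <- if (eps_t == 0) Inf else delta_s(s) / eps_t
  attr(out, "eps_t") <- eps_t
  attr(out, "noiseless") <- eps_t == 0
  out
}

#' Temporal Gaussian smoothing of a signal time course
#'
#' Replaces each sample by a normalized 5-tap Gaussian-weighted average
#' (used for the noisier hypoxia acquisitions); the kernel is renormalized
#' at the series edges.
#'
#' @param s A [signal_timecourse()].
#' @param width Kernel width in samples (odd, default 5).
#' @param sigma Kernel standard deviation in samples.
#' @return A smoothed `signal_timecourse`.
#' @export
temporal_gaussian_filter <- function(s, width = 5, sigma = 1) {
  n <- nrow(s)
  if (n < width) stop("series shorter than the kernel", call. = FALSE)
  half <- (width - 1) %/% 2
  ker <- exp(-((-half):half)^2 / (2 * sigma^2))
  ker <- ker / sum(ker)
  x <- s$signal
  out <- vapply(seq_len(n), function(i) {
    j <- (i - half):(i + half)
    keep <- j >= 1 & j <= n
    sum(x[j[keep]] * ker[keep]) / sum(ker[keep])
  }, numeric(1))
  s$signal <- out
  s
}

#' Truncate tissue, AIF and VOF series to the bolus window
#'
#' The analysis window runs from the start of the AIF bolus to the end of
#' the VOF bolus: from one sample before the first AIF sample whose
#' magnitude exceeds `onset_frac` of the AIF maximum (so the partial-rise
#' sample is kept), to the last VOF sample exceeding the same criterion.
#' All series are cropped identically.
#'
#' @param tissue,aif,vof `relaxation_timecourse`s on the same TR. `vof` may
#'   be `NULL`, in which case the window extends to the end of the series.
#' @param onset_frac Onset criterion as a fraction of the series maximum.
#' @return A list with elements `tissue`, `aif`, `vof` (cropped) and
#'   `window` (the sample indices kept).
#' @export
truncate_to_bolus_window <- function(tissue, aif, vof = NULL,
                                     onset_frac = 0.1) {
  a <- abs(aif$dr2s)
  if (max(a) <= 0) stop("no detectable bolus in the AIF", call. = FALSE)
  i0 <- max(1L, which(a >= onset_frac * max(a))[1] - 1L)
  if (is.null(vof)) {
    i1 <- nrow(aif)
  } else {
    v <- abs(vof$dr2s)
    if (max(v) <= 0) stop("no detectable bolus in the VOF", call. = FALSE)
    i1 <- max(which(v >= onset_frac * max(v)))
  }
  if (i1 <= i0) stop("empty bolus window", call. = FALSE)
  w <- i0:i1
  crop <- function(x) {
    if (is.null(x)) return(NULL)
    out <- x[w, , drop = FALSE]
    attributes(out) <- c(attributes(out),
                         attributes(x)[setdiff(names(attributes(x)),
                                               names(attributes(out)))])
    out
  }
  list(tissue = crop(tissue), aif = crop(aif), vof = crop(vof), window = w)
}

#' Relative cerebral blood volume
#'
#' `rCBV = kappa * (area of tissue dR2* / area of reference dR2*) * 100`
#' (mL/100g at unit brain density), where the reference is the arterial or
#' venous relaxation curve and kappa is the agent's hematocrit correction
#' factor ([kappa_factor()]). Areas are trapezoidal integrals over the
#' (already truncated) bolus window.
#'
#' @param tissue,reference `relaxation_timecourse`s, aligned and truncated.
#' @param agent `"Gd"` or `"dOHb"`.
#' @param Hct Hematocrit fraction.
#' @return rCBV (mL/100g). Attribute `kappa` records the correction used.
#'   `NA` with attribute `flagged` when the reference area is not positive.
#' @export
rcbv <- function(tissue, reference, agent = c("Gd", "dOHb"), Hct = 0.4) {
  agent <- match.arg(agent)
  kap <- kappa_factor(agent, Hct)
  area_t <- pracma::trapz(tissue$time, tissue$dr2s)
  area_r <- pracma::trapz(reference$time, reference$dr2s)
  if (area_r <= 0) {
    out <- NA_real_
    attr(out, "flagged") <- "nonpositive_reference_area"
    return(out)
  }
  out <- kap * (area_t / area_r) * 100
  attr(out, "kappa") <- kap
  out
}

#' Exclude voxels with negative rCBV
#'
#' Flags every estimate with `rcbv < 0` as excluded (reason
#' `"negative_rcbv"`) and reports exclusion counts by label.
#'
#' @param estimates A tibble with at least an `rcbv` column (and optionally
#'   a `label` column).
#' @return The tibble with `excluded` and `reason` columns; attribute
#'   `report` is a per-label count of exclusions.
#' @export
exclude_voxels <- function(estimates) {
  stopifnot("rcbv" %in% names(estimates))
  out <- dplyr::mutate(
    estimates,
    excluded = !is.na(.data$rcbv) & .data$rcbv < 0 | is.na(.data$rcbv),
    reason = dplyr::case_when(
      is.na(.data$rcbv) ~ "undefined_rcbv",
      .data$rcbv < 0 ~ "negative_rcbv",
      TRUE ~ NA_character_
    )
  )
  rep_by <- if ("label" %in% names(out)) "label" else character()
  report <- dplyr::summarise(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(rep_by))),
    n = dplyr::n(), n_excluded = sum(.data$excluded), .groups = "drop"
  )
  attr(out, "report") <- report
  out
}
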