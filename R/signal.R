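# Effective blood deoxygenation including the gadolinium equivalent.
# Negative values (hyperoxic overshoot) are clipped to zero with a warning:
# the quadratic intravascular term is symmetric in sign, which would turn an
# overshoot into a spurious relaxation increase.
effective_deoxygenation <- function(y0, dy, gd, constants) {
  deox <- 1 - y0 - dy + pseudo_oxygenation(constants) * gd
  if (any(deox < -1e-12)) {
    warning("effective deoxygenation below zero clipped to 0", call. = FALSE)
  }
  pmax(deox, 0)
}

#' Blood-surface frequency shift from deoxyhemoglobin and gadolinium
#'
#' Angular frequency shift (rad/s) at the vessel surface:
#' `chi_dohb * 1e-6 * Hct * (1 - Y0 - dY) * gamma * B0` for deoxyhemoglobin
#' plus `gamma * B0 * chi_gd * 1e-6 * [Gd]` for gadolinium. The two agents
#' are interchangeable through the pseudo-oxygenation constant, so the shift
#' is computed from the total effective deoxygenation
#' `(1 - Y0 - dY) + 0.246 * [Gd]`. Baseline deoxygenation `(1 - Y0)`
#' contributes: a vein at `Y0 = 0.60` has a large shift before any bolus.
#'
#' @param y0 Baseline oxygen saturation (fraction).
#' @param dy Signed saturation change (fraction; negative during hypoxia).
#' @param gd Gadolinium concentration (mM, >= 0).
#' @param constants A [physics_constants()] list.
#' @return Frequency shift(s), rad/s.
#' @examples
#' frequency_shift(0.6, 0, 0) # ~33.9 rad/s
#' frequency_shift(1, 0, 1)   # ~20.9 rad/s (1 mM Gd, fully oxygenated)
#' @export
frequency_shift <- function(y0, dy = 0, gd = 0,
                            constants = physics_constants()) {
  deox <- effective_deoxygenation(y0, dy, gd, constants)
  constants$chi_dohb * 1e-6 * constants$Hct * deox *
    constants$gamma * constants$B0
}

#' Extravascular contrast relaxation rate of a voxel
#'
#' Sums, over the voxel's vascular compartments, the product of the
#' compartment's percentage blood volume, its vessel-class coefficient and
#' its frequency shift: `sum_i pcbv_i * coeff_i * dv_i` (1/s). `pcbv` is in
#' percent because the coefficients are calibrated per one percent of CBV.
#'
#' @param voxel A [voxel_model()].
#' @param shifts Frequency shifts (rad/s), one per compartment (a vector for
#'   a single time point, or a matrix with one row per time point).
#' @return Relaxation rate(s), 1/s.
#' @export
ees_relaxation <- function(voxel, shifts) {
  w <- voxel$pcbv * ees_coeff_for(voxel$vessel_class)
  if (is.matrix(shifts)) {
    if (ncol(shifts) != nrow(voxel)) {
      stop("shifts must have one column per compartment", call. = FALSE)
    }
    drop(shifts %*% w)
  } else {
    if (length(shifts) != nrow(voxel)) {
      stop("one shift per compartment required", call. = FALSE)
    }
    sum(w * shifts)
  }
}

#' Intravascular contrast relaxation rate
#'
#' Quadratic in total effective deoxygenation:
#' `181 * ((1 - Y0 - dY) + 0.246 * [Gd])^2` (1/s), from a blood phantom
#' calibration at 3 T, Hct 0.4.
#'
#' @inheritParams frequency_shift
#' @return Relaxation rate(s), 1/s.
#' @examples
#' ivs_relaxation(0.6, 0, 0) # 181 * 0.16 = 28.96
#' @export
ivs_relaxation <- function(y0, dy = 0, gd = 0,
                           constants = physics_constants()) {
  deox <- effective_deoxygenation(y0, dy, gd, constants)
  constants$ivs_quadratic_coeff * deox^2
}

#' T2*-weighted signal of a voxel at given contrast levels
#'
#' Volume-weighted sum of one extravascular and per-compartment
#' intravascular monoexponentials:
#' `S = (1 - CBV) * exp(-TE*(R2*_0_EES + R2*_con_EES)) +
#'  sum_i CBV_i * exp(-TE*(R2*_0_IVS + R2*_con_IVS_i))`,
#' where the extravascular contrast rates of all compartments are summed
#' inside a single exponential while each intravascular compartment gets its
#' own exponential. `dy` and `gd` may be vectors (time courses shared by all
#' compartments of the voxel); the result is vectorized along them.
#'
#' @param voxel A [voxel_model()].
#' @inheritParams frequency_shift
#' @return Signal (arbitrary units, `<= 1`), same length as `dy`/`gd`.
#' @examples
#' voxel_signal(voxel_arterial(), dy = 0, gd = 0) # exp(-0.03*13.8)
#' voxel_signal(voxel_csf(), dy = 0, gd = 0)      # exp(-0.03*20.99)
#' @export
voxel_signal <- function(voxel, dy = 0, gd = 0,
                         constants = physics_constants()) {
  n <- max(length(dy), length(gd))
  dy <- rep_len(dy, n)
  gd <- rep_len(gd, n)
  cbv_frac_total <- voxel_total_cbv(voxel) / 100
  if (nrow(voxel) == 0) {
    return(rep(exp(-constants$TE * constants$R2_0_EES), n))
  }
  ees_con <- numeric(n)
  ivs_sig <- numeric(n)
  for (i in seq_len(nrow(voxel))) {
    deox <- effective_deoxygenation(voxel$y0[i], dy, gd, constants)
    dv <- constants$chi_dohb * 1e-6 * constants$Hct * deox *
      constants$gamma * constants$B0
    ees_con <- ees_con +
      voxel$pcbv[i] * ees_coeff_for(voxel$vessel_class[i]) * dv
    ivs_sig <- ivs_sig + (voxel$pcbv[i] / 100) *
      exp(-constants$TE *
            (constants$R2_0_IVS + constants$ivs_quadratic_coeff * deox^2))
  }
  (1 - cbv_frac_total) *
    exp(-constants$TE * (constants$R2_0_EES + ees_con)) + ivs_sig
}

#' Simulate an acquired signal time course for one voxel
#'
#' Composes transport and the voxel signal model: the inlet bolus is
#' propagated according to the voxel label (arterial voxels receive the
#' inlet unchanged, tissue and venous voxels their transported versions),
#' the fine-grid signal is computed, and samples are taken every TR.
#' For a hypoxic inlet the paradigm's baseline saturation replaces the fully
#' arterial `y0 = 1` compartments (see [voxel_model()]).
#'
#' @param inlet An `agent_bolus` on a fine grid.
#' @param voxel A [voxel_model()].
#' @param tr Repetition time (s); `NULL` keeps the fine simulation grid.
#' @param tissue_spec,venous_spec Transport specifications (defaults: tissue
#'   MTT ~3 s with 1 s delay; venous MTT 4 s with 2 s delay).
#' @param constants A [physics_constants()] list.
#' @param baseline_saturation Baseline override for `y0 = 1` compartments;
#'   default: the hypoxic paradigm's `base_sat` for dOHb inlets, none for
#'   gadolinium.
#' @return A `signal_timecourse` tibble (`time`, `signal`) with attributes
#'   `TR`, `TE`, `S0`, `agent`, `baseline_window`.
#' @export
simulate_signal_timecourse <- function(inlet, voxel, tr = 1.5,
                                       tissue_spec = tissue_transport(),
                                       venous_spec = venous_transport(),
                                       constants = physics_constants(),
                                       baseline_saturation = NULL) {
  agent <- bolus_agent(inlet)
  if (is.null(baseline_saturation) && identical(agent, "dOHb")) {
    baseline_saturation <- bolus_spec(inlet)$base_sat
  }
  voxel <- apply_baseline_saturation(voxel, baseline_saturation)
  label <- voxel_label(voxel)
  course <- switch(label,
    arterial = inlet,
    venous = transport(inlet, venous_spec),
    GM = ,
    WM = transport(inlet, tissue_spec),
    CSF = new_agent_bolus(inlet$time, rep(0, nrow(inlet)), agent),
    stop("unknown voxel label: ", label, call. = FALSE)
  )
  dy <- if (agent == "dOHb") course$value else 0
  gd <- if (agent == "Gd") course$value else 0
  s_fine <- voxel_signal(voxel, dy = dy, gd = gd, constants = constants)
  s0 <- voxel_signal(voxel, dy = 0, gd = 0, constants = constants)
  dt <- grid_dt(inlet$time)
  if (is.null(tr)) tr <- dt # keep the fine grid
  step <- max(1L, round(tr / dt))
  idx <- seq(1L, nrow(inlet), by = step)
  signal_timecourse(time = inlet$time[idx], signal = s_fine[idx],
                    tr = tr, te = constants$TE, s0 = s0, agent = agent,
                    label = label)
}

#' Construct a signal time course object
#'
#' @param time Sample times (s).
#' @param signal Signal values (> 0).
#' @param tr Repetition time (s).
#' @param te Echo time (s).
#' @param s0 Known baseline signal (optional; estimated from the baseline
#'   window when absent).
#' @param agent Contrast agent label.
#' @param label Voxel label (optional).
#' @param baseline_window Sample indices used for S0 and noise estimates
#'   (default: the first 10 samples).
#' @return A `signal_timecourse` tibble.
#' @export
signal_timecourse <- function(time, signal, tr, te, s0 = NULL, agent = NA,
                              label = NA,
                              baseline_window = seq_len(min(10, length(time)))) {
  out <- tibble::tibble(time = time, signal = signal)
  attr(out, "TR") <- tr
  attr(out, "TE") <- te
  attr(out, "S0") <- s0
  attr(out, "agent") <- agent
  attr(out, "label") <- label
  attr(out, "baseline_window") <- baseline_window
  class(out) <- c("signal_timecourse", class(out))
  out
}

#' @export
print.signal_timecourse <- function(x, ...) {
  cat("<signal_timecourse> agent:", attr(x, "agent"),
      " TR:", attr(x, "TR"), "s TE:", attr(x, "TE") * 1000, "ms n:",
      nrow(x), "\n")
  NextMethod()
}
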