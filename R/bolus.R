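new_agent_bolus <- function(time, value, agent, spec = list()) {
  out <- tibble::tibble(time = time, value = value)
  attr(out, "agent") <- agent
  attr(out, "spec") <- spec
  class(out) <- c("agent_bolus", class(out))
  out
}

#' @export
print.agent_bolus <- function(x, ...) {
  cat("<agent_bolus> agent:", attr(x, "agent"),
      " n:", nrow(x),
      " peak:", signif(max(abs(x$value)), 4), "\n")
  NextMethod()
}

bolus_agent <- function(bolus) attr(bolus, "agent")
bolus_spec <- function(bolus) attr(bolus, "spec")

#' Gamma-variate arterial gadolinium input
#'
#' The arterial gadolinium concentration time course is modeled as a gamma
#' variate, `a * ((t - onset)/b)^c * exp(c * (1 - (t - onset)/b))` for
#' `t >= onset` and zero before, which peaks at exactly `a` (mM) at
#' `t = onset + b`. Defaults follow a standard bolus injection observed at
#' 3 T: peak ~2 mM, time-to-peak 2.5 s, shape 3.
#'
#' @param grid Time grid (numeric vector from [time_grid()]).
#' @param a Peak concentration (mM, >= 0).
#' @param b Time to peak after onset (s, > 0).
#' @param c Unitless shape parameter (> 0).
#' @param onset Bolus arrival time (s).
#' @return An `agent_bolus` tibble (`time`, `value`) with `agent = "Gd"`.
#' @examples
#' bol <- gamma_variate_bolus(time_grid(60), a = 2, b = 2.5, c = 3, onset = 10)
#' max(bol$value) # 2
#' @export
gamma_variate_bolus <- function(grid, a = 2, b = 2.5, c = 3, onset = 0) {
  if (b <= 0 || c <= 0) stop("b and c must be positive", call. = FALSE)
  if (a < 0) stop("peak concentration a must be >= 0", call. = FALSE)
  u <- (grid - onset) / b
  v <- ifelse(u > 0, a * u^c * exp(c * (1 - u)), 0)
  new_agent_bolus(grid, v, "Gd",
                  list(a = a, b = b, c = c, onset = onset))
}

#' Hypoxic (deoxyhemoglobin) arterial input
#'
#' A transient drop in arterial oxygen saturation used as an endogenous
#' contrast bolus: a rectangular pulse of depth `-(base_sat - target_sat)`
#' and width `plateau_duration`, convolved with a unit-area decaying
#' exponential of time constant `rise_tau` (the lungs and vasculature take a
#' few breaths to reach the hypoxic target). With `return_mode = "step"`
#' only the descent is smoothed and the return to baseline is instantaneous
#' (experimentally the return happens in a single breath); the default
#' smooths both edges with the same exponential.
#'
#' Values are the signed saturation change relative to baseline, so they are
#' `<= 0` everywhere and approach `-(base_sat - target_sat)` when the
#' plateau is much longer than `rise_tau`.
#'
#' @inheritParams gamma_variate_bolus
#' @param base_sat Baseline arterial saturation (fraction).
#' @param target_sat Hypoxic target saturation (fraction, `<= base_sat`).
#' @param plateau_duration Width of the hypoxic plateau (s).
#' @param rise_tau Time constant of the smoothing exponential (s, >= 0).
#' @param return_mode `"exponential"` (both edges smoothed) or `"step"`.
#' @return An `agent_bolus` tibble with `agent = "dOHb"`; values are signed
#'   saturation-change fractions.
#' @examples
#' bol <- hypoxic_bolus(time_grid(120), base_sat = 0.98, target_sat = 0.75)
#' min(bol$value) # close to -0.23
#' @export
hypoxic_bolus <- function(grid, base_sat = 0.98, target_sat = 0.75,
                          plateau_duration = 30, onset = 0, rise_tau = 5,
                          return_mode = c("exponential", "step")) {
  return_mode <- match.arg(return_mode)
  if (target_sat > base_sat) {
    stop("target_sat must not exceed base_sat", call. = FALSE)
  }
  if (base_sat > 1 || target_sat < 0) {
    stop("saturations must lie in [0, 1]", call. = FALSE)
  }
  if (plateau_duration <= 0) stop("plateau_duration must be > 0", call. = FALSE)
  if (rise_tau < 0) stop("rise_tau must be >= 0", call. = FALSE)
  dt <- grid_dt(grid)
  depth <- base_sat - target_sat
  t_rel <- grid - onset
  in_plateau <- t_rel >= 0 & t_rel < plateau_duration
  if (rise_tau < dt / 2) {
    v <- ifelse(in_plateau, -depth, 0)
  } else if (return_mode == "step") {
    # first-order step response during the plateau, hard reset after
    v <- ifelse(in_plateau, -depth * (1 - exp(-t_rel / rise_tau)), 0)
  } else {
    rect <- ifelse(in_plateau, -depth, 0)
    ker <- exp(-seq(0, 10 * rise_tau, by = dt) / rise_tau)
    ker <- ker / sum(ker)
    v <- stats::convolve(rect, rev(ker), type = "open")[seq_along(grid)]
    v <- pmin(v, 0)
  }
  new_agent_bolus(grid, v, "dOHb",
                  list(base_sat = base_sat, target_sat = target_sat,
                       plateau_duration = plateau_duration, onset = onset,
                       rise_tau = rise_tau, return_mode = return_mode))
}

#' Shorten a hypoxic bolus to a reference duration
#'
#' Rebuilds the bolus from its stored specification with the plateau set to
#' the requested duration, keeping onset, depth, rise time constant and
#' return mode. Used to duration-match a long hypoxic bolus to a standard
#' (shorter) gadolinium bolus. The returned bolus records the area and peak
#' of both versions in its `provenance` attribute.
#'
#' @param bolus An `agent_bolus` created by [hypoxic_bolus()].
#' @param duration Target bolus width = plateau duration (s, > 0).
#' @return A new `agent_bolus` on the same grid.
#' @export
truncate_bolus_to_duration <- function(bolus, duration) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  sp <- bolus_spec(bolus)
  if (is.null(sp$plateau_duration)) {
    stop("truncate_bolus_to_duration requires a hypoxic bolus", call. = FALSE)
  }
  if (duration < 3 * sp$rise_tau) {
    warning("requested duration is shorter than the bolus rise; ",
            "plateau depth will not be reached", call. = FALSE)
  }
  out <- hypoxic_bolus(bolus$time,
                       base_sat = sp$base_sat, target_sat = sp$target_sat,
                       plateau_duration = duration, onset = sp$onset,
                       rise_tau = sp$rise_tau, return_mode = sp$return_mode)
  attr(out, "provenance") <- list(
    original_area = pracma::trapz(bolus$time, bolus$value),
    original_peak = min(bolus$value),
    truncated_area = pracma::trapz(out$time, out$value),
    truncated_peak = min(out$value)
  )
  out
}
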