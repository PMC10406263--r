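#' Contrast paradigms
#'
#' The experimental paradigms used throughout: a standard gadolinium bolus
#' (gamma variate, peak ~2 mM) and four hypoxic paradigms combining a small,
#' medium or large saturation drop with a high or low baseline saturation:
#' 98-90% (small drop, high baseline), 98-84% (medium), 98-75% (large) and
#' 88-80% (small drop, low baseline).
#'
#' @return A tibble with one row per paradigm: `name`, `agent`, `base_sat`,
#'   `target_sat`, `peak_mM`.
#' @export
dsc_paradigms <- function() {
  tibble::tibble(
    name = c("gd_standard", "dohb_98_90", "dohb_98_84", "dohb_98_75",
             "dohb_88_80"),
    agent = c("Gd", "dOHb", "dOHb", "dOHb", "dOHb"),
    base_sat = c(NA, 0.98, 0.98, 0.98, 0.88),
    target_sat = c(NA, 0.90, 0.84, 0.75, 0.80),
    peak_mM = c(2, NA, NA, NA, NA)
  )
}

#' Build the arterial inlet of a named paradigm
#'
#' @param name A paradigm name from [dsc_paradigms()], or a one-row tibble
#'   in the same format (custom paradigm).
#' @param grid Fine time grid.
#' @param onset Bolus arrival (s).
#' @param plateau_duration Hypoxic plateau width (s); ignored for
#'   gadolinium.
#' @param rise_tau Hypoxic smoothing time constant (s).
#' @param peak_mM Gadolinium peak concentration override (mM).
#' @return An `agent_bolus`.
#' @examples
#' inlet <- paradigm_inlet("dohb_98_75", time_grid(150))
#' @export
paradigm_inlet <- function(name, grid, onset = 10, plateau_duration = 30,
                           rise_tau = 5, peak_mM = NULL) {
  p <- if (is.data.frame(name)) {
    name
  } else {
    row <- dsc_paradigms()[dsc_paradigms()$name == name, ]
    if (nrow(row) == 0) stop("unknown paradigm: ", name, call. = FALSE)
    row
  }
  if (p$agent == "Gd") {
    gamma_variate_bolus(grid, a = if (is.null(peak_mM)) p$peak_mM else peak_mM,
                        onset = onset)
  } else {
    hypoxic_bolus(grid, base_sat = p$base_sat, target_sat = p$target_sat,
                  plateau_duration = plateau_duration, onset = onset,
                  rise_tau = rise_tau)
  }
}
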