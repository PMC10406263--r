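#' Physical and physiological constants of the signal model
#'
#' Bundles every constant the forward model needs: field strength,
#' gyromagnetic ratio, hematocrit, echo time, molar susceptibilities of the
#' two contrast agents, baseline transverse relaxation rates of the
#' extravascular (EES) and intravascular (IVS) compartments, and the
#' quadratic coefficient of the intravascular relaxation-rate dependence on
#' blood deoxygenation.
#'
#' The intravascular contrast contribution is quadratic in total
#' deoxygenation, `R2*_con_IVS = 181 * (1 - Y0 - dY)^2` (per second), a blood
#' phantom calibration at 3 T and Hct 0.4. Extravascular shifts are treated
#' as angular frequencies (rad/s) with `gamma = 2*pi*42.6e6` rad/s/T; the
#' vessel-class coefficients in [vessel_classes()] then carry units of
#' seconds so products are rates. This convention is isolated here so it can
#' be flipped wholesale if a cyclic-frequency convention is preferred.
#'
#' @param B0 Main field strength (tesla).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @param Hct Hematocrit fraction.
#' @param TE Echo time (seconds).
#' @param chi_dohb Susceptibility scale of fully deoxygenated blood (ppm).
#' @param chi_gd Molar susceptibility of gadolinium chelate (ppm/mM).
#' @param R2_0_EES Baseline extravascular relaxation rate (1/s).
#' @param R2_0_IVS Baseline intravascular relaxation rate for fully
#'   oxygenated blood (1/s).
#' @param ivs_quadratic_coeff Quadratic coefficient of the intravascular
#'   contrast relaxation rate (1/s per unit squared deoxygenation).
#'
#' @return A list of class `dsc_constants`.
#' @examples
#' k <- physics_constants()
#' pseudo_oxygenation(k) # ~0.246 saturation fraction per mM Gd
#' @export
physics_constants <- function(B0 = 3,
                              gamma = 2 * pi * 42.6e6,
                              Hct = 0.4,
                              TE = 0.030,
                              chi_dohb = 0.264,
                              chi_gd = 0.026,
                              R2_0_EES = 20.99,
                              R2_0_IVS = 13.8,
                              ivs_quadratic_coeff = 181) {
  k <- list(
    B0 = B0, gamma = gamma, Hct = Hct, TE = TE,
    chi_dohb = chi_dohb, chi_gd = chi_gd,
    R2_0_EES = R2_0_EES, R2_0_IVS = R2_0_IVS,
    ivs_quadratic_coeff = ivs_quadratic_coeff
  )
  bad <- vapply(k, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                logical(1))
  if (any(bad)) {
    stop("all physics constants must be positive scalars; offending: ",
         paste(names(k)[bad], collapse = ", "), call. = FALSE)
  }
  structure(k, class = "dsc_constants")
}

#' Saturation-change equivalent of 1 mM gadolinium (pseudo-oxygenation)
#'
#' The deoxyhemoglobin saturation change whose susceptibility (frequency
#' shift) effect equals that of 1 mM of gadolinium. Computed from the
#' configured constants as `chi_gd / (chi_dohb * Hct)` rather than
#' hard-coded, so changing the hematocrit keeps the two agents mutually
#' consistent. At the defaults (3 T, Hct 0.4) this is 0.24621, i.e. a 1 mM
#' gadolinium increase matches a 24.6% saturation drop.
#'
#' @param constants A [physics_constants()] list.
#' @return Saturation fraction per mM (positive scalar).
#' @export
pseudo_oxygenation <- function(constants = physics_constants()) {
  constants$chi_gd / (constants$chi_dohb * constants$Hct)
}

#' Convert gadolinium concentration to an equivalent saturation change
#'
#' Linear conversion `dY = -pseudo_oxygenation * [Gd]`: the signed
#' oxygenation change (negative, i.e. a deoxygenation) with the same
#' susceptibility effect as the given gadolinium concentration.
#'
#' @param gd_conc Gadolinium concentration(s), mM (non-negative).
#' @inheritParams pseudo_oxygenation
#' @return Signed saturation-change fraction(s), `<= 0`.
#' @examples
#' gd_to_dohb_equivalent(1) # -0.2462
#' @export
gd_to_dohb_equivalent <- function(gd_conc, constants = physics_constants()) {
  if (any(gd_conc < 0)) {
    stop("gadolinium concentration must be non-negative", call. = FALSE)
  }
  -pseudo_oxygenation(constants) * gd_conc
}

#' Extravascular relaxation-rate coefficients by vessel radius class
#'
#' Linear coefficients relating the blood-surface frequency shift (rad/s) to
#' the extravascular contrast relaxation rate contributed per one percent of
#' blood volume, for three vessel radius classes: 5 um capillaries,
#' 16-200 um vessels, and >=200 um vessels perpendicular to the field.
#'
#' @return A tibble with columns `class` and `ees_coeff` (seconds).
#' @export
vessel_classes <- function() {
  tibble::tibble(
    class = c("capillary_5um", "small_vessel_16_200um", "large_vessel_200um_90deg"),
    ees_coeff = c(0.0387, 0.0433, 0.0798)
  )
}

ees_coeff_for <- function(class) {
  vc <- vessel_classes()
  i <- match(class, vc$class)
  if (anyNA(i)) {
    stop("unknown vessel class: ",
         paste(unique(class[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  vc$ees_coeff[i]
}

#' Hematocrit correction factor for relative blood volume
#'
#' Gadolinium is confined to plasma, so its rCBV scaling is
#' `(1 - Hct) / (1 - 0.69 * Hct)`; deoxyhemoglobin is confined to the red
#' cells, giving `Hct / (0.69 * Hct) = 1/0.69`, independent of hematocrit.
#'
#' @param agent `"Gd"` or `"dOHb"`.
#' @param Hct Hematocrit fraction.
#' @return The scalar correction factor kappa.
#' @examples
#' kappa_factor("Gd")   # 0.8287
#' kappa_factor("dOHb") # 1.4493
#' @export
kappa_factor <- function(agent = c("Gd", "dOHb"), Hct = 0.4) {
  agent <- match.arg(agent)
  switch(agent,
    Gd = (1 - Hct) / (1 - 0.69 * Hct),
    dOHb = Hct / (0.69 * Hct)
  )
}
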