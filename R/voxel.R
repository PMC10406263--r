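#' Voxel models: vascular compartments of a simulated voxel
#'
#' A voxel model is a tibble of vascular compartments, each with a kind
#' (artery, arteriole, capillary, venule, vein), a percentage blood volume
#' `pcbv` (percent of voxel volume, *not* a fraction - the extravascular
#' coefficients are calibrated per one percent of CBV), a baseline oxygen
#' saturation `y0`, and a vessel radius class (see [vessel_classes()]).
#' The voxel label (`arterial`, `venous`, `GM`, `WM`, `CSF`) decides which
#' transport its compartments receive.
#'
#' Presets follow the standard simulated voxel properties: a dedicated
#' arterial or venous voxel is a single large-vessel (90 degrees to the
#' field) compartment at CBV 10-100% with baseline saturation 1.0 (artery)
#' or 0.60 (vein). A tissue voxel (GM ~4%, WM ~2% total CBV) splits its
#' blood volume 1:2:2 into an arterial/arteriolar part (divided equally
#' between artery at `y0 = 1.00` and arteriole at 0.95), a capillary part
#' (0.775), and a venous part (divided equally between venule and vein at
#' 0.60); capillaries use the 5 um radius class and all other tissue
#' vessels the 16-200 um class.
#'
#' @param compartments A tibble with columns `kind`, `pcbv`, `y0`,
#'   `vessel_class`.
#' @param label Voxel label: `"arterial"`, `"venous"`, `"GM"`, `"WM"`,
#'   `"CSF"`.
#' @return A `voxel_model` tibble.
#' @examples
#' voxel_tissue(cbv = 4, label = "GM")
#' voxel_arterial(cbv = 100)
#' @name voxel_model
NULL

#' @rdname voxel_model
#' @export
voxel_model <- function(compartments, label) {
  label <- match.arg(label, c("arterial", "venous", "GM", "WM", "CSF"))
  stopifnot(all(c("kind", "pcbv", "y0", "vessel_class") %in%
                  names(compartments)))
  if (any(compartments$pcbv < 0)) stop("pcbv must be >= 0", call. = FALSE)
  if (any(compartments$y0 < 0 | compartments$y0 > 1)) {
    stop("y0 must lie in [0, 1]", call. = FALSE)
  }
  total <- sum(compartments$pcbv)
  if (total > 100 + 1e-9) {
    stop("total CBV exceeds 100%", call. = FALSE)
  }
  ees_coeff_for(compartments$vessel_class) # validates classes
  out <- tibble::as_tibble(compartments)
  attr(out, "label") <- label
  attr(out, "total_cbv") <- total
  class(out) <- c("voxel_model", class(out))
  out
}

voxel_label <- function(voxel) attr(voxel, "label")
voxel_total_cbv <- function(voxel) attr(voxel, "total_cbv")

#' @rdname voxel_model
#' @param cbv Total voxel blood volume, percent.
#' @param y0 Baseline saturation of the blood compartment (dedicated
#'   arterial/venous voxels only).
#' @export
voxel_arterial <- function(cbv = 100, y0 = 1) {
  voxel_model(tibble::tibble(kind = "artery", pcbv = cbv, y0 = y0,
                             vessel_class = "large_vessel_200um_90deg"),
              "arterial")
}

#' @rdname voxel_model
#' @export
voxel_venous <- function(cbv = 100, y0 = 0.60) {
  voxel_model(tibble::tibble(kind = "vein", pcbv = cbv, y0 = y0,
                             vessel_class = "large_vessel_200um_90deg"),
              "venous")
}

#' @rdname voxel_model
#' @export
voxel_tissue <- function(cbv = 4, label = c("GM", "WM")) {
  label <- match.arg(label)
  part <- cbv / 5 # 1:2:2 split
  voxel_model(tibble::tibble(
    kind = c("artery", "arteriole", "capillary", "venule", "vein"),
    pcbv = c(part / 2, part / 2, 2 * part, part, part),
    y0 = c(1.00, 0.95, 0.775, 0.60, 0.60),
    vessel_class = c("small_vessel_16_200um", "small_vessel_16_200um",
                     "capillary_5um", "small_vessel_16_200um",
                     "small_vessel_16_200um")
  ), label)
}

#' @rdname voxel_model
#' @export
voxel_csf <- function() {
  voxel_model(tibble::tibble(kind = character(), pcbv = numeric(),
                             y0 = numeric(), vessel_class = character()),
              "CSF")
}

#' Default voxel library
#'
#' Named list of the standard simulated voxels: dedicated artery and vein at
#' CBV 100%, GM at 4%, WM at 2%, and CSF.
#'
#' @return A named list of `voxel_model`s.
#' @export
voxel_library <- function() {
  list(
    arterial = voxel_arterial(),
    venous = voxel_venous(),
    GM = voxel_tissue(4, "GM"),
    WM = voxel_tissue(2, "WM"),
    CSF = voxel_csf()
  )
}

# Replace the fully arterial baseline (y0 == 1) by the paradigm's baseline
# saturation. Hypoxic paradigms start from a base saturation below 1 (e.g.
# 0.98), which the dedicated arterial voxel and the arterial compartment of
# tissue share; venous baselines stay at their own value.
apply_baseline_saturation <- function(voxel, base_sat) {
  if (is.null(base_sat) || nrow(voxel) == 0) return(voxel)
  voxel$y0[voxel$y0 >= 1] <- base_sat
  voxel
}
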