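#' Cell geometry
#'
#' Cylindrical single-cell morphology of an isolated detrusor smooth muscle
#' cell. Only the lateral (side-wall) surface carries membrane in the
#' single-compartment convention; end caps are excluded.
#'
#' @param length_um Cylinder length in micrometres.
#' @param diameter_um Cylinder diameter in micrometres.
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry(200, 6)
#' lateral_area(geom)
#' @export
cell_geometry <- function(length_um = 200, diameter_um = 6) {
  if (!is.numeric(length_um) || length(length_um) != 1L || !is.finite(length_um) ||
      length_um <= 0) {
    stop("invalid geometry: `length_um` must be a single positive number")
  }
  if (!is.numeric(diameter_um) || length(diameter_um) != 1L ||
      !is.finite(diameter_um) || diameter_um <= 0) {
    stop("invalid geometry: `diameter_um` must be a single positive number")
  }
  structure(list(length_um = length_um, diameter_um = diameter_um),
            class = "cell_geometry")
}

#' Passive membrane properties
#'
#' Specific (per-area) passive electrical constants. Cytoplasmic resistivity
#' is stored for configuration fidelity but carries no axial current in a
#' single compartment.
#'
#' @param c_specific_uF_cm2 Specific membrane capacitance, uF/cm^2.
#' @param r_membrane_kohm_cm2 Specific membrane resistivity, kOhm*cm^2.
#' @param r_cytoplasm_ohm_cm Cytoplasmic resistivity, Ohm*cm.
#' @return An object of class `passive_properties`.
#' @export
passive_properties <- function(c_specific_uF_cm2 = 1,
                               r_membrane_kohm_cm2 = 138,
                               r_cytoplasm_ohm_cm = 183) {
  vals <- c(c_specific_uF_cm2, r_membrane_kohm_cm2, r_cytoplasm_ohm_cm)
  if (!is.numeric(vals) || length(vals) != 3L || any(!is.finite(vals)) ||
      any(vals <= 0)) {
    stop("invalid passive properties: all values must be strictly positive")
  }
  structure(list(c_specific_uF_cm2 = c_specific_uF_cm2,
                 r_membrane_kohm_cm2 = r_membrane_kohm_cm2,
                 r_cytoplasm_ohm_cm = r_cytoplasm_ohm_cm),
            class = "passive_properties")
}

#' Lateral membrane area
#'
#' Open-cylinder lateral surface, `pi * diameter * length`, in cm^2.
#'
#' @param geom A [cell_geometry()].
#' @return Area in cm^2.
#' @export
lateral_area <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  # um^2 -> cm^2: 1 um = 1e-4 cm
  pi * geom$diameter_um * geom$length_um * 1e-8
}

#' Total membrane capacitance
#'
#' @param geom A [cell_geometry()].
#' @param passive A [passive_properties()].
#' @return Capacitance in pF.
#' @export
total_capacitance <- function(geom, passive) {
  stopifnot(inherits(passive, "passive_properties"))
  # uF/cm^2 * cm^2 = uF; 1 uF = 1e6 pF
  passive$c_specific_uF_cm2 * lateral_area(geom) * 1e6
}

#' Leak conductance density implied by the membrane resistivity
#'
#' @param passive A [passive_properties()].
#' @return Conductance density in S/cm^2.
#' @export
leak_conductance_density <- function(passive) {
  stopifnot(inherits(passive, "passive_properties"))
  # 1 / (kOhm*cm^2) = 1e-3 S/cm^2
  1e-3 / passive$r_membrane_kohm_cm2
}
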