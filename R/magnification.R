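# Bennett ocular magnification correction for fundus-image area measures.

#' Bennett magnification constants
#'
#' Constants of the Bennett correction for the ocular magnification of the
#' imaging system: true area = measured area x (camera^2 x scale^2 x
#' (AL - nodal_offset)^2), with AL the axial length in mm. The defaults are
#' the standard values for the Cirrus HD-OCT (camera constant 3.382,
#' scale constant 0.01306 per mm, nodal-point offset 1.82 mm).
#'
#' @param camera_constant Dimensionless camera constant.
#' @param scale_constant Per-mm scale constant.
#' @param nodal_offset Nodal-point offset in mm; axial length must exceed it.
#' @return A named list of class `bennett_constants`.
#' @export
bennett_constants <- function(camera_constant = 3.382,
                              scale_constant = 0.01306,
                              nodal_offset = 1.82) {
  check_number(camera_constant, "camera_constant", lower = 1e-12)
  check_number(scale_constant, "scale_constant", lower = 1e-12)
  check_number(nodal_offset, "nodal_offset", lower = 1e-12)
  structure(list(camera_constant = camera_constant,
                 scale_constant = scale_constant,
                 nodal_offset = nodal_offset),
            class = "bennett_constants")
}

#' Bennett magnification correction factor
#'
#' The multiplicative factor converting a measured area to true area at a
#' given axial length. It equals 1 exactly at
#' AL = nodal_offset + 1 / (camera_constant x scale_constant), about
#' 24.46 mm with the default constants, and is strictly increasing in AL.
#'
#' @param axial_length Axial length(s) in mm; must exceed the nodal offset.
#' @param constants A [bennett_constants()] list.
#' @return Numeric vector of correction factors.
#' @export
bennett_correction_factor <- function(axial_length,
                                      constants = bennett_constants()) {
  stopifnot(inherits(constants, "bennett_constants"))
  if (any(!is.na(axial_length) & axial_length <= constants$nodal_offset)) {
    abort(paste0("axial_length must exceed the nodal offset (",
                 constants$nodal_offset, " mm)"))
  }
  (constants$camera_constant^2) * (constants$scale_constant^2) *
    (axial_length - constants$nodal_offset)^2
}

#' Bennett-corrected area
#'
#' Converts instrument-measured optic-disc area to true area using axial
#' length: corrected = measured x (3.382^2 x 0.01306^2 x (AL - 1.82)^2)
#' with the default constants. Exact arithmetic, no rounding; linear in the
#' measured area.
#'
#' @param measured_area Measured area(s) in mm^2, non-negative.
#' @param axial_length Axial length(s) in mm, greater than the nodal offset.
#' @param constants A [bennett_constants()] list.
#' @return Corrected area(s) in mm^2.
#' @export
bennett_corrected_area <- function(measured_area, axial_length,
                                   constants = bennett_constants()) {
  if (any(!is.na(measured_area) & measured_area < 0)) {
    abort("measured_area must be non-negative")
  }
  measured_area * bennett_correction_factor(axial_length, constants)
}

#' Add the magnification-corrected disc area to a cohort
#'
#' Computes `disc_area_corrected` from `disc_area_measured` and
#' `axial_length`, storing it alongside (never overwriting) the measured
#' value.
#'
#' @param cohort A cohort tibble with `disc_area_measured` and
#'   `axial_length` columns.
#' @param constants A [bennett_constants()] list.
#' @return The cohort with a `disc_area_corrected` column.
#' @export
add_corrected_disc_area <- function(cohort, constants = bennett_constants()) {
  stopifnot(is.data.frame(cohort))
  need <- setdiff(c("disc_area_measured", "axial_length"), names(cohort))
  if (length(need)) {
    abort(paste0("cohort lacks column(s): ", paste(need, collapse = ", ")))
  }
  dplyr::mutate(
    tibble::as_tibble(cohort),
    disc_area_corrected = bennett_corrected_area(
      .data$disc_area_measured, .data$axial_length, constants
    )
  )
}
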