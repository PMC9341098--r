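# Littmann-Bennett transverse magnification. The true linear dimension on
# the fundus is D_t = p * q * D_m with q = 0.01306 * (AL - 1.82): p is the
# instrument factor (device-specific), q the ocular factor, AL the axial
# length in mm, and 1.82 mm a constant related to the distance between the
# corneal apex and the eye's second principal plane. Areas scale with the
# square of the linear factor.

LITTMANN_Q_SLOPE <- 0.01306
LITTMANN_Q_OFFSET <- 1.82

#' OCTA device profile
#'
#' A device profile holds the instrument magnification factor `p` (the value
#' making measured equal true at the instrument's assumed axial length) and
#' that reference axial length. [rtvue_avanti()] returns the bundled profile
#' for the Optovue RTVue XR Avanti (p = 3.48, reference AL 23.95 mm, 3-mm
#' scan); no other vendor constants are bundled.
#'
#' @param name Device name.
#' @param p_factor Instrument magnification factor, unitless, positive.
#' @param reference_al Axial length at which measured = true, mm; must
#'   exceed the Littmann offset 1.82 mm.
#' @param scan_width Nominal scan field, mm, or `NULL` if not needed.
#' @return An object of class `device_profile`.
#' @examples
#' rtvue_avanti()
#' @export
device_profile <- function(name, p_factor, reference_al, scan_width = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(p_factor) || p_factor <= 0) {
    stop("`p_factor` must be positive.", call. = FALSE)
  }
  if (!is.numeric(reference_al) || reference_al <= LITTMANN_Q_OFFSET) {
    stop(sprintf("`reference_al` must exceed %.2f mm.", LITTMANN_Q_OFFSET),
         call. = FALSE)
  }
  if (!is.null(scan_width) && (!is.numeric(scan_width) || scan_width <= 0)) {
    stop("`scan_width` must be positive if given.", call. = FALSE)
  }
  structure(
    list(name = name, p_factor = p_factor, reference_al = reference_al,
         scan_width = scan_width),
    class = "device_profile"
  )
}

#' @rdname device_profile
#' @export
rtvue_avanti <- function() {
  device_profile("RTVue XR Avanti", p_factor = 3.48, reference_al = 23.95,
                 scan_width = 3)
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("Device profile: %s\n", x$name))
  cat(sprintf("  p factor: %.4g   reference AL: %.2f mm\n",
              x$p_factor, x$reference_al))
  if (!is.null(x$scan_width)) {
    cat(sprintf("  scan width: %g mm\n", x$scan_width))
  }
  invisible(x)
}

#' Ocular magnification factor q
#'
#' Littmann-Bennett ocular factor q = 0.01306 * (AL - 1.82). The constants
#' are fixed model parameters; override them only if you know your
#' schematic-eye convention differs.
#'
#' @param al Axial length, mm; must exceed `q_offset`. Vectorised.
#' @param q_slope,q_offset Littmann constants (expert override only).
#' @return Ocular magnification factor, unitless.
#' @examples
#' ocular_magnification_q(23.95)
#' @export
ocular_magnification_q <- function(al, q_slope = LITTMANN_Q_SLOPE,
                                   q_offset = LITTMANN_Q_OFFSET) {
  if (any(!is.finite(al) | al <= q_offset)) {
    stop(errorCondition(
      sprintf("Axial length must exceed the Littmann constant %.2f mm.", q_offset),
      class = c("ocumag_invalid_axial_length", "error", "condition")))
  }
  q_slope * (al - q_offset)
}

# Linear scale applied to measured dimensions. mode "littmann" is the
# standard p*q product; mode "ratio" rescales by q(al)/q(reference_al),
# which is exactly 1 at the device reference AL (p*q is only approximately
# 1 there with the published p).
linear_scale <- function(device, al, mode = c("littmann", "ratio")) {
  stopifnot(inherits(device, "device_profile"))
  mode <- match.arg(mode)
  q <- ocular_magnification_q(al)
  if (mode == "littmann") {
    device$p_factor * q
  } else {
    q / ocular_magnification_q(device$reference_al)
  }
}

#' True linear dimension on the fundus
#'
#' Corrects a measured linear fundus dimension for transverse magnification:
#' D_t = p * q(AL) * D_m.
#'
#' @param d_measured Measured linear dimension, mm; non-negative.
#' @param device A [device_profile()].
#' @param al Axial length used for correction, mm.
#' @param mode `"littmann"` (default) uses the p * q product; `"ratio"`
#'   uses q(AL)/q(reference AL), which is exactly 1 at the device's
#'   reference axial length.
#' @return True linear dimension, mm.
#' @examples
#' true_linear_dimension(1.0, rtvue_avanti(), al = 23.95)
#' @export
true_linear_dimension <- function(d_measured, device, al,
                                  mode = c("littmann", "ratio")) {
  if (any(d_measured < 0, na.rm = TRUE)) {
    stop("`d_measured` must be non-negative.", call. = FALSE)
  }
  linear_scale(device, al, mode) * d_measured
}

#' Correct an area measurement for transverse magnification
#'
#' Areas scale with the square of the linear magnification factor:
#' A_t = (p * q(AL))^2 * A_m. This is the correction applied to the foveal
#' avascular zone area.
#'
#' @param area_measured Measured area, mm^2; non-negative.
#' @inheritParams true_linear_dimension
#' @return Corrected (true) area, mm^2.
#' @examples
#' correct_area(0.25, rtvue_avanti(), al = 23.95)
#' @export
correct_area <- function(area_measured, device, al,
                         mode = c("littmann", "ratio")) {
  if (any(area_measured < 0, na.rm = TRUE)) {
    stop("`area_measured` must be non-negative.", call. = FALSE)
  }
  linear_scale(device, al, mode)^2 * area_measured
}

#' On-retina pixel pitch of a corrected scan
#'
#' True sampling pitch of the en-face image after magnification correction:
#' (p * q(AL) * scan width) / pixels across. Useful for rescaling images or
#' converting pixel counts to mm.
#'
#' @inheritParams true_linear_dimension
#' @param pixels_across Number of pixels across the scan; positive integer.
#' @return Pixel pitch, mm per pixel.
#' @examples
#' pixel_scale(rtvue_avanti(), al = 23.95, pixels_across = 304)
#' @export
pixel_scale <- function(device, al, pixels_across,
                        mode = c("littmann", "ratio")) {
  stopifnot(inherits(device, "device_profile"))
  if (is.null(device$scan_width)) {
    stop("Device profile `", device$name,
         "` has no scan_width; pixel_scale() needs one.", call. = FALSE)
  }
  if (any(pixels_across <= 0)) {
    stop("`pixels_across` must be positive.", call. = FALSE)
  }
  linear_scale(device, al, mode) * device$scan_width / pixels_across
}

#' Full correction result for one measurement
#'
#' Bundles the ocular factor, linear and area scales and the corrected
#' value for a single measurement, recording whether the axial length used
#' was measured or estimated.
#'
#' @inheritParams true_linear_dimension
#' @param value Measured value (mm for `type = "linear"`, mm^2 for
#'   `type = "area"`).
#' @param type `"area"` or `"linear"`.
#' @param al_source `"actual"` or `"estimated"` - provenance of `al`,
#'   carried into reports.
#' @return A list of class `correction_result` with elements `q`,
#'   `linear_scale`, `area_scale`, `corrected_value`, `al_source`.
#' @export
correct_measurement <- function(value, device, al, type = c("area", "linear"),
                                al_source = c("actual", "estimated"),
                                mode = c("littmann", "ratio")) {
  type <- match.arg(type)
  al_source <- match.arg(al_source)
  q <- ocular_magnification_q(al)
  ls <- linear_scale(device, al, mode)
  corrected <- if (type == "area") ls^2 * value else ls * value
  structure(
    list(q = q, linear_scale = ls, area_scale = ls^2,
         corrected_value = corrected, al_source = al_source),
    class = "correction_result"
  )
}

#' Read a device-profile registry from JSON
#'
#' The registry is a JSON array of objects with keys `name`, `p_factor`,
#' `reference_al_mm` and optionally `scan_width_mm`. Unknown keys are
#' rejected so typos do not silently become defaults.
#'
#' @param path Path to the registry JSON file.
#' @return A named list of [device_profile()] objects, keyed by name.
#' @export
read_device_registry <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(entries) == 0) stop("Device registry is empty.", call. = FALSE)
  allowed <- c("name", "p_factor", "reference_al_mm", "scan_width_mm")
  profiles <- lapply(entries, function(e) {
    unknown <- setdiff(names(e), allowed)
    if (length(unknown) > 0) {
      stop("Unknown key(s) in device registry entry: ",
           paste(unknown, collapse = ", "),
           ". Allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
    }
    required <- c("name", "p_factor", "reference_al_mm")
    miss <- setdiff(required, names(e))
    if (length(miss) > 0) {
      stop("Device registry entry missing key(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    device_profile(e$name, e$p_factor, e$reference_al_mm,
                   scan_width = e$scan_width_mm)
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  profiles
}

# Resolve a device argument: a device_profile, a bundled name, or a path to
# a registry JSON (optionally "path#name").
resolve_device <- function(device) {
  if (inherits(device, "device_profile")) return(device)
  stopifnot(is.character(device), length(device) == 1)
  bundled <- list("RTVue XR Avanti" = rtvue_avanti())
  if (device %in% names(bundled)) return(bundled[[device]])
  if (file.exists(device)) {
    reg <- read_device_registry(device)
    if (length(reg) == 1) return(reg[[1]])
    stop("Registry `", device, "` has multiple devices; pass a profile ",
         "selected from read_device_registry().", call. = FALSE)
  }
  stop("Unknown device `", device, "`. Pass a device_profile, the name of ",
       "a bundled device (", paste(names(bundled), collapse = ", "),
       "), or a registry JSON path.", call. = FALSE)
}
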