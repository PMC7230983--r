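#' Relative membrane-area increase upon adhesion of two identical vesicles
#'
#' Two identical spherical vesicles that adhere deform into truncated spheres
#' sharing a flat adhesion patch. At fixed encapsulated volume the membrane
#' area of each vesicle (curved cap plus its share of the flat patch) exceeds
#' the original sphere area. The closed form for the fractional increase is
#'
#' \deqn{f(\vartheta) = \frac{3 - \cos\vartheta}
#'   {2^{2/3}\,(1+\cos\vartheta)^{1/3}\,(2-\cos\vartheta)^{2/3}} - 1}
#'
#' where \eqn{\vartheta} is the contact angle, the arcsine of the adhesion
#' patch diameter normalised by the vesicle diameter. The model is derived
#' for identical vesicles and patches no larger than the equator, so
#' \eqn{\vartheta \in [0, \pi/2]}.
#'
#' @param contact_angle Contact angle in radians (see [deg_to_rad()]),
#'   in \eqn{[0, \pi/2]}. Vectorised.
#' @return Dimensionless area-increase fraction(s), \eqn{\ge 0}.
#' @examples
#' area_increase_fraction(deg_to_rad(40)) # about 0.012, i.e. ~1 %
#' @export
area_increase_fraction <- function(contact_angle) {
  stopifnot(is.numeric(contact_angle))
  if (any(contact_angle < 0 | contact_angle > pi / 2 + 1e-12)) {
    stop("contact_angle must lie in [0, pi/2]: the truncated-sphere model ",
         "is only valid for adhesion patches up to the equator", call. = FALSE)
  }
  ct <- cos(pmin(contact_angle, pi / 2))
  (3 - ct) / (2^(2 / 3) * (1 + ct)^(1 / 3) * (2 - ct)^(2 / 3)) - 1
}

#' Contact angle from adhesion patch and vesicle diameter
#'
#' The contact angle is defined as the arcsine of the adhesion patch diameter
#' normalised with respect to the vesicle diameter.
#'
#' @param patch_diameter Adhesion patch diameter (same length unit as
#'   `vesicle_diameter`).
#' @param vesicle_diameter Vesicle diameter, > 0.
#' @return Contact angle in radians, in \eqn{[0, \pi/2]}.
#' @examples
#' rad_to_deg(contact_angle_from_patch(5 * sin(deg_to_rad(40)), 5)) # 40
#' @export
contact_angle_from_patch <- function(patch_diameter, vesicle_diameter) {
  stopifnot(is.numeric(patch_diameter), is.numeric(vesicle_diameter))
  if (any(vesicle_diameter <= 0)) {
    stop("vesicle_diameter must be > 0", call. = FALSE)
  }
  if (any(patch_diameter < 0)) {
    stop("patch_diameter must be >= 0", call. = FALSE)
  }
  if (any(patch_diameter > vesicle_diameter * (1 + 1e-12))) {
    stop("patch_diameter cannot exceed vesicle_diameter", call. = FALSE)
  }
  asin(pmin(patch_diameter / vesicle_diameter, 1))
}

#' Adhesion patch diameter from contact angle
#'
#' Inverse of [contact_angle_from_patch()]:
#' patch diameter = vesicle diameter \eqn{\times \sin\vartheta}.
#'
#' @param contact_angle Contact angle in radians, in \eqn{[0, \pi/2]}.
#' @param vesicle_diameter Vesicle diameter, > 0.
#' @return Patch diameter in the unit of `vesicle_diameter`.
#' @export
patch_diameter_from_angle <- function(contact_angle, vesicle_diameter) {
  stopifnot(is.numeric(contact_angle), is.numeric(vesicle_diameter))
  if (any(contact_angle < 0 | contact_angle > pi / 2 + 1e-12)) {
    stop("contact_angle must lie in [0, pi/2]", call. = FALSE)
  }
  if (any(vesicle_diameter <= 0)) {
    stop("vesicle_diameter must be > 0", call. = FALSE)
  }
  vesicle_diameter * sin(contact_angle)
}

#' Membrane mechanical parameters
#'
#' Currently holds the area expansion modulus \eqn{K_A} that links membrane
#' tension increase to relative area strain. The default, 200 mJ/m^2, is a
#' typical value for fluid phospholipid bilayers.
#'
#' @param area_expansion_modulus_mj_m2 Area expansion modulus in mJ/m^2
#'   (equivalently mN/m), > 0.
#' @return An object of class `membrane_mechanics`.
#' @export
membrane_mechanics <- function(area_expansion_modulus_mj_m2 = 200) {
  stopifnot(is.numeric(area_expansion_modulus_mj_m2),
            length(area_expansion_modulus_mj_m2) == 1)
  if (area_expansion_modulus_mj_m2 <= 0) {
    stop("area expansion modulus must be > 0", call. = FALSE)
  }
  structure(list(area_expansion_modulus_mj_m2 = area_expansion_modulus_mj_m2),
            class = "membrane_mechanics")
}

#' @export
print.membrane_mechanics <- function(x, ...) {
  cat("Membrane mechanics: K_A =", x$area_expansion_modulus_mj_m2, "mJ/m^2\n")
  invisible(x)
}

#' Membrane tension increase from area strain
#'
#' Linear-elastic stretching response:
#' \eqn{\Delta\tau = K_A \, \Delta A / A_0}, reported in uN/m
#' (1 mJ/m^2 strain response = 1000 uN/m). The low-tension entropic
#' (logarithmic) regime is not modelled.
#'
#' @param mechanics A [membrane_mechanics()] object.
#' @param area_fraction Relative area increase \eqn{\Delta A/A_0 \ge 0},
#'   e.g. from [area_increase_fraction()]. Vectorised.
#' @return Tension increase(s) in uN/m.
#' @examples
#' tension_increase(membrane_mechanics(200), 1e-4) # 20 uN/m
#' @export
tension_increase <- function(mechanics, area_fraction) {
  stopifnot(inherits(mechanics, "membrane_mechanics"),
            is.numeric(area_fraction))
  if (any(area_fraction < 0)) {
    stop("area_fraction must be >= 0", call. = FALSE)
  }
  mechanics$area_expansion_modulus_mj_m2 * area_fraction * 1000
}

#' Construct an adhered vesicle pair
#'
#' Validates the truncated-sphere adhesion model's assumptions: the two
#' vesicles must be identical in size (the closed-form geometry is derived
#' only for that case; unequal sizes are rejected rather than approximated),
#' and the patch diameter must equal vesicle diameter times
#' \eqn{\sin\vartheta}.
#'
#' @param vesicle_a,vesicle_b [vesicle()] objects of equal radius.
#' @param contact_angle Contact angle in radians, in \eqn{[0, \pi/2]}.
#' @return An object of class `adhesion_pair` with fields `vesicle_a`,
#'   `vesicle_b`, `contact_angle` (radians) and `patch_diameter_um`.
#' @export
adhesion_pair <- function(vesicle_a, vesicle_b, contact_angle) {
  stopifnot(inherits(vesicle_a, "vesicle"), inherits(vesicle_b, "vesicle"))
  if (abs(vesicle_a$radius_um - vesicle_b$radius_um) >
      1e-9 * max(vesicle_a$radius_um, vesicle_b$radius_um)) {
    stop("unsupported case: the adhesion model assumes identical vesicle ",
         "sizes; got radii ", vesicle_a$radius_um, " and ",
         vesicle_b$radius_um, " um", call. = FALSE)
  }
  if (contact_angle < 0 || contact_angle > pi / 2 + 1e-12) {
    stop("contact_angle must lie in [0, pi/2]", call. = FALSE)
  }
  structure(list(
    vesicle_a = vesicle_a,
    vesicle_b = vesicle_b,
    contact_angle = contact_angle,
    patch_diameter_um = patch_diameter_from_angle(contact_angle,
                                                  2 * vesicle_a$radius_um)
  ), class = "adhesion_pair")
}

#' Degree/radian conversion helpers
#'
#' All package functions take and return angles in radians; experimental
#' contact angles are usually quoted in degrees.
#'
#' @param degrees,radians Angle(s) to convert.
#' @return Converted angle(s).
#' @export
deg_to_rad <- function(degrees) degrees * pi / 180

#' @rdname deg_to_rad
#' @export
rad_to_deg <- function(radians) radians * 180 / pi
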