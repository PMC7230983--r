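#' Construct a giant unilamellar vesicle record
#'
#' A GUV is described by its radius, ternary lipid composition, internal and
#' external solute mixtures, an optional membrane tension, and flags for
#' excess membrane area (tubules) and gold-nanoparticle labelling.
#'
#' @param radius_um Vesicle radius in micrometres, > 0. The study's vesicles
#'   are around 5 um in diameter (radius ~2.5 um).
#' @param composition A [ternary_composition()].
#' @param internal_solution,external_solution [solute_mixture()] objects.
#' @param tension_un_m Optional membrane tension in uN/m, >= 0.
#' @param has_excess_area Logical: flaccid vesicle with excess membrane
#'   area/tubules.
#' @param aunp_labelled Logical: membrane carries streptavidin-coated gold
#'   nanoparticles.
#' @return An object of class `vesicle`.
#' @export
vesicle <- function(radius_um,
                    composition = ternary_composition(1, 1, 1),
                    internal_solution = solute_mixture(sucrose = 0.75),
                    external_solution = solute_mixture(glucose = 0.35,
                                                       nacl = 0.2),
                    tension_un_m = NULL,
                    has_excess_area = FALSE,
                    aunp_labelled = FALSE) {
  stopifnot(is.numeric(radius_um), length(radius_um) == 1)
  if (!is.finite(radius_um) || radius_um <= 0) {
    stop("vesicle radius must be a positive finite number", call. = FALSE)
  }
  stopifnot(inherits(composition, "ternary_composition"),
            inherits(internal_solution, "solute_mixture"),
            inherits(external_solution, "solute_mixture"),
            is.logical(has_excess_area), is.logical(aunp_labelled))
  if (!is.null(tension_un_m)) {
    stopifnot(is.numeric(tension_un_m), length(tension_un_m) == 1)
    if (tension_un_m < 0) stop("tension must be >= 0", call. = FALSE)
  }
  structure(list(
    radius_um = radius_um,
    composition = composition,
    internal_solution = internal_solution,
    external_solution = external_solution,
    tension_un_m = tension_un_m,
    has_excess_area = has_excess_area,
    aunp_labelled = aunp_labelled
  ), class = "vesicle")
}

#' @export
print.vesicle <- function(x, ...) {
  ratio <- paste(to_integer_ratio(x$composition), collapse = ":")
  cat(sprintf("Vesicle: radius %.3g um, DOPC:EggSM:Chol %s, AuNP %s\n",
              x$radius_um, ratio, if (x$aunp_labelled) "yes" else "no"))
  invisible(x)
}

#' Vesicle volume and membrane area
#'
#' Spherical geometry: volume \eqn{4\pi R^3/3} (um^3) and area
#' \eqn{4\pi R^2} (um^2).
#'
#' @param v A [vesicle()] or a numeric radius in um.
#' @return Volume in um^3 / area in um^2.
#' @export
vesicle_volume_um3 <- function(v) {
  r <- if (inherits(v, "vesicle")) v$radius_um else v
  4 / 3 * pi * r^3
}

#' @rdname vesicle_volume_um3
#' @export
vesicle_area_um2 <- function(v) {
  r <- if (inherits(v, "vesicle")) v$radius_um else v
  4 * pi * r^2
}
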