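#' Construct a solute mixture
#'
#' A mixture is a set of solutes with molar concentrations and van't Hoff
#' dissociation factors (effective osmotically active particles per formula
#' unit). Known defaults: sucrose and glucose 1, NaCl 2; other solutes
#' default to 1 unless a factor is supplied.
#'
#' @param ... Named molar concentrations (M), e.g.
#'   `solute_mixture(glucose = 0.35, nacl = 0.2)`.
#' @param vant_hoff Optional named numeric vector of dissociation factors
#'   overriding the built-in defaults; factors must be >= 1.
#' @return An object of class `solute_mixture`: a data frame with columns
#'   `solute`, `conc_m`, `i`.
#' @examples
#' solute_mixture(sucrose = 0.75)
#' solute_mixture(glucose = 0.35, nacl = 0.2)
#' @export
solute_mixture <- function(..., vant_hoff = NULL) {
  conc <- c(...)
  if (length(conc) == 0) {
    out <- data.frame(solute = character(), conc_m = numeric(),
                      i = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("solute_mixture", class(out))
    return(out)
  }
  if (is.null(names(conc)) || any(names(conc) == "")) {
    stop("all solute concentrations must be named", call. = FALSE)
  }
  if (any(!is.finite(conc) | conc < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  defaults <- c(sucrose = 1, glucose = 1, nacl = 2)
  nm <- tolower(names(conc))
  i <- ifelse(nm %in% names(defaults), defaults[nm], 1)
  names(i) <- NULL
  if (!is.null(vant_hoff)) {
    stopifnot(is.numeric(vant_hoff), !is.null(names(vant_hoff)))
    if (any(vant_hoff < 1)) {
      stop("van't Hoff factors must be >= 1", call. = FALSE)
    }
    hit <- match(nm, tolower(names(vant_hoff)))
    i[!is.na(hit)] <- vant_hoff[hit[!is.na(hit)]]
  }
  out <- data.frame(solute = nm, conc_m = as.numeric(conc), i = i,
                    stringsAsFactors = FALSE)
  class(out) <- c("solute_mixture", class(out))
  out
}

#' Osmolarity of a solute mixture
#'
#' Van't Hoff bookkeeping: \eqn{\sum_j i_j c_j} in Osm/L. The study's
#' iso-osmotic external buffer (0.35 M glucose + 0.2 M NaCl) gives
#' 0.75 Osm/L, matching the 0.75 M sucrose interior.
#'
#' @param mixture A [solute_mixture()].
#' @return Osmolar concentration in Osm/L.
#' @examples
#' osmolarity(solute_mixture(glucose = 0.35, nacl = 0.2)) # 0.75
#' @export
osmolarity <- function(mixture) {
  stopifnot(inherits(mixture, "solute_mixture"))
  if (nrow(mixture) == 0) return(0)
  sum(mixture$i * mixture$conc_m)
}

#' Equilibrium volume ratio under an osmotic imbalance
#'
#' Ideal-osmometer rule for a solute-impermeable, water-permeable membrane:
#' water flows until internal osmolarity matches external, so
#' \eqn{V_{eq}/V_0 = \mathrm{Osm}_{int}/\mathrm{Osm}_{ext}}. Equal
#' osmolarities give 1; a hypertonic exterior gives < 1 (osmotic deflation,
#' leaving a flaccid, low-tension vesicle with excess membrane area).
#'
#' @param internal,external [solute_mixture()] objects; external osmolarity
#'   must be > 0.
#' @return Dimensionless equilibrium-to-initial volume ratio.
#' @examples
#' equilibrium_volume_ratio(solute_mixture(sucrose = 0.75),
#'                          solute_mixture(glucose = 0.4, nacl = 0.2)) # 0.9375
#' @export
equilibrium_volume_ratio <- function(internal, external) {
  osm_ext <- osmolarity(external)
  if (osm_ext <= 0) {
    stop("external osmolarity must be > 0 for the ideal-osmometer rule",
         call. = FALSE)
  }
  osmolarity(internal) / osm_ext
}

#' Radius of the vesicle formed by fusing two vesicles
#'
#' Fusion conserves the encapsulated volume, so the post-fusion radius is
#' \eqn{(r_1^3 + r_2^3)^{1/3}}.
#'
#' @param r1,r2 Input vesicle radii (same unit), >= 0, not both 0.
#'   Vectorised.
#' @return Post-fusion radius in the input unit.
#' @examples
#' fused_radius(2.5, 2.5) # 2^(1/3) * 2.5
#' @export
fused_radius <- function(r1, r2) {
  stopifnot(is.numeric(r1), is.numeric(r2))
  if (any(r1 < 0) || any(r2 < 0)) {
    stop("radii must be >= 0", call. = FALSE)
  }
  if (any(r1 == 0 & r2 == 0)) {
    stop("at least one radius must be > 0", call. = FALSE)
  }
  (r1^3 + r2^3)^(1 / 3)
}

#' Membrane-area deficit of volume-conserving fusion
#'
#' The post-fusion sphere has less membrane area than the two inputs
#' combined: the deficit fraction is
#' \eqn{1 - (r_1^3+r_2^3)^{2/3}/(r_1^2+r_2^2)}. It vanishes when one radius
#' is zero and is maximal for equal radii, where it equals
#' \eqn{1 - 2^{-1/3} \approx 0.206} — the "c. 20%" of membrane area freed
#' when two identical vesicles merge.
#'
#' @inheritParams fused_radius
#' @return Deficit fraction in \eqn{[0, 1 - 2^{-1/3}]}. Vectorised.
#' @examples
#' area_deficit(2.5, 2.5) # 1 - 2^(-1/3), about 0.206
#' @export
area_deficit <- function(r1, r2) {
  stopifnot(is.numeric(r1), is.numeric(r2))
  if (any(r1 < 0) || any(r2 < 0)) {
    stop("radii must be >= 0", call. = FALSE)
  }
  if (any(r1 == 0 & r2 == 0)) {
    stop("at least one radius must be > 0", call. = FALSE)
  }
  1 - (r1^3 + r2^3)^(2 / 3) / (r1^2 + r2^2)
}

#' Classify a laser-triggered fusion attempt as clean or disorderly
#'
#' Implements the observed outcome statistics as a two-regime Bernoulli
#' model. A fusion attempt requires the laser power at the trap to exceed a
#' threshold (default 150 mW); below it the event is rejected (no fusion).
#' Osmotically deflated pairs (internal/external equilibrium volume ratio
#' below 1) always fuse disorderly — pearling instabilities generate many
#' internal daughter vesicles. Iso-osmotic (or inflated) pairs fuse cleanly
#' with probability `clean_probability` (default 0.82, the observed clean
#' fraction over 50 events) and disorderly otherwise.
#'
#' The post-fusion vesicle is built with [fused_radius()] (volume conserved
#' to floating precision) and the composition mixed by ratio-part summation
#' ([mix_amounts()]); the freed-membrane budget is recorded as
#' [area_deficit()]. The number and sizes of internal daughter structures in
#' disorderly outcomes are not modelled.
#'
#' @param pair Either an [adhesion_pair()] or a list of two [vesicle()]
#'   objects (unequal sizes are allowed here: fusion bookkeeping, unlike the
#'   adhesion-geometry closed form, is size-general).
#' @param laser_power_mw Laser power at the trap in mW, >= 0.
#' @param osmotic_ratio Equilibrium volume ratio internal/external, e.g.
#'   from [equilibrium_volume_ratio()]. If `NULL`, computed from the first
#'   vesicle's solutions.
#' @param clean_probability Probability of a clean outcome under iso-osmotic
#'   conditions, in \[0, 1\]. Default 0.82.
#' @param rng_seed Optional integer seed; when given the draw is made under
#'   that seed without disturbing the global RNG state, making the event
#'   bit-reproducible.
#' @param fusion_threshold_mw Minimum power for fusion to initiate
#'   (default 150).
#' @param deflation_tolerance Ratios below `1 - deflation_tolerance` count
#'   as deflated (default 1e-6).
#' @return A `fusion_event` object: list with `outcome` ("clean",
#'   "disorderly" or "rejected"), `laser_power_mw`, `osmotic_ratio`,
#'   `post_fusion_vesicle` (NULL if rejected), `area_deficit`, `rng_seed`,
#'   and a `volume_audit` of input/output volumes.
#' @export
classify_fusion <- function(pair, laser_power_mw,
                            osmotic_ratio = NULL,
                            clean_probability = 0.82,
                            rng_seed = NULL,
                            fusion_threshold_mw = 150,
                            deflation_tolerance = 1e-6) {
  vs <- if (inherits(pair, "adhesion_pair")) {
    list(pair$vesicle_a, pair$vesicle_b)
  } else {
    pair
  }
  stopifnot(length(vs) == 2, inherits(vs[[1]], "vesicle"),
            inherits(vs[[2]], "vesicle"))
  if (!is.numeric(laser_power_mw) || laser_power_mw < 0) {
    stop("laser power must be >= 0", call. = FALSE)
  }
  if (!is.numeric(clean_probability) || clean_probability < 0 ||
      clean_probability > 1) {
    stop("clean_probability must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(osmotic_ratio)) {
    osmotic_ratio <- equilibrium_volume_ratio(vs[[1]]$internal_solution,
                                              vs[[1]]$external_solution)
  }

  r1 <- vs[[1]]$radius_um
  r2 <- vs[[2]]$radius_um
  if (laser_power_mw <= fusion_threshold_mw) {
    return(structure(list(
      outcome = "rejected", laser_power_mw = laser_power_mw,
      osmotic_ratio = osmotic_ratio, post_fusion_vesicle = NULL,
      area_deficit = NA_real_, rng_seed = rng_seed,
      volume_audit = c(volume_in_um3 = vesicle_volume_um3(r1) +
                         vesicle_volume_um3(r2),
                       volume_out_um3 = NA_real_)
    ), class = "fusion_event"))
  }

  if (osmotic_ratio < 1 - deflation_tolerance) {
    outcome <- "disorderly"
  } else {
    draw <- if (is.null(rng_seed)) {
      stats::runif(1)
    } else {
      withr::with_seed(rng_seed, stats::runif(1))
    }
    outcome <- if (draw < clean_probability) "clean" else "disorderly"
  }

  r_post <- fused_radius(r1, r2)
  post <- vesicle(
    radius_um = r_post,
    composition = mix_amounts(vs[[1]]$composition, 1, vs[[2]]$composition, 1),
    internal_solution = vs[[1]]$internal_solution,
    external_solution = vs[[1]]$external_solution,
    has_excess_area = outcome == "disorderly",
    aunp_labelled = vs[[1]]$aunp_labelled || vs[[2]]$aunp_labelled
  )
  structure(list(
    outcome = outcome, laser_power_mw = laser_power_mw,
    osmotic_ratio = osmotic_ratio, post_fusion_vesicle = post,
    area_deficit = area_deficit(r1, r2), rng_seed = rng_seed,
    volume_audit = c(volume_in_um3 = vesicle_volume_um3(r1) +
                       vesicle_volume_um3(r2),
                     volume_out_um3 = vesicle_volume_um3(r_post))
  ), class = "fusion_event")
}

#' @export
print.fusion_event <- function(x, ...) {
  cat(sprintf("Fusion event: %s (%.0f mW, osmotic ratio %.4g)\n",
              x$outcome, x$laser_power_mw, x$osmotic_ratio))
  if (!is.null(x$post_fusion_vesicle)) {
    cat(sprintf("  post-fusion radius %.4g um, area deficit %.1f%%\n",
                x$post_fusion_vesicle$radius_um, 100 * x$area_deficit))
  }
  invisible(x)
}
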