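#' Construct a ternary DOPC/EggSM/cholesterol composition
#'
#' Compositions are stored as non-negative ratio parts (e.g. 1:1:3) together
#' with derived mole fractions summing to 1. An optional fluorescent-probe
#' fraction (mol%) is carried as metadata only and takes no part in the
#' arithmetic.
#'
#' @param dopc,eggsm,chol Non-negative ratio parts; at least one > 0.
#' @param probe_molpct Optional fluorescent-lipid fraction in mol%
#'   (metadata).
#' @return An object of class `ternary_composition` with fields `amounts`
#'   (named numeric) and `fractions` (named, sums to 1).
#' @examples
#' ternary_composition(1, 1, 3)
#' @export
ternary_composition <- function(dopc, eggsm, chol, probe_molpct = NULL) {
  amounts <- c(dopc = dopc, eggsm = eggsm, chol = chol)
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    stop("composition amounts must be finite and >= 0", call. = FALSE)
  }
  if (sum(amounts) <= 0) {
    stop("at least one lipid amount must be > 0", call. = FALSE)
  }
  structure(list(
    amounts = amounts,
    fractions = amounts / sum(amounts),
    probe_molpct = probe_molpct
  ), class = "ternary_composition")
}

#' @export
print.ternary_composition <- function(x, ...) {
  cat("DOPC:EggSM:Chol", paste(signif(x$amounts, 6), collapse = ":"),
      sprintf("(fractions %.3f / %.3f / %.3f)\n",
              x$fractions[1], x$fractions[2], x$fractions[3]))
  invisible(x)
}

#' Mix two compositions by summing ratio parts
#'
#' The ratio-part rule: the mixed amounts are the weight-scaled
#' componentwise sums of the input amounts. With equal weights it reproduces
#' the expectation that fusing an identical-size 1:1:0 vesicle with a 1:1:3
#' vesicle yields a 2:2:3 membrane. Note this rule sums ratio parts as
#' written, so it is not mole-conserving when the inputs' ratios denote mole
#' fractions of different totals; see [mix_fractions()] for the
#' area-weighted alternative.
#'
#' @param c1,c2 [ternary_composition()] objects.
#' @param w1,w2 Positive mixing weights (default 1, i.e. equal parts).
#' @return The mixed `ternary_composition`.
#' @examples
#' mix_amounts(ternary_composition(1, 1, 0), 1,
#'             ternary_composition(1, 1, 3), 1) # 2:2:3
#' @export
mix_amounts <- function(c1, w1 = 1, c2, w2 = 1) {
  stopifnot(inherits(c1, "ternary_composition"),
            inherits(c2, "ternary_composition"))
  if (!is.numeric(w1) || !is.numeric(w2) || w1 <= 0 || w2 <= 0) {
    stop("mixing weights must be > 0", call. = FALSE)
  }
  a <- w1 * c1$amounts + w2 * c2$amounts
  ternary_composition(a[["dopc"]], a[["eggsm"]], a[["chol"]])
}

#' Mix two compositions by area-weighted mole fractions
#'
#' Physically consistent alternative to [mix_amounts()]: assuming equal area
#' per lipid molecule, the mixed mole fractions are the membrane-area
#' weighted average of the input fractions. Mixing 1:1:0 with 1:1:3 at equal
#' areas gives fractions (0.35, 0.35, 0.30), i.e. 7:7:6 — not the 2:2:3 of
#' the ratio-part rule.
#'
#' @param c1,c2 [ternary_composition()] objects.
#' @param area1,area2 Membrane areas (um^2), > 0.
#' @return The mixed `ternary_composition` (amounts set to the fractions).
#' @export
mix_fractions <- function(c1, area1, c2, area2) {
  stopifnot(inherits(c1, "ternary_composition"),
            inherits(c2, "ternary_composition"))
  if (!is.numeric(area1) || !is.numeric(area2) || area1 <= 0 || area2 <= 0) {
    stop("areas must be > 0", call. = FALSE)
  }
  f <- (area1 * c1$fractions + area2 * c2$fractions) / (area1 + area2)
  ternary_composition(f[["dopc"]], f[["eggsm"]], f[["chol"]])
}

#' Smallest integer ratio representing a composition
#'
#' Searches denominators up to `max_denominator` for the smallest integer
#' triple proportional to the composition within `tolerance` (relative, on
#' fractions), reduced by the greatest common divisor. If no small exact
#' ratio exists the fractions are rounded at the denominator bound.
#'
#' @param c A [ternary_composition()].
#' @param tolerance Relative tolerance (default 1e-6).
#' @param max_denominator Search bound (default 1000).
#' @return An integer vector `c(dopc, eggsm, chol)`.
#' @examples
#' to_integer_ratio(ternary_composition(2/7, 2/7, 3/7)) # 2 2 3
#' @export
to_integer_ratio <- function(c, tolerance = 1e-6, max_denominator = 1000) {
  stopifnot(inherits(c, "ternary_composition"))
  f <- c$fractions
  for (q in seq_len(max_denominator)) {
    k <- round(f * q)
    if (sum(k) == 0) next
    if (max(abs(k / sum(k) - f)) <= tolerance * max(f)) {
      return(as.integer(k / gcd3(k)))
    }
  }
  k <- round(f * max_denominator)
  as.integer(k / gcd3(k))
}

gcd3 <- function(k) {
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  pos <- k[k > 0]
  Reduce(gcd2, pos)
}

#' Convert barycentric lipid fractions to ternary-plot Cartesian coordinates
#'
#' Convention: (DOPC, EggSM, Chol) map to the bottom-left, bottom-right and
#' top vertices of a unit-edge triangle:
#' \eqn{x = (2\,\mathrm{EggSM} + \mathrm{Chol})/2},
#' \eqn{y = (\sqrt{3}/2)\,\mathrm{Chol}}.
#'
#' @param fractions Numeric length-3 (dopc, eggsm, chol) summing to 1, or an
#'   n x 3 matrix of such rows.
#' @return An n x 2 matrix of (x, y).
#' @export
barycentric_to_cartesian <- function(fractions) {
  m <- if (is.matrix(fractions)) fractions else matrix(fractions, nrow = 1)
  stopifnot(ncol(m) == 3)
  cbind(x = (2 * m[, 2] + m[, 3]) / 2, y = sqrt(3) / 2 * m[, 3])
}

#' @rdname barycentric_to_cartesian
#' @param xy An n x 2 matrix or length-2 vector of Cartesian coordinates.
#' @export
cartesian_to_barycentric <- function(xy) {
  m <- if (is.matrix(xy)) xy else matrix(xy, nrow = 1)
  stopifnot(ncol(m) == 2)
  chol <- m[, 2] * 2 / sqrt(3)
  eggsm <- (2 * m[, 1] - chol) / 2
  cbind(dopc = 1 - eggsm - chol, eggsm = eggsm, chol = chol)
}

#' Load a ternary phase diagram from JSON
#'
#' A phase diagram is a list of labelled polygonal regions over the ternary
#' simplex, each with vertices given as barycentric (dopc, eggsm, chol)
#' triples, plus a provenance string. Region labels are one of
#' `gel_liquid_coexistence`, `uniform_liquid`, `Lo_Ld_coexistence`, `other`.
#'
#' @param path Path to a diagram JSON file. The default loads the schematic
#'   diagram shipped with the package — an illustrative sketch, not an
#'   empirical diagram; supply a measured one for real compositional work.
#' @return An object of class `phase_diagram`.
#' @export
read_phase_diagram <- function(path = system.file("extdata",
                                                  "schematic_phase_diagram.json",
                                                  package = "vesifuse")) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels_ok <- c("gel_liquid_coexistence", "uniform_liquid",
                 "Lo_Ld_coexistence", "other")
  regions <- lapply(raw$regions, function(r) {
    if (!r$phase %in% labels_ok) {
      stop("unknown phase label: ", r$phase, call. = FALSE)
    }
    v <- matrix(unlist(r$vertices), ncol = 3, byrow = TRUE)
    if (nrow(v) < 3) stop("degenerate polygon in diagram", call. = FALSE)
    if (any(abs(rowSums(v) - 1) > 1e-9) || any(v < -1e-12)) {
      stop("diagram vertices must be barycentric triples summing to 1",
           call. = FALSE)
    }
    list(phase = r$phase, vertices = v)
  })
  structure(list(regions = regions,
                 provenance = raw$provenance %||% "unspecified"),
            class = "phase_diagram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phase_diagram <- function(x, ...) {
  cat("Ternary phase diagram:", length(x$regions), "regions\n")
  for (r in x$regions) cat("  -", r$phase, sprintf("(%d vertices)\n",
                                                   nrow(r$vertices)))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Look up the phase region of a composition
#'
#' Converts the composition's mole fractions to ternary-plot Cartesian
#' coordinates and classifies them against each region polygon in file
#' order; a point on a shared boundary is assigned to the region listed
#' first (deterministic tie-break). Points in no region return
#' `"unassigned"` — never a silent default.
#'
#' @param c A [ternary_composition()].
#' @param diagram A [read_phase_diagram()] object (default: the shipped
#'   schematic diagram).
#' @return A phase label string.
#' @examples
#' phase_lookup(ternary_composition(2, 2, 3)) # "Lo_Ld_coexistence"
#' @export
phase_lookup <- function(c, diagram = read_phase_diagram()) {
  stopifnot(inherits(c, "ternary_composition"),
            inherits(diagram, "phase_diagram"))
  p <- barycentric_to_cartesian(c$fractions)
  for (r in diagram$regions) {
    poly <- barycentric_to_cartesian(r$vertices)
    if (pracma::inpolygon(p[1], p[2], poly[, 1], poly[, 2],
                          boundary = TRUE)) {
      return(r$phase)
    }
  }
  "unassigned"
}
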