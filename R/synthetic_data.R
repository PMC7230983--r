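#' Specification for a synthetic vesicle population
#'
#' Describes the electroformed GUV preparation the generators emulate:
#' log-normally distributed diameters around a c. 5 um median, a set of
#' ternary compositions with assignment probabilities, sucrose interior
#' with glucose/NaCl exterior, and fractions of flaccid (excess-area) and
#' AuNP-labelled vesicles.
#'
#' @param n_vesicles Number of vesicles, >= 1.
#' @param diameter_median_um Median diameter in um (default 5).
#' @param diameter_sdlog Log-normal shape parameter (default 0.25); 0 gives
#'   all diameters equal to the median.
#' @param compositions List of `list(ratio = c(dopc, eggsm, chol),
#'   prob = p)`; probabilities must sum to 1.
#' @param internal_solution,external_solution [solute_mixture()] defaults:
#'   0.75 M sucrose inside, 0.35 M glucose + 0.2 M NaCl outside
#'   (iso-osmotic).
#' @param excess_area_fraction Fraction of vesicles with excess membrane
#'   area/tubules (default 0.2).
#' @param aunp_fraction Fraction of AuNP-labelled vesicles (default 0).
#' @param clean_fusion_probability Bernoulli parameter for clean fusion
#'   under iso-osmotic conditions (default 0.82).
#' @param seed Integer RNG seed; logged into the generated table.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_vesicles = 50,
                            diameter_median_um = 5,
                            diameter_sdlog = 0.25,
                            compositions = list(
                              list(ratio = c(1, 1, 1), prob = 1)),
                            internal_solution = solute_mixture(sucrose = 0.75),
                            external_solution = solute_mixture(glucose = 0.35,
                                                               nacl = 0.2),
                            excess_area_fraction = 0.2,
                            aunp_fraction = 0,
                            clean_fusion_probability = 0.82,
                            seed = 1L) {
  stopifnot(is.numeric(n_vesicles), n_vesicles >= 1,
            diameter_median_um > 0, diameter_sdlog >= 0,
            is.list(compositions), length(compositions) >= 1)
  probs <- vapply(compositions, function(x) x$prob, numeric(1))
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("composition probabilities must sum to 1", call. = FALSE)
  }
  for (frac in c(excess_area_fraction, aunp_fraction,
                 clean_fusion_probability)) {
    if (frac < 0 || frac > 1) {
      stop("fractions/probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(
    n_vesicles = as.integer(n_vesicles),
    diameter_median_um = diameter_median_um,
    diameter_sdlog = diameter_sdlog,
    compositions = compositions,
    internal_solution = internal_solution,
    external_solution = external_solution,
    excess_area_fraction = excess_area_fraction,
    aunp_fraction = aunp_fraction,
    clean_fusion_probability = clean_fusion_probability,
    seed = as.integer(seed)
  ), class = "population_spec")
}

#' Generate a synthetic vesicle population table
#'
#' Samples diameters from the log-normal, assigns compositions by the
#' specified probabilities and draws the excess-area and AuNP flags, all
#' under the spec's seed (bit-reproducible; the seed is recorded in the
#' table's `rng_seed` attribute and `seed` column).
#'
#' @param spec A [population_spec()].
#' @return A data frame with columns `id`, `diameter_um`, `dopc`, `eggsm`,
#'   `chol`, `internal_osm`, `external_osm`, `aunp`, `excess_area`, `seed`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_vesicles
  osm_in <- osmolarity(spec$internal_solution)
  osm_out <- osmolarity(spec$external_solution)
  tab <- withr::with_seed(spec$seed, {
    diam <- if (spec$diameter_sdlog == 0) {
      rep(spec$diameter_median_um, n)
    } else {
      stats::rlnorm(n, meanlog = log(spec$diameter_median_um),
                    sdlog = spec$diameter_sdlog)
    }
    probs <- vapply(spec$compositions, function(x) x$prob, numeric(1))
    which_comp <- sample.int(length(spec$compositions), n, replace = TRUE,
                             prob = probs)
    ratios <- t(vapply(spec$compositions,
                       function(x) as.numeric(x$ratio), numeric(3)))
    data.frame(
      id = seq_len(n),
      diameter_um = diam,
      dopc = ratios[which_comp, 1],
      eggsm = ratios[which_comp, 2],
      chol = ratios[which_comp, 3],
      internal_osm = osm_in,
      external_osm = osm_out,
      aunp = stats::runif(n) < spec$aunp_fraction,
      excess_area = stats::runif(n) < spec$excess_area_fraction,
      seed = spec$seed
    )
  })
  attr(tab, "rng_seed") <- spec$seed
  tab
}

#' Turn one population-table row into a vesicle object
#'
#' @param row One-row slice of a [generate_population()] table.
#' @param internal_solution,external_solution [solute_mixture()] objects
#'   matching the table's osmolarity columns.
#' @return A [vesicle()].
#' @export
row_to_vesicle <- function(row, internal_solution, external_solution) {
  vesicle(
    radius_um = row$diameter_um / 2,
    composition = ternary_composition(row$dopc, row$eggsm, row$chol),
    internal_solution = internal_solution,
    external_solution = external_solution,
    has_excess_area = isTRUE(row$excess_area),
    aunp_labelled = isTRUE(row$aunp)
  )
}

#' Simulate a seeded campaign of laser-triggered fusion events
#'
#' Pairs vesicles consecutively (rows 1+2, 3+4, ...) and classifies each
#' attempted fusion with [classify_fusion()] under the campaign conditions.
#' The osmotic ratio is taken from the table's osmolarity columns via the
#' ideal-osmometer rule. One RNG stream, seeded once, drives all draws;
#' identical inputs and seed give a bit-identical event table.
#'
#' @param population A [generate_population()] table with at least
#'   `2 * n_events` rows.
#' @param n_events Number of fusion attempts.
#' @param conditions List: `laser_power_mw` (default 200),
#'   `clean_probability` (default 0.82), `fusion_threshold_mw`
#'   (default 150).
#' @param seed Integer RNG seed for the campaign.
#' @return A data frame with one row per event: radii, osmotic ratio,
#'   outcome, post-fusion radius, area deficit and an exact volume audit.
#' @export
simulate_fusion_campaign <- function(population, n_events,
                                     conditions = list(), seed = 1L) {
  stopifnot(is.data.frame(population), n_events >= 1)
  if (nrow(population) < 2 * n_events) {
    stop("population has ", nrow(population), " vesicles; ",
         2 * n_events, " are needed for ", n_events, " pairings",
         call. = FALSE)
  }
  laser <- conditions$laser_power_mw %||% 200
  p_clean <- conditions$clean_probability %||% 0.82
  threshold <- conditions$fusion_threshold_mw %||% 150

  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(n_events), function(k) {
      a <- population[2 * k - 1, ]
      b <- population[2 * k, ]
      r1 <- a$diameter_um / 2
      r2 <- b$diameter_um / 2
      ratio <- a$internal_osm / a$external_osm
      ev <- classify_fusion(
        list(vesicle(r1), vesicle(r2)),
        laser_power_mw = laser, osmotic_ratio = ratio,
        clean_probability = p_clean, fusion_threshold_mw = threshold
      )
      data.frame(
        event = k, id_a = a$id, id_b = b$id,
        r1_um = r1, r2_um = r2,
        laser_power_mw = laser, osmotic_ratio = ratio,
        outcome = ev$outcome,
        post_radius_um = if (is.null(ev$post_fusion_vesicle)) NA_real_
                         else ev$post_fusion_vesicle$radius_um,
        area_deficit = ev$area_deficit,
        volume_in_um3 = ev$volume_audit[["volume_in_um3"]],
        volume_out_um3 = ev$volume_audit[["volume_out_um3"]],
        seed = as.integer(seed)
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate a random domain configuration
#'
#' Emulates a vesicle carrying several isolated liquid-disordered domains:
#' the requested total Ld area (a fraction of the vesicle surface
#' \eqn{4\pi R^2}, at most 0.5 so every cap and any merged cap stays within
#' a hemisphere) is partitioned among `n_domains` by a flat
#' Dirichlet(1, ..., 1) draw — a uniform split of the simplex.
#'
#' @param n_domains Number of domains, >= 1.
#' @param total_ld_area_fraction Fraction of the vesicle area occupied by
#'   Ld domains, in (0, 0.5].
#' @param vesicle_radius_um Host vesicle radius in um.
#' @param seed Integer RNG seed.
#' @param line_tension_pn Line tension passed to the configuration
#'   (default 1 pN).
#' @return A [domain_configuration()]; the seed is stored in its
#'   `rng_seed` field attribute.
#' @export
generate_domain_configuration <- function(n_domains, total_ld_area_fraction,
                                          vesicle_radius_um, seed = 1L,
                                          line_tension_pn = 1) {
  stopifnot(n_domains >= 1, vesicle_radius_um > 0)
  if (total_ld_area_fraction <= 0 || total_ld_area_fraction > 0.5) {
    stop("total_ld_area_fraction must lie in (0, 0.5] so all caps (and ",
         "their merges) stay within a hemisphere", call. = FALSE)
  }
  total_area <- total_ld_area_fraction * 4 * pi * vesicle_radius_um^2
  areas <- withr::with_seed(as.integer(seed), {
    g <- stats::rgamma(n_domains, shape = 1)
    g / sum(g) * total_area
  })
  # exact conservation of the requested total despite floating renormalisation
  areas[n_domains] <- total_area - sum(areas[-n_domains])
  doms <- lapply(areas, membrane_domain, phase = "Ld",
                 host_vesicle_radius_um = vesicle_radius_um)
  config <- domain_configuration(vesicle_radius_um, doms,
                                 line_tension_pn = line_tension_pn)
  attr(config, "rng_seed") <- as.integer(seed)
  config
}
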