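#' Spherical-cap membrane domain
#'
#' A coexisting-phase domain on a vesicle of radius \eqn{R} is modelled as
#' an in-plane spherical cap of area \eqn{A = 2\pi R^2(1-\cos\alpha)} with
#' half-angle \eqn{\alpha \le 90^\circ} (at most a hemisphere). The bulged
#' out-of-plane geometry seen experimentally — which shortens the boundary
#' further and kinetically stabilises multiple domains against spontaneous
#' coalescence — is not resolved geometrically; it is represented only by
#' the configuration-level `kinetically_trapped` flag.
#'
#' @param phase `"Ld"` or `"Lo"`.
#' @param area_um2 Domain area in um^2, in \eqn{(0, 2\pi R^2]}.
#' @param host_vesicle_radius_um Radius \eqn{R} of the host vesicle in um.
#' @return An object of class `membrane_domain` with the derived cap
#'   half-angle `alpha` (radians).
#' @export
membrane_domain <- function(phase, area_um2, host_vesicle_radius_um) {
  phase <- match.arg(phase, c("Ld", "Lo"))
  stopifnot(is.numeric(area_um2), is.numeric(host_vesicle_radius_um))
  if (host_vesicle_radius_um <= 0) {
    stop("host vesicle radius must be > 0", call. = FALSE)
  }
  hemi <- 2 * pi * host_vesicle_radius_um^2
  if (area_um2 <= 0 || area_um2 > hemi * (1 + 1e-12)) {
    stop("domain area must lie in (0, 2*pi*R^2]: the cap model covers at ",
         "most a hemisphere", call. = FALSE)
  }
  alpha <- acos(max(1 - area_um2 / hemi, -1))
  structure(list(phase = phase, area_um2 = area_um2,
                 host_vesicle_radius_um = host_vesicle_radius_um,
                 alpha = alpha),
            class = "membrane_domain")
}

#' In-plane boundary length of a spherical-cap domain
#'
#' \eqn{L = 2\pi R \sin\alpha}. In the flat-disc limit
#' (\eqn{A/R^2 \to 0}) this tends to \eqn{2\sqrt{\pi A}}.
#'
#' @param d A [membrane_domain()].
#' @return Boundary length in um.
#' @export
boundary_length <- function(d) {
  stopifnot(inherits(d, "membrane_domain"))
  2 * pi * d$host_vesicle_radius_um * sin(d$alpha)
}

#' A configuration of domains on one vesicle
#'
#' @param vesicle_radius_um Host vesicle radius in um.
#' @param domains List of [membrane_domain()] objects on that vesicle;
#'   total area must not exceed the vesicle area \eqn{4\pi R^2}.
#' @param line_tension_pn Phase-boundary line tension in pN, >= 0.
#' @param temperature_c Configuration temperature in degC (metadata for
#'   [line_tension_at()] bookkeeping).
#' @param kinetically_trapped If TRUE (default), domains never merge
#'   spontaneously — bulging-induced repulsion holds them apart — and
#'   merges occur only when commanded via [merge_pair()] or
#'   [sequential_merge()] (the optical trap acting as an abstract actuator).
#' @return An object of class `domain_configuration`.
#' @export
domain_configuration <- function(vesicle_radius_um, domains,
                                 line_tension_pn = 1,
                                 temperature_c = 21,
                                 kinetically_trapped = TRUE) {
  stopifnot(is.numeric(vesicle_radius_um), vesicle_radius_um > 0,
            is.list(domains),
            all(vapply(domains, inherits, logical(1), "membrane_domain")),
            is.numeric(line_tension_pn), line_tension_pn >= 0)
  for (d in domains) {
    if (abs(d$host_vesicle_radius_um - vesicle_radius_um) > 1e-9) {
      stop("all domains must live on the configuration's vesicle radius",
           call. = FALSE)
    }
  }
  total <- sum(vapply(domains, function(d) d$area_um2, numeric(1)))
  if (total > 4 * pi * vesicle_radius_um^2 * (1 + 1e-12)) {
    stop("total domain area exceeds the vesicle area", call. = FALSE)
  }
  structure(list(vesicle_radius_um = vesicle_radius_um, domains = domains,
                 line_tension_pn = line_tension_pn,
                 temperature_c = temperature_c,
                 kinetically_trapped = kinetically_trapped),
            class = "domain_configuration")
}

#' @export
print.domain_configuration <- function(x, ...) {
  cat(sprintf(
    "Domain configuration: %d domain(s) on R = %.3g um, gamma = %.3g pN\n",
    length(x$domains), x$vesicle_radius_um, x$line_tension_pn))
  invisible(x)
}

#' Total line energy of a domain configuration
#'
#' \eqn{E = \gamma \sum_i L_i}: line tension times the summed boundary
#' lengths, in pN um (1 pN um = 1e-18 J). Shorter total boundary at fixed
#' \eqn{\gamma} means lower energy, which is why domain coalescence is
#' energetically favourable.
#'
#' @param config A [domain_configuration()].
#' @return Line energy in pN um.
#' @export
line_energy <- function(config) {
  stopifnot(inherits(config, "domain_configuration"))
  config$line_tension_pn *
    sum(vapply(config$domains, boundary_length, numeric(1)))
}

#' Temperature-dependent line tension
#'
#' Local laser heating lowers the line tension between coexisting phases,
#' reducing domain bulging and the inter-domain repulsion. A linear ramp
#' vanishing at the miscibility temperature \eqn{T_c} captures this:
#' \deqn{\gamma(T) = \gamma_{ref} \max\{0, (T_c - T)/(T_c - T_{ref})\}.}
#'
#' @param gamma_ref_pn Reference line tension in pN at `t_ref_c`.
#' @param t_ref_c Reference temperature in degC; must be below `t_c_c`.
#' @param t_c Temperature(s) in degC at which to evaluate. Vectorised.
#' @param t_crit_c Miscibility (critical) temperature in degC.
#' @return Line tension(s) in pN, >= 0.
#' @export
line_tension_at <- function(gamma_ref_pn, t_ref_c, t_c, t_crit_c) {
  stopifnot(is.numeric(gamma_ref_pn), is.numeric(t_ref_c),
            is.numeric(t_c), is.numeric(t_crit_c))
  if (t_ref_c >= t_crit_c) {
    stop("reference temperature must be below the miscibility temperature",
         call. = FALSE)
  }
  if (gamma_ref_pn < 0) stop("line tension must be >= 0", call. = FALSE)
  gamma_ref_pn * pmax(0, (t_crit_c - t_c) / (t_crit_c - t_ref_c))
}

#' Merge two domains of the same phase
#'
#' Replaces domains `i` and `j` by a single cap whose area is the exact sum
#' of the two (area conserved by construction). Because cap boundary length
#' is a concave function of area vanishing at zero, the merged boundary is
#' never longer than the summed boundaries, so the line-energy change is
#' always <= 0. Merging across phases, or a merged cap exceeding a
#' hemisphere, is rejected.
#'
#' @param config A [domain_configuration()].
#' @param i,j Distinct domain indices.
#' @return A list with `config` (the post-merge configuration) and `event`,
#'   a `merge_event`: merged indices, pre/post boundary lengths, and the
#'   line-energy change in pN um.
#' @export
merge_pair <- function(config, i, j) {
  stopifnot(inherits(config, "domain_configuration"))
  n <- length(config$domains)
  if (!(i %in% seq_len(n)) || !(j %in% seq_len(n)) || i == j) {
    stop("i and j must be distinct valid domain indices", call. = FALSE)
  }
  di <- config$domains[[i]]
  dj <- config$domains[[j]]
  if (di$phase != dj$phase) {
    stop("unsupported case: cannot merge domains of different phases (",
         di$phase, " vs ", dj$phase, ")", call. = FALSE)
  }
  merged_area <- di$area_um2 + dj$area_um2
  hemi <- 2 * pi * config$vesicle_radius_um^2
  if (merged_area > hemi * (1 + 1e-12)) {
    stop("unsupported case: merged cap would exceed a hemisphere",
         call. = FALSE)
  }
  merged <- membrane_domain(di$phase, merged_area, config$vesicle_radius_um)
  pre_boundary <- boundary_length(di) + boundary_length(dj)
  post_boundary <- boundary_length(merged)
  keep <- config$domains[-c(i, j)]
  new_config <- domain_configuration(
    config$vesicle_radius_um, c(keep, list(merged)),
    line_tension_pn = config$line_tension_pn,
    temperature_c = config$temperature_c,
    kinetically_trapped = config$kinetically_trapped
  )
  event <- structure(list(
    merged_indices = c(i, j),
    phase = di$phase,
    area_um2 = merged_area,
    pre_boundary_um = pre_boundary,
    post_boundary_um = post_boundary,
    energy_change_pn_um = config$line_tension_pn *
      (post_boundary - pre_boundary)
  ), class = "merge_event")
  list(config = new_config, event = event)
}

#' Sequentially merge all domains into one
#'
#' Emulates the trap-driven experiment in which isolated domains are
#' dragged into contact one after another: nine initial domains collapse to
#' a single incrementally growing domain through eight fusion events.
#' Whatever the order, `n` domains always take exactly `n - 1` merge events
#' and conserve total area; total line energy is non-increasing along the
#' sequence.
#'
#' @param config A [domain_configuration()] with >= 1 domain.
#' @param order `"left-to-right"` (default: repeatedly merge the first two
#'   domains in list order) or a list of index pairs, each interpreted
#'   against the configuration as it stands when that merge is applied
#'   (merged domains are appended at the end of the list).
#' @return A list with `config` (single-domain final configuration) and
#'   `events`, the list of `merge_event`s in order.
#' @export
sequential_merge <- function(config, order = "left-to-right") {
  stopifnot(inherits(config, "domain_configuration"))
  if (length(config$domains) < 1) {
    stop("configuration must contain at least one domain", call. = FALSE)
  }
  events <- list()
  if (identical(order, "left-to-right")) {
    while (length(config$domains) > 1) {
      step <- merge_pair(config, 1, 2)
      config <- step$config
      events[[length(events) + 1]] <- step$event
    }
  } else {
    stopifnot(is.list(order))
    for (pair in order) {
      step <- merge_pair(config, pair[1], pair[2])
      config <- step$config
      events[[length(events) + 1]] <- step$event
    }
    if (length(config$domains) != 1) {
      stop("supplied merge order did not reduce the configuration to a ",
           "single domain", call. = FALSE)
    }
  }
  list(config = config, events = events)
}

#' Tabulate a merge-event log
#'
#' @param events List of `merge_event`s from [sequential_merge()].
#' @return A data frame with one row per event: indices, merged area,
#'   pre/post boundary lengths and line-energy change.
#' @export
merge_events_table <- function(events) {
  data.frame(
    event = seq_along(events),
    index_i = vapply(events, function(e) e$merged_indices[1], numeric(1)),
    index_j = vapply(events, function(e) e$merged_indices[2], numeric(1)),
    phase = vapply(events, function(e) e$phase, character(1)),
    merged_area_um2 = vapply(events, function(e) e$area_um2, numeric(1)),
    pre_boundary_um = vapply(events, function(e) e$pre_boundary_um,
                             numeric(1)),
    post_boundary_um = vapply(events, function(e) e$post_boundary_um,
                              numeric(1)),
    energy_change_pn_um = vapply(events, function(e) e$energy_change_pn_um,
                                 numeric(1))
  )
}
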