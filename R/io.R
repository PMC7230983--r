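#' Write a data table as CSV with a provenance header
#'
#' Tables are written UTF-8 with a header row, "." decimal separator, and a
#' leading block of `#` comment lines recording the package version, the
#' RNG seed (if any) and a content hash — so every artifact states how it
#' was made. [read_table_csv()] skips the comment block.
#'
#' @param tab A data frame. A `rng_seed` attribute, if present, is recorded.
#' @param path Output path.
#' @param seed Optional seed to record (overrides the attribute).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path, seed = attr(tab, "rng_seed")) {
  stopifnot(is.data.frame(tab))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

provenance_lines <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("vesifuse"))
  c(paste0("# vesifuse ", v),
    if (!is.null(seed)) paste0("# rng_seed: ", seed))
}

#' Read and write domain configurations as JSON
#'
#' The on-disk form lists the vesicle radius, line tension, temperature and
#' one `{phase, area_um2}` record per domain.
#'
#' @param config A [domain_configuration()].
#' @param path File path.
#' @return `read_domain_configuration()` returns a
#'   [domain_configuration()]; the writer returns `path` invisibly.
#' @export
write_domain_configuration <- function(config, path) {
  stopifnot(inherits(config, "domain_configuration"))
  out <- list(
    vesicle_radius_um = config$vesicle_radius_um,
    line_tension_pn = config$line_tension_pn,
    temperature_c = config$temperature_c,
    kinetically_trapped = config$kinetically_trapped,
    rng_seed = attr(config, "rng_seed"),
    domains = lapply(config$domains, function(d) {
      list(phase = d$phase, area_um2 = d$area_um2)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_domain_configuration
#' @export
read_domain_configuration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  doms <- lapply(raw$domains, function(d) {
    membrane_domain(d$phase, d$area_um2, raw$vesicle_radius_um)
  })
  config <- domain_configuration(
    raw$vesicle_radius_um, doms,
    line_tension_pn = raw$line_tension_pn,
    temperature_c = raw$temperature_c %||% 21,
    kinetically_trapped = raw$kinetically_trapped %||% TRUE
  )
  if (!is.null(raw$rng_seed)) attr(config, "rng_seed") <- raw$rng_seed
  config
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of model parameters (vesicle radius, elastic modulus,
#' solution recipes, laser powers, seeds, ...) and validates basic unit
#' conventions: angles in degrees, lengths in um, powers in mW, tensions in
#' uN/m — recorded under a `units` block if present.
#'
#' @param path Path to a YAML file.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$units)) {
    allowed <- list(angle = "degrees", length = "um", power = "mW",
                    tension = "uN/m")
    for (nm in names(cfg$units)) {
      if (nm %in% names(allowed) && !identical(cfg$units[[nm]],
                                               allowed[[nm]])) {
        stop("unsupported unit for ", nm, ": ", cfg$units[[nm]],
             " (expected ", allowed[[nm]], ")", call. = FALSE)
      }
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Parse a solution recipe string
#'
#' Accepts strings like `"sucrose:0.75"` or `"glucose:0.35,nacl:0.2"`
#' (solute name, molar concentration) and returns the corresponding
#' [solute_mixture()].
#'
#' @param text Recipe string.
#' @return A [solute_mixture()].
#' @examples
#' osmolarity(parse_solution("glucose:0.35,nacl:0.2")) # 0.75
#' @export
parse_solution <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  parts <- strsplit(trimws(strsplit(text, ",")[[1]]), ":")
  conc <- vapply(parts, function(p) {
    if (length(p) != 2) {
      stop("malformed solution term; expected name:concentration",
           call. = FALSE)
    }
    as.numeric(p[2])
  }, numeric(1))
  names(conc) <- vapply(parts, function(p) trimws(p[1]), character(1))
  do.call(solute_mixture, as.list(conc))
}
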