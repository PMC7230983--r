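#!/usr/bin/env Rscript
# Generate the synthetic vesicle populations used by the downstream
# analyses: 100 iso-osmotic GUVs (0.75 M sucrose in, 0.35 M glucose +
# 0.2 M NaCl out) and 100 osmotically deflated ones (0.4 M glucose +
# 0.2 M NaCl out), both with c. 5 um median diameters.

suppressPackageStartupMessages(library(vesifuse))
dir.create("results", showWarnings = FALSE)

iso <- generate_population(population_spec(
  n_vesicles = 100, diameter_median_um = 5, seed = 101L,
  compositions = list(list(ratio = c(1, 1, 0), prob = 0.5),
                      list(ratio = c(1, 1, 3), prob = 0.5))))
write_table_csv(iso, "results/population_iso.csv")

deflated <- generate_population(population_spec(
  n_vesicles = 100, diameter_median_um = 5, seed = 102L,
  external_solution = solute_mixture(glucose = 0.4, nacl = 0.2)))
write_table_csv(deflated, "results/population_deflated.csv")

cat(sprintf("Iso-osmotic population: %d vesicles, median diameter %.2f um,",
            nrow(iso), median(iso$diameter_um)),
    sprintf("osmolarity %.2f / %.2f Osm/L (in/out)\n",
            iso$internal_osm[1], iso$external_osm[1]))
cat(sprintf("Deflated population:    %d vesicles, median diameter %.2f um,",
            nrow(deflated), median(deflated$diameter_um)),
    sprintf("osmolarity %.2f / %.2f Osm/L -> volume ratio %.4f\n",
            deflated$internal_osm[1], deflated$external_osm[1],
            deflated$internal_osm[1] / deflated$external_osm[1]))
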