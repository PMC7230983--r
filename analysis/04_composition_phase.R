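#!/usr/bin/env Rscript
# Compositional consequence of fusing a 1:1:0 GUV with a 1:1:3 GUV of
# identical size, under both mixing conventions, plus phase assignments of
# the study compositions on the shipped schematic diagram.

suppressPackageStartupMessages(library(vesifuse))
dir.create("results", showWarnings = FALSE)

dia <- read_phase_diagram()
c_gel <- ternary_composition(1, 1, 0)
c_la <- ternary_composition(1, 1, 3)

by_parts <- mix_amounts(c_gel, 1, c_la, 1)
by_area <- mix_fractions(c_gel, 1, c_la, 1)
cat("Mixing 1:1:0 with 1:1:3 (equal size):\n")
cat("  ratio-part rule   ->", paste(to_integer_ratio(by_parts),
                                    collapse = ":"),
    "->", phase_lookup(by_parts, dia), "\n")
cat("  area-weighted rule->", paste(to_integer_ratio(by_area),
                                    collapse = ":"),
    "->", phase_lookup(by_area, dia), "\n")

comps <- list(`1:1:0` = c_gel, `1:1:3` = c_la, `2:2:3` = by_parts,
              `1:1:1` = ternary_composition(1, 1, 1))
tab <- data.frame(
  composition = names(comps),
  dopc_frac = vapply(comps, function(c) c$fractions[["dopc"]], numeric(1)),
  eggsm_frac = vapply(comps, function(c) c$fractions[["eggsm"]], numeric(1)),
  chol_frac = vapply(comps, function(c) c$fractions[["chol"]], numeric(1)),
  phase = vapply(comps, phase_lookup, character(1), diagram = dia)
)
write_table_csv(tab, "results/phase_assignments.csv")
cat("Phase assignments written; note the diagram is schematic",
    "(see its provenance string).\n")
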