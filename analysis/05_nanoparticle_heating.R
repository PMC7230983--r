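#!/usr/bin/env Rscript
# Steady-state temperature field around a membrane-bound 150 nm AuNP
# (radius 75 nm) in water for a range of absorbed powers, and the extent
# of the zone heated above representative thresholds.

suppressPackageStartupMessages(library(vesifuse))
dir.create("results", showWarnings = FALSE)

r_nm <- 10^seq(log10(10), log10(1e4), length.out = 60)
powers_uw <- c(5, 10, 20, 60)

profiles <- do.call(rbind, lapply(powers_uw, function(p) {
  src <- np_heat_source(np_radius_nm = 75, absorbed_power_uw = p)
  data.frame(absorbed_power_uw = p, r_nm = r_nm,
             dt_c = temperature_at(src, r_nm))
}))
write_table_csv(profiles, "results/np_temperature_profiles.csv")

src60 <- np_heat_source(75, 60)
dts <- surface_temperature_rise(src60)
cat(sprintf("60 uW absorbed: surface rise %.0f degC (> 100 degC regime);\n",
            dts))
cat(sprintf("  above half the surface rise only out to %.0f nm (= 2a);\n",
            hot_zone_extent(src60, dts / 2)))
cat(sprintf("  at 2.5 um (half a vesicle diameter) the rise is %.1f degC.\n",
            temperature_at(src60, 2500)))
cat("Heating is confined to a region comparable to the particle size;",
    "the 4-6 degC bulk rise near the focus is a configured constant,",
    "not part of this localized field.\n")
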