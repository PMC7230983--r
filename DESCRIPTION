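Package: vesifuse
Title: Mechanics of Optically Driven Giant Vesicle and Membrane Domain Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative models for laser-assisted fusion of giant
    unilamellar vesicles (GUVs) and of coexisting membrane domains:
    truncated-sphere adhesion geometry with the closed-form area-increase
    law and the linear-elastic tension response, volume-conserving fusion
    bookkeeping with the associated membrane-area deficit, van't Hoff
    osmolarity and ideal-osmometer deflation, a stochastic
    clean-versus-disorderly fusion outcome classifier, ternary
    DOPC/EggSM/cholesterol composition mixing with phase-region lookup on a
    schematic ternary diagram, the steady-state temperature field around an
    optically heated membrane-bound gold nanoparticle, and a spherical-cap
    model of lipid domain coalescence with a sequential merge scheduler.
    Includes seeded generators for synthetic vesicle populations, fusion
    campaigns and domain configurations so the full workflow runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
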