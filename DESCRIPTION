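Package: trophamp
Title: Trophic Amplification Diagnostics for Gridded Marine Ecosystem Ensembles
Version: 0.1.0
Authors@R: person("trophamp", "maintainers", email = "trophamp@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how climate-driven changes in net primary
    production propagate through marine food webs in gridded multi-model
    ensembles. Computes decadal change maps of net primary production, sea
    surface temperature and total consumer biomass, classifies every ocean
    cell into six biomass response types (positive/negative amplification,
    attenuation, inversion), derives the amplification ratio R, builds
    multi-model agreement maps by majority vote, bins R against warming, and
    disaggregates the amplification signal across size classes. Includes a
    seeded synthetic pseudo-ensemble generator with analytically known ground
    truth, minimal NetCDF-3 (classic) input/output for ISIMIP-like annual
    per-variable files, and a config-driven command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
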