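Package: isomox
Title: Isotope-Tracer Quantification of Methane Oxidation, Denitrification
    and Methanotroph Growth in Stratified Lake Waters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification chain for stable-isotope tracer studies of
    methane-cycling microbial communities in stratified water columns.
    Converts 13C-methane and 15N-nitrate incubation time series into
    volumetric rates of methane oxidation to CO2, denitrification (30N2
    production with headspace-dilution correction and isotope pairing), and
    methane-carbon assimilation into biomass; computes zone-wise Fickian
    methane fluxes from concentration-depth profiles; derives single-cell
    carbon assimilation and growth rates of methanotroph morphotypes from
    nanoSIMS region-of-interest ion counts (Poisson counting-error
    filtering, background-corrected excess enrichment, biovolume-to-carbon
    allometry); and aggregates CARD-FISH morphotype counts into population
    densities and biomass. A seeded synthetic-data generator reproduces the
    statistical structure of every input so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
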