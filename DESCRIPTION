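Package: vesikin
Title: Copy-Number Stoichiometry and Kinetics of Nanoparticle-Delivered mRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Absolute quantification toolbox for therapeutic mRNA tracked
    through lipid nanoparticles (LNPs), recipient cells, and secreted
    extracellular vesicles (EVs). Computes sequence-based nucleotide and
    amino-acid compositions and molecular weights, converts masses to
    molecule copy numbers (copies per particle, per cell, per EV; protein
    copies per mRNA), fits qPCR standard curves for absolute quantification
    with an R-squared quality gate, summarizes nanoparticle tracking and
    radiolabel-uptake measurements, locates kinetic peaks and compartment
    contrasts with the matching nonparametric test battery (Mann-Whitney,
    Kruskal-Wallis and Friedman with Dunn's post hoc), and ships a seeded
    compartmental simulator that generates synthetic assay datasets with the
    statistical structure of the wet-lab measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
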