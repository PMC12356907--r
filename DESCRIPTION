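Package: nucleodensity
Title: Dry-Mass Densitometry and Pressure-Balance Modelling of Nuclear
    Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline from refractive-index tomograms to
    subcellular dry-mass densities, and a colloid-osmotic pressure-balance
    model of nuclear assembly and growth. Converts optical diffraction
    tomography style refractive-index stacks into per-compartment volumes,
    dry masses and mean densities, computes nucleocytoplasmic density,
    volume and mass ratios, books osmotically active protein-complex
    concentrations and chromatin mass, and simulates nuclear volume and
    density as a quasi-static balance of colloid osmotic and chromatin
    pressure under perturbations (import inhibition, ploidy swap, extract
    dilution, senescence, cleavage). A seeded synthetic-data module stands
    in for the microscope: 3D phantoms with ground truth, assembly time
    courses and cleavage-stage embryo lineages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
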