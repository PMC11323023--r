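Package: coacervkit
Title: Quantitative Analysis of Peptide Coacervation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis chain of peptide
    liquid-liquid phase separation (coacervation) studies: multi-site
    Henderson-Hasselbalch charge speciation and isoelectric points for short
    peptides, coacervate formulation stoichiometry (weight percent, molarity,
    peptide:partner charge ratios, turbidity), a charged-droplet Rayleigh
    stability model converting zeta potential and droplet size into
    interfacial tension via the Grahame equation, composite small-angle
    X-ray scattering (SAXS) form-factor fitting (Porod power law plus
    generalized Gaussian coil plus correlation peak), and regularized
    non-negative inversion of dynamic light scattering (DLS) correlograms
    into hydrodynamic-radius distributions. Includes seeded synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
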