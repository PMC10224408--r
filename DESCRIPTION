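Package: leadsieve
Title: Descriptor-Based Lead Selection and Docking Post-Processing for
    Small-Molecule Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audited multi-criteria virtual-screening pipeline for small
    molecule libraries. Computes a physicochemical descriptor panel (Ertl TPSA,
    Wildman-Crippen WlogP and molar refractivity, Moriguchi MlogP, atom and
    bond counts), evaluates the Lipinski, Ghose, Veber, Egan and Muegge
    drug-likeness rule sets and the CNS multiparameter-optimization score,
    and runs a configurable ten-step elimination cascade over server-derived
    ADMET annotations with a full per-compound audit trail. Also provides
    acute-toxicity LD50 banding to OECD categories, site-of-metabolism
    scoring, and docking post-processing: inhibition constants from binding
    free energies, FullFitness cluster energetics, symmetry-corrected RMSD
    between poses, binding-site selection, polar-contact detection and
    active-torsion counts. A seeded synthetic-data module generates compound
    libraries, annotation tables and docking fixtures so the whole pipeline
    is testable without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ChemmineR,
    ChemmineOB,
    bio3d,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
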